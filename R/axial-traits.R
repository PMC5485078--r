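# Construction of the four analysis traits from specimen observations:
# length ratio (neck/trunk), count ratio (cervical/dorsal), unit length ratio
# (mean cervical vertebra length / mean dorsal vertebra length) and presacral
# count (cervical + dorsal). Vertebral counts recorded as ranges are resolved
# by uniform randomization, repeated across replicates so downstream results
# carry the count uncertainty.

validate_specimen_records <- function(records) {
  needed <- c(
    "taxon_id", "cervical_lo", "cervical_hi",
    "dorsal_lo", "dorsal_hi", "neck_length", "trunk_length"
  )
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0) {
    abort(paste0("Specimen table is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (nrow(records) == 0) {
    abort("Specimen table is empty.")
  }
  for (region in c("cervical", "dorsal")) {
    lo <- records[[paste0(region, "_lo")]]
    hi <- records[[paste0(region, "_hi")]]
    bad <- !is.na(lo) & !is.na(hi) & lo > hi
    if (any(bad)) {
      abort(paste0(
        "Inverted ", region, " count range for: ",
        paste(records$taxon_id[bad], collapse = ", ")
      ))
    }
    if (any(lo < 1, na.rm = TRUE)) {
      abort(paste0("All ", region, " counts must be >= 1."))
    }
  }
  for (len in c("neck_length", "trunk_length")) {
    if (any(records[[len]] <= 0, na.rm = TRUE)) {
      abort(paste0("`", len, "` must be positive where present."))
    }
  }
  invisible(records)
}

#' Resolve ambiguous vertebral counts by uniform randomization
#'
#' Where the cervical/dorsal boundary cannot be determined unambiguously a
#' taxon's count is recorded as an integer range `[lo, hi]`. For each
#' replicate a count is drawn uniformly from that range, independently per
#' taxon and per replicate, producing `n_replicates` resolved datasets that
#' together carry the count uncertainty through the analysis. Taxa with point
#' counts (`lo == hi`) are identical in every replicate.
#'
#' @param records tibble of specimen observations with columns `taxon_id`,
#'   `cervical_lo`, `cervical_hi`, `dorsal_lo`, `dorsal_hi`, `neck_length`,
#'   `trunk_length` (lengths in mm, `NA` = missing; `lo == hi` for point
#'   counts).
#' @param n_replicates number of randomized datasets (100 in a production
#'   run).
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @return A tibble with columns `replicate_id`, `taxon_id`,
#'   `cervical_count`, `dorsal_count`, `neck_length`, `trunk_length`,
#'   containing `n_replicates` resolved copies of the dataset.
#' @examples
#' recs <- tibble::tibble(
#'   taxon_id = c("a", "b"), cervical_lo = c(7, 35), cervical_hi = c(7, 37),
#'   dorsal_lo = c(14, 20), dorsal_hi = c(14, 20),
#'   neck_length = c(700, NA), trunk_length = c(5000, 2000)
#' )
#' resolve_ambiguous_counts(recs, n_replicates = 3, seed = 1)
#' @export
resolve_ambiguous_counts <- function(records, n_replicates = 100, seed = NULL) {
  validate_specimen_records(records)
  if (n_replicates < 1) {
    abort("`n_replicates` must be >= 1.")
  }
  n <- nrow(records)
  draw_one <- function(lo, hi) {
    lo <- as.integer(lo)
    hi <- as.integer(hi)
    out <- rep(NA_integer_, length(lo))
    ok <- !is.na(lo) & !is.na(hi)
    width <- hi[ok] - lo[ok] + 1L
    out[ok] <- lo[ok] + as.integer(floor(runif(sum(ok)) * width) %% width)
    out
  }
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      tibble(
        replicate_id = r,
        taxon_id = records$taxon_id,
        cervical_count = draw_one(records$cervical_lo, records$cervical_hi),
        dorsal_count = draw_one(records$dorsal_lo, records$dorsal_hi),
        neck_length = records$neck_length,
        trunk_length = records$trunk_length
      )
    })
  })
}

#' Compute the four axial analysis traits from resolved counts
#'
#' Adds, per taxon (and per replicate when a `replicate_id` column is
#' present):
#' * `length_ratio` = neck length / trunk length (body proportions);
#' * `count_ratio` = cervical count / dorsal count (homeotic
#'   regionalization);
#' * `unit_length_ratio` = (neck/cervical) / (trunk/dorsal), the mean length
#'   of a cervical vertebra relative to a dorsal one (post-patterning
#'   growth);
#' * `presacral_count` = cervical + dorsal (somitogenesis).
#'
#' A trait whose inputs include a missing measurement is `NA`, never zero;
#' count-only traits are still computed when lengths are missing.
#' Algebraically `length_ratio = count_ratio * unit_length_ratio` whenever
#' all three are defined.
#'
#' @param resolved tibble with columns `taxon_id`, `cervical_count`,
#'   `dorsal_count`, `neck_length`, `trunk_length` (e.g. output of
#'   [resolve_ambiguous_counts()]).
#' @return The input tibble with the four trait columns appended and an
#'   attribute `scale = "raw"`.
#' @export
compute_traits <- function(resolved) {
  needed <- c("taxon_id", "cervical_count", "dorsal_count", "neck_length", "trunk_length")
  miss <- setdiff(needed, names(resolved))
  if (length(miss) > 0) {
    abort(paste0("Resolved table is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (any(resolved$cervical_count < 1, na.rm = TRUE) ||
    any(resolved$dorsal_count < 1, na.rm = TRUE)) {
    abort("Resolved counts must be positive integers.")
  }
  if (any(resolved$trunk_length <= 0, na.rm = TRUE) ||
    any(resolved$neck_length <= 0, na.rm = TRUE)) {
    abort("Lengths must be positive where present.")
  }
  out <- resolved %>%
    mutate(
      length_ratio = .data$neck_length / .data$trunk_length,
      count_ratio = .data$cervical_count / .data$dorsal_count,
      unit_length_ratio = (.data$neck_length / .data$cervical_count) /
        (.data$trunk_length / .data$dorsal_count),
      presacral_count = .data$cervical_count + .data$dorsal_count
    )
  attr(out, "scale") <- "raw"
  out
}

#' Natural-log transform of the four analysis traits
#'
#' Returns the trait table with `length_ratio`, `count_ratio`,
#' `unit_length_ratio` and `presacral_count` replaced by their natural logs,
#' for analyses on the proportional scale. All present values must be
#' positive.
#'
#' @param traits output of [compute_traits()].
#' @return The table with logged trait columns and attribute `scale = "log"`.
#' @export
log_transform_traits <- function(traits) {
  cols <- c("length_ratio", "count_ratio", "unit_length_ratio", "presacral_count")
  miss <- setdiff(cols, names(traits))
  if (length(miss) > 0) {
    abort(paste0("Trait table is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (identical(attr(traits, "scale"), "log")) {
    abort("Trait table is already on the log scale.")
  }
  for (cl in cols) {
    if (any(traits[[cl]] <= 0, na.rm = TRUE)) {
      abort(paste0("Non-positive value in `", cl, "`; cannot log-transform."))
    }
  }
  out <- traits %>% mutate(across(dplyr::all_of(cols), log))
  attr(out, "scale") <- "log"
  out
}

#' Diagnostic for analysis scale: contrast magnitude vs node estimate
#'
#' Tests whether the magnitude of inferred evolutionary change (the absolute
#' standardized independent contrast at each internal node) correlates with
#' the trait value estimated at that node. A significant positive
#' correlation indicates variance growing with the trait value, i.e. that a
#' proportional (log) scale is more appropriate; a non-significant result
#' licenses analysis on the raw scale. Pearson product-moment correlation is
#' used.
#'
#' @param data tibble with `taxon_id` and the trait column.
#' @param tree time-scaled binary `phylo` tree.
#' @param trait name of the trait column.
#' @param alpha significance level used for the `recommended_scale` verdict.
#' @return One-row tibble: `trait`, `estimate` (correlation), `p.value`,
#'   `n` (contrasts), `status` (`"ok"` or `"undefined"` when the trait is
#'   constant so all contrasts are zero), `recommended_scale`.
#' @export
scale_diagnostic <- function(data, tree, trait, alpha = 0.05) {
  pr <- prune_to_trait(tree, data, trait)
  if (ape::Ntip(pr$tree) < 4) {
    abort("Need at least four taxa with trait values for the scale diagnostic.")
  }
  eng <- pic_engine(pr$tree, pr$values)
  std <- eng$contrast / eng$sd
  if (all(abs(std) < .Machine$double.eps^0.5)) {
    return(tibble(
      trait = trait, estimate = NA_real_, p.value = NA_real_,
      n = length(std), status = "undefined", recommended_scale = NA_character_
    ))
  }
  ct <- cor.test(abs(std), eng$node_estimate, method = "pearson")
  tibble(
    trait = trait,
    estimate = unname(ct$estimate),
    p.value = ct$p.value,
    n = length(std),
    status = "ok",
    recommended_scale = if (ct$p.value < alpha && ct$estimate > 0) "log" else "raw"
  )
}

#' Read a specimen observation table from CSV
#'
#' Expects columns `taxon_id`, `cervical_lo`, `cervical_hi`, `dorsal_lo`,
#' `dorsal_hi`, `neck_length`, `trunk_length`; empty cells are missing
#' values, and `lo == hi` encodes a point count.
#'
#' @param path path to the CSV file.
#' @return A validated specimen tibble.
#' @export
read_specimen_records <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_specimen_records(df)
  df
}
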