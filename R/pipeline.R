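# Orchestration across trees x count-randomization replicates, mirroring the
# 100-tree design. By default replicate i of the count randomization is
# analyzed on tree i (one-to-one pairing, preserving one analysis per tree);
# a fully crossed trees x replicates design is also supported. Per-cell
# failures are logged and skipped, never silently dropped.

#' Build a run manifest for [run_full_analysis()]
#'
#' @param trees list of trees: rooted binary cladograms (to be time-scaled;
#'   supply `ranges` and `outgroup_ages`) or already time-scaled trees.
#' @param records specimen tibble (see [resolve_ambiguous_counts()]).
#' @param ranges stratigraphic interval tibble, required when time-scaling.
#' @param outgroup_ages successively older calibrating ages (Ma), required
#'   when time-scaling.
#' @param t0,n_bins dating options passed to [hedman_timescale()].
#' @param constrain `NULL`, or `list(tips =, max_age =)` applying a hard
#'   maximum node age (e.g. `max_age = 208.5` for a Rhaetian bound on a
#'   clade's basal node) by isotropic compression.
#' @param clade_tips tip labels whose MRCA defines the focal clade used for
#'   rate comparisons and the period factor (e.g. Plesiosauria).
#' @param ratebm `NULL` to skip rate inference, or a list with elements
#'   `trait` (default `"presacral_count"`), `n_generations`, `thin`,
#'   `n_chains` (default 2), `burnin_frac` (default 0.25), `n_perm`
#'   (default 499).
#' @param log_scale analyze log-transformed traits?
#' @param alpha significance level for summaries.
#' @param eps_pure pure-change tolerance for the decomposition.
#' @param pairing `"paired"` analyzes count-randomization replicate i on
#'   tree i (one analysis per tree, the default); `"crossed"` analyzes every
#'   replicate on every tree.
#' @param n_replicates number of count-randomization replicates; defaults to
#'   the number of trees under `"paired"`.
#' @param seed master seed; per-cell seeds are derived deterministically.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(trees, records, ranges = NULL, outgroup_ages = NULL,
                         t0 = NULL, n_bins = 1000, constrain = NULL,
                         clade_tips = NULL, ratebm = NULL, log_scale = FALSE,
                         alpha = 0.05, eps_pure = 0.05,
                         pairing = c("paired", "crossed"),
                         n_replicates = NULL, seed = 1) {
  pairing <- match.arg(pairing)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) abort("Supply at least one tree.")
  if (is.null(n_replicates)) n_replicates <- length(trees)
  if (pairing == "paired" && n_replicates != length(trees)) {
    abort("Paired design needs as many replicates as trees.")
  }
  validate_specimen_records(records)
  if (!is.null(ratebm)) {
    ratebm$trait <- ratebm$trait %||% "presacral_count"
    ratebm$n_generations <- ratebm$n_generations %||% 2e5
    ratebm$thin <- ratebm$thin %||% max(1L, as.integer(ratebm$n_generations / 1000))
    ratebm$n_chains <- ratebm$n_chains %||% 2L
    ratebm$burnin_frac <- ratebm$burnin_frac %||% 0.25
    ratebm$n_perm <- ratebm$n_perm %||% 499L
    if (is.null(clade_tips)) {
      abort("Rate comparisons need `clade_tips` to define the branch partition.")
    }
  }
  structure(
    list(
      trees = trees, records = records, ranges = ranges,
      outgroup_ages = outgroup_ages, t0 = t0, n_bins = n_bins,
      constrain = constrain, clade_tips = clade_tips, ratebm = ratebm,
      log_scale = log_scale, alpha = alpha, eps_pure = eps_pure,
      pairing = pairing, n_replicates = n_replicates, seed = seed
    ),
    class = "run_manifest"
  )
}

# The regression battery run on every (tree, replicate) cell: the three
# univariate PIC fits, the bivariate fit, the count-ratio ~ presacral fit,
# and the non-phylogenetic tip-value fit.
regression_models <- function() {
  list(
    lr_on_cr = list(response = "length_ratio", predictors = "count_ratio"),
    lr_on_ulr = list(response = "length_ratio", predictors = "unit_length_ratio"),
    lr_on_cr_ulr = list(
      response = "length_ratio",
      predictors = c("count_ratio", "unit_length_ratio")
    ),
    cr_on_psc = list(response = "count_ratio", predictors = "presacral_count")
  )
}

#' Run the full analysis across trees and replicates
#'
#' For each (tree i, replicate i) pair: time-scale the cladogram if needed
#' (optionally applying the hard node-age constraint), resolve ambiguous
#' counts, compute the four traits (optionally log-transformed), fit the PIC
#' regression battery (three univariate fits, the bivariate fit, count ratio
#' on presacral count) plus the non-phylogenetic regression, run the
#' period-interaction ANCOVA and the cervical/dorsal decomposition, and -
#' when requested - infer variable-rate BM posteriors for the focal trait
#' and compare clade rates by t-test and permutation test. Failures in any
#' cell are collected in `$failures` and the cell skipped.
#'
#' @param manifest a [run_manifest()].
#' @return A list of tibbles: `regressions`, `raw_regressions`, `ancova`,
#'   `decomposition`, `rate_tests`, `r2_summary`, `significance`, `failures`,
#'   plus `traits` (per-replicate trait tables) and the manifest hash in
#'   attribute `manifest_hash` (embedded in every table).
#' @export
run_full_analysis <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  m <- manifest
  hash <- rlang::hash(m)
  cells <- if (m$pairing == "paired") {
    tibble(tree_id = seq_along(m$trees), replicate_id = seq_along(m$trees))
  } else {
    tidyr::expand_grid(
      tree_id = seq_along(m$trees),
      replicate_id = seq_len(m$n_replicates)
    )
  }
  resolved <- resolve_ambiguous_counts(m$records,
    n_replicates = m$n_replicates, seed = m$seed
  )
  traits_all <- compute_traits(resolved)
  if (m$log_scale) traits_all <- log_transform_traits(traits_all)

  regs <- raws <- ancv <- deco <- rtst <- fails <- list()
  for (cell_idx in seq_len(nrow(cells))) {
    i <- cells$tree_id[cell_idx]
    j <- cells$replicate_id[cell_idx]
    cell_seed <- m$seed + 1000L * i + 7L * j
    cell <- tryCatch(
      {
        tree <- m$trees[[i]]
        if (is.null(tree$edge.length)) {
          ages <- sample_tip_ages(m$ranges, seed = cell_seed)
          tree <- hedman_timescale(tree, ages, m$outgroup_ages,
            t0 = m$t0, n_bins = m$n_bins, seed = cell_seed + 1L
          )
        }
        if (!is.null(m$constrain)) {
          tree <- constrain_node_age(
            tree, m$constrain$tips, m$constrain$max_age
          )
        }
        tr <- traits_all %>% filter(.data$replicate_id == j)
        reg_i <- purrr::imap_dfr(regression_models(), function(spec, nm) {
          fit <- pic_ols(tr, tree, spec$response, spec$predictors)
          glance(fit) %>%
            mutate(
              model = nm, tree_id = i, replicate_id = j,
              slope = fit$coefficients$estimate[1],
              p.value = fit$coefficients$p.value[1],
              .before = 1
            )
        })
        raw_i <- {
          fit <- raw_ols(tr, "length_ratio", "count_ratio")
          glance(fit) %>%
            mutate(
              model = "raw_lr_on_cr", tree_id = i, replicate_id = j,
              slope = fit$coefficients$estimate[2],
              p.value = fit$coefficients$p.value[2],
              .before = 1
            )
        }
        anc_i <- if (!is.null(m$clade_tips)) {
          pic_ancova(tr, tree, "count_ratio", "presacral_count",
            scheme = "clade", clade_tips = m$clade_tips
          ) %>% mutate(tree_id = i, replicate_id = j, .before = 1)
        } else {
          NULL
        }
        dec_i <- pure_change_decomposition(tr, tree,
          logged = m$log_scale, eps = m$eps_pure
        ) %>%
          as_tibble() %>%
          mutate(tree_id = i, replicate_id = j, .before = 1)
        rt_i <- NULL
        if (!is.null(m$ratebm)) {
          chains <- purrr::map(seq_len(m$ratebm$n_chains), function(ci) {
            rjmcmc_sample(tr, tree, m$ratebm$trait,
              n_generations = m$ratebm$n_generations, thin = m$ratebm$thin,
              seed = cell_seed + 10L + ci
            )
          })
          comb <- combine_chains(chains, burnin_frac = m$ratebm$burnin_frac)
          part <- clade_partition(
            comb$tree, intersect(m$clade_tips, comb$tree$tip.label)
          )
          summ <- branch_rate_summary(comb) %>%
            left_join(part %>% select("child", "in_clade"), by = "child")
          tt <- compare_clade_rates_ttest(summ)
          pt <- permutation_test_posteriors(comb, part,
            n_perm = m$ratebm$n_perm, seed = cell_seed + 99L
          )
          rt_i <- tibble(
            tree_id = i, replicate_id = j, trait = m$ratebm$trait,
            rate_min = min(summ$median), rate_max = max(summ$median),
            t_statistic = tt$statistic, t_p.value = tt$p.value,
            perm_p.value = pt$p.value
          )
        }
        list(reg = reg_i, raw = raw_i, anc = anc_i, dec = dec_i, rt = rt_i)
      },
      error = function(e) {
        structure(list(msg = conditionMessage(e)), class = "cell_failure")
      }
    )
    if (inherits(cell, "cell_failure")) {
      fails[[length(fails) + 1L]] <- tibble(
        tree_id = i, replicate_id = j, error = cell$msg
      )
    } else {
      regs[[cell_idx]] <- cell$reg
      raws[[cell_idx]] <- cell$raw
      ancv[[cell_idx]] <- cell$anc
      deco[[cell_idx]] <- cell$dec
      rtst[[cell_idx]] <- cell$rt
    }
  }

  regressions <- bind_rows(regs)
  rate_tests <- bind_rows(rtst)
  out <- list(
    traits = traits_all,
    regressions = regressions,
    raw_regressions = bind_rows(raws),
    ancova = bind_rows(ancv),
    decomposition = bind_rows(deco),
    rate_tests = rate_tests,
    r2_summary = if (nrow(regressions) > 0) {
      median_r2_across_trees(regressions)
    } else {
      tibble()
    },
    significance = if (nrow(rate_tests) > 0) {
      summarize_significance_fraction(rate_tests$t_p.value, alpha = m$alpha)
    } else {
      tibble()
    },
    failures = bind_rows(fails)
  )
  out <- purrr::map(out, function(x) {
    attr(x, "manifest_hash") <- hash
    x
  })
  attr(out, "manifest_hash") <- hash
  out
}

#' Fraction of trees with a significant result
#'
#' @param p_values per-tree p-values.
#' @param alpha significance level (default 0.05).
#' @return One-row tibble: `fraction`, `n_significant`, `n`.
#' @export
summarize_significance_fraction <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) abort("No p-values supplied.")
  tibble(
    fraction = mean(p_values < alpha),
    n_significant = sum(p_values < alpha),
    n = length(p_values)
  )
}
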