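# Standardized phylogenetic independent contrasts and the regression
# machinery built on them: through-origin OLS (univariate and multivariate),
# ANCOVA with a time-period interaction, non-phylogenetic OLS on tip values,
# and the cervical/dorsal pure-change decomposition.

#' Standardized phylogenetic independent contrasts
#'
#' Felsenstein's pruning algorithm: at each cherry the contrast is the
#' difference of the two (tip or reconstructed) values, its expected
#' standard deviation is the square root of the summed adjusted branch
#' durations, the ancestral value is the variance-weighted mean, and the
#' parent branch is extended by `v1*v2/(v1+v2)`. Standardized contrasts are
#' raw contrasts divided by their expected SD; each corresponds to one
#' internal node and is a point estimate of the evolutionary rate at that
#' node. Taxa missing the trait are pruned first (per-trait pruning).
#'
#' @param data tibble with `taxon_id` and the trait column (one row per
#'   taxon), or a named numeric vector.
#' @param tree binary time-scaled `phylo` tree with positive durations.
#' @param trait trait column name.
#' @return A tibble of class `pic_set` with one row per internal node of the
#'   pruned tree: `node`, `contrast` (raw), `sd`, `std_contrast`,
#'   `node_estimate`, `node_age` (Ma), `trait`.
#' @export
standardized_pics <- function(data, tree, trait = NULL) {
  if (is.data.frame(data)) {
    if (is.null(trait)) abort("Supply `trait` when `data` is a data frame.")
    pr <- prune_to_trait(tree, data, trait)
  } else {
    keep <- names(data)[!is.na(data)]
    sub <- if (length(keep) < ape::Ntip(tree)) ape::keep.tip(tree, keep) else tree
    pr <- list(tree = sub, values = data[sub$tip.label])
    trait <- trait %||% "trait"
  }
  eng <- pic_engine(pr$tree, pr$values)
  ages <- node_ages(pr$tree)
  out <- tibble(
    node = eng$node,
    contrast = eng$contrast,
    sd = eng$sd,
    std_contrast = eng$contrast / eng$sd,
    node_estimate = eng$node_estimate,
    node_age = ages$age[eng$node],
    trait = trait
  )
  class(out) <- c("pic_set", class(out))
  attr(out, "tree") <- pr$tree
  out
}

# Contrasts for several traits on the taxa jointly complete for all of
# them, so node sets match across traits. Returns a wide tibble of
# standardized contrasts plus node ages, and the pruned tree.
joint_pics <- function(data, tree, traits) {
  traits <- unique(traits)
  miss <- setdiff(c("taxon_id", traits), names(data))
  if (length(miss) > 0) {
    abort(paste0("Missing columns: ", paste(miss, collapse = ", ")))
  }
  sub <- data %>% filter(.data$taxon_id %in% tree$tip.label)
  ok <- complete.cases(sub[traits])
  sub <- sub[ok, , drop = FALSE]
  if (nrow(sub) < 3) abort("Fewer than three taxa are complete for all traits.")
  pr_tree <- if (nrow(sub) < ape::Ntip(tree)) {
    prune_to_trait(tree, sub, traits[1])$tree
  } else {
    tree
  }
  wide <- NULL
  for (tr in traits) {
    p <- standardized_pics(sub, pr_tree, tr)
    cols <- setNames(tibble(p$std_contrast), tr)
    if (is.null(wide)) {
      wide <- bind_cols(tibble(node = p$node, node_age = p$node_age), cols)
    } else {
      wide <- bind_cols(wide, cols)
    }
  }
  list(pics = wide, tree = pr_tree)
}

new_axevol_ols <- function(fit, data, response, predictors, through_origin,
                           n, positivized) {
  sm <- summary(fit)
  coefs <- as_tibble(sm$coefficients, rownames = "term")
  names(coefs) <- c("term", "estimate", "std.error", "statistic", "p.value")
  structure(
    list(
      fit = fit, data = data, response = response, predictors = predictors,
      coefficients = coefs, r.squared = sm$r.squared, n = n,
      through_origin = through_origin, positivized = positivized
    ),
    class = "axevol_ols"
  )
}

#' @export
print.axevol_ols <- function(x, ...) {
  cat(
    "<axevol_ols> ", x$response, " ~ ", paste(x$predictors, collapse = " + "),
    if (x$through_origin) " (through origin, standardized PICs)" else " (tip values)",
    "\n  n = ", x$n, ", R^2 = ", signif(x$r.squared, 4), "\n",
    sep = ""
  )
  for (i in seq_len(nrow(x$coefficients))) {
    cat(
      "  ", x$coefficients$term[i], ": slope ",
      signif(x$coefficients$estimate[i], 4), ", p = ",
      format.pval(x$coefficients$p.value[i], digits = 3), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Through-origin OLS regression of standardized contrasts
#'
#' Regresses the response trait's standardized contrasts on one or more
#' predictor traits' contrasts, with the intercept suppressed (contrasts
#' have arbitrary sign, so the regression must pass through the origin).
#' R-squared uses the through-origin definition `1 - RSS / sum(y^2)`. By
#' default each node's contrasts are "positivized": signs are flipped so the
#' first predictor's contrast is non-negative, the standard treatment for
#' through-origin contrast regression (R-squared is unaffected). All traits
#' are computed on the taxa jointly complete for them, so node sets match.
#'
#' @param data tibble with `taxon_id` and the trait columns.
#' @param tree binary time-scaled `phylo` tree.
#' @param response response trait column name.
#' @param predictors character vector of predictor trait column names.
#' @param positivize flip contrast signs so the first predictor is
#'   non-negative?
#' @return An `axevol_ols` object; see [tidy()] and [glance()] methods.
#' @export
pic_ols <- function(data, tree, response, predictors, positivize = TRUE) {
  jp <- joint_pics(data, tree, c(response, predictors))
  d <- jp$pics
  if (nrow(d) < length(predictors) + 1) {
    abort("Fewer contrasts than regression parameters.")
  }
  if (positivize) {
    flip <- sign(d[[predictors[1]]])
    flip[flip == 0] <- 1
    for (tr in c(response, predictors)) d[[tr]] <- d[[tr]] * flip
  }
  # regress a copy so a trait can be regressed on itself (lm drops a
  # response that reappears on the right-hand side)
  d[[".response"]] <- d[[response]]
  fml <- stats::as.formula(sprintf(
    ".response ~ 0 + %s",
    paste(sprintf("`%s`", predictors), collapse = " + ")
  ))
  fit <- lm(fml, data = d)
  new_axevol_ols(fit, select(d, -".response"), response, predictors,
    through_origin = TRUE, n = nrow(d), positivized = positivize
  )
}

#' Ordinary (non-phylogenetic) regression of tip values
#'
#' Intercept-included OLS of the observed trait values across taxa, with no
#' phylogenetic correction; the cross-sectional complement to [pic_ols()].
#'
#' @param data tibble with `taxon_id` and the trait columns.
#' @param response,predictors trait column names.
#' @return An `axevol_ols` object.
#' @export
raw_ols <- function(data, response, predictors) {
  keep <- complete.cases(data[c(response, predictors)])
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < length(predictors) + 2) abort("Need at least 3 complete pairs.")
  for (p in predictors) {
    if (var(d[[p]]) == 0) abort(paste0("Predictor `", p, "` is constant."))
  }
  fml <- stats::as.formula(sprintf(
    "`%s` ~ %s", response,
    paste(sprintf("`%s`", predictors), collapse = " + ")
  ))
  fit <- lm(fml, data = d)
  new_axevol_ols(fit, as_tibble(d), response, predictors,
    through_origin = FALSE, n = nrow(d), positivized = FALSE
  )
}

# Assign each contrast/node to a time-period group. Clade scheme: nodes
# inside the clade (MRCA of `clade_tips`) are the second level. Age scheme:
# nodes older than `age_boundary` (Ma) are "Triassic".
node_period <- function(pics, tree, scheme = c("clade", "age"),
                        clade_tips = NULL, age_boundary = 201.3) {
  scheme <- match.arg(scheme)
  if (scheme == "clade") {
    if (is.null(clade_tips)) abort("Supply `clade_tips` for the clade scheme.")
    clade_tips <- intersect(clade_tips, tree$tip.label)
    if (length(clade_tips) < 2) {
      abort("Fewer than two clade tips remain after per-trait pruning.")
    }
    node <- mrca_node(tree, clade_tips)
    inside <- c(node, descendant_nodes(tree, node))
    factor(
      ifelse(pics$node %in% inside, "Jurassic-Cretaceous", "Triassic"),
      levels = c("Triassic", "Jurassic-Cretaceous")
    )
  } else {
    factor(
      ifelse(pics$node_age > age_boundary, "Triassic", "Jurassic-Cretaceous"),
      levels = c("Triassic", "Jurassic-Cretaceous")
    )
  }
}

#' ANCOVA of contrasts with a time-period interaction
#'
#' Fits the through-origin model `y ~ 0 + x + x:period` on standardized
#' contrasts and tests whether the regression slope differs between periods
#' (Triassic vs Jurassic-Cretaceous). Periods are assigned per node either
#' by clade membership (default; e.g. plesiosaurian vs non-plesiosaurian
#' nodes, matching split-subset analyses) or by node age against a geological
#' boundary.
#'
#' @param data tibble with `taxon_id` and the trait columns.
#' @param tree binary time-scaled `phylo` tree.
#' @param response,predictor trait column names.
#' @param scheme `"clade"` or `"age"` period assignment.
#' @param clade_tips tip labels whose MRCA defines the second-period clade.
#' @param age_boundary boundary age (Ma) for the `"age"` scheme; default
#'   201.3 (Triassic-Jurassic).
#' @param period optional custom assignment overriding `scheme`: a function
#'   of node age (Ma) returning one of the two period labels per node.
#' @param positivize flip signs so predictor contrasts are non-negative.
#' @return One-row tibble: per-group slopes and sizes, `estimate` (slope
#'   difference, second minus first group), `statistic` (t), `p.value`, `n`.
#' @export
pic_ancova <- function(data, tree, response, predictor,
                       scheme = c("clade", "age"), clade_tips = NULL,
                       age_boundary = 201.3, period = NULL,
                       positivize = TRUE) {
  jp <- joint_pics(data, tree, c(response, predictor))
  d <- jp$pics
  d$period <- if (is.function(period)) {
    lv <- c("Triassic", "Jurassic-Cretaceous")
    out <- vapply(d$node_age, period, character(1))
    if (!all(out %in% lv)) {
      abort("`period` must return 'Triassic' or 'Jurassic-Cretaceous'.")
    }
    factor(out, levels = lv)
  } else {
    node_period(d, jp$tree,
      scheme = scheme, clade_tips = clade_tips,
      age_boundary = age_boundary
    )
  }
  if (any(table(d$period) < 3)) {
    abort("Each period group needs at least three contrasts.")
  }
  if (positivize) {
    flip <- sign(d[[predictor]])
    flip[flip == 0] <- 1
    d[[response]] <- d[[response]] * flip
    d[[predictor]] <- d[[predictor]] * flip
  }
  d$x <- d[[predictor]]
  d$y <- d[[response]]
  fit <- lm(y ~ 0 + x + x:period, data = d)
  sm <- summary(fit)$coefficients
  int_row <- grep(":period", rownames(sm))
  slopes <- tapply(seq_len(nrow(d)), d$period, function(i) {
    unname(coef(lm(y ~ 0 + x, data = d[i, ])))
  })
  tibble(
    response = response, predictor = predictor,
    slope_triassic = slopes[["Triassic"]],
    slope_jurassic_cretaceous = slopes[["Jurassic-Cretaceous"]],
    estimate = unname(sm[int_row, "Estimate"]),
    statistic = unname(sm[int_row, "t value"]),
    p.value = unname(sm[int_row, "Pr(>|t|)"]),
    n_triassic = sum(d$period == "Triassic"),
    n_jurassic_cretaceous = sum(d$period == "Jurassic-Cretaceous"),
    n = nrow(d)
  )
}

#' Pure-change geometry for a set of contrast pairs
#'
#' Given paired contrasts of cervical (`c`) and dorsal (`d`) counts, returns
#' the perpendicular distances to the pure-homeotic line `d = -c` (constant
#' presacral total), `|c + d| / sqrt(2)`, and to the pure-somitogenetic line
#' `d = c` (constant count ratio), `|c - d| / sqrt(2)`, plus the magnitudes
#' of change along each diagonal. A point lies on a line iff the
#' corresponding distance is zero.
#'
#' @param cervical,dorsal numeric vectors of paired contrasts.
#' @return A tibble: `cervical`, `dorsal`, `dist_homeotic`,
#'   `dist_somitogenetic`, `mag_homeotic`, `mag_somitogenetic`.
#' @export
decomposition_geometry <- function(cervical, dorsal) {
  if (length(cervical) != length(dorsal)) {
    abort("`cervical` and `dorsal` must have matching nodes.")
  }
  tibble(
    cervical = cervical,
    dorsal = dorsal,
    dist_homeotic = abs(cervical + dorsal) / sqrt(2),
    dist_somitogenetic = abs(cervical - dorsal) / sqrt(2),
    mag_homeotic = abs(cervical - dorsal) / sqrt(2),
    mag_somitogenetic = abs(cervical + dorsal) / sqrt(2)
  )
}

#' Decompose cervical/dorsal contrasts into pure-change components
#'
#' For each internal node, compares the standardized contrast of cervical
#' count (`c`) with that of dorsal count (`d`). On the raw scale the
#' pure-homeotic expectation is the line `d = -c` (vertebrae reallocated
#' between neck and trunk at constant presacral total); the perpendicular
#' distance `|c + d| / sqrt(2)` measures the co-occurring somitogenetic
#' change. On the log scale the pure-somitogenetic expectation is `d = c`
#' (proportional change at constant cervical/dorsal ratio); the distance
#' `|c - d| / sqrt(2)` measures the co-occurring homeotic change. Each node
#' gets both distances, the magnitude of change along the relevant diagonal,
#' and a pure-change classification at tolerance `eps`.
#'
#' Contrast pairs keep a shared node orientation (the cervical contrast's
#' sign fixes the dorsal's), since the sign relationship is the object of
#' study.
#'
#' @param data tibble with `taxon_id`, `cervical_count`, `dorsal_count`.
#' @param tree binary time-scaled `phylo` tree.
#' @param logged analyze natural-log counts (pure-somitogenetic reference)
#'   instead of raw counts (pure-homeotic reference)?
#' @param eps tolerance (standardized units) below which the
#'   alternative-mechanism distance counts as zero, classifying the node as
#'   a pure change.
#' @return A tibble of class `axevol_decomposition`: `node`, `node_age`,
#'   `cervical`, `dorsal` (standardized contrasts), `dist_homeotic`,
#'   `dist_somitogenetic` (perpendicular distances to the two reference
#'   lines), `magnitude` (along the relevant diagonal), `pure` (logical).
#' @export
pure_change_decomposition <- function(data, tree, logged = FALSE, eps = 0.05) {
  d2 <- data
  if (logged) {
    if (any(d2$cervical_count <= 0 | d2$dorsal_count <= 0, na.rm = TRUE)) {
      abort("Counts must be positive to log-transform.")
    }
    d2$cervical_count <- log(d2$cervical_count)
    d2$dorsal_count <- log(d2$dorsal_count)
  }
  jp <- joint_pics(d2, tree, c("cervical_count", "dorsal_count"))
  cc <- jp$pics$cervical_count
  dd <- jp$pics$dorsal_count
  # orient each node pair by the cervical contrast's sign
  flip <- sign(cc)
  flip[flip == 0] <- 1
  cc <- cc * flip
  dd <- dd * flip
  geom <- decomposition_geometry(cc, dd)
  out <- bind_cols(
    tibble(node = jp$pics$node, node_age = jp$pics$node_age),
    geom
  ) %>%
    mutate(
      magnitude = if (logged) .data$mag_somitogenetic else .data$mag_homeotic,
      pure = if (logged) {
        .data$dist_somitogenetic < eps
      } else {
        .data$dist_homeotic < eps
      }
    )
  class(out) <- c("axevol_decomposition", class(out))
  attr(out, "logged") <- logged
  attr(out, "eps") <- eps
  out
}

#' Summarize R-squared across trees and replicates
#'
#' Median, minimum and maximum of the coefficient of determination across a
#' set of per-tree regression results, reported as percentages (grouped by
#' `model` when that column is present).
#'
#' @param results tibble with an `r.squared` column (e.g. the `regressions`
#'   table from [run_full_analysis()]).
#' @return A tibble with `median_r2_pct`, `min_r2_pct`, `max_r2_pct`, `n`
#'   (per model where applicable).
#' @export
median_r2_across_trees <- function(results) {
  if (nrow(results) == 0) abort("No regression results supplied.")
  if (!"r.squared" %in% names(results)) abort("Need an `r.squared` column.")
  grouped <- if ("model" %in% names(results)) {
    results %>% group_by(.data$model)
  } else {
    results
  }
  grouped %>%
    summarise(
      median_r2_pct = 100 * median(.data$r.squared),
      min_r2_pct = 100 * min(.data$r.squared),
      max_r2_pct = 100 * max(.data$r.squared),
      n = n(),
      .groups = "drop"
    )
}
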