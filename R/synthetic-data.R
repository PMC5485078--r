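# Synthetic data with the statistical structure the pipeline assumes:
# non-ultrametric birth-death fossil trees with stratigraphic tip intervals,
# (multi-rate, optionally correlated) Brownian traits with known ground
# truth, and specimen tables with count-range ambiguity and missingness.
# Every generator is seed-reproducible and returns its ground truth so
# recovery can be tested end to end.

#' Simulate a non-ultrametric fossil tree with stratigraphic ranges
#'
#' Forward birth-death simulation over a fixed time span in which extinct
#' lineages are retained as dated tips, giving the non-ultrametric shape of
#' fossil phylogenies. Simulation repeats until at least `n_tips` lineages
#' are produced; the tree is then uniformly downsampled to exactly `n_tips`
#' tips (fossil datasets are themselves downsampled to taxa with data). Each
#' tip receives a stratigraphic interval whose width is uniform between
#' `interval_width[1]` and `interval_width[2]` Myr, positioned uniformly
#' around the true age and truncated at the present.
#'
#' @param n_tips number of tips returned.
#' @param birth,death speciation/extinction rates (events/lineage/Myr);
#'   `birth > death >= 0`. Defaults give the high-turnover regime typical of
#'   Mesozoic marine reptile clades.
#' @param time_span total simulated history (Myr); the default spans a
#'   Mesozoic-scale 180 Myr.
#' @param interval_width range (Myr) of stratigraphic interval widths.
#' @param root_age age (Ma) of the root, placing the span in absolute time;
#'   defaults to `time_span` so surviving lineages are extant (age 0).
#' @param seed integer seed.
#' @param max_retries attempts before giving up when lineages keep dying out.
#' @param downsample if `FALSE`, keep every simulated lineage instead of
#'   downsampling to exactly `n_tips` (`n_tips` then acts as a minimum).
#' @return A list: `tree` (a `phylo` with `root.time`), `ranges` (tibble of
#'   `taxon_id`, `interval_start`, `interval_end`), and `ages` (tibble of
#'   true tip ages, Ma).
#' @export
simulate_fossil_tree <- function(n_tips = 64, birth = 0.1, death = 0.08,
                                 time_span = 180, interval_width = c(1, 10),
                                 root_age = time_span, seed = NULL,
                                 max_retries = 200, downsample = TRUE) {
  if (birth <= death || death < 0) abort("Need `birth` > `death` >= 0.")
  if (n_tips < 3) abort("`n_tips` must be at least 3.")
  with_seed(seed, {
    tree <- NULL
    for (i in seq_len(max_retries)) {
      cand <- tryCatch(
        ape::rlineage(birth, death, Tmax = time_span),
        error = function(e) NULL
      )
      if (!is.null(cand) && ape::Ntip(cand) >= n_tips) {
        tree <- cand
        break
      }
    }
    if (is.null(tree)) {
      abort("Lineages died out before reaching `n_tips` in every retry.")
    }
    tree$root.time <- root_age
    if (downsample && ape::Ntip(tree) > n_tips) {
      ages_full <- node_ages(tree)
      drop <- sample(tree$tip.label, ape::Ntip(tree) - n_tips)
      pruned <- ape::drop.tip(tree, drop)
      anchor <- pruned$tip.label[1]
      tip_age <- ages_full$age[match(anchor, ages_full$label)]
      depth <- ape::node.depth.edgelength(pruned)[match(anchor, pruned$tip.label)]
      pruned$root.time <- tip_age + depth
      tree <- pruned
    }
    tree$tip.label <- paste0("t", seq_len(ape::Ntip(tree)))
    n_tips <- ape::Ntip(tree)
    age <- node_ages(tree) %>% filter(.data$is_tip)
    # extant tips can acquire a tiny negative age from floating point
    true_age <- pmax(age$age, 0)
    w <- runif(n_tips, interval_width[1], interval_width[2])
    u <- runif(n_tips)
    start <- true_age + w * u
    end <- pmax(true_age - w * (1 - u), 0)
    list(
      tree = tree,
      ranges = tibble(
        taxon_id = age$label, interval_start = start, interval_end = end
      ),
      ages = tibble(taxon_id = age$label, age = true_age)
    )
  })
}

# Per-edge rates implied by a base rate and clade-specific multipliers.
# shifts: tibble/list with elements `tips` (list of tip-label vectors or a
# single vector) and `multiplier`.
shift_edge_rates <- function(tree, sigma2, shifts = NULL) {
  rates <- rep(sigma2, nrow(tree$edge))
  if (is.null(shifts)) {
    return(rates)
  }
  if (!is.null(shifts$tips) && !is.list(shifts$tips)) {
    shifts <- list(tips = list(shifts$tips), multiplier = shifts$multiplier)
  }
  for (i in seq_along(shifts$multiplier)) {
    node <- mrca_node(tree, shifts$tips[[i]])
    flags <- clade_edge_flags(tree, node, include_stem = TRUE)
    rates[flags] <- rates[flags] * shifts$multiplier[i]
  }
  rates
}

#' Simulate a trait under (multi-rate) Brownian motion
#'
#' Gaussian increments per branch with variance `rate * duration`; the rate
#' is `sigma2` everywhere except inside the clades named in `shifts`, whose
#' rates are multiplied (stem branch included). The true per-branch rate map
#' is returned for recovery tests.
#'
#' @param tree time-scaled `phylo` tree.
#' @param sigma2 base Brownian variance (trait units^2/Myr).
#' @param shifts `NULL`, or a list with `tips` (tip-label vector, or list of
#'   vectors) and `multiplier` (numeric, same length) defining shifted
#'   clades.
#' @param root_state trait value at the root.
#' @param seed integer seed.
#' @return A list: `traits` (tibble `taxon_id`, `value`) and `rates` (tibble
#'   `edge`, `child`, `rate` in `tree$edge` order).
#' @export
simulate_multirate_bm <- function(tree, sigma2 = 1, shifts = NULL,
                                  root_state = 0, seed = NULL) {
  check_phylo(tree)
  rates <- shift_edge_rates(tree, sigma2, shifts)
  with_seed(seed, {
    ne <- nrow(tree$edge)
    inc <- rnorm(ne, 0, sqrt(rates * tree$edge.length))
    ntip <- ape::Ntip(tree)
    val <- rep(NA_real_, ntip + tree$Nnode)
    val[ntip + 1L] <- root_state
    pre <- ape::reorder.phylo(tree, "postorder")$edge
    ord <- match(
      paste(pre[, 1], pre[, 2]),
      paste(tree$edge[, 1], tree$edge[, 2])
    )
    for (i in rev(seq_len(nrow(pre)))) {
      val[pre[i, 2]] <- val[pre[i, 1]] + inc[ord[i]]
    }
    list(
      traits = tibble(taxon_id = tree$tip.label, value = val[seq_len(ntip)]),
      rates = tibble(
        edge = seq_len(ne), child = tree$edge[, 2], rate = rates
      )
    )
  })
}

#' Simulate two traits under correlated Brownian motion
#'
#' Bivariate BM: per-branch increments are bivariate normal with correlation
#' `rho` and variances `rates[i] * duration`. The cross-correlation of the
#' two traits' independent contrasts is a consistent estimator of `rho`, so
#' through-origin PIC regressions recover `R^2 = rho^2` on average.
#'
#' @param tree time-scaled `phylo` tree.
#' @param rho per-increment correlation, in `[-1, 1]`.
#' @param rates length-2 vector of Brownian variances.
#' @param root_state length-2 root values.
#' @param seed integer seed.
#' @return A tibble: `taxon_id`, `trait_x`, `trait_y`.
#' @export
simulate_correlated_traits <- function(tree, rho, rates = c(1, 1),
                                       root_state = c(0, 0), seed = NULL) {
  check_phylo(tree)
  if (abs(rho) > 1) abort("`rho` must lie in [-1, 1].")
  with_seed(seed, {
    ne <- nrow(tree$edge)
    len <- tree$edge.length
    z1 <- rnorm(ne)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(ne)
    inc_x <- sqrt(rates[1] * len) * z1
    inc_y <- sqrt(rates[2] * len) * z2
    ntip <- ape::Ntip(tree)
    vx <- vy <- rep(NA_real_, ntip + tree$Nnode)
    vx[ntip + 1L] <- root_state[1]
    vy[ntip + 1L] <- root_state[2]
    pre <- ape::reorder.phylo(tree, "postorder")$edge
    ord <- match(
      paste(pre[, 1], pre[, 2]),
      paste(tree$edge[, 1], tree$edge[, 2])
    )
    for (i in rev(seq_len(nrow(pre)))) {
      vx[pre[i, 2]] <- vx[pre[i, 1]] + inc_x[ord[i]]
      vy[pre[i, 2]] <- vy[pre[i, 1]] + inc_y[ord[i]]
    }
    tibble(
      taxon_id = tree$tip.label,
      trait_x = vx[seq_len(ntip)],
      trait_y = vy[seq_len(ntip)]
    )
  })
}

#' Simulate axial specimen records with count ambiguity and missingness
#'
#' Latent cervical and dorsal counts evolve by correlated Brownian motion on
#' the log scale (cervical counts more variable than dorsal, as observed in
#' sauropterygians) and are rounded to integers; counts are then nudged
#' minimally so every presacral total lies inside `presacral_envelope`.
#' Per-region unit vertebra lengths evolve as independent lognormal BM, and
#' neck/trunk lengths follow as count x unit length, so the recovered
#' count and length ratios of noiseless records reproduce the latent ratios
#' exactly. Count-range ambiguity of width 1-3 vertebrae is injected with
#' probability `ambiguity_prob` per count, and neck/trunk measurements are
#' deleted with probability `missing_prob`.
#'
#' @param tree time-scaled `phylo` tree.
#' @param root_counts length-2 vector: cervical and dorsal count at the root.
#' @param sigma2_log_counts length-2 vector of log-scale Brownian variances
#'   for cervical and dorsal counts (per Myr).
#' @param rho_counts correlation of cervical/dorsal log-count increments.
#' @param presacral_envelope permitted range of presacral totals.
#' @param sigma2_log_unit log-scale Brownian variance of the two unit
#'   vertebra lengths (per Myr).
#' @param root_unit_lengths length-2 vector: cervical and dorsal unit
#'   vertebra length at the root (mm).
#' @param ambiguity_prob probability that a count is recorded as a range.
#' @param ambiguity_widths integer widths (hi - lo) sampled for ranges.
#' @param missing_prob probability that each length measurement is missing.
#' @param seed integer seed.
#' @return A list: `records` (specimen tibble for
#'   [resolve_ambiguous_counts()]) and `truth` (tibble of latent counts,
#'   lengths and the four true traits per taxon).
#' @export
simulate_axial_specimens <- function(tree,
                                     root_counts = c(15, 22),
                                     sigma2_log_counts = c(2e-3, 4e-4),
                                     rho_counts = 0.4,
                                     presacral_envelope = c(19, 94),
                                     sigma2_log_unit = 5e-4,
                                     root_unit_lengths = c(40, 45),
                                     ambiguity_prob = 0.2,
                                     ambiguity_widths = 1:3,
                                     missing_prob = 0.2,
                                     seed = NULL) {
  check_phylo(tree)
  with_seed(seed, {
    counts <- simulate_correlated_traits(
      tree, rho_counts,
      rates = sigma2_log_counts,
      root_state = log(root_counts)
    )
    cerv <- pmax(1L, as.integer(round(exp(counts$trait_x))))
    dors <- pmax(1L, as.integer(round(exp(counts$trait_y))))
    # minimal nudge of the dorsal count keeps presacral totals inside the
    # envelope (cervical is the biologically variable region)
    tot <- cerv + dors
    dors <- dors + pmax(0L, presacral_envelope[1] - tot)
    tot <- cerv + dors
    over <- pmax(0L, tot - presacral_envelope[2])
    take_c <- pmin(over, cerv - 1L)
    cerv <- cerv - take_c
    dors <- dors - (over - take_c)
    if (any(dors < 1L)) abort("Presacral envelope infeasible for simulated counts.")
    units <- simulate_correlated_traits(
      tree, 0,
      rates = c(sigma2_log_unit, sigma2_log_unit),
      root_state = log(root_unit_lengths)
    )
    neck <- cerv * exp(units$trait_x)
    trunk <- dors * exp(units$trait_y)
    n <- ape::Ntip(tree)
    make_range <- function(count) {
      amb <- runif(n) < ambiguity_prob
      w <- sample(ambiguity_widths, n, replace = TRUE)
      off <- vapply(w, function(wi) sample.int(wi + 1L, 1L) - 1L, integer(1))
      lo <- ifelse(amb, pmax(1L, count - off), count)
      hi <- ifelse(amb, lo + w, count)
      list(lo = as.integer(lo), hi = as.integer(hi))
    }
    cr <- make_range(cerv)
    dr <- make_range(dors)
    neck_obs <- ifelse(runif(n) < missing_prob, NA_real_, neck)
    trunk_obs <- ifelse(runif(n) < missing_prob, NA_real_, trunk)
    records <- tibble(
      taxon_id = tree$tip.label,
      cervical_lo = cr$lo, cervical_hi = cr$hi,
      dorsal_lo = dr$lo, dorsal_hi = dr$hi,
      neck_length = neck_obs, trunk_length = trunk_obs
    )
    truth <- tibble(
      taxon_id = tree$tip.label,
      cervical_count = cerv, dorsal_count = dors,
      neck_length = neck, trunk_length = trunk,
      length_ratio = neck / trunk,
      count_ratio = cerv / dors,
      unit_length_ratio = (neck / cerv) / (trunk / dors),
      presacral_count = cerv + dors
    )
    list(records = records, truth = truth)
  })
}
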