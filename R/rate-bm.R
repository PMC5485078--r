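# Variable-rate Brownian motion by reversible-jump MCMC. The model places
# an unknown number k of rate shifts on branches; a shift multiplies the
# Brownian variance sigma^2 of its branch and all descendant branches until
# overridden. Priors: k ~ Poisson(log 2) truncated at the number of
# branches, multipliers ~ lognormal(0, 1.25), sigma^2_0 log-uniform on
# [1e-6, 1e6]; the root state is removed by REML so it carries no prior.

# postorder edge bookkeeping shared by the likelihood and sampler
rjmcmc_edge_data <- function(tree, x) {
  po <- postorder_edges(tree)
  e <- po$edge
  ne <- nrow(e)
  # postorder index of the edge above each edge's ancestor node (-1 at root)
  child_of <- match(e[, 1], e[, 2]) # edge whose child is this edge's parent
  child_of[is.na(child_of)] <- 0L
  list(
    anc = e[, 1] - 1L,
    des = e[, 2] - 1L,
    len = po$length,
    parent_edge = child_of - 1L,
    edge_tbl = tibble(
      edge = seq_len(ne),
      parent = e[, 1],
      child = e[, 2],
      child_label = ifelse(e[, 2] <= ape::Ntip(tree),
        tree$tip.label[pmin(e[, 2], ape::Ntip(tree))], NA_character_
      ),
      length = po$length
    ),
    xtip = as.numeric(x),
    ntip = ape::Ntip(tree),
    nnode = tree$Nnode
  )
}

#' Brownian-motion REML log-likelihood with per-branch rates
#'
#' Contrast-based (REML) log-likelihood of a continuous trait under Brownian
#' motion in which each branch duration is multiplied by its own rate
#' `sigma^2_b`. Equal to the dense multivariate-normal evaluation on the
#' rate-scaled covariance matrix, up to the REML elimination of the root
#' state.
#'
#' @param data tibble with `taxon_id` and the trait column, or a named
#'   numeric vector.
#' @param tree binary time-scaled `phylo` tree; all tips must have data
#'   (prune beforehand).
#' @param trait trait column name (ignored for a named vector).
#' @param rates per-branch rates in the order of `tree$edge` rows, or a
#'   single rate recycled to all branches.
#' @return The log-likelihood (scalar).
#' @export
bm_loglik <- function(data, tree, trait = NULL, rates = 1) {
  check_phylo(tree)
  check_binary(tree)
  x <- if (is.data.frame(data)) {
    if (is.null(trait)) abort("Supply `trait` when `data` is a data frame.")
    tip_values(tree, setNames(data[[trait]], data$taxon_id))
  } else {
    tip_values(tree, data)
  }
  if (anyNA(x)) abort("Missing tip values: prune the tree to taxa with data first.")
  if (any(rates <= 0)) abort("All branch rates must be positive.")
  ne <- nrow(tree$edge)
  rates <- rep_len(rates, ne)
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- match(
    paste(po$edge[, 1], po$edge[, 2]),
    paste(tree$edge[, 1], tree$edge[, 2])
  )
  ed <- rjmcmc_edge_data(tree, x)
  bm_pruning_loglik_cpp(
    ed$anc, ed$des, ed$len * rates[ord], ed$xtip, ed$ntip, ed$nnode
  )
}

#' Prior specification for the variable-rate BM sampler
#'
#' @param shift_rate mean of the (truncated) Poisson prior on the number of
#'   rate shifts; the default `log(2)` puts half the prior mass on k = 0.
#' @param mult_sdlog standard deviation (log scale) of the lognormal prior
#'   on shift multipliers.
#' @param sigma2_bounds lower/upper bounds of the log-uniform prior on the
#'   base rate.
#' @return A list of prior settings for [rjmcmc_sample()].
#' @export
rate_priors <- function(shift_rate = log(2), mult_sdlog = 1.25,
                        sigma2_bounds = c(1e-6, 1e6)) {
  stopifnot(shift_rate > 0, mult_sdlog > 0, sigma2_bounds[1] > 0,
    sigma2_bounds[2] > sigma2_bounds[1])
  list(
    shift_rate = shift_rate, mult_sdlog = mult_sdlog,
    sigma2_bounds = sigma2_bounds
  )
}

#' Proposal settings for the variable-rate BM sampler
#'
#' Weights follow the mix: 30% multiplier rescale, 20% base-rate rescale,
#' 10% add shift, 10% delete shift, 20% relocate shift, 10% swap
#' multipliers. Add and delete weights must be equal (the acceptance ratio
#' assumes it). Relocation proposes a uniformly chosen shift-free branch,
#' which is an exactly symmetric move.
#'
#' @param weights numeric vector of six move weights (rescale multiplier,
#'   rescale sigma2_0, add, delete, relocate, swap).
#' @param win_mult,win_s2 half-widths of the log-scale sliding windows.
#' @return A list of proposal settings for [rjmcmc_sample()].
#' @export
rate_proposals <- function(weights = c(0.3, 0.2, 0.1, 0.1, 0.2, 0.1),
                           win_mult = 1.0, win_s2 = 0.7) {
  stopifnot(length(weights) == 6, all(weights >= 0), win_mult > 0, win_s2 > 0)
  if (abs(weights[3] - weights[4]) > 1e-12) {
    abort("Add and delete move weights must be equal.")
  }
  list(weights = weights, win_mult = win_mult, win_s2 = win_s2)
}

#' Sample rate-shift configurations by reversible-jump MCMC
#'
#' Runs a single Markov chain over variable-rate Brownian-motion
#' configurations (shift count k, shift placements and multipliers, base
#' rate sigma^2_0) using Metropolis-Hastings-Green acceptance. Production
#' analyses use two independent chains of 5 million generations each,
#' combined with [combine_chains()] after discarding the first quarter as
#' burn-in; a short "test profile" (2e5 generations) is adequate for
#' simulation checks.
#'
#' @param data tibble with `taxon_id` and the trait column, or a named
#'   numeric vector of tip values. Taxa missing the trait are pruned.
#' @param tree binary time-scaled `phylo` tree.
#' @param trait trait column name (when `data` is a data frame).
#' @param n_generations chain length.
#' @param thin sampling interval; `n_generations/thin` samples are kept.
#' @param seed integer seed; the chain is deterministic given the seed.
#' @param priors see [rate_priors()].
#' @param proposals see [rate_proposals()].
#' @return A `posterior_chain` object: `$draws` (tibble of generation, k,
#'   sigma2_0, loglik), `$rates` (samples x branches matrix of per-branch
#'   rates), `$edges` (branch table keyed by child node), the pruned
#'   `$tree`, and acceptance diagnostics.
#' @export
rjmcmc_sample <- function(data, tree, trait = NULL, n_generations = 2e5,
                          thin = max(1L, as.integer(n_generations / 2000)),
                          seed = NULL, priors = rate_priors(),
                          proposals = rate_proposals()) {
  check_phylo(tree)
  if (n_generations < thin) abort("`n_generations` must be at least `thin`.")
  if (is.data.frame(data)) {
    if (is.null(trait)) abort("Supply `trait` when `data` is a data frame.")
    pr <- prune_to_trait(tree, data, trait)
    tree <- pr$tree
    x <- pr$values
  } else {
    x <- data[!is.na(data)]
    if (length(x) == 0) abort("All trait values are missing.")
    keep <- intersect(tree$tip.label, names(x))
    if (length(keep) < length(tree$tip.label)) {
      tree <- ape::keep.tip(tree, keep)
    }
    x <- x[tree$tip.label]
    trait <- trait %||% "trait"
  }
  check_binary(tree)
  ed <- rjmcmc_edge_data(tree, x)
  # start sigma2_0 at the single-rate REML estimate (mean squared
  # standardized contrast)
  eng <- pic_engine(tree, ed$xtip)
  s2_init <- mean((eng$contrast / eng$sd)^2)
  s2_init <- min(max(s2_init, priors$sigma2_bounds[1] * 10), priors$sigma2_bounds[2] / 10)

  res <- with_seed(seed, {
    rjmcmc_cpp(
      ed$anc, ed$des, ed$len, ed$parent_edge, ed$xtip, ed$ntip, ed$nnode,
      as.integer(n_generations), as.integer(thin),
      priors$shift_rate, priors$mult_sdlog,
      priors$sigma2_bounds[1], priors$sigma2_bounds[2],
      s2_init, proposals$weights, proposals$win_mult, proposals$win_s2
    )
  })
  moves <- c("rescale_mult", "rescale_sigma2", "add", "delete", "move", "swap")
  structure(
    list(
      draws = tibble(
        generation = res$generation, k = res$k,
        sigma2_0 = res$sigma2_0, loglik = res$loglik
      ),
      rates = res$rates,
      edges = ed$edge_tbl,
      tree = tree,
      trait = trait,
      thin = as.integer(thin),
      n_generations = as.integer(n_generations),
      burnin_frac = 0,
      acceptance = tibble(
        move = moves, proposed = res$proposed, accepted = res$accepted
      )
    ),
    class = "posterior_chain"
  )
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(
    "<posterior_chain> ", nrow(x$draws), " samples (thin ", x$thin,
    ", burn-in ", x$burnin_frac, ") over ", nrow(x$edges), " branches; trait: ",
    x$trait, "\n",
    sep = ""
  )
  invisible(x)
}

#' Combine independent chains after burn-in removal
#'
#' Discards the first `burnin_frac` of each chain's retained samples, then
#' concatenates the chains. The default quarter burn-in matches the
#' production protocol of two 5-million-generation chains.
#'
#' @param chains list of `posterior_chain` objects over the same tree and
#'   trait.
#' @param burnin_frac fraction of each chain discarded (0 <= f < 1).
#' @return A combined `posterior_chain`.
#' @export
combine_chains <- function(chains, burnin_frac = 0.25) {
  if (inherits(chains, "posterior_chain")) chains <- list(chains)
  if (length(chains) == 0) abort("No chains supplied.")
  if (burnin_frac < 0 || burnin_frac >= 1) abort("`burnin_frac` must be in [0, 1).")
  ref <- chains[[1]]
  for (ch in chains[-1]) {
    if (!identical(ch$edges$child, ref$edges$child) ||
      !identical(ch$tree$tip.label, ref$tree$tip.label)) {
      abort("Chains were run on different trees; cannot combine.")
    }
  }
  trimmed <- purrr::map(chains, function(ch) {
    n <- nrow(ch$draws)
    keep <- seq.int(floor(n * burnin_frac) + 1L, n)
    list(draws = ch$draws[keep, ], rates = ch$rates[keep, , drop = FALSE])
  })
  out <- ref
  out$draws <- bind_rows(purrr::map(trimmed, "draws"))
  out$rates <- do.call(rbind, purrr::map(trimmed, "rates"))
  out$burnin_frac <- burnin_frac
  acc <- purrr::compact(purrr::map(chains, "acceptance"))
  if (length(acc) == length(chains)) {
    out$acceptance <- bind_rows(acc) %>%
      group_by(.data$move) %>%
      summarise(
        proposed = sum(.data$proposed), accepted = sum(.data$accepted),
        .groups = "drop"
      )
  }
  out
}

ess_numeric <- function(x) {
  n <- length(x)
  if (n < 10) abort("Need at least 10 samples for an ESS estimate.")
  if (var(x) == 0 || !is.finite(var(x))) {
    return(c(ess = n, constant = 1))
  }
  c(ess = unname(coda::effectiveSize(coda::mcmc(x))), constant = 0)
}

#' Effective sample size of posterior scalar series
#'
#' Autocorrelation-time-based ESS (spectral estimate). For a
#' `posterior_chain` the log-likelihood, shift count and base rate series
#' are summarized, with a warning when any falls below `warn_below`
#' (production runs aim for ESS > 1000). Constant series are flagged and
#' reported at the raw sample count.
#'
#' @param x a `posterior_chain` or a numeric series.
#' @param warn_below warn when any ESS is below this value (chains only).
#' @param ... unused.
#' @return For chains, a tibble with `series`, `ess`, `constant`; for a
#'   numeric series, a single number (attribute `constant` when flagged).
#' @export
ess <- function(x, ...) UseMethod("ess")

#' @rdname ess
#' @export
ess.posterior_chain <- function(x, warn_below = 1000, ...) {
  out <- purrr::map_dfr(c("loglik", "k", "sigma2_0"), function(sc) {
    e <- ess_numeric(x$draws[[sc]])
    tibble(series = sc, ess = e[["ess"]], constant = e[["constant"]] == 1)
  })
  low <- out$series[out$ess < warn_below & !out$constant]
  if (length(low) > 0) {
    warn(paste0(
      "Effective sample size below ", warn_below, " for: ",
      paste(low, collapse = ", "), ". Consider longer chains."
    ))
  }
  out
}

#' @rdname ess
#' @export
ess.numeric <- function(x, ...) {
  e <- ess_numeric(x)
  structure(e[["ess"]], constant = e[["constant"]] == 1)
}

#' Posterior per-branch rate summaries
#'
#' Median and credible interval of the per-branch rate sigma^2_b across
#' post-burn-in samples, plus a classification of each branch as `"above"`,
#' `"below"` or `"at"` the tree-wide median rate (a branch is `"at"` when
#' its credible interval contains the tree-wide median), the scheme used to
#' color phenograms red/blue/gray.
#'
#' @param chain a `posterior_chain` (combine chains first).
#' @param prob credible-interval mass (default 0.9).
#' @return A tibble with one row per branch: `edge`, `child`, `child_label`,
#'   `median`, `lower`, `upper`, `class`.
#' @export
branch_rate_summary <- function(chain, prob = 0.9) {
  if (nrow(chain$draws) == 0) abort("Chain has no retained samples.")
  a <- (1 - prob) / 2
  med <- apply(chain$rates, 2, median)
  lo <- apply(chain$rates, 2, quantile, probs = a)
  hi <- apply(chain$rates, 2, quantile, probs = 1 - a)
  tree_med <- median(med)
  chain$edges %>%
    mutate(
      median = med, lower = lo, upper = hi,
      class = dplyr::case_when(
        lo <= tree_med & tree_med <= hi ~ "at",
        med > tree_med ~ "above",
        TRUE ~ "below"
      )
    ) %>%
    select(-dplyr::any_of("length"))
}

#' Welch t-test comparing branch rates between two clades
#'
#' Two-sample Welch t-test on per-branch posterior median rates between the
#' two sides of a branch partition (e.g. plesiosaurian vs non-plesiosaurian
#' branches). Degenerate input with identical constant rates on both sides
#' returns t = 0, p = 1.
#'
#' @param data tibble with a rate column and a logical/two-level partition
#'   column, e.g. [branch_rate_summary()] joined with [clade_partition()].
#' @param rate name of the rate column (default `"median"`).
#' @param partition name of the partition column (default `"in_clade"`).
#' @return One-row tibble: `estimate` (mean difference, first level minus
#'   second), `statistic`, `df`, `p.value`, `n_a`, `n_b`.
#' @export
compare_clade_rates_ttest <- function(data, rate = "median",
                                      partition = "in_clade") {
  g <- data[[partition]]
  v <- data[[rate]]
  if (is.logical(g)) g <- factor(g, levels = c(TRUE, FALSE))
  g <- droplevels(as.factor(g))
  if (nlevels(g) != 2) abort("Partition must have exactly two non-empty levels.")
  a <- v[g == levels(g)[1]]
  b <- v[g == levels(g)[2]]
  if (length(a) < 2 || length(b) < 2) abort("Each partition needs >= 2 branches.")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(
        estimate = 0, statistic = 0, df = NA_real_, p.value = 1,
        n_a = length(a), n_b = length(b)
      ))
    }
    return(tibble(
      estimate = mean(a) - mean(b), statistic = Inf, df = NA_real_,
      p.value = 0, n_a = length(a), n_b = length(b)
    ))
  }
  tt <- t.test(a, b)
  tibble(
    estimate = unname(diff(rev(tt$estimate))), statistic = unname(tt$statistic),
    df = unname(tt$parameter), p.value = tt$p.value,
    n_a = length(a), n_b = length(b)
  )
}

#' Permutation test of full posterior rate distributions between clades
#'
#' A conservative alternative to the t-test on branch medians: the observed
#' statistic is the difference in mean branch rate between the two partition
#' sides, computed within each posterior sample and averaged over samples.
#' The null distribution is built by permuting the branch partition labels;
#' the two-sided p-value is `(1 + #{|null| >= |obs|}) / (1 + n_perm)`.
#'
#' @param chain a `posterior_chain`.
#' @param partition logical vector over branches (in `chain$edges` order) or
#'   the tibble from [clade_partition()] on the chain's tree.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return One-row tibble: `observed`, `p.value`, `n_perm`.
#' @export
permutation_test_posteriors <- function(chain, partition, n_perm = 999,
                                        seed = NULL) {
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  if (is.data.frame(partition)) {
    # align by child node: partition tables are in tree$edge order while the
    # chain stores branches in postorder
    partition <- partition$in_clade[match(chain$edges$child, partition$child)]
  }
  flags <- as.logical(partition)
  ne <- nrow(chain$edges)
  if (length(flags) != ne) abort("Partition length must match the branch count.")
  n_in <- sum(flags)
  if (n_in == 0 || n_in == ne) abort("Partition must split the branches in two.")
  # averaging the per-sample mean difference over samples equals the mean
  # difference of time-averaged branch rates
  bm <- colMeans(chain$rates)
  obs <- mean(bm[flags]) - mean(bm[!flags])
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      f <- sample(flags)
      mean(bm[f]) - mean(bm[!f])
    }, numeric(1))
    tibble(
      observed = obs,
      p.value = (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm),
      n_perm = n_perm
    )
  })
}
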