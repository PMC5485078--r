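# Time-scaling of cladograms against the fossil record. Tip ages are drawn
# uniformly from each taxon's narrowest known stratigraphic interval; the
# root age is drawn from the consecutive-outgroup (Hedman-style) conditional
# distribution evaluated on a discrete grid; remaining internal nodes are
# sampled root-to-tip, uniform between the hard bounds given by the parent's
# sampled age and the oldest descendant tip. A hard maximum-age constraint
# (e.g. the 208.5 Ma Rhaetian bound for a clade's basal node) is applied by
# isotropic compression of the clade's internal node ages.

# Minimum branch duration (Myr) reserved structurally during dating, so that
# independent-contrast variances stay positive without post-hoc flooring.
DURATION_FLOOR <- 0.001

validate_strat_ranges <- function(ranges) {
  needed <- c("taxon_id", "interval_start", "interval_end")
  miss <- setdiff(needed, names(ranges))
  if (length(miss) > 0) {
    abort(paste0("Stratigraphic table is missing columns: ", paste(miss, collapse = ", ")))
  }
  bad <- ranges$interval_start < ranges$interval_end | ranges$interval_end < 0
  if (any(bad)) {
    abort(paste0(
      "Invalid stratigraphic interval (need start >= end >= 0) for: ",
      paste(ranges$taxon_id[bad], collapse = ", ")
    ))
  }
  invisible(ranges)
}

#' Sample tip ages from stratigraphic intervals
#'
#' Draws one occurrence age per taxon, uniform across the narrowest interval
#' from which the taxon is known. Point intervals are returned exactly.
#'
#' @param ranges tibble with columns `taxon_id`, `interval_start` (older
#'   bound, Ma), `interval_end` (younger bound, Ma).
#' @param seed integer seed for reproducibility.
#' @return A tibble with columns `taxon_id` and `age` (Ma).
#' @export
sample_tip_ages <- function(ranges, seed = NULL) {
  validate_strat_ranges(ranges)
  with_seed(seed, {
    tibble(
      taxon_id = ranges$taxon_id,
      age = runif(nrow(ranges), ranges$interval_end, ranges$interval_start)
    )
  })
}

# Marginal density of the ingroup root age on a grid, from successively
# older outgroup first appearances a_1 < ... < a_m and a hard upper bound
# t0. Divergences satisfy x_m ~ U(a_m, t0) and x_i | x_{i+1} ~ U(a_i,
# x_{i+1}); the ingroup root is uniform on [lower, x_1]. Each conditioning
# step is the integral p_i(x) = sum_{s >= max(x, a_i)} p_{i+1}(s) / (s -
# a_i), computed by a reverse cumulative sum over the grid.
hedman_root_density <- function(outgroup_ages, t0, lower, n_bins) {
  ages <- sort(outgroup_ages)
  g <- seq(lower, t0, length.out = n_bins)
  binw <- if (n_bins > 1) g[2] - g[1] else 1
  p <- as.numeric(g >= ages[length(ages)] - 1e-12)
  if (sum(p) == 0) p[n_bins] <- 1
  p <- p / sum(p)
  cascade <- function(p, a) {
    w <- ifelse(g > a, p / pmax(g - a, binw / 2), 0)
    q <- rev(cumsum(rev(w)))
    q[g < a - 1e-12] <- 0
    if (sum(q) == 0) q[which.max(g >= a)] <- 1
    q / sum(q)
  }
  if (length(ages) > 1) {
    for (a in rev(ages[-length(ages)])) p <- cascade(p, a)
  }
  p <- cascade(p, lower)
  list(grid = g, density = p, binw = binw)
}

# Feasibility bound per node: oldest descendant tip age plus one duration
# floor per intervening internal node, so every sampled age leaves room for
# strictly positive branch durations below it.
node_lower_bounds <- function(tree, tip_age_vec) {
  ntip <- ape::Ntip(tree)
  need <- c(tip_age_vec, rep(NA_real_, tree$Nnode))
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]
    ch <- po[i, 2]
    cand <- need[ch] + DURATION_FLOOR
    if (is.na(need[p]) || cand > need[p]) need[p] <- cand
  }
  need
}

#' Time-scale a cladogram with the consecutive-outgroup (Hedman) method
#'
#' Assigns absolute ages to the internal nodes of a rooted binary cladogram.
#' The root age is drawn from the conditional distribution implied by the
#' first-appearance ages of successively older outgroups (each divergence
#' uniform between the next outgroup's age bound and the divergence above
#' it), evaluated on a discrete grid of `n_bins` time bins and truncated
#' below by the oldest ingroup tip. Every other internal node is then
#' sampled root-to-tip, uniform between its oldest descendant tip age and
#' its parent's sampled age. A floor of 0.001 Myr per branch is reserved
#' structurally so that all durations are strictly positive and node ages
#' remain exactly additive along root-to-tip paths.
#'
#' @param cladogram rooted binary `phylo` tree; branch lengths are ignored.
#' @param tip_ages tibble from [sample_tip_ages()] (columns `taxon_id`,
#'   `age`) or a named numeric vector of ages (Ma).
#' @param outgroup_ages numeric vector of successively older first-appearance
#'   ages (Ma), closest outgroup first; must be strictly increasing.
#' @param t0 hard upper bound on divergence ages (Ma); defaults to 20 Myr
#'   older than the oldest calibrating age and must not be younger than it.
#' @param n_bins number of grid bins for the root-age cascade.
#' @param seed integer seed.
#' @return A time-scaled `phylo` tree with branch lengths in Myr and
#'   `root.time` set; node ages are recoverable with [node_ages()].
#' @export
hedman_timescale <- function(cladogram, tip_ages, outgroup_ages,
                             t0 = NULL, n_bins = 1000, seed = NULL) {
  if (!inherits(cladogram, "phylo")) {
    abort("`cladogram` must be a 'phylo' object.")
  }
  if (ape::Ntip(cladogram) < 2) {
    abort("Cladogram must have at least two tips.")
  }
  check_binary(cladogram)
  if (length(outgroup_ages) < 1 || any(diff(outgroup_ages) <= 0)) {
    abort("`outgroup_ages` must be a strictly increasing age sequence (Ma).")
  }
  if (is.null(t0)) {
    t0 <- max(outgroup_ages) + 20
  }
  if (t0 < max(outgroup_ages)) {
    abort("`t0` must be at least as old as the oldest calibrating age.")
  }
  if (is.data.frame(tip_ages)) {
    tip_ages <- setNames(tip_ages$age, tip_ages$taxon_id)
  }
  miss <- setdiff(cladogram$tip.label, names(tip_ages))
  if (length(miss) > 0) {
    abort(paste0("No age for tips: ", paste(head(miss, 5), collapse = ", ")))
  }
  ntip <- ape::Ntip(cladogram)
  nnode <- cladogram$Nnode
  tipv <- as.numeric(tip_ages[cladogram$tip.label])

  with_seed(seed, {
    need <- node_lower_bounds(cladogram, tipv)
    root <- ntip + 1L
    if (need[root] >= t0) {
      abort("`t0` is too young: the oldest ingroup tips leave no room for the root age.")
    }
    dens <- hedman_root_density(outgroup_ages, t0, need[root], n_bins)
    idx <- sample.int(n_bins, 1, prob = dens$density)
    root_age <- min(
      max(dens$grid[idx] + runif(1, -dens$binw / 2, dens$binw / 2), need[root]),
      t0
    )
    age <- c(tipv, rep(NA_real_, nnode))
    age[root] <- root_age
    pre <- ape::reorder.phylo(cladogram, "postorder")$edge
    pre <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]
    for (i in seq_len(nrow(pre))) {
      ch <- pre[i, 2]
      if (ch <= ntip) next
      lo <- need[ch]
      hi <- age[pre[i, 1]] - DURATION_FLOOR
      age[ch] <- if (hi <= lo) lo else runif(1, lo, hi)
    }
    out <- cladogram
    out$edge.length <- age[out$edge[, 1]] - age[out$edge[, 2]]
    out$root.time <- root_age
    out
  })
}

#' Apply a hard maximum-age constraint to a node by isotropic compression
#'
#' If the node is already no older than `max_age` the tree is returned
#' unchanged. Otherwise the node's age is set to exactly `max_age` and all
#' internal-node ages within its clade are compressed linearly between a
#' fixed pivot (the clade's oldest tip age) and the bound:
#' `age -> P + (age - P) * (max_age - P) / (old_age - P)`. This preserves tip
#' ages exactly, preserves the relative proportions of the compressed
#' segments, keeps all branch durations positive, and is idempotent. The
#' branch subtending the node absorbs the displaced time.
#'
#' @param tree time-scaled `phylo` tree.
#' @param node node to constrain: an ape node number, or a character vector
#'   of tip labels whose MRCA is used.
#' @param max_age maximum permitted age (Ma); must be at least the age of
#'   the node's oldest descendant tip.
#' @return The constrained time tree.
#' @export
constrain_node_age <- function(tree, node, max_age) {
  check_phylo(tree)
  if (is.character(node)) {
    node <- mrca_node(tree, node)
  }
  node <- as.integer(node)
  ntip <- ape::Ntip(tree)
  if (node <= ntip || node > ntip + tree$Nnode) {
    abort("`node` must refer to an internal node of the tree.")
  }
  ages <- node_ages(tree)$age
  old_age <- ages[node]
  if (old_age <= max_age) {
    return(tree)
  }
  desc <- descendant_nodes(tree, node)
  tips_in <- desc[desc <= ntip]
  internal_in <- c(node, desc[desc > ntip])
  pivot <- max(ages[tips_in])
  if (max_age < pivot) {
    abort("Infeasible constraint: `max_age` is younger than a descendant tip.")
  }
  f <- (max_age - pivot) / (old_age - pivot)
  new_ages <- ages
  new_ages[internal_in] <- pivot + (ages[internal_in] - pivot) * f
  out <- tree
  out$edge.length <- new_ages[out$edge[, 1]] - new_ages[out$edge[, 2]]
  if (node == ntip + 1L) {
    out$root.time <- max_age
  } else {
    out$root.time <- root_time(tree)
  }
  out
}
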