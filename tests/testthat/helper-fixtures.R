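# Fixtures built in code: small specimen tables, trees, and a paired-trait
# simulator with group-specific slopes (for ANCOVA power/type-I checks).

make_records <- function() {
  tibble::tibble(
    taxon_id = c("placo", "notho", "pisto", "plesio", "elasmo"),
    cervical_lo = c(6L, 15L, 35L, 28L, 71L),
    cervical_hi = c(6L, 17L, 37L, 28L, 76L),
    dorsal_lo = c(20L, 19L, 20L, 21L, 18L),
    dorsal_hi = c(20L, 19L, 22L, 21L, 18L),
    neck_length = c(140, 520, NA, 1800, 7000),
    trunk_length = c(1000, 700, 900, 2100, 3500)
  )
}

# random binary fossil tree with known seed
fixture_tree <- function(n = 16, seed = 1) {
  simulate_fossil_tree(n_tips = n, seed = seed)$tree
}

# tips of the non-root clade whose size is closest to frac * Ntip
pick_clade <- function(tree, frac = 0.4) {
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 2):(ntip + tree$Nnode)
  sizes <- purrr::map_int(internal, function(n) {
    ape::Ntip(ape::extract.clade(tree, n))
  })
  best <- internal[which.min(abs(sizes - frac * ntip))]
  ape::extract.clade(tree, best)$tip.label
}

# Simulate x by BM and y with per-branch increments slope(branch) * dx plus
# independent noise, where the slope differs inside/outside a clade. Gives
# tip data whose PIC regression slopes differ by group.
sim_grouped_slopes <- function(tree, clade_tips, slope_in, slope_out,
                               noise_sd = 0.2) {
  ne <- nrow(tree$edge)
  part <- clade_partition(tree, clade_tips)
  slope <- ifelse(part$in_clade, slope_in, slope_out)
  len <- tree$edge.length
  dx <- stats::rnorm(ne, 0, sqrt(len))
  dy <- slope * dx + stats::rnorm(ne, 0, noise_sd * sqrt(len))
  ntip <- ape::Ntip(tree)
  vx <- vy <- rep(NA_real_, ntip + tree$Nnode)
  vx[ntip + 1] <- vy[ntip + 1] <- 0
  po <- ape::reorder.phylo(tree, "postorder")$edge
  ord <- match(paste(po[, 1], po[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
  for (i in rev(seq_len(nrow(po)))) {
    vx[po[i, 2]] <- vx[po[i, 1]] + dx[ord[i]]
    vy[po[i, 2]] <- vy[po[i, 1]] + dy[ord[i]]
  }
  tibble::tibble(
    taxon_id = tree$tip.label,
    x = vx[seq_len(ntip)],
    y = vy[seq_len(ntip)]
  )
}

# dense-matrix GLS quantities for a trait on a tree (the brute-force oracle)
gls_oracle <- function(tree, x) {
  V <- ape::vcv(tree)
  x <- x[rownames(V)]
  Vi <- solve(V)
  ones <- rep(1, length(x))
  mu <- sum(Vi %*% x) / sum(Vi)
  qf <- as.numeric(t(x - mu) %*% Vi %*% (x - mu))
  n <- length(x)
  ll_ml <- -0.5 * (n * log(2 * pi) + as.numeric(determinant(V)$modulus) + qf)
  vroot <- 1 / sum(Vi)
  list(qf = qf, ll_reml = ll_ml + 0.5 * log(2 * pi * vroot))
}

# a posterior_chain with iid exchangeable branch rates (single-rate null)
null_chain <- function(n_branches, n_samples, seed) {
  withr_seed <- function(s, code) {
    set.seed(s)
    code
  }
  withr_seed(seed, {
    base <- stats::rexp(n_samples, 1)
    rates <- matrix(base, n_samples, n_branches) *
      matrix(exp(stats::rnorm(n_samples * n_branches, 0, 0.3)),
        n_samples, n_branches
      )
    structure(
      list(
        rates = rates,
        draws = tibble::tibble(
          generation = seq_len(n_samples), k = 0L,
          sigma2_0 = base, loglik = stats::rnorm(n_samples)
        ),
        edges = tibble::tibble(
          edge = seq_len(n_branches), child = seq_len(n_branches),
          child_label = NA_character_
        ),
        thin = 1L, n_generations = n_samples, burnin_frac = 0,
        trait = "synthetic"
      ),
      class = "posterior_chain"
    )
  })
}
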