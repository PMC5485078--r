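test_that("pruning likelihood matches closed forms and the dense oracle", {
  # two equal tips: contrast 0 with variance 2
  t2 <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(
    bm_loglik(c(a = 1, b = 1), t2),
    -0.5 * log(4 * pi),
    tolerance = 1e-12
  )

  set.seed(14)
  tr <- fixture_tree(10, 2)
  x <- stats::setNames(rnorm(10), tr$tip.label)
  # doubling durations at sigma2 = 1 equals sigma2 = 2 at original durations
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 2
  expect_equal(bm_loglik(x, tr, rates = 2), bm_loglik(x, tr2, rates = 1),
    tolerance = 1e-10
  )

  # dense multivariate-normal oracle with random per-branch rates
  for (i in 1:10) {
    n <- sample(4:12, 1)
    trn <- ape::rtree(n)
    xv <- stats::setNames(rnorm(n), trn$tip.label)
    rates <- stats::runif(nrow(trn$edge), 0.2, 3)
    scaled <- trn
    scaled$edge.length <- trn$edge.length * rates
    expect_equal(
      bm_loglik(xv, trn, rates = rates),
      gls_oracle(scaled, xv)$ll_reml,
      tolerance = 1e-8
    )
  }

  expect_error(bm_loglik(x, tr, rates = -1), "positive")
})

test_that("rjMCMC is seed-deterministic and shows no spurious shifts on null data", {
  tr <- fixture_tree(64, 11)
  bm <- simulate_multirate_bm(tr, sigma2 = 2, seed = 12)
  x <- stats::setNames(bm$traits$value, bm$traits$taxon_id)

  c1 <- rjmcmc_sample(x, tr, n_generations = 2e4, seed = 5)
  c2 <- rjmcmc_sample(x, tr, n_generations = 2e4, seed = 5)
  expect_identical(c1$draws, c2$draws)
  c3 <- rjmcmc_sample(x, tr, n_generations = 2e4, seed = 6)
  expect_false(identical(c1$draws$loglik, c3$draws$loglik))

  ch <- combine_chains(
    list(
      rjmcmc_sample(x, tr, n_generations = 1e5, seed = 7),
      rjmcmc_sample(x, tr, n_generations = 1e5, seed = 8)
    ),
    burnin_frac = 0.25
  )
  # posterior shift count stays at or below the prior mean on single-rate data
  expect_lte(mean(ch$draws$k), log(2) + 0.35)
  expect_equal(median(ch$draws$k), 0)
  # posterior sigma2 tracks the realized REML estimate
  reml <- mean((standardized_pics(x, tr)$std_contrast)^2)
  expect_equal(median(ch$draws$sigma2_0), reml, tolerance = 0.15)
})

test_that("fixed-dimension sampler matches the grid-normalized posterior", {
  # with add/delete/move/swap weights zero the sampler reduces to sigma2
  # under the REML likelihood and log-uniform prior; compare with a dense
  # grid evaluation of the same posterior by KS distance
  tr <- ape::read.tree(text = "((a:1,b:1):0.5,(c:0.8,d:1.2):0.7);")
  set.seed(2)
  x <- stats::setNames(rnorm(4, sd = 1.3), tr$tip.label)
  ch <- rjmcmc_sample(x, tr,
    n_generations = 2e5, thin = 2, seed = 3,
    proposals = rate_proposals(weights = c(0, 1, 0, 0, 0, 0))
  )
  draws <- ch$draws$sigma2_0[-(1:5000)]

  lgrid <- seq(log(1e-4), log(1e4), length.out = 4001)
  logpost <- purrr::map_dbl(exp(lgrid), function(s2) bm_loglik(x, tr, rates = s2))
  # prior 1/s2 times Jacobian s2 of the log transform cancel: flat in log s2
  w <- exp(logpost - max(logpost))
  cdf <- cumsum(w) / sum(w)
  grid_cdf <- stats::approxfun(lgrid, cdf, yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(log(draws), grid_cdf))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("chain combination removes burn-in and pools correctly", {
  nc <- null_chain(12, 1000, seed = 4)
  nc2 <- null_chain(12, 1000, seed = 5)
  comb <- combine_chains(list(nc, nc2), burnin_frac = 0.25)
  expect_equal(nrow(comb$draws), 1500)
  expect_equal(nrow(comb$rates), 1500)
  expect_identical(comb$burnin_frac, 0.25)

  plain <- combine_chains(list(nc, nc2), burnin_frac = 0)
  expect_equal(nrow(plain$draws), 2000)

  # combined per-branch medians lie between the per-chain medians
  m1 <- apply(nc$rates, 2, median)
  m2 <- apply(nc2$rates, 2, median)
  mc <- apply(plain$rates, 2, median)
  expect_true(all(mc >= pmin(m1, m2) - 1e-12 & mc <= pmax(m1, m2) + 1e-12))

  other <- null_chain(13, 1000, seed = 6)
  expect_error(combine_chains(list(nc, other), 0.25), "different trees")
})

test_that("ESS matches iid and AR(1) oracles and flags constants", {
  set.seed(9)
  wn <- rnorm(10000)
  expect_equal(as.numeric(ess(wn)), 10000, tolerance = 0.15)

  phi <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = phi), n = 10000))
  expect_equal(
    as.numeric(ess(ar)),
    10000 * (1 - phi) / (1 + phi),
    tolerance = 0.20
  )

  flat <- ess(rep(2, 500))
  expect_equal(as.numeric(flat), 500)
  expect_true(attr(flat, "constant"))

  nc <- null_chain(6, 400, seed = 2)
  tab <- suppressWarnings(ess(nc))
  expect_setequal(tab$series, c("loglik", "k", "sigma2_0"))
  expect_true(tab$constant[tab$series == "k"])
  expect_warning(ess(nc, warn_below = 1e6), "Effective sample size")
})

test_that("branch rate summaries are order-invariant and flag the fast clade", {
  nc <- null_chain(10, 500, seed = 3)
  s1 <- branch_rate_summary(nc)
  perm <- nc
  set.seed(1)
  ord <- sample(nrow(perm$rates))
  perm$rates <- perm$rates[ord, ]
  perm$draws <- perm$draws[ord, ]
  expect_equal(branch_rate_summary(perm)$median, s1$median)

  # constructed single-rate chain: every branch shares sigma2_0 exactly
  flatc <- null_chain(8, 300, seed = 7)
  flatc$rates <- matrix(flatc$draws$sigma2_0, 300, 8)
  sf <- branch_rate_summary(flatc)
  expect_equal(sf$median, rep(median(flatc$draws$sigma2_0), 8))

  # recovery: fast branches concentrate in the true shifted clade
  tr <- fixture_tree(48, 21)
  tips <- pick_clade(tr, 0.3)
  bm <- simulate_multirate_bm(tr, 1, shifts = list(tips = tips, multiplier = 10), seed = 31)
  x <- stats::setNames(bm$traits$value, bm$traits$taxon_id)
  ch <- combine_chains(list(rjmcmc_sample(x, tr, n_generations = 5e4, seed = 32)), 0.25)
  summ <- branch_rate_summary(ch)
  part <- clade_partition(tr, tips)
  j <- dplyr::left_join(summ, part[, c("child", "in_clade")], by = "child")
  frac_fast_in <- mean(j$class[j$in_clade] == "above")
  frac_fast_out <- mean(j$class[!j$in_clade] == "above")
  expect_gt(frac_fast_in, frac_fast_out)
})

test_that("Welch t-test comparison matches the textbook oracle", {
  d <- tibble::tibble(
    median = c(10, 11, 12, 13, 1, 2, 2, 3),
    in_clade = rep(c(TRUE, FALSE), each = 4)
  )
  out <- compare_clade_rates_ttest(d)
  # hand Welch computation
  a <- c(10, 11, 12, 13)
  b <- c(1, 2, 2, 3)
  se <- sqrt(var(a) / 4 + var(b) / 4)
  tstat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(out$statistic, tstat, tolerance = 1e-12)
  expect_equal(out$df, df, tolerance = 1e-12)
  expect_equal(out$p.value, 2 * stats::pt(-abs(tstat), df), tolerance = 1e-12)

  # label swap negates t, keeps p
  d2 <- dplyr::mutate(d, in_clade = !in_clade)
  out2 <- compare_clade_rates_ttest(d2)
  expect_equal(out2$statistic, -out$statistic)
  expect_equal(out2$p.value, out$p.value)

  # identical constant vectors: t = 0, p = 1
  flat <- tibble::tibble(median = rep(5, 8), in_clade = rep(c(TRUE, FALSE), 4))
  outf <- compare_clade_rates_ttest(flat)
  expect_equal(outf$statistic, 0)
  expect_equal(outf$p.value, 1)

  expect_error(
    compare_clade_rates_ttest(tibble::tibble(median = 1:3, in_clade = c(TRUE, FALSE, FALSE))),
    ">= 2 branches"
  )
})

test_that("permutation test attains its floor and respects exchangeability", {
  nc <- null_chain(30, 100, seed = 8)
  # extreme separation: all clade branches 100x background
  nc$rates[, 1:10] <- nc$rates[, 1:10] * 100
  flags <- c(rep(TRUE, 10), rep(FALSE, 20))
  out <- permutation_test_posteriors(nc, flags, n_perm = 199, seed = 1)
  expect_equal(out$p.value, 1 / 200)

  # permuting labels before the test leaves the p-value distribution alone:
  # with a null chain both orderings give non-extreme p-values
  nc0 <- null_chain(30, 100, seed = 9)
  p1 <- permutation_test_posteriors(nc0, flags, n_perm = 199, seed = 2)$p.value
  set.seed(3)
  p2 <- permutation_test_posteriors(nc0, sample(flags), n_perm = 199, seed = 2)$p.value
  expect_gt(min(p1, p2), 1 / 200)

  expect_error(
    permutation_test_posteriors(nc0, rep(TRUE, 30), n_perm = 199, seed = 1),
    "split"
  )
  expect_error(
    permutation_test_posteriors(nc0, flags, n_perm = 10, seed = 1),
    "n_perm"
  )
})
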