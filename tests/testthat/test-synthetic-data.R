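test_that("fossil tree generator honors tip count, extancy, and seed", {
  sim <- simulate_fossil_tree(n_tips = 40, seed = 1)
  expect_equal(ape::Ntip(sim$tree), 40)
  expect_true(all(sim$tree$edge.length > 0))
  # non-ultrametric: extinct tips at positive ages
  expect_gt(max(sim$ages$age), 0)

  # stratigraphic intervals bracket the true age
  joined <- dplyr::left_join(sim$ranges, sim$ages, by = "taxon_id")
  expect_true(all(joined$interval_start >= joined$age - 1e-9))
  expect_true(all(joined$interval_end <= joined$age + 1e-9))
  expect_true(all(joined$interval_end >= 0))

  # pure birth over the full span: every tip extant (age 0)
  ext <- simulate_fossil_tree(
    n_tips = 10, birth = 0.05, death = 0,
    time_span = 80, seed = 2
  )
  expect_true(all(abs(ext$ages$age) < 1e-9))

  s1 <- simulate_fossil_tree(n_tips = 20, seed = 3)
  s2 <- simulate_fossil_tree(n_tips = 20, seed = 3)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$ranges, s2$ranges)

  expect_error(simulate_fossil_tree(n_tips = 10, birth = 0.1, death = 0.2), "birth")
})

test_that("pure-birth richness matches the Yule expectation", {
  # the simulation starts from the root split (two founder lineages), so
  # E[N(T)] = 2 * exp(birth * T)
  lam <- 0.05
  Tspan <- 40
  counts <- purrr::map_int(1:400, function(i) {
    sim <- simulate_fossil_tree(
      n_tips = 3, birth = lam, death = 0, time_span = Tspan,
      seed = 7000 + i, downsample = FALSE
    )
    ape::Ntip(sim$tree)
  })
  expect_equal(mean(counts), 2 * exp(lam * Tspan), tolerance = 0.10)
})

test_that("multi-rate BM obeys the variance law and the rate map", {
  # star tree: tip values iid N(root, sigma2 * T)
  star <- ape::read.tree(text = paste0(
    "(", paste0("s", 1:1000, ":5", collapse = ","), ");"
  ))
  star <- ape::multi2di(star)
  star$edge.length[star$edge.length == 0] <- 1e-8
  bm <- simulate_multirate_bm(star, sigma2 = 2, seed = 4)
  expect_equal(var(bm$traits$value), 2 * 5, tolerance = 0.10)

  # zero-rate clade: identical values throughout
  tr <- fixture_tree(24, 5)
  tips <- ape::extract.clade(tr, mrca_node(tr, c("t2", "t9")))$tip.label
  bm0 <- simulate_multirate_bm(tr, 1, shifts = list(tips = tips, multiplier = 0), seed = 5)
  vals <- bm0$traits$value[bm0$traits$taxon_id %in% tips]
  expect_true(length(unique(round(vals, 12))) <= 1 || sd(vals) < 1e-12)
  # true rate map marks the clade (stem included)
  part <- clade_partition(tr, tips)
  expect_true(all(bm0$rates$rate[part$in_clade] == 0))
  expect_true(all(bm0$rates$rate[!part$in_clade] == 1))

  b1 <- simulate_multirate_bm(tr, 1, seed = 6)
  b2 <- simulate_multirate_bm(tr, 1, seed = 6)
  expect_identical(b1$traits, b2$traits)
})

test_that("correlated BM attains the exact and null R^2 limits", {
  tr <- fixture_tree(20, 9)
  d <- simulate_correlated_traits(tr, rho = 1, seed = 7)
  names(d) <- c("taxon_id", "y", "x")
  fit <- suppressWarnings(pic_ols(d, tr, "y", "x")) # collinear by design
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)

  # rho = 0: mean through-origin R^2 equals the Beta null mean 1/m where m
  # is the number of contrasts
  set.seed(8)
  m <- ape::Ntip(tr) - 1
  r2 <- purrr::map_dbl(1:300, function(i) {
    d0 <- simulate_correlated_traits(tr, rho = 0)
    names(d0) <- c("taxon_id", "y", "x")
    pic_ols(d0, tr, "y", "x")$r.squared
  })
  expect_equal(mean(r2), 1 / m, tolerance = 0.3)

  expect_error(simulate_correlated_traits(tr, rho = 1.2), "rho")
})

test_that("specimen generator respects envelope, ambiguity, and round-trips", {
  tr <- fixture_tree(48, 13)
  sim <- simulate_axial_specimens(tr, seed = 10)
  expect_true(all(sim$truth$presacral_count >= 19))
  expect_true(all(sim$truth$presacral_count <= 94))
  expect_true(all(sim$records$cervical_lo <= sim$records$cervical_hi))
  expect_true(all(sim$records$cervical_lo >= 1))

  # no ambiguity: all ranges are points; no missingness: exact round-trip
  clean <- simulate_axial_specimens(tr,
    ambiguity_prob = 0, missing_prob = 0, seed = 11
  )
  expect_true(all(clean$records$cervical_lo == clean$records$cervical_hi))
  expect_true(all(clean$records$dorsal_lo == clean$records$dorsal_hi))
  resolved <- resolve_ambiguous_counts(clean$records, n_replicates = 1, seed = 1)
  tt <- compute_traits(resolved)
  expect_equal(tt$count_ratio, clean$truth$count_ratio, tolerance = 1e-12)
  expect_equal(tt$length_ratio, clean$truth$length_ratio, tolerance = 1e-12)

  # ambiguous ranges contain the truth
  amb <- simulate_axial_specimens(tr, ambiguity_prob = 1, seed = 12)
  expect_true(all(amb$records$cervical_lo <= amb$truth$cervical_count))
  expect_true(all(amb$records$cervical_hi >= amb$truth$cervical_count))
  expect_true(all(amb$records$cervical_hi - amb$records$cervical_lo >= 1))

  s1 <- simulate_axial_specimens(tr, seed = 14)
  s2 <- simulate_axial_specimens(tr, seed = 14)
  expect_identical(s1$records, s2$records)
})

test_that("pipeline recovers the planted rate shift and correlation end to end", {
  sim <- simulate_fossil_tree(n_tips = 48, seed = 15)
  tr <- sim$tree
  tips <- pick_clade(tr, 0.3)
  bm <- simulate_multirate_bm(tr, 1, shifts = list(tips = tips, multiplier = 10), seed = 16)
  x <- stats::setNames(bm$traits$value, bm$traits$taxon_id)
  ch <- combine_chains(
    list(rjmcmc_sample(x, tr, n_generations = 5e4, seed = 17)), 0.25
  )
  summ <- branch_rate_summary(ch)
  part <- clade_partition(tr, tips)
  j <- dplyr::left_join(summ, part[, c("child", "in_clade")], by = "child")
  expect_gt(
    median(j$median[j$in_clade]) / median(j$median[!j$in_clade]),
    3
  )

  # correlation recovery through the trait pipeline
  rho <- 0.87
  r2 <- purrr::map_dbl(1:30, function(i) {
    t2 <- simulate_fossil_tree(n_tips = 100, seed = 8000 + i)$tree
    d <- simulate_correlated_traits(t2, rho)
    names(d) <- c("taxon_id", "y", "x")
    pic_ols(d, t2, "y", "x")$r.squared
  })
  expect_equal(mean(r2), rho^2, tolerance = 0.06)
})
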