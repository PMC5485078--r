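test_that("standardized contrasts match closed forms, ape, and the GLS oracle", {
  t2 <- ape::read.tree(text = "(a:1,b:1);")
  p <- standardized_pics(c(a = 3, b = 1), t2)
  expect_equal(abs(p$std_contrast), 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(p$sd, sqrt(2), tolerance = 1e-12)

  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n)
    x <- stats::setNames(rnorm(n), tr$tip.label)
    mine <- standardized_pics(x, tr)
    ref <- ape::pic(x, tr)
    expect_equal(
      mine$std_contrast[match(names(ref), mine$node)],
      unname(ref),
      tolerance = 1e-10
    )
    # sum of squared standardized contrasts equals the GLS quadratic form
    expect_equal(sum(mine$std_contrast^2), gls_oracle(tr, x)$qf, tolerance = 1e-8)
    # translation invariance
    shifted <- standardized_pics(x + 100, tr)
    expect_equal(shifted$std_contrast, mine$std_contrast, tolerance = 1e-9)
  }
})

test_that("contrasts require binary trees, positive durations, enough data", {
  poly <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_error(standardized_pics(c(a = 1, b = 2, c = 3), poly), "binary")
  neg <- ape::read.tree(text = "((a:1,b:1):0,c:2);")
  expect_error(standardized_pics(c(a = 1, b = 2, c = 3), neg), "positive")
})

test_that("through-origin PIC regression has exact algebraic behavior", {
  tr <- fixture_tree(24, 6)
  set.seed(51)
  bm <- simulate_multirate_bm(tr, 1)$traits
  d <- tibble::tibble(
    taxon_id = bm$taxon_id,
    x = bm$value,
    y = 2 * bm$value,
    z = rnorm(nrow(bm))
  )
  fit <- suppressWarnings(pic_ols(d, tr, "y", "x")) # exact fit
  expect_equal(fit$coefficients$estimate, 2, tolerance = 1e-10)
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
  expect_true(fit$through_origin)

  # regression of a trait on itself: R^2 = 1 exactly
  self <- suppressWarnings(pic_ols(d, tr, "x", "x"))
  expect_equal(self$r.squared, 1, tolerance = 1e-12)

  # nested-model monotonicity: bivariate R^2 >= each univariate R^2
  # (y = 2x exactly, so these fits are also perfect)
  bi <- suppressWarnings(pic_ols(d, tr, "y", c("x", "z")))
  u1 <- suppressWarnings(pic_ols(d, tr, "y", "x"))
  u2 <- pic_ols(d, tr, "y", "z")
  expect_gte(bi$r.squared + 1e-12, u1$r.squared)
  expect_gte(bi$r.squared + 1e-12, u2$r.squared)

  # positivization flips signs pairwise and leaves R^2 unchanged
  fit_raw <- pic_ols(d, tr, "y", "z", positivize = FALSE)
  fit_pos <- pic_ols(d, tr, "y", "z", positivize = TRUE)
  expect_equal(fit_raw$r.squared, fit_pos$r.squared, tolerance = 1e-12)
  expect_true(all(fit_pos$data$z >= 0))

  expect_error(pic_ols(d[1:2, ], tr, "y", "x"), "three taxa")
})

test_that("PIC regression recovers the generating correlation", {
  # R^2 of the through-origin contrast regression estimates rho^2
  set.seed(61)
  r2 <- purrr::map_dbl(1:60, function(i) {
    tr <- simulate_fossil_tree(n_tips = 100, seed = 600 + i)$tree
    d <- simulate_correlated_traits(tr, rho = 0.8)
    names(d) <- c("taxon_id", "y", "x")
    pic_ols(d, tr, "y", "x")$r.squared
  })
  expect_equal(mean(r2), 0.64, tolerance = 0.05)
})

test_that("contrasts from single-rate BM are standard normal", {
  tree <- fixture_tree(64, 13)
  set.seed(71)
  pvals <- purrr::map_dbl(1:300, function(i) {
    bm <- simulate_multirate_bm(tree, sigma2 = 1)$traits
    x <- stats::setNames(bm$value, bm$taxon_id)
    stats::shapiro.test(standardized_pics(x, tree)$std_contrast)$p.value
  })
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("ANCOVA detects slope heterogeneity and only that", {
  tr <- fixture_tree(120, 17)
  clade_tips <- pick_clade(tr, 0.5)

  set.seed(81)
  # equal slopes: interaction rejected at roughly the nominal rate
  p_null <- purrr::map_dbl(1:200, function(i) {
    d <- sim_grouped_slopes(tr, clade_tips, slope_in = 1, slope_out = 1)
    pic_ancova(d, tr, "y", "x", clade_tips = clade_tips)$p.value
  })
  expect_gt(mean(p_null < 0.05), 0.01)
  expect_lt(mean(p_null < 0.05), 0.12)

  # 3x slope in one group: detected nearly always
  p_alt <- purrr::map_dbl(1:60, function(i) {
    d <- sim_grouped_slopes(tr, clade_tips, slope_in = 3, slope_out = 1)
    pic_ancova(d, tr, "y", "x", clade_tips = clade_tips)$p.value
  })
  expect_gte(mean(p_alt < 0.05), 0.95)

  # group relabeling flips the interaction sign, p unchanged
  d <- sim_grouped_slopes(tr, clade_tips, slope_in = 2, slope_out = 1)
  boundary <- median(node_ages(tr)$age[!node_ages(tr)$is_tip])
  lab <- function(age) if (age > boundary) "Triassic" else "Jurassic-Cretaceous"
  swapped <- function(age) if (age > boundary) "Jurassic-Cretaceous" else "Triassic"
  a1 <- pic_ancova(d, tr, "y", "x", period = lab)
  a2 <- pic_ancova(d, tr, "y", "x", period = swapped)
  expect_equal(a1$p.value, a2$p.value, tolerance = 1e-9)
  expect_equal(a1$estimate, -a2$estimate, tolerance = 1e-9)
})

test_that("non-phylogenetic regression matches hand computation", {
  d <- tibble::tibble(
    taxon_id = paste0("t", 1:5),
    x = c(1, 2, 3, 4, 5),
    y = c(2.1, 3.9, 6.2, 8.1, 9.8)
  )
  fit <- raw_ols(d, "y", "x")
  # closed-form simple regression
  b1 <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) / sum((d$x - mean(d$x))^2)
  b0 <- mean(d$y) - b1 * mean(d$x)
  expect_equal(fit$coefficients$estimate[2], b1, tolerance = 1e-12)
  expect_equal(fit$coefficients$estimate[1], b0, tolerance = 1e-12)
  expect_false(fit$through_origin)

  exact <- suppressWarnings(raw_ols(dplyr::mutate(d, y = x + 1), "y", "x"))
  expect_equal(exact$r.squared, 1, tolerance = 1e-12)
  expect_equal(exact$coefficients$estimate[2], 1, tolerance = 1e-12)

  expect_error(raw_ols(dplyr::mutate(d, x = 1), "y", "x"), "constant")
})

test_that("decomposition geometry matches the diagonal formulas", {
  g <- decomposition_geometry(2, -2)
  expect_equal(g$dist_homeotic, 0, tolerance = 1e-12)
  expect_equal(g$mag_homeotic, 2 * sqrt(2), tolerance = 1e-12)

  g2 <- decomposition_geometry(0.3, 0.3)
  expect_equal(g2$dist_somitogenetic, 0, tolerance = 1e-12)

  g3 <- decomposition_geometry(3, 1)
  expect_equal(g3$dist_homeotic, 4 / sqrt(2), tolerance = 1e-12)
  expect_equal(g3$dist_homeotic, 2.828427, tolerance = 1e-6)

  set.seed(91)
  cc <- rnorm(200)
  dd <- rnorm(200)
  g4 <- decomposition_geometry(cc, dd)
  expect_true(all(g4$dist_homeotic >= 0 & g4$dist_somitogenetic >= 0))
  expect_equal(g4$dist_homeotic, abs(cc + dd) / sqrt(2), tolerance = 1e-12)
  expect_equal(g4$dist_somitogenetic, abs(cc - dd) / sqrt(2), tolerance = 1e-12)
  on_hom <- abs(g4$dist_homeotic) < 1e-12
  expect_identical(on_hom, dd == -cc)

  expect_error(decomposition_geometry(1:3, 1:2), "matching")
})

test_that("per-node decomposition classifies pure changes on both scales", {
  tr <- fixture_tree(32, 19)
  truth <- simulate_axial_specimens(tr,
    ambiguity_prob = 0, missing_prob = 0, seed = 23
  )$truth
  raw <- pure_change_decomposition(truth, tr, logged = FALSE, eps = 0.05)
  expect_equal(nrow(raw), ape::Ntip(tr) - 1)
  expect_true(all(raw$dist_homeotic >= 0))
  # orientation convention: cervical contrast non-negative
  expect_true(all(raw$cervical >= 0))
  lg <- pure_change_decomposition(truth, tr, logged = TRUE, eps = 0.05)
  expect_true(all(lg$dist_somitogenetic >= 0))
  expect_identical(lg$pure, lg$dist_somitogenetic < 0.05)
})

test_that("R^2 summaries aggregate medians and ranges as percentages", {
  res <- tibble::tibble(r.squared = c(0.2, 0.5, 0.8))
  out <- median_r2_across_trees(res)
  expect_equal(out$median_r2_pct, 50)
  expect_equal(out$min_r2_pct, 20)
  expect_equal(out$max_r2_pct, 80)

  single <- median_r2_across_trees(tibble::tibble(r.squared = 0.4))
  expect_equal(single$median_r2_pct, single$min_r2_pct)

  shuffled <- median_r2_across_trees(res[c(3, 1, 2), ])
  expect_identical(out, shuffled)

  grouped <- median_r2_across_trees(
    tibble::tibble(model = c("a", "a", "b"), r.squared = c(0.2, 0.4, 0.9))
  )
  expect_equal(nrow(grouped), 2)
  expect_error(median_r2_across_trees(res[0, ]), "No regression")
})

test_that("tidiers and autoplot expose fits in broom/ggplot2 idiom", {
  tr <- fixture_tree(16, 29)
  set.seed(101)
  d <- simulate_correlated_traits(tr, 0.9)
  names(d) <- c("taxon_id", "y", "x")
  fit <- pic_ols(d, tr, "y", "x")
  td <- tidy(fit)
  expect_setequal(
    names(td),
    c("term", "estimate", "std.error", "statistic", "p.value")
  )
  gl <- glance(fit)
  expect_true(gl$through_origin)
  expect_equal(gl$nobs, 15)
  expect_s3_class(autoplot(fit), "ggplot")

  dec <- pure_change_decomposition(
    simulate_axial_specimens(tr, seed = 3)$truth, tr
  )
  expect_s3_class(autoplot(dec), "ggplot")
})
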