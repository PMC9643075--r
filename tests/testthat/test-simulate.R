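test_that("simulated trees are ultrametric, bifurcating and deterministic", {
  tr <- simulate_tree(3, seed = 1)
  expect_equal(tr$Nnode, 2L)
  depths <- ape::node.depth.edgelength(tr)[seq_len(3)]
  expect_lt(diff(range(depths)), 1e-8)

  t1 <- simulate_tree(100, seed = 1)
  t2 <- simulate_tree(100, seed = 1)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_true(ape::is.binary(t1))
  expect_equal(max(ape::node.depth.edgelength(t1)), 1, tolerance = 1e-12)

  expect_error(simulate_tree(2), "n_tips")
})

test_that("tree covariance is symmetric positive definite", {
  tr <- simulate_tree(200, seed = 7)
  C <- phylo_covariance(tr)
  expect_identical(C, t(C))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("lambda-trait simulation honours its degenerate and null cases", {
  tr <- fixture_tree(30)
  expect_identical(unname(simulate_lambda_trait(tr, 0.5, 0, mu = 3, seed = 1)),
                   rep(3, 30))

  # lambda = 0: tips are independent; across replicate draws the sample
  # correlation of any tip pair stays near zero
  draws <- sapply(1:2000, function(i)
    simulate_lambda_trait(tr, 0, 1, 0, seed = derive_seed(5, i))[1:6])
  cors <- cor(t(draws))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.1)

  y1 <- simulate_lambda_trait(tr, 1, 2, 1, seed = 9)
  y2 <- simulate_lambda_trait(tr, 1, 2, 1, seed = 9)
  expect_identical(y1, y2)
})

test_that("lambda = 1 recovery: the estimator finds strong signal", {
  est <- sapply(1:15, function(i) {
    tr <- simulate_tree(200, seed = derive_seed(21, i))
    y <- simulate_lambda_trait(tr, 1, 1, 0, seed = derive_seed(22, i))
    estimate_lambda(y, tr)$lambda_hat
  })
  expect_gte(mean(est), 0.9)
})

test_that("mixed-model trait simulation returns its ground truth", {
  tr <- fixture_tree(40)
  s0 <- simulate_lynch_trait(tr, 0, 1, mu = 2, seed = 3)
  expect_identical(unname(s0$a), rep(0, 40))

  se0 <- simulate_lynch_trait(tr, 1, 0, mu = 2, seed = 4)
  expect_equal(unname(se0$y - 2), unname(se0$a), tolerance = 1e-12)

  dg <- simulate_lynch_trait(tr, 0, 0, mu = 5, seed = 5)
  expect_identical(dg$flag, "degenerate")
  expect_identical(unname(dg$y), rep(5, 40))
})

test_that("sigma2_a = 0 traits show no phylogenetic distance structure", {
  tr <- fixture_tree(60, seed = 11)
  D <- ape::cophenetic.phylo(tr)
  cors <- sapply(1:200, function(i) {
    y <- simulate_lynch_trait(tr, 0, 1, seed = derive_seed(31, i))$y
    td <- abs(outer(y, y, "-"))
    cor(td[upper.tri(td)], D[upper.tri(D)])
  })
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("lambda = 1 Brownian and residual-free mixed-model draws share
          mean and covariance", {
  tr <- fixture_tree(25, seed = 13)
  C <- phylo_covariance(tr)
  ya <- sapply(1:1500, function(i)
    simulate_lambda_trait(tr, 1, 1, 1, seed = derive_seed(41, i)))
  yb <- sapply(1:1500, function(i)
    simulate_lynch_trait(tr, 1, 0, 1, seed = derive_seed(42, i))$y)
  expect_equal(mean(ya), mean(yb), tolerance = 0.05)
  # both empirical covariances approach C (up to the depth normalisation)
  ca <- cov(t(ya)); cb <- cov(t(yb)) * max(diag(C))
  expect_lt(mean(abs(ca - cb)), 0.1)
})

test_that("ordinal simulation matches its closed-form marginal and a binary
          oracle", {
  zeta <- qlogis(c(0.3, 0.6, 0.85))
  n <- 1e5
  y <- simulate_ordinal_response(matrix(0, n, 1), 0, zeta, seed = 8)
  freq <- tabulate(y + 1L, nbins = 4) / n
  expect_equal(freq, diff(c(0, plogis(zeta), 1)), tolerance = 0.01)

  # K = 2 equals Bernoulli(logit^-1(x beta - zeta1)) under the same uniforms
  set.seed(77)
  x <- matrix(rnorm(500), ncol = 1)
  y2 <- simulate_ordinal_response(x, 1.3, 0.4, seed = 99)
  set.seed(99)
  u <- runif(500)
  bern <- as.integer(u > plogis(0.4 - 1.3 * x[, 1]))
  expect_identical(y2, bern)

  expect_error(simulate_ordinal_response(x, 1, c(1, 0.5)), "increasing")
})

test_that("ordinal recovery: the proportional-odds fit finds the simulated
          coefficient", {
  errs <- sapply(1:40, function(i) {
    set.seed(derive_seed(51, i))
    x <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "x"))
    y <- simulate_ordinal_response(x, -0.7, qlogis(c(0.6, 0.8, 0.92)),
                                   seed = derive_seed(52, i))
    fit_proportional_odds(x, y)$coefficients$estimate + 0.7
  })
  expect_lt(median(abs(errs)), 0.15)
})

test_that("rendered specimens are deterministic with exact geometry and
          ground truth", {
  wing <- cbind(c(0.06, 0.5, 0.5, 0.06), c(0.1, 0.35, -0.1, -0.05))
  sp <- specimen_spec(1.2, 0.12, list(wing), body_gray = 80,
                      wing_gray_profile = 200, dpi = 1200)
  r1 <- render_specimen_image(sp)
  r2 <- render_specimen_image(sp)
  expect_identical(r1, r2)

  expect_equal(r1$truth$body_width_px, round(0.12 * 1200 / 2.54))
  expect_equal(r1$truth$body_length_px, round(1.2 * 1200 / 2.54))
  expect_equal(sum(r1$body_mask), r1$truth$body_width_px * r1$truth$body_length_px)
  expect_false(any(r1$body_mask & r1$wing_mask))

  # ground-truth area equals the longhand shoelace formula
  expect_equal(r1$truth$wing_area_cm2, oracle_shoelace(wing), tolerance = 1e-12)
  # analytic cylinder oracle within discretisation tolerance
  expect_equal(body_volume(r1$body_mask, 1200), pi * 0.06^2 * 1.2,
               tolerance = 0.02)

  allwhite <- specimen_spec(0.5, 0.1, body_gray = 255, dpi = 600)
  rw <- render_specimen_image(allwhite)
  expect_equal(color_lightness(rw$image, rw$body_mask, NULL), 255)

  expect_error(render_specimen_image(specimen_spec(0.0005, 0.0005, dpi = 300)),
               "one pixel")
  expect_error(specimen_spec(1, 0.1, body_gray = 300), "gray")
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(specimen_spec(1, 0.1, list(bowtie)), "self-intersecting")
})

test_that("specimen round-trip through PNG + sidecar preserves masks and dpi", {
  sp <- specimen_spec(0.6, 0.08, list(cbind(c(0.05, 0.3, 0.3, 0.05),
                                            c(0.05, 0.25, -0.15, -0.05))),
                      body_gray = 60, wing_gray_profile = 190, dpi = 600)
  r <- render_specimen_image(sp)
  d <- withr::local_tempdir()
  write_specimen(r, d, "sp1")
  back <- read_specimen(d, "sp1")
  expect_equal(back$dpi, 600)
  expect_identical(back$body_mask, r$body_mask)
  expect_identical(back$wing_mask, r$wing_mask)
  expect_equal(max(abs(back$image - r$image)), 0, tolerance = 0.5)
  expect_equal(back$truth$body_volume_cm3, r$truth$body_volume_cm3,
               tolerance = 1e-12)
})

test_that("derived seeds are reproducible and within integer range", {
  s1 <- derive_seed(123, 1:50)
  expect_identical(s1, derive_seed(123, 1:50))
  expect_true(all(s1 > 0 & s1 < 2^31))
  expect_equal(length(unique(s1)), 50)
})
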