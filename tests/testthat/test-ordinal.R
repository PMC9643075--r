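test_that("red-list categories map onto the 0..4 risk scale", {
  expect_identical(encode_status(c("LC", "NT", "VU", "EN", "CR")), 0:4)
  expect_identical(encode_status(c("lc", " cr ")), c(0L, 4L))
  expect_error(encode_status("DD"), "unsupported")
  expect_error(encode_status(c("LC", "NE")), "NE")
})

test_that("a two-category fit equals the binary logistic oracle", {
  set.seed(41)
  X <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("a", "b")))
  y <- simulate_ordinal_response(X, c(0.8, -0.5), 0.3, seed = 42)
  f <- fit_proportional_odds(X, y)
  # binary model: P(Y = 1) = logistic(x beta - zeta1)
  o <- oracle_binary_logit(X, y)
  expect_equal(f$coefficients$estimate, o$coef[2:3], tolerance = 1e-6)
  expect_equal(f$zeta, -o$coef[1], tolerance = 1e-6)
  expect_equal(f$coefficients$std_error, unname(o$se[2:3]), tolerance = 1e-4)
})

test_that("null data recover the thresholds from cumulative frequencies", {
  set.seed(43)
  X <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "x"))
  zeta <- qlogis(c(0.5, 0.75, 0.9))
  y <- simulate_ordinal_response(X, 0, zeta, seed = 44)
  f <- fit_proportional_odds(X, y)
  cumf <- cumsum(tabulate(y + 1, 4))[1:3] / 2000
  expect_equal(f$zeta, qlogis(cumf), tolerance = 0.02)
  expect_lt(abs(f$coefficients$estimate), 0.15)
})

test_that("sign convention: positive coefficients push toward higher risk and
          reversing the order negates them", {
  set.seed(45)
  X <- matrix(rnorm(800), ncol = 1, dimnames = list(NULL, "x"))
  y <- simulate_ordinal_response(X, 1.2, qlogis(c(0.4, 0.7, 0.9)), seed = 46)
  f <- fit_proportional_odds(X, y)
  expect_gt(f$coefficients$estimate, 0)
  frev <- fit_proportional_odds(X, max(y) - y)
  expect_equal(frev$coefficients$estimate, -f$coefficients$estimate,
               tolerance = 1e-5)
  expect_equal(sort(-rev(frev$zeta)), sort(f$zeta), tolerance = 1e-5)
})

test_that("standardising a predictor rescales beta but not z or p", {
  set.seed(47)
  X <- matrix(rnorm(900, sd = 3), ncol = 1, dimnames = list(NULL, "x"))
  y <- simulate_ordinal_response(X, 0.4, qlogis(c(0.5, 0.8)), seed = 48)
  f1 <- fit_proportional_odds(X, y)
  k <- sd(X[, 1])
  f2 <- fit_proportional_odds(X / k, y)
  expect_equal(f2$coefficients$estimate, f1$coefficients$estimate * k,
               tolerance = 1e-6)
  expect_equal(f2$coefficients$z_value, f1$coefficients$z_value,
               tolerance = 1e-6)
  expect_equal(f2$coefficients$p_value, f1$coefficients$p_value,
               tolerance = 1e-6)
})

test_that("the fitted model nests above the intercept-only model", {
  set.seed(49)
  X <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- simulate_ordinal_response(X, c(0.5, 0), qlogis(c(0.3, 0.6, 0.85)),
                                 seed = 50)
  f <- fit_proportional_odds(X, y)
  expect_gte(f$loglik, f$loglik_null)
  expect_true(all(diff(f$zeta) > 0))
  expect_equal(f$coefficients$z_value,
               f$coefficients$estimate / f$coefficients$std_error)
  expect_equal(f$coefficients$p_value, 2 * pnorm(-abs(f$coefficients$z_value)))
})

test_that("degenerate designs raise named singularity errors", {
  set.seed(51)
  X <- cbind(zero = rep(0, 100), x = rnorm(100))
  y <- simulate_ordinal_response(X, c(0, 0.5), qlogis(c(0.4, 0.8)), seed = 52)
  expect_error(fit_proportional_odds(X, y), "zero")
  X2 <- cbind(a = rnorm(100))
  X2 <- cbind(X2, b = 2 * X2[, "a"])
  expect_error(fit_proportional_odds(X2, y), "linearly dependent")
  expect_error(fit_proportional_odds(X[, 2, drop = FALSE], rep(1L, 100)),
               "fewer than 2")
})

test_that("empty middle categories are collapsed with a warning", {
  set.seed(53)
  x <- matrix(rnorm(300), ncol = 1, dimnames = list(NULL, "x"))
  y <- simulate_ordinal_response(x, 0.3, qlogis(c(0.45, 0.9)), seed = 54)
  y[y == 1L] <- 0L  # empty out NT
  expect_warning(f <- fit_proportional_odds(x, y), "collapsing")
  expect_equal(f$K, 2L)
})

test_that("estimates agree with the reference polr implementation", {
  skip_if_not_installed("MASS")
  set.seed(55)
  X <- matrix(rnorm(1500), 500, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- simulate_ordinal_response(X, c(-0.7, 0.4, 0), qlogis(c(0.5, 0.75, 0.9)),
                                 seed = 56)
  f <- fit_proportional_odds(X, y)
  ref <- MASS::polr(factor(y, ordered = TRUE) ~ X, Hess = TRUE)
  expect_equal(f$coefficients$estimate, unname(coef(ref)), tolerance = 1e-4)
  expect_equal(f$zeta, unname(ref$zeta), tolerance = 1e-4)
  expect_equal(f$coefficients$std_error,
               unname(sqrt(diag(vcov(ref)))[1:3]), tolerance = 1e-3)
})

test_that("block fits run jointly by default and per-trait behind the flag", {
  set.seed(57)
  X <- matrix(rnorm(1320), 330, 4,
              dimnames = list(NULL, c("body_volume", "wing_area",
                                      "color_lightness", "range_occupancy")))
  y <- simulate_ordinal_response(X, c(0, 0, 0, -0.7),
                                 qlogis(c(0.8, 0.9, 0.95, 0.98)), seed = 58)
  joint <- fit_table2_block(X, y)
  expect_s3_class(joint, "ordinal_fit")
  expect_equal(joint$coefficients$predictor, colnames(X))
  per <- fit_table2_block(X, y, joint = FALSE)
  expect_named(per, colnames(X))
  expect_s3_class(per$range_occupancy, "ordinal_fit")
})
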