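test_that("pixel edge length converts dpi to cm", {
  expect_equal(pixel_edge_cm(1200), 2.54 / 1200)
  expect_equal(pixel_edge_cm(2.54), 1.0)
  expect_equal(pixel_edge_cm(300), 2.54 / 300)
  expect_error(pixel_edge_cm(0), "positive")
  expect_error(pixel_edge_cm(-10), "positive")
})

test_that("body volume treats each pixel row as a cylindrical disc", {
  s <- 0.01
  dpi <- 2.54 / s
  mask <- matrix(FALSE, 100, 30)
  mask[, 11:20] <- TRUE  # 10 pixels wide, 100 rows
  expect_equal(body_volume(mask, dpi), 100 * pi * (10 * s / 2)^2 * s,
               tolerance = 1e-12)

  one <- matrix(TRUE, 1, 1)
  expect_equal(body_volume(one, 2.54), pi / 4, tolerance = 1e-12)

  expect_error(body_volume(matrix(FALSE, 5, 5), 300), "empty")

  # width varying by row: sum of per-row discs
  vmask <- matrix(FALSE, 3, 10)
  vmask[1, 1:2] <- TRUE; vmask[2, 1:6] <- TRUE; vmask[3, 1:4] <- TRUE
  expect_equal(body_volume(vmask, dpi),
               pi * s^3 / 4 * (2^2 + 6^2 + 4^2), tolerance = 1e-12)
})

test_that("rendered synthetic cylinder recovers the analytic volume within 2%", {
  sp <- specimen_spec(1.2, 0.12, dpi = 1200)
  r <- render_specimen_image(sp)
  expect_equal(body_volume(r$body_mask, 1200), pi * 0.06^2 * 1.2,
               tolerance = 0.02)
})

test_that("color lightness is the exact mean gray of the scored pixels", {
  img <- array(255, c(4, 4, 3))
  mask <- matrix(TRUE, 4, 4)
  expect_equal(color_lightness(img, mask, NULL), 255)
  expect_equal(color_lightness(img * 0, mask, NULL), 0)
  img2 <- img
  img2[, 1:2, ] <- 0
  expect_equal(color_lightness(img2, mask, NULL), 127.5)
  # invariant to pixel order: scrambling rows/cols leaves the mean unchanged
  perm <- img2[sample(4), sample(4), , drop = FALSE]
  expect_equal(color_lightness(perm, mask, NULL), 127.5)
  expect_error(color_lightness(img, matrix(FALSE, 4, 4), NULL), "empty")
})

test_that("odonate mode scores the body only", {
  img <- array(0, c(6, 6, 3))     # dark body
  body <- matrix(FALSE, 6, 6); body[, 3:4] <- TRUE
  wing <- matrix(FALSE, 6, 6); wing[, c(1, 6)] <- TRUE
  img[, c(1, 6), ] <- 255         # bright wings
  expect_equal(color_lightness(img, body, wing, include_wings = FALSE), 0)
  expect_gt(color_lightness(img, body, wing, include_wings = TRUE,
                            proximal_fraction = 1), 0)
})

test_that("proximal wing region keeps the distance-ranked nearest fraction", {
  body <- matrix(FALSE, 9, 40); body[, 1:3] <- TRUE
  wing <- matrix(FALSE, 9, 40); wing[, 4:33] <- TRUE  # 30-column strip

  expect_identical(proximal_wing_region(wing, body, 1), wing)

  sel <- proximal_wing_region(wing, body, 1 / 3)
  expect_equal(sum(sel), ceiling(sum(wing) / 3))
  expect_true(all(which(colSums(sel) > 0) == 4:13))  # the 10 nearest columns
  expect_identical(sel, oracle_proximal(wing, body, 1 / 3))

  # empty wing mask is allowed and returns an empty mask
  expect_identical(proximal_wing_region(wing & FALSE, body, 0.5), wing & FALSE)
})

test_that("two symmetric wings are reduced per component, not jointly", {
  body <- matrix(FALSE, 11, 41); body[, 19:23] <- TRUE
  wing <- matrix(FALSE, 11, 41)
  wing[4:8, 5:16] <- TRUE    # left wing
  wing[4:8, 26:37] <- TRUE   # right wing
  sel <- proximal_wing_region(wing, body, 1 / 3)
  left <- sum(sel[, 1:20]); right <- sum(sel[, 22:41])
  expect_lte(abs(left - right), 1)
  expect_equal(left + right, 2 * ceiling(sum(wing) / 2 / 3))
  expect_identical(sel, oracle_proximal(wing, body, 1 / 3))
})

test_that("irregular wing shapes match the brute-force distance oracle", {
  set.seed(4)
  body <- matrix(FALSE, 25, 25); body[10:16, 11:14] <- TRUE
  wing <- matrix(FALSE, 25, 25)
  wing[3:22, 3:8] <- matrix(runif(120) < 0.7, 20, 6)
  wing[3:22, 17:23] <- matrix(runif(140) < 0.7, 20, 7)
  wing <- wing & !body
  for (f in c(0.2, 1 / 3, 0.8)) {
    got <- proximal_wing_region(wing, body, f)
    want <- oracle_proximal(wing, body, f)
    expect_identical(got, want)
  }
})

test_that("wing area is pixel count times pixel area", {
  s <- 0.01
  mask <- matrix(TRUE, 100, 100)
  expect_equal(wing_area(mask, 2.54 / s), 1.0, tolerance = 1e-12)
  expect_equal(wing_area(mask & FALSE, 300), 0)
})

test_that("rendered polygon wings recover the shoelace area within 1%", {
  wing <- cbind(c(0.1, 1.1, 1.4, 0.7, 0.1), c(0.0, 0.45, -0.2, -0.6, -0.3))
  sp <- specimen_spec(1.0, 0.08, list(wing), dpi = 1200)
  r <- render_specimen_image(sp)
  expect_gt(sum(r$wing_mask), 1e4)
  expect_equal(wing_area(r$wing_mask, 1200), oracle_shoelace(wing),
               tolerance = 0.01)
})

test_that("area and volume scale as s^2 and s^3 under exact 2x downsampling", {
  mask <- matrix(FALSE, 200, 60); mask[21:180, 11:50] <- TRUE
  half <- mask[seq(1, 200, 2), seq(1, 60, 2)] &
    mask[seq(2, 200, 2), seq(1, 60, 2)] &
    mask[seq(1, 200, 2), seq(2, 60, 2)] &
    mask[seq(2, 200, 2), seq(2, 60, 2)]
  a1 <- wing_area(mask, 1200); a2 <- wing_area(half, 600)
  v1 <- body_volume(mask, 1200); v2 <- body_volume(half, 600)
  expect_lt(abs(a2 - a1) / a1, 0.02)
  expect_lt(abs(v2 - v1) / v1, 0.04)
})

test_that("residual wing area matches the normal-equations oracle", {
  # perfect power law: all residuals vanish
  v <- c(0.5, 1, 2, 4, 8)
  a <- 3 * v^0.66
  expect_equal(residual_wing_area(a, v), rep(0, 5), tolerance = 1e-10)

  set.seed(12)
  vols <- exp(rnorm(100, 0, 0.8))
  areas <- exp(0.4 + 0.66 * log(vols) + rnorm(100, 0, 0.2))
  got <- residual_wing_area(areas, vols)
  expect_equal(got, oracle_log_residuals(areas, vols), tolerance = 1e-8)
  expect_lt(abs(sum(got)), 1e-10)
  # invariant to rescaling all volumes (intercept absorbs the shift)
  expect_equal(got, residual_wing_area(areas, vols * 37), tolerance = 1e-10)

  expect_error(residual_wing_area(c(1, 2), c(1, 2)), "at least 3")
  expect_error(residual_wing_area(c(1, -2, 3), c(1, 2, 3)), "positive")
  expect_error(residual_wing_area(c(1, 2, 3), c(2, 2, 2)), "singular")
})

test_that("a specimen directory yields a complete morphometric table", {
  d <- withr::local_tempdir()
  set.seed(30)
  for (i in 1:4) {
    w <- 0.06 + 0.02 * i; l <- 0.5 + 0.2 * i
    wing <- cbind(c(w / 2, w / 2 + 0.4, w / 2 + 0.3, w / 2),
                  c(l / 4, l / 3, -l / 4, -l / 8))
    sp <- specimen_spec(l, w, list(wing), body_gray = 40 + 30 * i,
                        wing_gray_profile = 150, dpi = 600)
    write_specimen(render_specimen_image(sp), d, paste0("sp", i))
  }
  tab <- measure_specimen_dir(d)
  expect_equal(nrow(tab), 4)
  expect_named(tab, c("species", "body_volume_cm3", "color_lightness",
                      "wing_area_cm2", "residual_wing_area"))
  expect_true(all(tab$body_volume_cm3 > 0))
  expect_lt(abs(sum(tab$residual_wing_area)), 1e-10)
})
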