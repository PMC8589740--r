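make_brain <- function(n_voxels, dims = c(30, 30, 30), vox_mm = 1) {
  m <- array(0L, dims)
  m[seq_len(n_voxels)] <- 1L
  structure(list(mask = ct_volume(m, spacing = rep(vox_mm, 3)),
                 brain_volume_ml = n_voxels * vox_mm^3 / 1000),
            class = "brain_mask")
}

test_that("MTA measure is the forced volume fraction", {
  dims <- c(30, 30, 30)
  brain <- make_brain(10000, dims)
  csf <- array(0L, dims); csf[1:100] <- 1L
  mtl_l <- array(0L, dims); mtl_l[1:200] <- 1L
  mtl_r <- array(0L, dims); mtl_r[5000 + 1:200] <- 1L
  m <- measure_mta(ct_volume(csf), ct_volume(mtl_l), ct_volume(mtl_r),
                   brain)
  expect_equal(unname(m["mta_left_raw"]), 0.01)
  expect_equal(unname(m["mta_right_raw"]), 0)
  empty <- measure_mta(ct_volume(csf * 0L), ct_volume(mtl_l),
                       ct_volume(mtl_r), brain)
  expect_equal(unname(empty["mta_left_raw"]), 0)
})

test_that("GCA measure counts strict exceedances of the percentile map", {
  dims <- c(40, 40, 40)
  brain <- make_brain(50000, dims)
  p99 <- array(0.9, dims)
  prob <- array(0.5, dims)
  m0 <- measure_gca(ct_volume(prob), ct_volume(p99), brain)
  expect_equal(unname(m0["gca_raw"]), 0)
  prob[1:500] <- 1
  m1 <- measure_gca(ct_volume(prob), ct_volume(p99), brain)
  expect_equal(unname(m1["gca_raw"]), 0.01)
  # equality is not an exceedance (strict >)
  prob_eq <- array(0.9, dims)
  meq <- measure_gca(ct_volume(prob_eq), ct_volume(p99), brain)
  expect_equal(unname(meq["gca_raw"]), 0)
})

test_that("per-lobe abnormal volumes add up over the lobe partition", {
  dims <- c(40, 40, 40)
  brain <- make_brain(64000, dims, vox_mm = 1)
  brain$mask <- ct_volume(array(1L, dims))
  brain$brain_volume_ml <- 64000 / 1000
  set.seed(41)
  prob <- array(runif(64000), dims)
  p99 <- array(0.7, dims)
  lobes <- array(sample(1:4, 64000, TRUE), dims)
  m <- measure_gca(ct_volume(prob), ct_volume(p99), brain,
                   ct_volume(lobes))
  lobe_sum <- sum(m[c("gca_frontal_raw", "gca_temporal_raw",
                      "gca_parietal_raw", "gca_occipital_raw")])
  expect_equal(lobe_sum, unname(m["gca_raw"]), tolerance = 1e-12)
})

test_that("Fazekas measure restricts lesions to the deep WM mask", {
  dims <- c(30, 30, 30)
  brain <- make_brain(25000, dims)
  wml <- array(0L, dims); wml[1:250] <- 1L
  deep <- array(1L, dims)
  m <- measure_fazekas(ct_volume(wml), ct_volume(deep), brain)
  expect_equal(unname(m["fazekas_raw"]), 0.01)
  outside <- array(0L, dims); outside[26000 + 1:100] <- 1L
  deep2 <- array(0L, dims); deep2[1:1000] <- 1L
  m2 <- measure_fazekas(ct_volume(outside), ct_volume(deep2), brain)
  expect_equal(unname(m2["fazekas_raw"]), 0)
})

test_that("calibration reproduces an exactly linear relation", {
  set.seed(42)
  measure <- runif(60, 0, 0.05)
  grade <- 2 + 50 * measure  # exactly linear, spans 3+ rounded grades
  fit <- fit_calibration(measure, grade, "mta")
  pred <- apply_calibration(fit, measure)
  expect_equal(pred, grade, tolerance = 1e-8)
  # step-2 knots sit on the identity line
  expect_equal(fit$knots_x, fit$knots_y, tolerance = 1e-8)
})

test_that("calibration matches per-grade medians on the training data", {
  set.seed(43)
  n <- 150
  grade <- runif(n, 0, 4)
  measure <- 0.002 + 0.01 * grade^1.5 + rnorm(n, 0, 0.002)
  fit <- fit_calibration(measure, grade, "mta")
  pred <- apply_calibration(fit, measure)
  g_round <- round(pmin(pmax(grade, 0), 4))
  for (g in sort(unique(g_round))) {
    sel <- g_round == g
    # each knot maps the group's median step-1 estimate to the group's
    # median ground-truth grade; since the linear step is monotone, the
    # median measure maps there exactly
    expect_equal(apply_calibration(fit, median(measure[sel])),
                 median(grade[sel]), tolerance = 1e-6)
    expect_equal(median(pred[sel]), median(grade[sel]), tolerance = 0.15)
  }
  expect_gt(pearson_r(pred, grade), 0.9)
})

test_that("calibrated prediction is monotone and extrapolates linearly", {
  model <- structure(list(coef = c(0, 10), knots_x = c(1, 2, 3),
                          knots_y = c(0.5, 2, 2.5), scale = "gca",
                          grade_range = c(0, 3), n_train = 20),
                     class = "ct_calibration")
  xs <- seq(0, 0.5, length.out = 40)
  out <- apply_calibration(model, xs)
  expect_true(all(diff(out) >= -1e-12))
  # beyond the last knot: slope of the final segment (0.5 per unit)
  expect_equal(apply_calibration(model, 0.4), 2.5 + 0.5 * 1)
  # below the first knot: slope of the first segment (1.5 per unit)
  expect_equal(apply_calibration(model, 0), 0.5 - 1.5 * 1)
  # knots map exactly
  expect_equal(apply_calibration(model, c(0.1, 0.2, 0.3)),
               c(0.5, 2, 2.5))
})

test_that("calibration is invariant to affine rescaling of the measure", {
  set.seed(44)
  grade <- runif(80, 0, 3)
  measure <- 0.01 + 0.005 * grade + rnorm(80, 0, 0.001)
  f1 <- fit_calibration(measure, grade, "gca")
  f2 <- fit_calibration(1000 * measure + 7, grade, "gca")
  x_new <- seq(min(measure), max(measure), length.out = 11)
  expect_equal(apply_calibration(f1, x_new),
               apply_calibration(f2, 1000 * x_new + 7), tolerance = 1e-8)
})

test_that("calibration input contracts are enforced", {
  expect_error(fit_calibration(rep(0.1, 20), runif(20, 0, 3), "gca"),
               "degenerate")
  expect_error(fit_calibration(runif(5), runif(5, 0, 3), "gca"),
               "at least 10")
  expect_error(fit_calibration(runif(20), rep(c(0.9, 1.1), 10), "gca"),
               "3 distinct")
})

test_that("categorization clamps then rounds, and flags normality", {
  expect_equal(categorize(4.7, c(0, 4))$categorical, 4L)
  expect_equal(categorize(-0.3, c(0, 3))$categorical, 0L)
  expect_equal(categorize(c(2.4, 2.6), c(0, 3))$categorical, c(2L, 3L))
  # half-integers round away from zero
  expect_equal(categorize(2.5, c(0, 3))$categorical, 3L)
  cats <- categorize(c(1, 2), c(0, 3))
  expect_equal(cats$abnormal, c(FALSE, TRUE))
  expect_error(categorize(NaN, c(0, 3)), "NA")
  expect_equal(grade_range("mta"), c(0, 4))
  expect_equal(grade_range("fazekas"), c(0, 3))
})
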