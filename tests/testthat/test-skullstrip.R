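test_that("nonlocal means fixes constants and respects h = 0", {
  v <- ct_volume(array(12, c(10, 10, 10)))
  expect_equal(denoise_nlm(v, h = 5)$data, v$data, tolerance = 1e-12)
  set.seed(2)
  w <- ct_volume(array(rnorm(10^3), c(10, 10, 10)))
  expect_identical(denoise_nlm(w, h = 0)$data, w$data)
})

test_that("nonlocal means reduces per-class noise on a phantom", {
  ph <- make_phantom(phantom_spec(noise_sd = 10, rng_seed = 3))
  den <- denoise_nlm(ph$ct)
  for (cls in c("gm", "wm", "csf")) {
    sel <- ph$labels$data == phantom_labels[[cls]]
    expect_lt(sd(den$data[sel]), sd(ph$ct$data[sel]))
  }
})

test_that("outlier removal clips to the computed percentile range", {
  set.seed(4)
  v <- ct_volume(array(rnorm(12^3, 50, 5), c(12, 12, 12)))
  expect_equal(remove_outliers(v, 0, 100)$data, v$data)
  spiked <- v
  spiked$data[5, 5, 5] <- 1e6
  q <- quantile(as.vector(spiked$data), 0.999, names = FALSE)
  out <- remove_outliers(spiked, 0, 99.9)
  expect_equal(max(out$data), q)
  flat <- ct_volume(array(7, c(8, 8, 8)))
  expect_equal(remove_outliers(flat)$data, flat$data)
  expect_error(remove_outliers(v, 50, 40), "low_pct")
})

test_that("EM recovers a well-separated two-class mixture", {
  set.seed(11)
  x <- c(rnorm(5000, 0, 5), rnorm(5000, 100, 5))
  em <- em_two_class(x)
  expect_lt(abs(em$class_means[1] - 0), 1)
  expect_lt(abs(em$class_means[2] - 100), 1)
  expect_equal(rowSums(em$posteriors), rep(1, length(x)), tolerance = 1e-12)
  # log-likelihood nondecreasing at every iteration
  expect_true(all(diff(em$loglik_trace) > -1e-9))
})

test_that("EM at the true parameters converges immediately", {
  set.seed(12)
  x <- c(rnorm(4000, 0, 5), rnorm(4000, 100, 5))
  em <- em_two_class(x, init = list(means = c(0, 100), sds = c(5, 5)))
  expect_lte(em$n_iter, 3)
  expect_true(em$converged)
})

test_that("EM rejects degenerate input", {
  expect_error(em_two_class(rep(5, 1000)), "variance")
  expect_error(em_two_class(c(1, 2)), "few")
})

test_that("skull threshold solves the posterior-equality equation", {
  sym <- structure(list(class_means = c(20, 80), class_sds = c(10, 10),
                        class_priors = c(0.5, 0.5)), class = "em_model")
  expect_equal(skull_threshold_from_em(sym), 50)
  # asymmetric SDs: compare with a numeric root of the density equality
  asym <- structure(list(class_means = c(20, 400), class_sds = c(15, 80),
                         class_priors = c(0.5, 0.5)), class = "em_model")
  thr <- skull_threshold_from_em(asym)
  f <- function(x) 0.5 * dnorm(x, 20, 15) - 0.5 * dnorm(x, 400, 80)
  root <- uniroot(f, c(20, 400))$root
  expect_equal(thr, root, tolerance = 1e-4)
  degen <- structure(list(class_means = c(50, 50), class_sds = c(5, 5),
                          class_priors = c(0.5, 0.5)), class = "em_model")
  expect_warning(thr2 <- skull_threshold_from_em(degen), "fallback|separable")
  expect_equal(thr2, 200)
})

test_that("morphological fine-tuning yields one hole-free component", {
  d <- c(24, 24, 24)
  ball <- array(0L, d)
  cc <- (12 - seq_len(24))^2
  r2 <- outer(outer(cc, cc, `+`), cc, `+`)
  ball[r2 <= 64] <- 1L
  ball_v <- ct_volume(ball)
  bm <- refine_mask_morphology(ball_v)
  expect_gt(dice(bm$mask$data, ball), 0.95)

  speck <- ball
  speck[2, 2, 2] <- 1L
  bm2 <- refine_mask_morphology(ct_volume(speck))
  expect_equal(bm2$mask$data[2, 2, 2], 0L)

  holed <- ball
  holed[11:13, 11:13, 11:13] <- 0L
  bm3 <- refine_mask_morphology(ct_volume(holed))
  expect_equal(sum(bm3$mask$data[11:13, 11:13, 11:13] == 0), 0)
  expect_error(refine_mask_morphology(ct_volume(array(0L, c(8, 8, 8)))),
               "empty")
})

test_that("skull stripping recovers the phantom brain", {
  ph <- make_phantom(phantom_spec(mta_severity = 1, gca_severity = 1,
                                  noise_sd = 0, rng_seed = 21))
  bm <- skull_strip(ph$ct)
  truth <- ph$labels$data >= phantom_labels[["gm"]]
  expect_gt(dice(bm$mask$data, truth), 0.98)
  expect_gt(bm$brain_volume_ml, 0)
  # final mask excludes every voxel above the skull threshold
  expect_equal(sum(bm$mask$data != 0 & ph$ct$data > bm$skull_threshold), 0)
  # air-only input fails with a stage-labelled error
  air <- ct_volume(array(-1000, c(48, 48, 48)))
  expect_error(skull_strip(air), "air threshold|failed")
})
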