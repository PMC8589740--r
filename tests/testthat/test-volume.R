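test_that("ct_volume validates its grid metadata", {
  expect_error(ct_volume(matrix(0, 2, 2)), "3D")
  expect_error(ct_volume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "positive")
  v <- ct_volume(array(1:8, c(2, 2, 2)), spacing = c(1, 2, 3),
                 origin = c(-1, 0, 5))
  expect_identical(dim(v), c(2L, 2L, 2L))
  expect_equal(voxel_volume_ml(v), 6 / 1000)
  expect_true(same_grid(v, with_data(v, v$data * 2)))
})

test_that("NIfTI round trip preserves data, spacing and origin", {
  dir <- withr::local_tempdir()
  lab <- array(sample(0L:5L, 6^3, TRUE), c(6, 6, 6))
  vi <- ct_volume(lab, spacing = c(2.5, 2.5, 5), origin = c(-10, 4, 2))
  pi_ <- file.path(dir, "lab.nii.gz")
  write_volume(vi, pi_, datatype = "int16")
  ri <- read_volume(pi_)
  expect_identical(array(as.integer(ri$data), dim(lab)), lab)
  expect_equal(ri$spacing, vi$spacing, tolerance = 1e-6)
  expect_equal(ri$origin, vi$origin, tolerance = 1e-5)

  vd <- ct_volume(array(rnorm(6^3), c(6, 6, 6)), spacing = c(1, 1.5, 2))
  pd <- file.path(dir, "ct.nii.gz")
  write_volume(vd, pd)
  rd <- read_volume(pd)
  expect_equal(rd$data, vd$data, tolerance = 1e-12)
})

test_that("dice matches its definition and handles empty masks", {
  a <- array(0, c(4, 4, 4)); a[1:2, , ] <- 1
  b <- array(0, c(4, 4, 4)); b[2:3, , ] <- 1
  expect_equal(dice(a, b), 2 * 16 / (32 + 32))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a * 0, a * 0), 1)
})

test_that("gaussian smoothing preserves constants and mass", {
  v <- ct_volume(array(3.5, c(8, 8, 8)))
  expect_equal(smooth_gaussian(v, 1.2)$data, v$data, tolerance = 1e-12)
  set.seed(1)
  w <- ct_volume(array(runif(8^3), c(8, 8, 8)))
  sm <- smooth_gaussian(w, 1)
  expect_lt(sd(sm$data), sd(w$data))
  expect_equal(mean(sm$data), mean(w$data), tolerance = 0.02)
})
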