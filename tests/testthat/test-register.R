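test_that("affine transform composes rotation, scale and translation", {
  tf <- affine_transform(c(1, 2, 3), c(0, 0, 90), c(2, 1, 1),
                         center = c(0, 0, 0))
  M <- affine_matrix(tf)
  # 90 deg about z sends scaled x-axis (2,0,0) to (0,2,0), plus t
  p <- M %*% c(1, 0, 0, 1)
  expect_equal(as.vector(p)[1:3], c(0 + 1, 2 + 2, 0 + 3), tolerance = 1e-12)
  expect_error(affine_transform(scale = c(0, 1, 1)), "positive")
})

test_that("registering a mask to itself returns the identity", {
  bundle <- small_bundle()
  tf <- affine_register_masks(bundle$skull_mask, bundle$skull_mask,
                              rotation_starts = 0)
  expect_lt(max(abs(tf$translation)), 0.1 * 2.5)
  expect_lt(max(abs(tf$rotation)), 0.1)
  expect_lt(max(abs(tf$scale - 1)), 0.01)
})

test_that("known translations and scales are recovered", {
  bundle <- small_bundle()
  skull <- bundle$skull_mask
  center <- ctquant:::mask_centroid_world(skull)
  tf_true <- affine_transform(c(3, -2, 1) * 2.5, c(0, 0, 0), c(1, 1, 1),
                              center = center)
  moved <- transport(skull, tf_true, skull, "inverse", "nearest")
  tf_hat <- affine_register_masks(moved, skull, rotation_starts = 0)
  expect_lt(max(abs(tf_hat$translation - tf_true$translation)) / 2.5, 0.5)

  tf_scale <- affine_transform(c(0, 0, 0), c(0, 0, 0), rep(1.05, 3),
                               center = center)
  scaled <- transport(skull, tf_scale, skull, "inverse", "nearest")
  tf_hat2 <- affine_register_masks(scaled, skull, rotation_starts = 0)
  expect_lt(max(abs(tf_hat2$scale - 1.05)), 0.02)
})

test_that("empty masks are rejected", {
  empty <- ct_volume(array(0L, c(16, 16, 16)))
  ball <- empty
  ball$data[6:10, 6:10, 6:10] <- 1L
  expect_error(affine_register_masks(empty, ball), "empty")
})

test_that("transport preserves grids, labels and round trips", {
  ph <- demo_phantom()
  lab <- ph$labels
  # identity transform, nearest: bit-exact
  out <- transport(lab, NULL, lab, "forward", "nearest")
  expect_equal(out$data, lab$data * 1.0)
  # labels stay in the original alphabet under nearest interpolation
  tf <- affine_transform(c(2, -1, 3), c(4, -3, 2), c(1.02, 0.98, 1),
                         center = c(70, 70, 70))
  warped <- transport(lab, tf, lab, "forward", "nearest")
  expect_true(all(warped$data %in% phantom_labels))
  # affine round trip on a smooth volume stays within interpolation error
  smooth <- smooth_gaussian(ph$ct, 2)
  fwd <- transport(smooth, tf, smooth, "forward", "linear",
                   fill = min(smooth$data))
  back <- transport(fwd, tf, smooth, "inverse", "linear",
                    fill = min(smooth$data))
  interior <- ctquant:::.cq_morph(
    array(as.integer(ph$labels$data >= 2), dim(lab$data)), 4, 0L)
  err <- abs(back$data - smooth$data)[interior == 1]
  expect_lt(max(err), 12)
  expect_lt(median(err), 1.5)
})

test_that("z-scoring fulfils its contract and affine invariance", {
  ph <- demo_phantom()
  mask <- ctquant:::phantom_brain_mask(ph)
  z <- zscore_brain(ph$ct, mask)
  sel <- mask$data != 0
  expect_equal(mean(z$data[sel]), 0, tolerance = 1e-6)
  expect_equal(sd(z$data[sel]), 1, tolerance = 1e-6)
  expect_true(all(z$data[!sel] == 0))
  rescaled <- with_data(ph$ct, 3.7 * ph$ct$data + 11)
  z2 <- zscore_brain(rescaled, mask)
  expect_equal(z2$data, z$data, tolerance = 1e-9)
  one <- with_data(mask, array(0L, dim(mask$data)))
  one$data[2, 2, 2] <- 1L
  expect_error(zscore_brain(ph$ct, one), "fewer than 2")
  flat <- with_data(ph$ct, array(5, dim(ph$ct$data)))
  expect_error(zscore_brain(flat, mask), "variance")
})

test_that("NMI is maximal for self-comparison", {
  ph <- demo_phantom()
  x <- smooth_gaussian(ph$ct, 1)
  tf <- affine_transform(c(3, 0, 0), c(0, 0, 5), c(1, 1, 1),
                         center = c(70, 70, 70))
  moved <- transport(x, tf, x, "forward", "linear", fill = min(x$data))
  expect_gt(nmi(x, x), nmi(x, moved))
  expect_error(nmi(rep(1, 10), 1:10), "constant")
})

test_that("nonrigid refinement leaves identical images in place", {
  ph <- make_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                  voxel_size_mm = 5, noise_sd = 3,
                                  rng_seed = 31))
  x <- ph$ct
  def <- nonrigid_refine(x, x, max_iter = 8, knot_spacing_vox = 6)
  expect_lt(max(abs(def$field)) / 5, 0.2)
  expect_true(all(diff(def$nmi_trace) > -1e-12))
})

test_that("nonrigid refinement increases NMI for a warped image", {
  ph <- make_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                  voxel_size_mm = 5, noise_sd = 3,
                                  rng_seed = 32))
  fixed <- ph$ct
  # synthetic smooth warp of the template as the moving image
  d <- dim(fixed$data)
  ctr <- (d - 1) / 2 * fixed$spacing
  W <- voxel_world_coords(fixed)
  disp <- array(0, c(d, 3))
  disp[, , , 1] <- array(4 * sin(W[, 2] / 40), d)
  disp[, , , 2] <- array(3 * cos(W[, 1] / 50), d)
  moving <- ctquant:::resample_to_grid(
    fixed, d, fixed$spacing, fixed$origin, diag(4),
    disp = list(field = disp, spacing = fixed$spacing,
                origin = fixed$origin),
    fill = min(fixed$data))
  nmi0 <- nmi(fixed, moving)
  def <- nonrigid_refine(fixed, moving, max_iter = 20,
                         knot_spacing_vox = 4)
  expect_gt(tail(def$nmi_trace, 1), nmi0)
  expect_true(all(diff(def$nmi_trace) > -1e-12))
})
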