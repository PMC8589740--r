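test_that("mean template averages voxelwise, NaN-aware", {
  a <- ct_volume(array(rnorm(4^3), c(4, 4, 4)))
  expect_equal(build_mean_template(list(a, a))$data, a$data)
  b <- with_data(a, -a$data)
  expect_equal(build_mean_template(list(a, b))$data,
               array(0, c(4, 4, 4)))
  # voxels missing in one subject use the remaining subjects
  c1 <- with_data(a, a$data)
  c1$data[1, 1, 1] <- NA
  m <- build_mean_template(list(c1, b))
  expect_equal(m$data[1, 1, 1], b$data[1, 1, 1])
  expect_error(build_mean_template(list(a)), "at least 2")
})

test_that("mean of noisy phantoms approaches class intensities", {
  phs <- lapply(1:10, function(i)
    make_phantom(phantom_spec(noise_sd = 8, rng_seed = 100 + i))$ct)
  m <- build_mean_template(phs)
  lab <- make_phantom(phantom_spec(noise_sd = 0, rng_seed = 1))$labels
  # default severities: identical geometry across seeds, only noise varies
  wm <- lab$data == phantom_labels[["wm"]]
  csf <- lab$data == phantom_labels[["csf"]]
  expect_equal(mean(m$data[wm]), 30, tolerance = 0.05)
  expect_equal(mean(m$data[csf]), 8, tolerance = 0.3)
})

test_that("percentile map obeys the order-statistic definition", {
  set.seed(51)
  common <- ct_volume(array(runif(5^3), c(5, 5, 5)))
  same <- replicate(12, common, simplify = FALSE)
  for (p in c(25, 50, 99))
    expect_equal(build_csf_percentile_map(same, p)$data, common$data)

  refs <- replicate(100, ct_volume(array(runif(5^3), c(5, 5, 5))),
                    simplify = FALSE)
  p99 <- build_csf_percentile_map(refs, 99)
  expect_equal(mean(p99$data), 0.99, tolerance = 0.02)
  # at each voxel at most 1% of subjects strictly exceed the map value
  mat <- sapply(refs, function(v) as.vector(v$data))
  frac_above <- rowMeans(mat > as.vector(p99$data))
  expect_true(all(frac_above <= 0.01 + 1e-9))
  # permutation invariance in subject order
  p99b <- build_csf_percentile_map(refs[sample(100)], 99)
  expect_equal(p99b$data, p99$data)
  expect_error(build_csf_percentile_map(refs[1:5]), "at least 10")
  expect_error(build_csf_percentile_map(refs, 100), "strictly")
})

test_that("lobe labels extend into CSF by nearest-site distance", {
  # two-lobe toy grid with a CSF band between them
  d <- c(20, 8, 8)
  parc <- array(0L, d)
  parc[1:6, , ] <- 1L
  parc[15:20, , ] <- 4L
  csf <- array(0L, d)
  csf[7:14, , ] <- 1L
  out <- build_lobe_labels(ct_volume(parc, spacing = c(1, 1, 1)),
                           ct_volume(csf, spacing = c(1, 1, 1)))
  # brute-force nearest-neighbour oracle over all voxels
  sites <- which(parc != 0, arr.ind = TRUE)
  for (v in seq(1, prod(d), by = 37)) {
    idx <- arrayInd(v, d)
    if (csf[v] == 0 || parc[v] != 0) next
    dists <- sqrt(rowSums(sweep(sites, 2, as.numeric(idx))^2))
    best <- min(dists)
    labs <- parc[sites[dists < best + 1e-9, , drop = FALSE]]
    expect_equal(out$data[v], min(labs))
  }
  # equidistant plane at x = 10/11 splits between labels 1 and 4
  expect_true(all(out$data[7:10, , ] == 1L))
  expect_true(all(out$data[11:14, , ] == 4L))
  # no CSF outside the parcellation: unchanged
  out2 <- build_lobe_labels(ct_volume(parc), ct_volume(array(0L, d)))
  expect_identical(out2$data, parc)
  expect_error(build_lobe_labels(ct_volume(array(0L, d)),
                                 ct_volume(csf)), "empty")
})

test_that("synthetic MTL and deep-WM masks cover their phantom targets", {
  bundle <- small_bundle()
  skull <- bundle$skull_mask$data != 0
  expect_equal(sum(bundle$mtl_mask$data != 0 & skull), 0)
  expect_equal(sum(bundle$deep_wm_mask$data != 0 & skull), 0)
  ph <- make_phantom(phantom_spec(mta_severity = c(3, 3),
                                  fazekas_severity = 2.5, noise_sd = 0,
                                  rng_seed = 13))
  # zero pose: template grid and phantom grid coincide
  dil <- function(m)
    ctquant:::.cq_morph(array(as.integer(m != 0), dim(m)), 2, 1L)
  # every lesion voxel lies within the (dilated) deep-WM mask
  wml_in <- ph$labels$data == phantom_labels[["wml"]]
  expect_gt(sum(wml_in), 0)
  expect_true(all(dil(bundle$deep_wm_mask$data)[wml_in] == 1))
  # the medial-temporal CSF pockets lie within the (dilated) MTL mask:
  # pocket voxels are the CSF voxels inside the analytic pocket spheres
  g <- ctquant:::phantom_geometry()
  r_pocket <- (g$mtl_r0_mm^3 + 3 * g$mtl_vol_per_sev /
                 (4 * pi / 3))^(1 / 3)
  W <- voxel_world_coords(ph$labels)
  ctr <- (dim(ph$labels$data) - 1) / 2 * ph$labels$spacing
  W <- sweep(W, 2, ctr)
  in_pocket <- rep(FALSE, nrow(W))
  for (h in 1:2)
    in_pocket <- in_pocket |
      sqrt(rowSums(sweep(W, 2, g$mtl_centers[h, ])^2)) <= r_pocket
  pocket_csf <- in_pocket & ph$labels$data == phantom_labels[["csf"]]
  expect_gt(sum(pocket_csf), 0)
  expect_true(all(dil(bundle$mtl_mask$data)[pocket_csf] == 1))
})

test_that("lobe label map covers brain plus peripheral CSF with 4 labels", {
  bundle <- small_bundle()
  labs <- unique(as.vector(bundle$lobe_labels$data))
  expect_true(all(labs %in% 0:4))
  expect_setequal(setdiff(labs, 0L), 1:4)
})

test_that("template bundle round-trips through disk", {
  bundle <- small_bundle()
  dir <- withr::local_tempdir()
  write_template_bundle(bundle, dir)
  expect_true(file.exists(file.path(dir, "bundle.json")))
  back <- read_template_bundle(dir)
  expect_identical(back$lobe_labels$data, bundle$lobe_labels$data)
  expect_identical(back$mtl_mask$data, bundle$mtl_mask$data)
  expect_equal(back$mean_ct$data, bundle$mean_ct$data, tolerance = 1e-9)
  expect_equal(back$csf_p99$data, bundle$csf_p99$data, tolerance = 1e-9)
  expect_equal(back$mean_ct$spacing, bundle$mean_ct$spacing,
               tolerance = 1e-6)
})
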