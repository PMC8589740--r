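test_that("spec validation enforces severity ranges and grid size", {
  expect_error(phantom_spec(mta_severity = 5), "mta")
  expect_error(phantom_spec(gca_severity = -0.1), "gca")
  expect_error(phantom_spec(fazekas_severity = 3.5), "fazekas")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(grid_shape = c(16, 64, 64)), "32")
})

test_that("zero-severity noise-free phantom has no lesions and clean classes", {
  ph <- make_phantom(phantom_spec(noise_sd = 0))
  lab <- ph$labels$data
  expect_equal(sum(lab == phantom_labels[["wml"]]), 0)
  expect_true(all(lab %in% phantom_labels))
  # noise contract: intensities piecewise constant per class
  for (cls in names(phantom_labels)) {
    sel <- lab == phantom_labels[[cls]]
    if (any(sel)) expect_equal(sd(ph$ct$data[sel]), 0)
  }
  # baseline MTL CSF fraction: the r0-sized pocket of the geometry
  expect_gt(ph$truth$mta_left_raw, 0)
  expect_lt(ph$truth$mta_left_raw, 0.01)
})

test_that("same spec and seed give bit-identical volumes", {
  spec <- phantom_spec(mta_severity = c(1, 2), gca_severity = 1,
                       fazekas_severity = 1.5, noise_sd = 7, rng_seed = 42)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$labels$data, b$labels$data)
})

test_that("skull and lesions respect the anatomy partition", {
  ph <- demo_phantom()
  lab <- ph$labels$data
  brain <- lab >= phantom_labels[["gm"]]
  skull <- lab == phantom_labels[["skull"]]
  expect_equal(sum(brain & skull), 0)
  # WML voxels can only arise inside white matter, hence inside the brain
  expect_true(all(brain[lab == phantom_labels[["wml"]]]))
})

test_that("ground-truth volumes are monotone in their severities", {
  sweep_vals <- c(0, 1, 2, 3)
  wml_counts <- sapply(sweep_vals, function(f)
    sum(make_phantom(phantom_spec(fazekas_severity = f, noise_sd = 0,
                                  rng_seed = 5))$labels$data ==
          phantom_labels[["wml"]]))
  expect_true(all(diff(wml_counts) > 0))

  mtl <- sapply(c(0, 1, 2, 3, 4), function(m)
    make_phantom(phantom_spec(mta_severity = m, noise_sd = 0,
                              rng_seed = 5))$truth$mta_left_raw)
  expect_true(all(diff(mtl) > 0))

  csf <- sapply(c(0, 1, 2, 3), function(g)
    make_phantom(phantom_spec(gca_severity = g, noise_sd = 0,
                              rng_seed = 5))$truth$csf_raw)
  expect_true(all(diff(csf) > 0))
})

test_that("truth fractions are stable under consistent resampling", {
  a <- make_phantom(phantom_spec(mta_severity = 3, gca_severity = 2,
                                 fazekas_severity = 2, noise_sd = 0,
                                 rng_seed = 9, voxel_size_mm = 2.5))
  b <- make_phantom(phantom_spec(mta_severity = 3, gca_severity = 2,
                                 fazekas_severity = 2, noise_sd = 0,
                                 rng_seed = 9, voxel_size_mm = 2,
                                 grid_shape = c(80, 80, 80)))
  for (nm in c("mta_left_raw", "csf_raw", "fazekas_raw")) {
    expect_equal(a$truth[[nm]], b$truth[[nm]], tolerance = 0.12,
                 label = nm)
  }
})

test_that("cohort generation is reproducible and matches its sampler", {
  one <- make_cohort(1, seed = 3, grid_shape = c(32, 32, 32),
                     voxel_size_mm = 5)
  expect_equal(nrow(one$table), 1)

  a <- make_cohort(5, seed = 12, grid_shape = c(32, 32, 32),
                   voxel_size_mm = 5)
  b <- make_cohort(5, seed = 12, grid_shape = c(32, 32, 32),
                   voxel_size_mm = 5)
  expect_identical(a$table, b$table)
  expect_identical(a$pairs[[3]]$ct$data, b$pairs[[3]]$ct$data)

  big <- make_cohort(150, seed = 4, grid_shape = c(32, 32, 32),
                     voxel_size_mm = 5, noise_sd = 0, random_pose = FALSE)
  ks <- ks.test(big$table$gca, "punif", 0, 3)
  expect_gt(ks$p.value, 0.01)
  expect_error(make_cohort(0), "n must be")
})

test_that("cohorts write NIfTI pairs plus a readable cohort table", {
  dir <- withr::local_tempdir()
  co <- make_cohort(2, seed = 8, grid_shape = c(32, 32, 32),
                    voxel_size_mm = 5)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "sub-001_ct.nii.gz")))
  expect_true(file.exists(file.path(dir, "sub-002_labels.nii.gz")))
  tab <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(tab), 2)
  lab <- read_volume(file.path(dir, "sub-001_labels.nii.gz"))
  expect_identical(array(as.integer(lab$data), dim(lab$data)),
                   co$pairs[[1]]$labels$data)
})
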