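#' Label codes used by the head phantom
#'
#' Integer codes of the tissue classes in phantom label volumes:
#' air/background 0, skull 1, grey matter 2, white matter 3, CSF 4,
#' white-matter lesion (WML) 5.
#' @export
phantom_labels <- c(air = 0L, skull = 1L, gm = 2L, wm = 3L, csf = 4L,
                    wml = 5L)

#' Specification of a synthetic head phantom
#'
#' The phantom is a parametric head: concentric skull shell, brain
#' parenchyma split into a cortical grey-matter band and white-matter core,
#' lateral-ventricle analogues, bilateral medial-temporal CSF pockets whose
#' volume grows linearly with `mta_severity`, a sulcal CSF rim whose
#' thickness grows with `gca_severity` (plus mild ventricular enlargement),
#' and deep white-matter lesion blobs whose total volume grows linearly
#' with `fazekas_severity`. Intensities are pseudo-Hounsfield units with
#' CT-like contrast ordering (bone >> parenchyma > lesion > CSF >> air)
#' plus additive Gaussian noise.
#'
#' @param grid_shape voxels per axis (each >= 32), default `c(64, 64, 64)`.
#' @param voxel_size_mm isotropic spacing in mm (scalar), or length 3 for
#'   anisotropic grids mimicking thick-slice CT.
#' @param mta_severity medial-temporal atrophy severity in \[0, 4\]; scalar
#'   or `c(left, right)`.
#' @param gca_severity global cortical atrophy severity in \[0, 3\].
#' @param fazekas_severity white-matter-lesion load in \[0, 3\].
#' @param noise_sd additive Gaussian noise SD in intensity units (>= 0).
#' @param rng_seed integer seed controlling noise and lesion placement.
#' @param pose small rigid perturbation: list with `translation_vox`
#'   (length 3, voxels) and `rotation_deg` (length 3, degrees).
#' @param intensities named intensity lookup per class (pseudo-HU).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_size_mm = 2.5,
                         mta_severity = 0,
                         gca_severity = 0,
                         fazekas_severity = 0,
                         noise_sd = 5,
                         rng_seed = 1L,
                         pose = list(translation_vox = c(0, 0, 0),
                                     rotation_deg = c(0, 0, 0)),
                         intensities = c(air = -1000, skull = 900, gm = 38,
                                         wm = 30, csf = 8, wml = 20)) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  mta_severity <- rep_len(as.numeric(mta_severity), 2L)
  if (any(grid_shape < 32L)) stop("each grid axis must have >= 32 voxels")
  if (any(voxel_size_mm <= 0)) stop("voxel size must be positive")
  if (any(mta_severity < 0 | mta_severity > 4))
    stop("mta_severity must lie in [0, 4]")
  if (gca_severity < 0 || gca_severity > 3)
    stop("gca_severity must lie in [0, 3]")
  if (fazekas_severity < 0 || fazekas_severity > 3)
    stop("fazekas_severity must lie in [0, 3]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(pose$translation_vox)) pose$translation_vox <- c(0, 0, 0)
  if (is.null(pose$rotation_deg)) pose$rotation_deg <- c(0, 0, 0)
  if (!all(names(phantom_labels) %in% names(intensities)))
    stop("intensities must name all classes: ",
         paste(names(phantom_labels), collapse = ", "))
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 mta_severity = mta_severity, gca_severity = gca_severity,
                 fazekas_severity = fazekas_severity, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed), pose = pose,
                 intensities = intensities),
            class = "phantom_spec")
}

# Fixed head geometry (mm). The skull shell and tissue bands are nested
# ellipsoids; structure volumes are tied to severities so that ground-truth
# volume is (approximately) linear in each severity parameter.
phantom_geometry <- function() {
  list(
    head_radii = c(70, 75, 65),
    skull_thickness = 5,
    # asymmetric bony landmarks (frontal sinus, occipital protuberance,
    # right mastoid): they give the skull a rotationally identifiable shape
    skull_features = list(
      list(center = c(0, 72, -22), radii = c(14, 10, 10)),
      list(center = c(0, -74, -6), radii = c(11, 9, 13)),
      list(center = c(58, -28, -24), radii = c(9, 11, 9))),
    rim_base_mm = 2, rim_per_gca_mm = 3,
    cortex_mm = 8,
    vent_centers = rbind(c(-14, 5, 8), c(14, 5, 8)),
    vent_radii = c(6, 22, 8),
    vent_scale_per_gca = 0.12,
    mtl_centers = rbind(left = c(-33, -13, -18), right = c(33, -13, -18)),
    mtl_r0_mm = 3, mtl_vol_per_sev = 175.5 * 4 * pi / 3,  # ~linear volume
    mtl_region_r_mm = 11,
    wml_n_blobs = 6L,
    wml_vol_per_sev = 4000,          # mm^3 of lesion per Fazekas unit
    wml_jitter_mm = c(8, 20, 6),
    deep_wm_margin_mm = 15
  )
}

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# normalized ellipsoidal radius^2 of points P (n x 3, mm) for semi-axes a
ell2 <- function(P, a, center = c(0, 0, 0)) {
  ((P[, 1] - center[1]) / a[1])^2 + ((P[, 2] - center[2]) / a[2])^2 +
    ((P[, 3] - center[3]) / a[3])^2
}

#' Generate a synthetic head phantom
#'
#' Deterministic given `spec$rng_seed`: the same spec yields bit-identical
#' CT and label volumes. Ground-truth normalized volume fractions
#' (MTL CSF left/right, total and per-lobe CSF, deep-WM lesion volume, all
#' divided by intracranial volume) are recorded in `$truth` together with
#' the generating severities.
#'
#' @param spec a [phantom_spec()].
#' @return A `ct_phantom` list: `ct` (a [ct_volume()]), `labels`
#'   (integer-coded [ct_volume()], see [phantom_labels]), `truth`
#'   (one-row data frame), `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  g <- phantom_geometry()
  d <- spec$grid_shape
  sp <- spec$voxel_size_mm
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$rng_seed)

  # voxel centres in mm relative to grid centre, inverse-posed so the head
  # appears rotated/translated on the grid without any resampling
  ctr <- (d - 1) / 2 * sp
  i <- (seq_len(d[1]) - 1) * sp[1] - ctr[1]
  j <- (seq_len(d[2]) - 1) * sp[2] - ctr[2]
  k <- (seq_len(d[3]) - 1) * sp[3] - ctr[3]
  P <- cbind(rep(i, times = d[2] * d[3]),
             rep(rep(j, each = d[1]), times = d[3]),
             rep(k, each = d[1] * d[2]))
  t_mm <- spec$pose$translation_vox * sp
  R <- rotation_matrix(spec$pose$rotation_deg)
  P <- sweep(P, 2, t_mm) %*% R  # (R^-1 (x - t))' = (x - t)' R

  a_outer <- g$head_radii
  a_inner <- g$head_radii - g$skull_thickness
  rim <- g$rim_base_mm + g$rim_per_gca_mm * spec$gca_severity
  a_par <- a_inner - rim
  a_gm <- a_par - g$cortex_mm

  lab <- integer(nrow(P))
  in_outer <- ell2(P, a_outer) <= 1
  in_inner <- ell2(P, a_inner) <= 1
  in_par <- ell2(P, a_par) <= 1
  in_gm_core <- ell2(P, a_gm) <= 1
  lab[in_outer & !in_inner] <- phantom_labels[["skull"]]
  for (f in g$skull_features) {
    in_f <- ell2(P, f$radii, f$center) <= 1
    lab[in_f & !in_inner] <- phantom_labels[["skull"]]
  }
  lab[in_inner & !in_par] <- phantom_labels[["csf"]]   # sulcal rim
  lab[in_par & !in_gm_core] <- phantom_labels[["gm"]]
  lab[in_gm_core] <- phantom_labels[["wm"]]

  vent_r <- g$vent_radii * (1 + g$vent_scale_per_gca * spec$gca_severity)
  in_vent <- ell2(P, vent_r, g$vent_centers[1, ]) <= 1 |
    ell2(P, vent_r, g$vent_centers[2, ]) <= 1
  lab[in_vent & in_par] <- phantom_labels[["csf"]]

  # medial-temporal CSF pockets, volume linear in per-hemisphere severity
  mtl_r <- (g$mtl_r0_mm^3 +
              spec$mta_severity * g$mtl_vol_per_sev / (4 * pi / 3))^(1 / 3)
  in_mtl_l <- ell2(P, rep(mtl_r[1], 3), g$mtl_centers["left", ]) <= 1
  in_mtl_r <- ell2(P, rep(mtl_r[2], 3), g$mtl_centers["right", ]) <= 1
  lab[(in_mtl_l | in_mtl_r) & in_inner] <- phantom_labels[["csf"]]

  # deep white-matter lesions: fixed blob sites, total volume linear in load
  blob_centers <- matrix(0, 2 * g$wml_n_blobs, 3)
  for (b in seq_len(2 * g$wml_n_blobs)) {
    vent <- g$vent_centers[(b - 1) %% 2 + 1, ]
    blob_centers[b, ] <- vent + runif(3, -1, 1) * g$wml_jitter_mm
  }
  wml_total <- g$wml_vol_per_sev * spec$fazekas_severity
  wml_r <- (wml_total / (2 * g$wml_n_blobs) / (4 * pi / 3))^(1 / 3)
  if (wml_r > 0) {
    in_wml <- rep(FALSE, nrow(P))
    for (b in seq_len(nrow(blob_centers)))
      in_wml <- in_wml | ell2(P, rep(wml_r, 3), blob_centers[b, ]) <= 1
    lab[in_wml & lab == phantom_labels[["wm"]]] <- phantom_labels[["wml"]]
  }

  inten <- spec$intensities[c("air", "skull", "gm", "wm", "csf", "wml")]
  ct <- inten[lab + 1L]
  if (spec$noise_sd > 0) ct <- ct + rnorm(length(ct), 0, spec$noise_sd)

  dim(ct) <- d
  dim(lab) <- d
  ct_v <- ct_volume(ct, spacing = sp)
  lab_v <- ct_volume(lab, spacing = sp)

  # ground truth normalized fractions from the label grid
  brain <- lab >= phantom_labels[["gm"]]
  nb <- sum(brain)
  mtl_reg_l <- ell2(P, rep(g$mtl_region_r_mm, 3), g$mtl_centers["left", ]) <= 1
  mtl_reg_r <- ell2(P, rep(g$mtl_region_r_mm, 3), g$mtl_centers["right", ]) <= 1
  deep_a <- vent_r + g$deep_wm_margin_mm
  deep_wm <- ell2(P, deep_a, g$vent_centers[1, ]) <= 1 |
    ell2(P, deep_a, g$vent_centers[2, ]) <= 1
  is_csf <- lab == phantom_labels[["csf"]]
  is_wml <- lab == phantom_labels[["wml"]]
  truth <- data.frame(
    mta_left = spec$mta_severity[1], mta_right = spec$mta_severity[2],
    gca = spec$gca_severity, fazekas = spec$fazekas_severity,
    mta_left_raw = sum(is_csf & mtl_reg_l & brain) / nb,
    mta_right_raw = sum(is_csf & mtl_reg_r & brain) / nb,
    csf_raw = sum(is_csf) / nb,
    fazekas_raw = sum(is_wml & deep_wm) / nb,
    brain_volume_ml = nb * prod(sp) / 1000
  )
  structure(list(ct = ct_v, labels = lab_v, truth = truth, spec = spec),
            class = "ct_phantom")
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf(paste0("<ct_phantom> %s voxels, MTA L/R %.2f/%.2f, ",
                     "GCA %.2f, Fazekas %.2f, noise SD %.1f, seed %d\n"),
              paste(dim(x$ct$data), collapse = "x"),
              x$spec$mta_severity[1], x$spec$mta_severity[2],
              x$spec$gca_severity, x$spec$fazekas_severity,
              x$spec$noise_sd, x$spec$rng_seed))
  invisible(x)
}

#' Default cohort severity sampler
#'
#' Draws independent uniform severities over the full grade ranges: MTA
#' left/right in \[0, 4\], GCA and Fazekas in \[0, 3\]. Left and right MTA
#' are correlated (right = left + uniform jitter, clamped) as hemispheric
#' atrophy is in reality strongly symmetric.
#'
#' @param n number of subjects.
#' @return Data frame with columns `mta_left`, `mta_right`, `gca`,
#'   `fazekas`.
#' @export
uniform_severity_sampler <- function(n) {
  left <- runif(n, 0, 4)
  right <- pmin(4, pmax(0, left + runif(n, -0.8, 0.8)))
  data.frame(mta_left = left, mta_right = right,
             gca = runif(n, 0, 3), fazekas = runif(n, 0, 3))
}

#' Generate a cohort of phantoms with sampled severities
#'
#' @param n number of subjects (>= 1).
#' @param severity_sampler function of `n` returning a data frame with
#'   columns `mta_left`, `mta_right`, `gca`, `fazekas`; defaults to
#'   [uniform_severity_sampler()].
#' @param seed integer seed; severities, poses, noise realizations and
#'   per-subject phantom seeds all derive from it.
#' @param noise_sd noise level passed to every phantom.
#' @param random_pose if `TRUE` each subject gets a small random rigid pose
#'   (translations within ±2 voxels, rotations within ±5 degrees).
#' @param grid_shape,voxel_size_mm forwarded to [phantom_spec()].
#' @return A `ct_cohort` list: `pairs` (list of `ct_phantom`) and `table`
#'   (one row per subject: id, severities, ground-truth fractions).
#' @export
make_cohort <- function(n, severity_sampler = uniform_severity_sampler,
                        seed = 1L, noise_sd = 5, random_pose = TRUE,
                        grid_shape = c(64, 64, 64), voxel_size_mm = 2.5) {
  if (n < 1) stop("n must be >= 1")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  sev <- severity_sampler(n)
  stopifnot(all(c("mta_left", "mta_right", "gca", "fazekas") %in%
                  colnames(sev)))
  sub_seeds <- sample.int(2^30, n)
  poses <- lapply(seq_len(n), function(i) {
    if (random_pose)
      list(translation_vox = runif(3, -2, 2), rotation_deg = runif(3, -5, 5))
    else
      list(translation_vox = c(0, 0, 0), rotation_deg = c(0, 0, 0))
  })
  pairs <- vector("list", n)
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    spec <- phantom_spec(grid_shape = grid_shape,
                         voxel_size_mm = voxel_size_mm,
                         mta_severity = c(sev$mta_left[s], sev$mta_right[s]),
                         gca_severity = sev$gca[s],
                         fazekas_severity = sev$fazekas[s],
                         noise_sd = noise_sd, rng_seed = sub_seeds[s],
                         pose = poses[[s]])
    ph <- make_phantom(spec)
    pairs[[s]] <- ph
    rows[[s]] <- cbind(data.frame(subject_id = sprintf("sub-%03d", s)),
                       ph$truth)
  }
  structure(list(pairs = pairs, table = do.call(rbind, rows)),
            class = "ct_cohort")
}

#' Write a cohort to disk as NIfTI pairs plus a cohort CSV
#'
#' Writes `sub-XXX_ct.nii.gz` and `sub-XXX_labels.nii.gz` per subject and
#' `cohort.csv` with severities and ground-truth fractions.
#'
#' @param cohort a `ct_cohort` from [make_cohort()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(cohort$pairs)) {
    id <- cohort$table$subject_id[s]
    write_volume(cohort$pairs[[s]]$ct,
                 file.path(out_dir, paste0(id, "_ct.nii.gz")))
    write_volume(cohort$pairs[[s]]$labels,
                 file.path(out_dir, paste0(id, "_labels.nii.gz")),
                 datatype = "int16")
  }
  write.csv(cohort$table, file.path(out_dir, "cohort.csv"),
            row.names = FALSE)
  invisible(out_dir)
}

# ground-truth brain mask (GM + WM + CSF + WML) of a phantom
phantom_brain_mask <- function(phantom) {
  with_data(phantom$labels,
            (phantom$labels$data >= phantom_labels[["gm"]]) * 1L)
}
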