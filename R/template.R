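#' Voxelwise mean of aligned CT volumes
#'
#' NaN-aware: at each voxel the mean is taken over the volumes with a
#' finite value there (voxels outside a subject's field of view can be
#' encoded as `NA`/`NaN`).
#'
#' @param aligned_cts list of >= 2 [ct_volume()]s on a common grid.
#' @return Mean-intensity [ct_volume()].
#' @export
build_mean_template <- function(aligned_cts) {
  if (length(aligned_cts) < 2) stop("need at least 2 aligned volumes")
  ref <- aligned_cts[[1]]
  acc <- array(0, dim(ref$data))
  cnt <- array(0, dim(ref$data))
  for (v in aligned_cts) {
    stopifnot_same_grid(ref, v, "aligned volumes")
    ok <- is.finite(v$data)
    acc[ok] <- acc[ok] + v$data[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  with_data(ref, out)
}

#' Voxelwise percentile map across reference probability volumes
#'
#' For each voxel, the empirical `pct` percentile (linear interpolation
#' between order statistics) of the values across subjects. The default
#' 99th percentile of reference CSF probabilities defines the normative
#' upper bound used by the cortical-atrophy measure: voxels of a new
#' subject exceeding it are counted as abnormal CSF.
#'
#' @param reference_probs list of >= 10 aligned probability
#'   [ct_volume()]s.
#' @param pct percentile in (0, 100), default 99.
#' @return Percentile-map [ct_volume()].
#' @export
build_csf_percentile_map <- function(reference_probs, pct = 99) {
  if (length(reference_probs) < 10)
    stop("need at least 10 reference volumes")
  if (pct <= 0 || pct >= 100) stop("pct must lie strictly in (0, 100)")
  ref <- reference_probs[[1]]
  for (v in reference_probs) stopifnot_same_grid(ref, v, "reference maps")
  m <- vapply(reference_probs, function(v) as.vector(v$data),
              numeric(length(ref$data)))
  with_data(ref, array(.cq_row_quantile(m, pct / 100), dim(ref$data)))
}

#' Extend a cortical lobe parcellation into surrounding CSF
#'
#' Each CSF voxel outside the parcellation is assigned the label of the
#' nearest labelled voxel (Euclidean distance in world mm, robust to
#' anisotropic spacing); exact ties resolve to the smaller label code
#' (label priority frontal < temporal < parietal < occipital).
#'
#' @param cortical_parcellation integer-label [ct_volume()] (0 background,
#'   1 frontal, 2 temporal, 3 parietal, 4 occipital).
#' @param csf_mask binary [ct_volume()]: the CSF voxels to absorb.
#' @return Label [ct_volume()] covering parcellation plus CSF.
#' @export
build_lobe_labels <- function(cortical_parcellation, csf_mask) {
  stopifnot_same_grid(cortical_parcellation, csf_mask,
                      "parcellation and CSF mask")
  lab <- array(as.integer(cortical_parcellation$data),
               dim(cortical_parcellation$data))
  if (sum(lab != 0) == 0) stop("empty parcellation")
  dom <- array(as.integer(csf_mask$data != 0), dim(lab))
  out <- .cq_nearest_label(lab, cortical_parcellation$spacing, dom)
  with_data(cortical_parcellation, out)
}

# Angular-sector cortical parcellation of the phantom geometry:
# 1 frontal (anterior), 2 temporal (lateral-inferior), 3 parietal
# (lateral-superior), 4 occipital (posterior).
phantom_lobe_parcellation <- function(geom_vol, cortex_mask) {
  d <- dim(geom_vol$data)
  sp <- geom_vol$spacing
  ctr <- (d - 1) / 2 * sp
  i <- (seq_len(d[1]) - 1) * sp[1] - ctr[1]
  j <- (seq_len(d[2]) - 1) * sp[2] - ctr[2]
  k <- (seq_len(d[3]) - 1) * sp[3] - ctr[3]
  X <- rep(i, times = d[2] * d[3])
  Y <- rep(rep(j, each = d[1]), times = d[3])
  Z <- rep(k, each = d[1] * d[2])
  lab <- integer(length(X))
  ant <- Y >= abs(X)
  post <- Y <= -abs(X)
  lat <- !ant & !post
  lab[ant] <- 1L
  lab[post] <- 4L
  lab[lat & Z < 0] <- 2L
  lab[lat & Z >= 0] <- 3L
  lab[as.vector(cortex_mask$data) == 0] <- 0L
  with_data(geom_vol, array(lab, d))
}

#' Parametric MTL and deep-white-matter masks in phantom template space
#'
#' Stands in for manually drawn template masks: the MTL mask covers the
#' bilateral medial-temporal CSF-pocket region of the phantom geometry and
#' the deep-WM mask covers the periventricular lesion region. Both are
#' synthetic by construction (parametric placement, not expert drawings).
#'
#' @param template_vol a [ct_volume()] defining the template grid (assumed
#'   centred phantom geometry, zero pose).
#' @return List with binary [ct_volume()]s `mtl_mask`, `mtl_left`,
#'   `mtl_right`, `deep_wm_mask`.
#' @export
draw_synthetic_masks <- function(template_vol) {
  g <- phantom_geometry()
  d <- dim(template_vol$data)
  sp <- template_vol$spacing
  ctr <- (d - 1) / 2 * sp
  i <- (seq_len(d[1]) - 1) * sp[1] - ctr[1]
  j <- (seq_len(d[2]) - 1) * sp[2] - ctr[2]
  k <- (seq_len(d[3]) - 1) * sp[3] - ctr[3]
  P <- cbind(rep(i, times = d[2] * d[3]),
             rep(rep(j, each = d[1]), times = d[3]),
             rep(k, each = d[1] * d[2]))
  r <- rep(g$mtl_region_r_mm, 3)
  left <- ell2(P, r, g$mtl_centers["left", ]) <= 1
  right <- ell2(P, r, g$mtl_centers["right", ]) <= 1
  vent_max <- g$vent_radii * (1 + g$vent_scale_per_gca * 3)
  deep_a <- vent_max + g$deep_wm_margin_mm
  deep <- ell2(P, deep_a, g$vent_centers[1, ]) <= 1 |
    ell2(P, deep_a, g$vent_centers[2, ]) <= 1
  mk <- function(v) with_data(template_vol, array(as.integer(v), d))
  list(mtl_mask = mk(left | right), mtl_left = mk(left),
       mtl_right = mk(right), deep_wm_mask = mk(deep))
}

#' Build a complete template bundle from a reference phantom cohort
#'
#' Generates `n_ref` zero-pose reference phantoms spanning the severity
#' range, averages their CT volumes into a mean template, derives the
#' template skull and brain masks, draws the parametric MTL/deep-WM masks,
#' builds the lobe label map extended into peripheral CSF, and computes
#' the percentile map of reference CSF probabilities (label indicator
#' smoothed to a probability, default 99th percentile).
#'
#' @param n_ref number of reference phantoms.
#' @param seed RNG seed for the reference cohort.
#' @param grid_shape,voxel_size_mm phantom grid settings.
#' @param noise_sd reference phantom noise level.
#' @param pct percentile for the CSF map.
#' @return A `template_bundle`: `mean_ct`, `skull_mask`, `brain_mask`,
#'   `mtl_left`, `mtl_right`, `mtl_mask`, `deep_wm_mask`, `lobe_labels`,
#'   `csf_p99`, `provenance`.
#' @export
build_template_bundle <- function(n_ref = 12, seed = 100,
                                  grid_shape = c(64, 64, 64),
                                  voxel_size_mm = 2.5, noise_sd = 5,
                                  pct = 99) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  sev <- data.frame(mta_left = runif(n_ref, 0, 2),
                    mta_right = runif(n_ref, 0, 2),
                    gca = runif(n_ref, 0, 1.5),
                    fazekas = runif(n_ref, 0, 1))
  refs <- lapply(seq_len(n_ref), function(s)
    make_phantom(phantom_spec(grid_shape = grid_shape,
                              voxel_size_mm = voxel_size_mm,
                              mta_severity = c(sev$mta_left[s],
                                               sev$mta_right[s]),
                              gca_severity = sev$gca[s],
                              fazekas_severity = sev$fazekas[s],
                              noise_sd = noise_sd,
                              rng_seed = seed + s)))
  mean_ct <- build_mean_template(lapply(refs, `[[`, "ct"))
  lab0 <- refs[[1]]$labels
  skull <- with_data(lab0, (lab0$data == phantom_labels[["skull"]]) * 1L)
  brain <- phantom_brain_mask(refs[[1]])
  masks <- draw_synthetic_masks(mean_ct)
  cortex <- with_data(lab0, (lab0$data == phantom_labels[["gm"]]) * 1L)
  parc <- phantom_lobe_parcellation(mean_ct, cortex)
  csf_any <- with_data(lab0, (lab0$data == phantom_labels[["csf"]]) * 1L)
  lobes <- build_lobe_labels(parc, csf_any)
  csf_probs <- lapply(refs, function(ph)
    smooth_gaussian(with_data(ph$labels,
                              (ph$labels$data ==
                                 phantom_labels[["csf"]]) * 1.0), 1))
  csf_p99 <- build_csf_percentile_map(csf_probs, pct)
  structure(list(mean_ct = mean_ct, skull_mask = skull, brain_mask = brain,
                 mtl_left = masks$mtl_left, mtl_right = masks$mtl_right,
                 mtl_mask = masks$mtl_mask,
                 deep_wm_mask = masks$deep_wm_mask, lobe_labels = lobes,
                 csf_p99 = csf_p99,
                 provenance = list(n_ref = n_ref, seed = seed,
                                   grid_shape = grid_shape,
                                   voxel_size_mm = voxel_size_mm,
                                   noise_sd = noise_sd, pct = pct)),
            class = "template_bundle")
}

#' @export
print.template_bundle <- function(x, ...) {
  cat(sprintf("<template_bundle> grid %s, %d reference subjects\n",
              paste(dim(x$mean_ct$data), collapse = "x"),
              x$provenance$n_ref))
  invisible(x)
}

template_volume_roles <- function() {
  list(mean_ct = "double", skull_mask = "int16", brain_mask = "int16",
       mtl_left = "int16", mtl_right = "int16", mtl_mask = "int16",
       deep_wm_mask = "int16", lobe_labels = "int16", csf_p99 = "double")
}

#' Write a template bundle to a directory of NIfTI files + manifest
#' @param bundle a `template_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_template_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roles <- template_volume_roles()
  for (nm in names(roles))
    write_volume(bundle[[nm]], file.path(dir, paste0(nm, ".nii.gz")),
                 datatype = roles[[nm]])
  jsonlite::write_json(
    list(volumes = names(roles), provenance = bundle$provenance),
    file.path(dir, "bundle.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a template bundle written by [write_template_bundle()]
#' @param dir bundle directory.
#' @return A `template_bundle`.
#' @export
read_template_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "bundle.json"),
                                  simplifyVector = TRUE)
  roles <- template_volume_roles()
  out <- lapply(names(roles), function(nm) {
    v <- read_volume(file.path(dir, paste0(nm, ".nii.gz")))
    if (roles[[nm]] == "int16")
      v$data <- array(as.integer(round(v$data)), dim(v$data))
    v
  })
  names(out) <- names(roles)
  out$provenance <- manifest$provenance
  class(out) <- "template_bundle"
  out
}
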