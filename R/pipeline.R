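#' Pipeline stage configuration
#'
#' One block per stage; validated up front so configuration errors
#' surface before any computation starts.
#'
#' @param skullstrip a [skullstrip_config()].
#' @param seg a [segmenter_config()] used when training.
#' @param K ensemble repetitions (independently seeded trainings).
#' @param nonrigid logical: refine the template-to-native transport of
#'   masks and percentile maps with NMI nonrigid registration. Off by
#'   default at desk scale, where phantom pose is rigid and the affine
#'   transport is already exact up to voxel sampling.
#' @param nmi_bins,reg_weight,nonrigid_iter nonrigid settings (see
#'   [nonrigid_refine()]).
#' @param reg_rotation_starts rotation multi-start grid for the affine
#'   stage (see [affine_register_masks()]); the default single start
#'   assumes head poses within roughly 10 degrees of the template, the
#'   usual case for axially acquired head CT.
#' @param seed seed for training-stage randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(skullstrip = skullstrip_config(),
                            seg = segmenter_config(), K = 3,
                            nonrigid = FALSE, nmi_bins = 32,
                            reg_weight = 0.05, nonrigid_iter = 15,
                            reg_rotation_starts = 0, seed = 1L) {
  if (K < 2) stop("K must be >= 2")
  structure(list(skullstrip = skullstrip, seg = seg, K = as.integer(K),
                 nonrigid = isTRUE(nonrigid), nmi_bins = nmi_bins,
                 reg_weight = reg_weight, nonrigid_iter = nonrigid_iter,
                 reg_rotation_starts = reg_rotation_starts,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# carry class labels to template space for training: per-class one-hot
# maps are resampled linearly and the argmax taken; voxels whose winning
# class probability falls below `conf` sit on resampling-ambiguous
# boundaries (their interpolated intensity blends classes) and get
# training weight 0
transport_training_labels <- function(classes, tf, target, conf = 0.5) {
  n_cls <- 3L
  best <- NULL
  lab <- NULL
  for (cl in seq_len(n_cls) - 1L) {
    p <- transport(with_data(classes, (classes$data == cl) * 1.0), tf,
                   target, "forward", "linear")$data
    if (is.null(best)) {
      best <- p
      lab <- array(0L, dim(p))
    } else {
      sel <- p > best
      lab[sel] <- cl
      best[sel] <- p[sel]
    }
  }
  list(labels = ct_volume(lab, target$spacing, target$origin),
       weight = ct_volume(array(as.integer(best >= conf), dim(best)),
                          target$spacing, target$origin))
}

# fixed working grid for the segmentation stage: the template cropped to
# the brain bounding box (padded to even axis lengths for the down/up
# sampling path); identical for every subject of a bundle
template_crop <- function(bundle, margin = 3L) {
  idx <- which(bundle$brain_mask$data != 0, arr.ind = TRUE)
  d <- dim(bundle$brain_mask$data)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  len <- hi - lo + 1L
  hi <- pmin(hi + len %% 2L, d)
  lo <- lo - (((hi - lo + 1L) %% 2L))
  lo <- pmax(lo, 1L)
  list(lo = lo, hi = hi,
       grid = ct_volume(bundle$mean_ct$data[lo[1]:hi[1], lo[2]:hi[2],
                                            lo[3]:hi[3], drop = FALSE],
                        bundle$mean_ct$spacing,
                        bundle$mean_ct$origin +
                          (lo - 1) * bundle$mean_ct$spacing),
       brain = ct_volume(bundle$brain_mask$data[lo[1]:hi[1], lo[2]:hi[2],
                                                lo[3]:hi[3], drop = FALSE],
                         bundle$mean_ct$spacing,
                         bundle$mean_ct$origin +
                           (lo - 1) * bundle$mean_ct$spacing))
}

# denoise, skull strip, register to template, z-score in template space;
# the denoised CT also feeds the z-scoring/CNN stage so that the lesion
# contrast (about 10 HU) is not buried in acquisition noise
preprocess_subject <- function(ct, bundle, config) {
  den <- denoise_nlm(ct, config$skullstrip$patch_radius,
                     config$skullstrip$search_radius, config$skullstrip$h)
  cfg_ss <- config$skullstrip
  cfg_ss$h <- 0  # already denoised
  bm <- skull_strip(den, cfg_ss)
  ct <- den
  skull_t <- with_data(bundle$skull_mask,
                       array(as.integer(bundle$skull_mask$data != 0),
                             dim(bundle$skull_mask$data)))
  tf <- affine_register_masks(bm$skull_mask, skull_t,
                              rotation_starts =
                                config$reg_rotation_starts)
  crop <- template_crop(bundle)
  # cubic interpolation keeps one/two-voxel structures (small lesions)
  # from being washed out on the way to template space; the working grid
  # is the template cropped to the brain bounding box
  ct_t <- transport(ct, tf, crop$grid, "forward", "cubic",
                    fill = min(ct$data))
  brain_t <- transport(bm$mask, tf, crop$grid, "forward", "nearest")
  z <- zscore_brain(ct_t, brain_t, stat_erosion_vox = 2)
  def <- NULL
  if (config$nonrigid) {
    ct_full <- transport(ct, tf, bundle$mean_ct, "forward", "cubic",
                         fill = min(ct$data))
    def <- nonrigid_refine(ct_full, bundle$mean_ct,
                           nmi_bins = config$nmi_bins,
                           reg_weight = config$reg_weight,
                           max_iter = config$nonrigid_iter)
  }
  list(brain = bm, transform = tf, ct_template = ct_t,
       z_template = z, brain_template = brain_t, deformation = def,
       crop = crop)
}

#' Train the full CT grading pipeline on a phantom cohort
#'
#' Builds (or reuses) a template bundle, preprocesses every training
#' subject (skull stripping, affine registration, z-scoring), trains the
#' segmentation ensemble on template-space image/label pairs, runs the
#' measurement pipeline on the training subjects, and fits one
#' [fit_calibration()] model per grade scale (MTA left/right, GCA global
#' and per lobe, Fazekas) against the known severities.
#'
#' @param cohort a `ct_cohort` from [make_cohort()].
#' @param bundle optional pre-built [build_template_bundle()].
#' @param config a [pipeline_config()].
#' @param verbose print progress.
#' @return A `ct_pipeline` model: `bundle`, `segmenters`, `calibrations`,
#'   `config`, `train_table`.
#' @export
train_pipeline <- function(cohort, bundle = NULL,
                           config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(bundle)) {
    say("building template bundle")
    gs <- dim(cohort$pairs[[1]]$ct$data)
    bundle <- build_template_bundle(grid_shape = gs,
                                    voxel_size_mm =
                                      cohort$pairs[[1]]$ct$spacing)
  }
  n <- length(cohort$pairs)
  say("preprocessing %d training subjects", n)
  prep <- lapply(seq_len(n), function(s) {
    say("  subject %d/%d", s, n)
    preprocess_subject(cohort$pairs[[s]]$ct, bundle, config)
  })
  seg_pairs <- lapply(seq_len(n), function(s)
    c(list(ct = prep[[s]]$z_template),
      transport_training_labels(
        segmentation_classes(cohort$pairs[[s]]$labels),
        prep[[s]]$transform, prep[[s]]$crop$grid)))
  say("training %d-member segmentation ensemble", config$K)
  cfg <- config$seg
  cfg$seed <- config$seed
  segmenters <- train_ensemble(seg_pairs, K = config$K, config = cfg,
                               verbose = verbose)
  model <- structure(list(bundle = bundle, segmenters = segmenters,
                          calibrations = NULL, config = config),
                     class = "ct_pipeline")
  say("measuring training subjects")
  meas <- lapply(seq_len(n), function(s) {
    run_subject(cohort$pairs[[s]]$ct, model, prep = prep[[s]])$measures
  })
  mtab <- do.call(rbind, lapply(meas, function(m) as.data.frame(t(m))))
  truth <- cohort$table
  # a degenerate measure (e.g. no lesions detected on a very small
  # training cohort) cannot support the two-step fit; fall back to a
  # constant predictor at the mean training grade with a warning rather
  # than aborting the whole training run
  fit_or_fallback <- function(measure, grade, scale) {
    tryCatch(fit_calibration(measure, grade, scale),
             error = function(e) {
               warning("calibration fallback for ", scale, " (",
                       conditionMessage(e), "); using constant predictor",
                       call. = FALSE)
               structure(list(coef = c(mean(grade), 0),
                              knots_x = mean(grade),
                              knots_y = mean(grade), scale = scale,
                              grade_range = grade_range(scale),
                              n_train = length(grade)),
                         class = "ct_calibration")
             })
  }
  calib <- list(
    mta_left = fit_or_fallback(mtab$mta_left_raw, truth$mta_left, "mta"),
    mta_right = fit_or_fallback(mtab$mta_right_raw, truth$mta_right,
                                "mta"),
    gca = fit_or_fallback(mtab$gca_raw, truth$gca, "gca"),
    gca_frontal = fit_or_fallback(mtab$gca_frontal_raw, truth$gca, "gca"),
    gca_temporal = fit_or_fallback(mtab$gca_temporal_raw, truth$gca,
                                   "gca"),
    gca_parietal = fit_or_fallback(mtab$gca_parietal_raw, truth$gca,
                                   "gca"),
    gca_occipital = fit_or_fallback(mtab$gca_occipital_raw, truth$gca,
                                    "gca"),
    fazekas = fit_or_fallback(mtab$fazekas_raw, truth$fazekas,
                              "fazekas"))
  model$calibrations <- calib
  model$train_table <- cbind(truth["subject_id"], mtab)
  model
}

#' @export
print.ct_pipeline <- function(x, ...) {
  cat(sprintf(paste0("<ct_pipeline> %d-member ensemble (%s preset), %s, ",
                     "nonrigid %s\n"),
              length(x$segmenters), x$config$seg$preset,
              if (is.null(x$calibrations)) "uncalibrated" else
                paste0(length(x$calibrations), " calibrated scales"),
              if (x$config$nonrigid) "on" else "off"))
  invisible(x)
}

#' Run the grading pipeline on one subject
#'
#' Executes the full stage sequence: skull stripping, affine registration
#' of skull masks to the template, z-scoring, ensemble CNN segmentation in
#' template space, correlation-weighted fusion, transport of the fused
#' segmentations (affine) and template data (affine, plus nonrigid when
#' enabled) to native space, volumetric measures, and calibrated grades.
#' All measures are computed on native-space data.
#'
#' @param ct subject CT [ct_volume()] (or path to a NIfTI file).
#' @param model a trained `ct_pipeline`. Running with `calibrations =
#'   NULL` yields measures only.
#' @param prep optional precomputed [preprocess_subject] result (used
#'   internally during training).
#' @param keep_intermediates return template-space intermediates.
#' @return List: `measures` (named numeric), `grades` (data frame with
#'   continuous, categorical and abnormal flags per scale; `NULL` when
#'   uncalibrated), `brain_volume_ml`, and optionally `intermediates`.
#' @export
run_subject <- function(ct, model, prep = NULL,
                        keep_intermediates = FALSE) {
  if (!inherits(model, "ct_pipeline")) stop("`model` must be a ct_pipeline")
  if (is.character(ct)) {
    if (!file.exists(ct)) stop("input CT not found: ", ct)
    ct <- read_volume(ct)
  }
  bundle <- model$bundle
  config <- model$config
  if (is.null(prep)) prep <- preprocess_subject(ct, bundle, config)
  bm <- prep$brain
  tf <- prep$transform
  ens <- predict_ensemble(model$segmenters, prep$z_template)
  dom <- prep$crop$brain
  fus_csf <- fuse_ensemble(ens$csf, mask = dom)
  fus_wml <- fuse_ensemble(ens$wml, mask = dom)
  # fused segmentations travel with the affine only; template data with
  # the affine plus the nonrigid refinement when enabled
  to_native <- function(vol, interp, def = NULL)
    transport(vol, tf, ct, "inverse", interp, deformation = def)
  def <- prep$deformation
  csf_mask_n <- to_native(fus_csf$fused, "nearest")
  csf_prob_n <- to_native(fus_csf$mean_prob, "linear")
  wml_mask_n <- to_native(fus_wml$fused, "nearest")
  mtl_l_n <- to_native(bundle$mtl_left, "nearest", def)
  mtl_r_n <- to_native(bundle$mtl_right, "nearest", def)
  deep_n <- to_native(bundle$deep_wm_mask, "nearest", def)
  lobes_n <- to_native(bundle$lobe_labels, "nearest", def)
  p99_n <- to_native(bundle$csf_p99, "linear", def)
  measures <- c(
    measure_mta(csf_mask_n, mtl_l_n, mtl_r_n, bm),
    measure_gca(csf_prob_n, p99_n, bm, lobes_n),
    measure_fazekas(wml_mask_n, deep_n, bm),
    brain_volume_ml = bm$brain_volume_ml)
  grades <- NULL
  if (!is.null(model$calibrations)) {
    cal <- model$calibrations
    cont <- c(mta_left = apply_calibration(cal$mta_left,
                                           measures[["mta_left_raw"]]),
              mta_right = apply_calibration(cal$mta_right,
                                            measures[["mta_right_raw"]]),
              gca = apply_calibration(cal$gca, measures[["gca_raw"]]),
              gca_frontal = apply_calibration(cal$gca_frontal,
                                              measures[["gca_frontal_raw"]]),
              gca_temporal = apply_calibration(cal$gca_temporal,
                                               measures[["gca_temporal_raw"]]),
              gca_parietal = apply_calibration(cal$gca_parietal,
                                               measures[["gca_parietal_raw"]]),
              gca_occipital = apply_calibration(cal$gca_occipital,
                                                measures[["gca_occipital_raw"]]),
              fazekas = apply_calibration(cal$fazekas,
                                          measures[["fazekas_raw"]]))
    # combined MTA: mean of the left/right continuous grades
    cont <- c(cont, mta = unname((cont["mta_left"] + cont["mta_right"]) / 2))
    fam <- ifelse(grepl("^mta", names(cont)), "mta",
                  ifelse(grepl("^gca", names(cont)), "gca", "fazekas"))
    cats <- mapply(function(v, f) categorize(v, grade_range(f)),
                   cont, fam, SIMPLIFY = FALSE)
    grades <- data.frame(scale = names(cont), continuous = unname(cont),
                         categorical = vapply(cats, `[[`, 0L,
                                              "categorical"),
                         abnormal = vapply(cats, `[[`, TRUE, "abnormal"),
                         row.names = NULL)
  }
  out <- list(measures = measures, grades = grades,
              brain_volume_ml = bm$brain_volume_ml)
  if (keep_intermediates)
    out$intermediates <- list(prep = prep, fusion_csf = fus_csf,
                              fusion_wml = fus_wml)
  out
}

#' Run the pipeline over a cohort and tabulate grades
#'
#' Per-subject failures are caught and logged; the run continues and the
#' failed subjects are reported in the `failures` attribute.
#'
#' @param subjects a `ct_cohort`, a list of [ct_volume()]s, or a character
#'   vector of NIfTI paths.
#' @param model a trained, calibrated `ct_pipeline`.
#' @param reference optional reference grade table (`subject_id` +
#'   continuous grade columns) to evaluate against with [full_report()].
#' @param out_csv optional path; the grade table is written there.
#' @param verbose print progress.
#' @return A `cohort_run` list: `table` (one row per subject: measures,
#'   continuous/categorical grades, normality flags), `report`
#'   (a [full_report()] or `NULL`), `failures` (named list of error
#'   messages).
#' @export
run_cohort <- function(subjects, model, reference = NULL, out_csv = NULL,
                       verbose = FALSE) {
  if (inherits(subjects, "ct_cohort")) {
    ids <- subjects$table$subject_id
    cts <- lapply(subjects$pairs, `[[`, "ct")
  } else if (is.character(subjects)) {
    ids <- sub("\\.nii(\\.gz)?$", "", basename(subjects))
    cts <- as.list(subjects)
  } else {
    ids <- sprintf("sub-%03d", seq_along(subjects))
    cts <- subjects
  }
  if (length(cts) == 0) stop("empty subject list")
  if (is.null(model$calibrations))
    stop("pipeline model has no calibrations; train or attach them first")
  rows <- list()
  failures <- list()
  for (s in seq_along(cts)) {
    if (verbose) message("subject ", ids[s], " (", s, "/", length(cts),
                         ")")
    res <- tryCatch(run_subject(cts[[s]], model), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[ids[s]]] <- conditionMessage(res)
      next
    }
    g <- res$grades
    row <- data.frame(subject_id = ids[s], as.data.frame(t(res$measures)))
    for (i in seq_len(nrow(g))) {
      row[[g$scale[i]]] <- g$continuous[i]
      row[[paste0(g$scale[i], "_cat")]] <- g$categorical[i]
      row[[paste0(g$scale[i], "_abnormal")]] <- g$abnormal[i]
    }
    rows[[length(rows) + 1]] <- row
  }
  if (length(rows) == 0) stop("all subjects failed; first error: ",
                              failures[[1]])
  tab <- do.call(rbind, rows)
  report <- NULL
  if (!is.null(reference)) {
    shared <- intersect(setdiff(names(reference), "subject_id"),
                        names(tab))
    report <- full_report(reference[c("subject_id", shared)],
                          tab[c("subject_id", shared)])
  }
  if (!is.null(out_csv)) write.csv(tab, out_csv, row.names = FALSE)
  structure(list(table = tab, report = report, failures = failures),
            class = "cohort_run")
}

#' @export
print.cohort_run <- function(x, ...) {
  cat(sprintf("<cohort_run> %d subjects graded, %d failures\n",
              nrow(x$table), length(x$failures)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
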