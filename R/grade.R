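#' Grade ranges of the three visual rating scales
#'
#' MTA (Scheltens) 0--4; GCA (Pasquier) and Fazekas 0--3.
#' @param scale one of `"mta"`, `"gca"`, `"fazekas"`.
#' @return Length-2 numeric range.
#' @export
grade_range <- function(scale = c("mta", "gca", "fazekas")) {
  scale <- match.arg(scale)
  if (scale == "mta") c(0, 4) else c(0, 3)
}

measure_fraction <- function(n_voxels, vol, brain) {
  bv <- if (inherits(brain, "brain_mask")) brain$brain_volume_ml * 1000
  else stop("`brain` must be a brain_mask")
  if (bv <= 0) stop("empty brain")
  n_voxels * prod(vol$spacing) / bv
}

#' Medial-temporal CSF fraction per hemisphere
#'
#' Volume of CSF inside each hemisphere's medial-temporal-lobe mask,
#' normalized to the total brain volume.
#'
#' @param csf_mask binary native-space CSF [ct_volume()].
#' @param mtl_left,mtl_right binary native-space MTL masks.
#' @param brain a `brain_mask` (defines the normalizing brain volume).
#' @return Named numeric: `mta_left_raw`, `mta_right_raw` (unitless
#'   fractions).
#' @export
measure_mta <- function(csf_mask, mtl_left, mtl_right, brain) {
  stopifnot_same_grid(csf_mask, mtl_left, "CSF and MTL masks")
  stopifnot_same_grid(csf_mask, mtl_right, "CSF and MTL masks")
  csf <- csf_mask$data != 0
  c(mta_left_raw = measure_fraction(sum(csf & mtl_left$data != 0),
                                    csf_mask, brain),
    mta_right_raw = measure_fraction(sum(csf & mtl_right$data != 0),
                                     csf_mask, brain))
}

#' Abnormal-CSF fraction for global (and per-lobe) cortical atrophy
#'
#' Counts voxels where the subject's CSF probability (the un-thresholded
#' consensus segmentation) strictly exceeds the normative percentile map,
#' within the brain; the volume is normalized to total brain volume. With
#' a lobe label map the same computation is restricted to each lobe.
#'
#' @param csf_prob native-space CSF probability [ct_volume()].
#' @param csf_p99_native native-space percentile map [ct_volume()].
#' @param brain a `brain_mask`.
#' @param lobe_labels_native optional native-space lobe label
#'   [ct_volume()] (1 frontal, 2 temporal, 3 parietal, 4 occipital).
#' @param min_abnormal_prob floor applied to the percentile map: where
#'   the normative map is essentially zero (deep white matter has no
#'   reference CSF), any positive segmentation probability would
#'   otherwise count as abnormal, so a voxel must additionally reach this
#'   CSF probability to be counted. Set to 0 for the bare strict
#'   comparison.
#' @return Named numeric: `gca_raw` and, when lobe labels are given,
#'   `gca_frontal_raw`, `gca_temporal_raw`, `gca_parietal_raw`,
#'   `gca_occipital_raw`.
#' @export
measure_gca <- function(csf_prob, csf_p99_native, brain,
                        lobe_labels_native = NULL,
                        min_abnormal_prob = 0.05) {
  stopifnot_same_grid(csf_prob, csf_p99_native,
                      "probability and percentile maps")
  inb <- brain$mask$data != 0
  abn <- csf_prob$data > pmax(csf_p99_native$data, min_abnormal_prob) &
    inb
  out <- c(gca_raw = measure_fraction(sum(abn), csf_prob, brain))
  if (!is.null(lobe_labels_native)) {
    stopifnot_same_grid(csf_prob, lobe_labels_native,
                        "probability map and lobe labels")
    lobes <- c(frontal = 1L, temporal = 2L, parietal = 3L, occipital = 4L)
    for (nm in names(lobes))
      out[paste0("gca_", nm, "_raw")] <-
        measure_fraction(sum(abn & lobe_labels_native$data == lobes[nm]),
                         csf_prob, brain)
  }
  out
}

#' Deep-white-matter lesion fraction for the Fazekas grade
#'
#' @param wml_mask binary native-space WML [ct_volume()].
#' @param deep_wm_native binary native-space deep-white-matter mask.
#' @param brain a `brain_mask`.
#' @return `fazekas_raw`, the WML-inside-deep-WM volume fraction of the
#'   brain volume.
#' @export
measure_fazekas <- function(wml_mask, deep_wm_native, brain) {
  stopifnot_same_grid(wml_mask, deep_wm_native, "WML and deep-WM masks")
  n <- sum(wml_mask$data != 0 & deep_wm_native$data != 0)
  c(fazekas_raw = measure_fraction(n, wml_mask, brain))
}

#' Fit the two-step measure-to-grade calibration
#'
#' Step 1 is ordinary least squares of grade on measure. Step 2 is a
#' piecewise-linear correction with one knot per observed rounded grade:
#' the knot maps the median step-1 estimate within that grade group to the
#' group's median ground-truth grade, so after calibration the per-grade
#' medians of predicted and true grades coincide on the training data.
#' Non-monotone knot targets are repaired isotonically (with a warning);
#' beyond the outer knots the map extrapolates linearly with the end
#' segments' slopes.
#'
#' @param measure numeric vector of raw measures (training set).
#' @param grade numeric vector of ground-truth grades (continuous or
#'   integer), same length.
#' @param scale grade scale, see [grade_range()].
#' @return A `ct_calibration` model with `coef` (step-1 intercept/slope),
#'   `knots_x`/`knots_y` (step-2 breakpoints), `scale`, `grade_range`,
#'   `n_train`.
#' @export
fit_calibration <- function(measure, grade,
                            scale = c("mta", "gca", "fazekas")) {
  scale <- match.arg(scale)
  ok <- is.finite(measure) & is.finite(grade)
  measure <- measure[ok]; grade <- grade[ok]
  if (length(measure) < 10) stop("need at least 10 training pairs")
  if (sd(measure) == 0) stop("degenerate measure (zero variance)")
  rng <- grade_range(scale)
  g_round <- round(pmin(pmax(grade, rng[1]), rng[2]))
  if (length(unique(g_round)) < 3)
    stop("training grades must span at least 3 distinct rounded grades")
  fit <- lm(grade ~ measure)
  est <- as.numeric(fitted(fit))
  groups <- sort(unique(g_round))
  kx <- vapply(groups, function(g) median(est[g_round == g]), 0)
  ky <- vapply(groups, function(g) median(grade[g_round == g]), 0)
  ord <- order(kx)
  kx <- kx[ord]; ky <- ky[ord]
  if (any(diff(ky) < 0)) {
    warning("non-monotone per-grade medians; applying isotonic repair")
    ky <- isoreg(seq_along(ky), ky)$yf
  }
  if (any(diff(kx) <= 0)) {
    keep <- !duplicated(kx)
    kx <- kx[keep]; ky <- ky[keep]
  }
  structure(list(coef = coef(fit), knots_x = kx, knots_y = ky,
                 scale = scale, grade_range = rng,
                 n_train = length(measure)),
            class = "ct_calibration")
}

#' @export
print.ct_calibration <- function(x, ...) {
  cat(sprintf(paste0("<ct_calibration> %s scale, linear %.3g + %.3g * m, ",
                     "%d knots, n = %d\n"),
              x$scale, x$coef[1], x$coef[2], length(x$knots_x), x$n_train))
  invisible(x)
}

# piecewise-linear interpolation with linear extrapolation from the end
# segments
piecewise_linear <- function(x, kx, ky) {
  if (length(kx) == 1) return(x - kx + ky)
  out <- approx(kx, ky, xout = x, rule = 2)$y
  slope_lo <- (ky[2] - ky[1]) / (kx[2] - kx[1])
  n <- length(kx)
  slope_hi <- (ky[n] - ky[n - 1]) / (kx[n] - kx[n - 1])
  lo <- x < kx[1]
  hi <- x > kx[n]
  out[lo] <- ky[1] + slope_lo * (x[lo] - kx[1])
  out[hi] <- ky[n] + slope_hi * (x[hi] - kx[n])
  out
}

#' Apply a fitted calibration to new measures
#'
#' Linear step followed by the piecewise-linear correction; the result is
#' a continuous grade that may exceed the allowed range (clamping happens
#' in [categorize()]).
#'
#' @param model a `ct_calibration`.
#' @param measure numeric vector of raw measures.
#' @return Continuous grade estimates.
#' @export
apply_calibration <- function(model, measure) {
  est <- model$coef[1] + model$coef[2] * measure
  piecewise_linear(est, model$knots_x, model$knots_y)
}

#' @export
predict.ct_calibration <- function(object, newdata, ...) {
  apply_calibration(object, newdata)
}

#' Categorical grade and normality flag from a continuous grade
#'
#' The continuous value is first cut to the allowed range and then
#' rounded to the nearest integer (half-integers round away from zero).
#' Normality dichotomizes grades 0--1 (no or minor changes) against
#' grades above 1 (clearly abnormal).
#'
#' @param continuous numeric vector of continuous grades.
#' @param range grade range, e.g. `c(0, 4)` for MTA (see [grade_range()]).
#' @return Data frame with `categorical` (integer) and `abnormal`
#'   (logical, `TRUE` for grades > 1).
#' @export
categorize <- function(continuous, range = c(0, 3)) {
  if (any(is.na(continuous))) stop("NA/NaN continuous grade")
  clamped <- pmin(pmax(continuous, range[1]), range[2])
  cat_g <- as.integer(floor(clamped + 0.5))
  data.frame(categorical = cat_g, abnormal = cat_g > 1L)
}
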