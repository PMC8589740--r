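#' Nonlocal-means denoising of a CT volume
#'
#' Averages each voxel with voxels of similar patch neighbourhoods within a
#' search window; preserves class-boundary edges better than a Gaussian
#' blur of comparable variance reduction.
#'
#' @param ct a [ct_volume()].
#' @param patch_radius patch half-width in voxels.
#' @param search_radius search window half-width in voxels.
#' @param h filtering strength (intensity units); `h = 0` returns the
#'   input unchanged. `NULL` ties `h` to a noise estimate (1.5 times the
#'   median absolute first-difference along x, scaled to SD units).
#' @return Denoised `ct_volume`.
#' @export
denoise_nlm <- function(ct, patch_radius = 1, search_radius = 3, h = NULL) {
  if (!is_ct_volume(ct)) stop("`ct` must be a ct_volume")
  if (any(!is.finite(ct$data))) stop("`ct` must be finite-valued")
  if (is.null(h)) {
    dif <- abs(diff(as.vector(ct$data), lag = 1))
    h <- 1.5 * median(dif) / (sqrt(2) * 0.6745)
  }
  if (h <= 0) return(ct)
  with_data(ct, .cq_nlm(ct$data * 1.0, as.integer(patch_radius),
                        as.integer(search_radius), h))
}

#' Clip outlier intensities to a percentile range
#'
#' @param ct a [ct_volume()].
#' @param low_pct,high_pct percentile bounds, `0 <= low < high <= 100`.
#' @return `ct_volume` with intensities clipped to the empirical
#'   \[low, high\] percentile range.
#' @export
remove_outliers <- function(ct, low_pct = 0.1, high_pct = 99.9) {
  if (!is_ct_volume(ct)) stop("`ct` must be a ct_volume")
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100))
    stop("need 0 <= low_pct < high_pct <= 100")
  v <- as.vector(ct$data)
  if (length(v) == 0) stop("empty field of view")
  q <- quantile(v, c(low_pct, high_pct) / 100, names = FALSE)
  with_data(ct, array(pmin(pmax(ct$data, q[1]), q[2]), dim(ct)))
}

#' Two-class Gaussian mixture fit by expectation-maximization
#'
#' Fits a two-component Gaussian mixture to the intensities with the class
#' priors held fixed throughout (only means and SDs are updated). The
#' log-likelihood is checked to be nondecreasing at every iteration.
#'
#' @param ct a [ct_volume()], or a numeric vector of intensities.
#' @param priors fixed mixing proportions, length 2, summing to 1.
#' @param init optional list with `means` (length 2) and `sds` (length 2);
#'   defaults to the 25th/75th intensity percentiles and the pooled SD.
#' @param max_iter maximum EM iterations.
#' @param tol stop when the mean log-likelihood improves by less than this.
#' @param mask optional logical/0-1 array restricting the fit.
#' @return An `em_model` list: `class_means`, `class_sds`, `class_priors`
#'   (classes ordered low then high), `posteriors` (matrix n x 2 when
#'   fitted on a volume: per-voxel posteriors, rows sum to 1),
#'   `loglik_trace`, `converged`, `n_iter`.
#' @export
em_two_class <- function(ct, priors = c(0.5, 0.5), init = NULL,
                         max_iter = 100, tol = 1e-7, mask = NULL) {
  x <- if (is_ct_volume(ct)) as.vector(ct$data) else as.numeric(ct)
  if (!is.null(mask)) x <- x[as.vector(mask) != 0]
  if (length(x) < 10) stop("too few voxels for EM")
  if (abs(sum(priors) - 1) > 1e-8 || length(priors) != 2L)
    stop("priors must be two proportions summing to 1")
  if (var(x) == 0)
    stop("degenerate intensity distribution (zero variance); EM cannot ",
         "separate two classes")
  if (is.null(init)) {
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    if (q[1] == q[2]) q <- q + c(-1, 1) * sd(x) / 2
    init <- list(means = q, sds = rep(max(sd(x), 1e-6), 2))
  }
  mu <- sort(init$means)
  sg <- pmax(init$sds, 1e-6)
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    d1 <- priors[1] * dnorm(x, mu[1], sg[1])
    d2 <- priors[2] * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- mean(log(tot))
    if (length(ll_trace) > 0 && ll < tail(ll_trace, 1) - 1e-9)
      stop("EM log-likelihood decreased; numerical failure")
    done <- length(ll_trace) > 0 && (ll - tail(ll_trace, 1)) < tol
    ll_trace <- c(ll_trace, ll)
    if (done) { converged <- TRUE; break }
    if (it >= max_iter) break
    r2 <- d2 / tot
    r1 <- 1 - r2
    # M-step with fixed priors: update means/SDs only
    mu[1] <- sum(r1 * x) / sum(r1)
    mu[2] <- sum(r2 * x) / sum(r2)
    sg[1] <- sqrt(sum(r1 * (x - mu[1])^2) / sum(r1))
    sg[2] <- sqrt(sum(r2 * (x - mu[2])^2) / sum(r2))
    sg <- pmax(sg, 1e-6)
    if (mu[1] > mu[2]) { mu <- rev(mu); sg <- rev(sg) }
  }
  d1 <- priors[1] * dnorm(x, mu[1], sg[1])
  d2 <- priors[2] * dnorm(x, mu[2], sg[2])
  tot <- pmax(d1 + d2, .Machine$double.xmin)
  structure(list(class_means = mu, class_sds = sg, class_priors = priors,
                 posteriors = cbind(low = d1 / tot, high = d2 / tot),
                 loglik_trace = ll_trace, converged = converged,
                 n_iter = it),
            class = "em_model")
}

#' @export
print.em_model <- function(x, ...) {
  cat(sprintf(paste0("<em_model> means %.1f / %.1f, SDs %.1f / %.1f, ",
                     "priors %.2f / %.2f, %d iterations (%s)\n"),
              x$class_means[1], x$class_means[2], x$class_sds[1],
              x$class_sds[2], x$class_priors[1], x$class_priors[2],
              x$n_iter, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Bone intensity threshold from a fitted two-class EM model
#'
#' Returns the intensity above which voxels are classified as skull/bone:
#' the equal-posterior crossing between the two Gaussian classes (the root
#' of the posterior-equality quadratic lying between the class means),
#' optionally shifted toward bone by `margin`.
#'
#' @param model an `em_model` from [em_two_class()].
#' @param margin additive shift toward bone (intensity units).
#' @param fallback threshold used (with a warning) when the classes are not
#'   separable (coincident means).
#' @return Scalar intensity threshold.
#' @export
skull_threshold_from_em <- function(model, margin = 0, fallback = 200) {
  mu <- model$class_means; sg <- model$class_sds; pr <- model$class_priors
  if (abs(mu[2] - mu[1]) < 1e-8 * max(1, abs(mu[1]))) {
    warning("EM classes not separable; falling back to fixed cutoff ",
            fallback)
    return(fallback)
  }
  # pi1 N(x; mu1, s1) = pi2 N(x; mu2, s2)  =>  a x^2 + b x + c = 0
  a <- 1 / sg[2]^2 - 1 / sg[1]^2
  b <- 2 * (mu[1] / sg[1]^2 - mu[2] / sg[2]^2)
  cc <- mu[2]^2 / sg[2]^2 - mu[1]^2 / sg[1]^2 +
    2 * log((pr[1] * sg[2]) / (pr[2] * sg[1]))
  if (abs(a) < 1e-12) {
    thr <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) {
      warning("no real posterior crossing; falling back to fixed cutoff ",
              fallback)
      return(fallback)
    }
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    inside <- roots >= mu[1] & roots <= mu[2]
    thr <- if (any(inside)) roots[inside][1] else
      roots[which.min(abs(roots - mean(mu)))]
  }
  thr + margin
}

#' Morphological fine-tuning of a raw brain mask
#'
#' Applies a configurable sequence (default: opening, largest connected
#' component, closing, hole filling) so the result is a single connected,
#' hole-free component.
#'
#' @param raw_mask binary [ct_volume()] (or 0/1 array).
#' @param radius structuring-element (Euclidean ball) radius in voxels.
#' @param ops character vector, subset/ordering of
#'   `c("open", "largest", "close", "fill")`.
#' @return A `brain_mask` object: `mask` (binary `ct_volume`),
#'   `brain_volume_ml`.
#' @export
refine_mask_morphology <- function(raw_mask, radius = 2,
                                   ops = c("open", "largest", "close",
                                           "fill")) {
  if (!is_ct_volume(raw_mask)) stop("`raw_mask` must be a ct_volume")
  m <- array(as.integer(raw_mask$data != 0), dim(raw_mask))
  if (sum(m) == 0) stop("raw mask is empty")
  for (op in ops) {
    m <- switch(op,
      open = {
        er <- .cq_morph(m, radius, 0L)
        .cq_morph(er, radius, 1L)
      },
      close = {
        di <- .cq_morph(m, radius, 1L)
        .cq_morph(di, radius, 0L)
      },
      largest = {
        cc <- .cq_label_cc(m)
        if (length(cc$sizes) == 0)
          stop("mask vanished during morphology (extraction failure)")
        keep <- which.max(cc$sizes)
        array(as.integer(cc$labels == keep), dim(m))
      },
      fill = .cq_fill_holes(m),
      stop("unknown morphology op: ", op))
    if (sum(m) == 0) stop("mask vanished during morphology (extraction ",
                          "failure at op '", op, "')")
  }
  mask_v <- with_data(raw_mask, m)
  structure(list(mask = mask_v,
                 brain_volume_ml = sum(m) * voxel_volume_ml(raw_mask)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d voxels, %.1f ml\n", sum(x$mask$data),
              x$brain_volume_ml))
  invisible(x)
}

#' Configuration for EM skull stripping
#'
#' @param air_threshold voxels at or below this intensity are treated as
#'   outside the head before EM.
#' @param patch_radius,search_radius,h nonlocal-means parameters
#'   (see [denoise_nlm()]).
#' @param low_pct,high_pct outlier-clipping percentiles.
#' @param priors fixed EM class priors.
#' @param margin shift of the bone threshold toward bone.
#' @param morph_radius structuring-element radius for mask fine-tuning.
#' @param max_iter,tol EM stopping controls.
#' @return A plain list of settings.
#' @export
skullstrip_config <- function(air_threshold = -200, patch_radius = 1,
                              search_radius = 3, h = NULL, low_pct = 0.1,
                              high_pct = 99.9, priors = c(0.5, 0.5),
                              margin = 0, morph_radius = 2, max_iter = 100,
                              tol = 1e-7) {
  as.list(environment())
}

#' Extract the brain from a head CT by expectation-maximization
#'
#' Five steps: (1) nonlocal-means denoising, (2) outlier-intensity
#' clipping, (3) two-class EM intensity classification with fixed priors
#' over head voxels, (4) bone threshold from the EM fit, (5) morphological
#' fine-tuning of the sub-threshold head tissue into a single connected,
#' hole-free brain mask.
#'
#' @param ct a head CT [ct_volume()] with visible skull contrast.
#' @param config a [skullstrip_config()].
#' @param verbose print per-stage summaries.
#' @return A `brain_mask` with extra fields: `skull_mask` (binary
#'   `ct_volume` of voxels above the bone threshold), `em` (the fitted
#'   `em_model`), `skull_threshold`, `config`.
#' @export
skull_strip <- function(ct, config = skullstrip_config(), verbose = FALSE) {
  if (!is_ct_volume(ct)) stop("`ct` must be a ct_volume")
  say <- function(...) if (verbose) message(sprintf(...))
  den <- denoise_nlm(ct, config$patch_radius, config$search_radius,
                     config$h)
  say("[denoise] intensity SD %.1f -> %.1f", sd(ct$data), sd(den$data))
  clipped <- remove_outliers(den, config$low_pct, config$high_pct)
  head_mask <- clipped$data > config$air_threshold
  if (sum(head_mask) < 100)
    stop("skull stripping failed: no head tissue above the air threshold")
  say("[head] %d voxels above air threshold", sum(head_mask))
  em <- tryCatch(
    em_two_class(clipped$data[head_mask], priors = config$priors,
                 max_iter = config$max_iter, tol = config$tol),
    error = function(e) stop("skull stripping failed at EM stage: ",
                             conditionMessage(e)))
  say("[em] means %.1f / %.1f after %d iterations", em$class_means[1],
      em$class_means[2], em$n_iter)
  thr <- skull_threshold_from_em(em, margin = config$margin)
  say("[threshold] bone threshold %.1f", thr)
  skull <- with_data(ct, array(as.integer(clipped$data > thr &
                                            head_mask), dim(ct)))
  raw <- with_data(ct, array(as.integer(head_mask & clipped$data <= thr),
                             dim(ct)))
  bm <- tryCatch(
    refine_mask_morphology(raw, radius = config$morph_radius),
    error = function(e) stop("skull stripping failed at morphology stage: ",
                             conditionMessage(e)))
  say("[mask] %.1f ml brain", bm$brain_volume_ml)
  bm$skull_mask <- skull
  bm$em <- em
  bm$skull_threshold <- thr
  bm$config <- config
  bm
}
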