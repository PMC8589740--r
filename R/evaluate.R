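#' Pearson correlation between continuous grade vectors
#'
#' @param x,y numeric vectors of continuous grades (n >= 3, both
#'   nonconstant).
#' @return Product-moment correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for constant input")
  cor(x, y)
}

#' Identical and within-one grade agreement, with confusion matrix
#'
#' @param a,b integer categorical grades in `[0, G]` (`a` is the
#'   reference source, `b` the test source).
#' @param G maximum grade of the scale.
#' @return List: `pct_identical`, `pct_within_one` (percentages of n),
#'   `confusion` ((G+1)x(G+1) integer matrix, rows = reference `a`,
#'   columns = test `b`, dimnames are the grades).
#' @export
grade_agreement <- function(a, b, G) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (any(a < 0 | a > G | b < 0 | b > G))
    stop("grades out of range [0, ", G, "]")
  n <- length(a)
  confusion <- table(factor(a, levels = 0:G), factor(b, levels = 0:G))
  confusion <- matrix(as.integer(confusion), G + 1, G + 1,
                      dimnames = list(reference = 0:G, test = 0:G))
  list(pct_identical = 100 * sum(a == b) / n,
       pct_within_one = 100 * sum(abs(a - b) <= 1) / n,
       confusion = confusion)
}

#' Agreement of the normal-versus-abnormal dichotomy
#'
#' Grades 0--1 count as normal (no or minor changes), grades above 1 as
#' abnormal.
#'
#' @param a,b integer categorical grades.
#' @return Percentage of cases with matching dichotomized class.
#' @export
normality_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  100 * mean((a > 1) == (b > 1))
}

#' Quadratically weighted Cohen's kappa from a confusion matrix
#'
#' `kappa = 1 - sum(w * O) / sum(w * E)` with disagreement weights
#' `w_ij = ((i - j) / G)^2` (any positive scaling of `w` cancels) and
#' chance-expected counts `E` from the marginal products.
#'
#' @param confusion square contingency matrix (rows reference, columns
#'   test), indexed by grades `0..G`.
#' @param weighting `"quadratic"` (default) or `"identity"` (reduces to
#'   unweighted Cohen's kappa).
#' @return Kappa in `[-1, 1]`.
#' @export
weighted_kappa <- function(confusion, weighting = c("quadratic",
                                                    "identity")) {
  weighting <- match.arg(weighting)
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  n <- sum(confusion)
  if (n == 0) stop("empty confusion matrix")
  G <- nrow(confusion) - 1
  rm <- rowSums(confusion)
  cm <- colSums(confusion)
  if (sum(rm > 0) < 2 || sum(cm > 0) < 2)
    stop("degenerate marginal: one source is constant, kappa undefined")
  i <- matrix(0:G, G + 1, G + 1)
  j <- t(i)
  w <- if (weighting == "quadratic") ((i - j) / G)^2 else (i != j) * 1
  expected <- outer(rm, cm) / n
  1 - sum(w * confusion) / sum(w * expected)
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = x - y`, mean difference (bias) and 95% limits of
#' agreement `mean(d) +/- 1.96 sd(d)`, plus the per-subject
#' (mean, difference) pairs used for plotting.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return A `bland_altman` list: `mean_diff`, `loa_low`, `loa_high`,
#'   `pairs` (data frame with `mean` and `diff`).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  d <- x - y
  m <- mean(d)
  s <- sd(d)
  structure(list(mean_diff = m, loa_low = m - 1.96 * s,
                 loa_high = m + 1.96 * s,
                 pairs = data.frame(mean = (x + y) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, 95%% LoA [%.3f, %.3f], n = %d\n",
              x$mean_diff, x$loa_low, x$loa_high, nrow(x$pairs)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$pairs$mean, x$pairs$diff, xlab = "mean of sources",
       ylab = "difference (ref - test)", ...)
  abline(h = x$mean_diff, lty = 1)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Full agreement report between two grade sources for one scale
#'
#' @param ref_cont,test_cont continuous grades (reference and test
#'   source).
#' @param ref_cat,test_cat categorical grades; derived from the
#'   continuous values via [categorize()] when omitted.
#' @param scale grade scale name (see [grade_range()]).
#' @return An `agreement_report`: `scale`, `n`, `pearson_r`,
#'   `pct_identical`, `pct_within_one`, `pct_normality_identical`,
#'   `kappa_quadratic`, `bland_altman`, `confusion`.
#' @export
agreement_report <- function(ref_cont, test_cont, ref_cat = NULL,
                             test_cat = NULL,
                             scale = c("mta", "gca", "fazekas")) {
  scale <- match.arg(scale)
  rng <- grade_range(scale)
  if (is.null(ref_cat)) ref_cat <- categorize(ref_cont, rng)$categorical
  if (is.null(test_cat)) test_cat <- categorize(test_cont, rng)$categorical
  ga <- grade_agreement(ref_cat, test_cat, rng[2])
  kappa <- tryCatch(weighted_kappa(ga$confusion),
                    error = function(e) NA_real_)
  structure(list(scale = scale, n = length(ref_cont),
                 pearson_r = pearson_r(ref_cont, test_cont),
                 pct_identical = ga$pct_identical,
                 pct_within_one = ga$pct_within_one,
                 pct_normality_identical = normality_agreement(ref_cat,
                                                               test_cat),
                 kappa_quadratic = kappa,
                 bland_altman = bland_altman(ref_cont, test_cont),
                 confusion = ga$confusion),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report> %s (n = %d): r = %.2f, ",
                     "identical %.0f%%, <=1 %.0f%%, normality %.0f%%, ",
                     "kappa_q = %.2f\n"),
              x$scale, x$n, x$pearson_r, x$pct_identical,
              x$pct_within_one, x$pct_normality_identical,
              x$kappa_quadratic))
  invisible(x)
}

#' Agreement reports across all grade scales of two grade tables
#'
#' Joins two per-subject grade tables on `subject_id` and produces one
#' [agreement_report()] per requested scale column, plus a summary data
#' frame shaped like the headline agreement tables of CT-versus-reference
#' comparisons (one row per scale: r, % identical, % within one,
#' % identical normality, quadratic kappa).
#'
#' @param ref,test data frames with `subject_id` and per-scale continuous
#'   grade columns (e.g. `mta`, `gca`, `fazekas`, `gca_frontal`, ...).
#' @param scales named character vector mapping column names to scale
#'   families (`"mta"`, `"gca"` or `"fazekas"`); default: every shared
#'   grade column, family inferred from its name prefix.
#' @return A `full_report` list: `summary` (data frame), `reports` (list
#'   of `agreement_report`).
#' @export
full_report <- function(ref, test, scales = NULL) {
  if (!all(c("subject_id") %in% names(ref)) ||
      !all(c("subject_id") %in% names(test)))
    stop("both tables need a subject_id column")
  merged <- merge(ref, test, by = "subject_id",
                  suffixes = c("_ref", "_test"))
  missing_ref <- setdiff(ref$subject_id, merged$subject_id)
  missing_test <- setdiff(test$subject_id, merged$subject_id)
  if (length(missing_ref) || length(missing_test))
    stop("subject mismatch; unmatched ids: ",
         paste(c(missing_ref, missing_test), collapse = ", "))
  if (is.null(scales)) {
    shared <- intersect(setdiff(names(ref), "subject_id"),
                        setdiff(names(test), "subject_id"))
    scales <- setNames(ifelse(grepl("^mta", shared), "mta",
                              ifelse(grepl("^gca", shared), "gca",
                                     "fazekas")), shared)
  }
  reports <- lapply(names(scales), function(col) {
    agreement_report(merged[[paste0(col, "_ref")]],
                     merged[[paste0(col, "_test")]],
                     scale = scales[[col]])
  })
  names(reports) <- names(scales)
  summary <- do.call(rbind, lapply(names(reports), function(col) {
    r <- reports[[col]]
    data.frame(scale = col, n = r$n, pearson_r = r$pearson_r,
               pct_identical = r$pct_identical,
               pct_within_one = r$pct_within_one,
               pct_normality_identical = r$pct_normality_identical,
               kappa_quadratic = r$kappa_quadratic)
  }))
  structure(list(summary = summary, reports = reports),
            class = "full_report")
}

#' @export
print.full_report <- function(x, ...) {
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
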