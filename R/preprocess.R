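# Probe filtering and normalization: detection filter, cross-array MA-loess
# against a median pseudo-reference, log2 transform.

#' Filter probes by detection call
#'
#' Retains exactly the probes whose detection p-value is strictly below
#' `alpha` in at least `min_samples` samples (the presence rule for
#' one-color arrays: p < 0.05 in >= 3 of 12 samples by default). Probe order
#' is preserved; the operation is idempotent.
#'
#' @param em an [expression_matrix()] carrying detection p-values.
#' @param alpha detection significance level; the comparison is strict
#'   (`p < alpha`).
#' @param min_samples minimum number of samples with significant detection.
#' @return The filtered [expression_matrix()]; filter settings are appended
#'   to its `provenance`.
#' @export
detection_filter <- function(em, alpha = 0.05, min_samples = 3) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(em$detection_p))
    abort_validation(paste(
      "expression matrix has no detection p-values;",
      "skip the detection filter explicitly if the data are pre-filtered"
    ))
  if (min_samples < 1 || min_samples > ncol(em$intensity))
    abort_validation("min_samples must lie between 1 and the number of samples")
  keep <- rowSums(em$detection_p < alpha) >= min_samples
  expression_matrix(
    em$intensity[keep, , drop = FALSE],
    em$detection_p[keep, , drop = FALSE],
    provenance = c(em$provenance, list(detection_filter = list(
      alpha = alpha, min_samples = min_samples,
      probes_in = nrow(em$intensity), probes_out = sum(keep)
    )))
  )
}

#' Loess-normalize arrays against a median pseudo-reference
#'
#' Removes smooth intensity-dependent chip-to-chip bias. For each array j a
#' robust loess curve is fitted to M = log2(x_j) - log2(ref) versus
#' A = (log2(x_j) + log2(ref)) / 2, where ref is the per-probe median across
#' arrays (the pseudo-reference array), and the fitted curve is subtracted
#' from log2(x_j). Values are returned on the linear scale. When all arrays
#' are identical the operation is exactly a no-op (M is identically zero, so
#' the correction divides by 2^0 = 1 and the input bits are returned).
#'
#' @param em an [expression_matrix()] (linear-scale, all intensities > 0).
#' @param span loess span (fraction of probes in each local window).
#' @param iterations robustness iterations for the symmetric (Tukey biweight)
#'   family.
#' @param degree local polynomial degree for the smoother.
#' @return The normalized [expression_matrix()] with settings appended to
#'   `provenance`.
#' @export
loess_normalize <- function(em, span = 0.4, iterations = 3, degree = 2) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  x <- em$intensity
  if (ncol(x) < 2) abort_validation("loess normalization needs at least 2 arrays")
  if (nrow(x) < 10) abort_validation("loess normalization is underdetermined with fewer than 10 probes")
  lg <- log2(x)
  ref <- apply(lg, 1, stats::median)
  out <- x
  for (j in seq_len(ncol(x))) {
    M <- lg[, j] - ref
    if (all(M == 0)) next   # identical to the reference: exact no-op
    if (stats::mad(M) == 0) {
      # the bulk of the probes sits at one exact offset from the reference:
      # the biweight robustness weights are undefined, and the only
      # identifiable chip-to-chip bias is that constant shift
      shift <- stats::median(M)
      if (shift != 0) out[, j] <- x[, j] / 2^shift
      next
    }
    A <- (lg[, j] + ref) / 2
    fit <- stats::loess(
      M ~ A, span = span, degree = degree, family = "symmetric",
      control = stats::loess.control(iterations = iterations, surface = "direct")
    )
    out[, j] <- x[, j] / 2^stats::fitted(fit)
  }
  expression_matrix(
    out, em$detection_p,
    provenance = c(em$provenance, list(loess_normalize = list(
      span = span, iterations = iterations, degree = degree,
      reference = "per-probe median pseudo-array"
    )))
  )
}

#' Fit the residual M-vs-A trend of one array against the pseudo-reference
#'
#' Diagnostic companion to [loess_normalize()]: returns the fitted loess
#' trend of M on A for array `j`, used to quantify how much
#' intensity-dependent bias remains (its max absolute value is the trend
#' amplitude).
#'
#' @param em an [expression_matrix()].
#' @param j array (column) index.
#' @inheritParams loess_normalize
#' @return Numeric vector of fitted M values, one per probe.
#' @export
ma_trend <- function(em, j, span = 0.4, iterations = 3, degree = 2) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  lg <- log2(em$intensity)
  ref <- apply(lg, 1, stats::median)
  M <- lg[, j] - ref
  if (all(M == 0)) return(rep(0, nrow(lg)))
  A <- (lg[, j] + ref) / 2
  fit <- stats::loess(
    M ~ A, span = span, degree = degree, family = "symmetric",
    control = stats::loess.control(iterations = iterations, surface = "direct")
  )
  stats::fitted(fit)
}

#' Log2-transform an expression matrix
#'
#' @param em an [expression_matrix()] with strictly positive intensities.
#' @return A `NormalizedMatrix`: list with `log2_intensity` (probes x
#'   samples) and `provenance` (accumulated filter and normalization
#'   settings).
#' @export
log2_transform <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  bad <- which(em$intensity <= 0, arr.ind = TRUE)
  if (nrow(bad))
    abort_validation(sprintf(
      "non-positive intensity at probe '%s', sample '%s'",
      rownames(em$intensity)[bad[1, 1]], colnames(em$intensity)[bad[1, 2]]
    ))
  structure(
    list(
      log2_intensity = log2(em$intensity),
      provenance = c(em$provenance, list(log2_transform = TRUE))
    ),
    class = "NormalizedMatrix"
  )
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d probes x %d samples (log2 scale)\n",
              nrow(x$log2_intensity), ncol(x$log2_intensity)))
  invisible(x)
}

#' @export
dim.NormalizedMatrix <- function(x) dim(x$log2_intensity)
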