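#' Expression matrix container
#'
#' Probes x samples linear-scale fluorescence intensities, optionally with an
#' aligned matrix of per-probe per-sample detection p-values. Intensities must
#' be strictly positive (the pipeline log2-transforms them), probe and sample
#' identifiers must be unique, and the two matrices must be congruent.
#'
#' @param intensity numeric matrix, probes x samples, with rownames (probe
#'   ids) and colnames (sample ids); all values > 0.
#' @param detection_p optional numeric matrix of detection p-values in
#'   \[0, 1\], same dimensions and dimnames as `intensity`.
#' @param provenance optional list recording filter/normalization settings
#'   already applied.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `intensity`, `detection_p` (possibly `NULL`), and `provenance`.
#' @export
expression_matrix <- function(intensity, detection_p = NULL, provenance = list()) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    abort_validation("'intensity' must be a numeric matrix")
  probe_ids <- rownames(intensity)
  sample_ids <- colnames(intensity)
  if (is.null(probe_ids) || is.null(sample_ids))
    abort_validation("'intensity' must carry probe ids as rownames and sample ids as colnames")
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup))
    abort_validation(sprintf("duplicate probe id(s): %s", paste(unique(dup), collapse = ", ")))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    abort_validation(sprintf("duplicate sample id(s): %s", paste(unique(dup), collapse = ", ")))
  bad <- which(!is.finite(intensity) | intensity <= 0, arr.ind = TRUE)
  if (nrow(bad))
    abort_validation(sprintf(
      "non-positive or non-finite intensity at probe '%s', sample '%s' (value %s)",
      probe_ids[bad[1, 1]], sample_ids[bad[1, 2]],
      format(intensity[bad[1, 1], bad[1, 2]])
    ))
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !is.numeric(detection_p))
      abort_validation("'detection_p' must be a numeric matrix")
    if (!identical(dim(detection_p), dim(intensity)))
      abort_validation(sprintf(
        "detection matrix shape (%d x %d) does not match intensity (%d x %d)",
        nrow(detection_p), ncol(detection_p), nrow(intensity), ncol(intensity)
      ))
    if (!identical(rownames(detection_p), probe_ids) ||
        !identical(colnames(detection_p), sample_ids))
      abort_validation("detection matrix probe/sample ids do not match the intensity matrix")
    if (anyNA(detection_p) || any(detection_p < 0 | detection_p > 1))
      abort_validation("detection p-values must lie in [0, 1]")
  }
  structure(
    list(intensity = intensity, detection_p = detection_p, provenance = provenance),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d probes x %d samples (%s detection p-values)\n",
    nrow(x$intensity), ncol(x$intensity),
    if (is.null(x$detection_p)) "no" else "with"
  ))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$intensity)

probe_ids <- function(em) rownames(em$intensity)
sample_ids <- function(em) colnames(em$intensity)

#' Read an expression matrix (and optional detection p-values) from TSV
#'
#' Files are tab-separated with a header row of sample ids and the probe id
#' in the first column. The optional detection file must have the identical
#' layout.
#'
#' @param path path to the intensity TSV.
#' @param detection_path optional path to a congruent detection p-value TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, detection_path = NULL) {
  intensity <- read_matrix_tsv(path)
  detection_p <- if (!is.null(detection_path)) read_matrix_tsv(detection_path) else NULL
  expression_matrix(intensity, detection_p)
}

read_matrix_tsv <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort_io(sprintf("expected probe id column plus >=1 sample column in %s", path))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    abort_validation(sprintf(
      "duplicate probe id(s) in %s: %s", path,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort_validation(sprintf("non-numeric values in %s", path))
  rownames(m) <- ids
  m
}

#' Write an expression matrix (and detection p-values) to TSV
#'
#' Inverse of [read_expression()]: `read_expression(write_expression(em, ...))`
#' reproduces `em` up to numeric formatting (15 significant digits).
#'
#' @param em an [expression_matrix()].
#' @param path destination for the intensity TSV.
#' @param detection_path optional destination for the detection TSV.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(em, path, detection_path = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  write_matrix_tsv(em$intensity, path, id_col = "probe_id")
  if (!is.null(detection_path)) {
    if (is.null(em$detection_p))
      abort_validation("expression matrix carries no detection p-values to write")
    write_matrix_tsv(em$detection_p, detection_path, id_col = "probe_id")
  }
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_raw(df, path)
}

write_tsv_raw <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort_io(sprintf("cannot write %s: %s", path, conditionMessage(ok)))
  invisible(path)
}
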