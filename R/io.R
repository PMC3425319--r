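# Readers/writers for the tabular artifacts around the expression matrix:
# study design, mRNA DE table, target-prediction tables, GMT pathway sets,
# and a deterministic generic table writer.

GROUP_LEVELS <- c("CONTROL", "S1", "S6")

# accepted spellings for the three experimental groups; "25*1" / "25*6" are
# the stretch-group designations (25% delta-SA for 1 h / 6 h)
GROUP_ALIASES <- c(
  "CONTROL" = "CONTROL", "CONTROLS" = "CONTROL", "UNSTRETCHED" = "CONTROL",
  "S1" = "S1", "25*1" = "S1",
  "S6" = "S6", "25*6" = "S6"
)

canonical_group <- function(x) {
  key <- toupper(trimws(x))
  out <- unname(GROUP_ALIASES[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort_validation(sprintf(
      "unknown group label(s): %s (allowed: %s)",
      paste(bad, collapse = ", "),
      paste(unique(names(GROUP_ALIASES)), collapse = ", ")
    ))
  }
  factor(out, levels = GROUP_LEVELS)
}

#' Construct and validate a study design table
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group group labels; `"CONTROL"`, `"S1"`/`"25*1"` (25% delta-SA, 1 h)
#'   and `"S6"`/`"25*6"` (25% delta-SA, 6 h) are accepted.
#' @param animal_id animal identifiers (one animal contributes one sample per
#'   group in the default design).
#' @return A `StudyDesign` data frame with columns `sample_id`,
#'   `group` (factor with levels CONTROL, S1, S6), `animal_id`.
#' @export
study_design <- function(sample_id, group, animal_id) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    abort_validation(sprintf(
      "duplicate sample id(s) in design: %s",
      paste(unique(sample_id[duplicated(sample_id)]), collapse = ", ")
    ))
  df <- data.frame(
    sample_id = sample_id,
    group = canonical_group(group),
    animal_id = as.character(animal_id),
    stringsAsFactors = FALSE
  )
  class(df) <- c("StudyDesign", "data.frame")
  df
}

#' Read a study design TSV (columns sample_id, group, animal_id)
#' @param path path to the design TSV.
#' @return A [study_design()] table.
#' @export
read_design <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "group", "animal_id"))
  study_design(df$sample_id, df$group, df$animal_id)
}

#' Construct and validate an mRNA differential-expression table
#'
#' Gene symbols are upper-cased on ingest so that rat array symbols match the
#' prediction databases regardless of source casing.
#'
#' @param gene_symbol character vector; unique after upper-casing.
#' @param log2fc per-gene log2 fold change (stretch minus control).
#' @param q_value BH-adjusted p-value in \[0, 1\].
#' @return A `MrnaDETable` data frame.
#' @export
mrna_de_table <- function(gene_symbol, log2fc, q_value) {
  gene_symbol <- toupper(as.character(gene_symbol))
  if (anyDuplicated(gene_symbol))
    abort_validation(sprintf(
      "duplicate gene symbol(s) after case normalization: %s",
      paste(unique(gene_symbol[duplicated(gene_symbol)]), collapse = ", ")
    ))
  log2fc <- as.numeric(log2fc)
  q_value <- as.numeric(q_value)
  if (anyNA(q_value) || any(q_value < 0 | q_value > 1))
    abort_validation("mRNA q-values must lie in [0, 1]")
  if (anyNA(log2fc) || any(!is.finite(log2fc)))
    abort_validation("mRNA log2 fold changes must be finite")
  df <- data.frame(gene_symbol = gene_symbol, log2fc = log2fc,
                   q_value = q_value, stringsAsFactors = FALSE)
  class(df) <- c("MrnaDETable", "data.frame")
  df
}

#' Read an mRNA DE table TSV (columns gene_symbol, log2fc, q_value)
#' @param path path to the TSV.
#' @return A [mrna_de_table()].
#' @export
read_mrna_de <- function(path) {
  df <- read_tsv_checked(path, c("gene_symbol", "log2fc", "q_value"))
  mrna_de_table(df$gene_symbol, df$log2fc, df$q_value)
}

#' Construct and validate a target-prediction table
#'
#' Two database dialects are supported: `DB_A` rows carry a context
#' percentile (a rank-normalized confidence in \[0, 100\], higher = more
#' confident); `DB_B` rows are presence-only.
#'
#' @param mirna_id miRNA identifiers (pre-mapped to the array's probe naming;
#'   mapping array probe names to database identifiers is the caller's
#'   responsibility).
#' @param gene_symbol predicted target gene symbols (upper-cased on ingest).
#' @param source `"DB_A"` (context-scored) or `"DB_B"` (presence-only); a
#'   single label for the whole table.
#' @param context_percentile numeric in \[0, 100\]; required when
#'   `source == "DB_A"`, must be absent/NA for `DB_B`.
#' @return A `TargetPredictionTable` data frame.
#' @export
target_table <- function(mirna_id, gene_symbol, source, context_percentile = NULL) {
  source <- match.arg(source, c("DB_A", "DB_B"))
  mirna_id <- as.character(mirna_id)
  gene_symbol <- toupper(as.character(gene_symbol))
  n <- max(length(mirna_id), length(gene_symbol))
  if (length(mirna_id) == 1) mirna_id <- rep(mirna_id, n)
  if (length(gene_symbol) == 1) gene_symbol <- rep(gene_symbol, n)
  if (length(gene_symbol) != length(mirna_id))
    abort_validation("mirna_id and gene_symbol lengths differ")
  if (source == "DB_A") {
    if (is.null(context_percentile) || anyNA(context_percentile))
      abort_validation("DB_A rows must all carry a context_percentile")
    context_percentile <- as.numeric(context_percentile)
    if (any(context_percentile < 0 | context_percentile > 100))
      abort_validation("context percentiles must lie in [0, 100]")
  } else {
    context_percentile <- rep(NA_real_, n)
  }
  key <- paste(mirna_id, gene_symbol, source, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    abort_validation(sprintf(
      "duplicate prediction edge (%s, %s) in %s", mirna_id[d], gene_symbol[d], source
    ))
  }
  df <- data.frame(mirna_id = mirna_id, gene_symbol = gene_symbol,
                   source = rep(source, length(mirna_id)),
                   context_percentile = context_percentile,
                   stringsAsFactors = FALSE)
  class(df) <- c("TargetPredictionTable", "data.frame")
  df
}

#' Read a target-prediction TSV
#'
#' Expected columns: `mirna_id`, `gene_symbol`, and (for `DB_A`)
#' `context_percentile`.
#'
#' @param path path to the TSV.
#' @param source_label `"DB_A"` or `"DB_B"`.
#' @return A [target_table()].
#' @export
read_targets <- function(path, source_label) {
  source_label <- match.arg(source_label, c("DB_A", "DB_B"))
  need <- c("mirna_id", "gene_symbol")
  df <- read_tsv_checked(path, need)
  cp <- if (source_label == "DB_A") {
    if (!"context_percentile" %in% names(df))
      abort_validation(sprintf("%s: DB_A table lacks a context_percentile column", path))
    df$context_percentile
  } else NULL
  target_table(df$mirna_id, df$gene_symbol, source_label, cp)
}

#' Construct a pathway gene-set database
#'
#' @param term_id character vector of unique term identifiers.
#' @param term_name free-text term names.
#' @param genes list of character vectors of member gene symbols
#'   (upper-cased, de-duplicated; each set must be non-empty).
#' @return A `PathwayDB` object (list with `term_id`, `term_name`, `genes`).
#' @export
pathway_db <- function(term_id, term_name, genes) {
  term_id <- as.character(term_id)
  if (anyDuplicated(term_id))
    abort_validation(sprintf(
      "duplicate pathway term id(s): %s",
      paste(unique(term_id[duplicated(term_id)]), collapse = ", ")
    ))
  genes <- lapply(genes, function(g) sort(unique(toupper(as.character(g)))))
  empty <- lengths(genes) == 0
  if (any(empty))
    abort_validation(sprintf(
      "pathway term(s) with empty gene set: %s",
      paste(term_id[empty], collapse = ", ")
    ))
  structure(
    list(term_id = term_id, term_name = as.character(term_name), genes = genes),
    class = "PathwayDB"
  )
}

#' @export
print.PathwayDB <- function(x, ...) {
  cat(sprintf("PathwayDB: %d terms, %d distinct genes\n",
              length(x$term_id), length(unique(unlist(x$genes)))))
  invisible(x)
}

#' @export
length.PathwayDB <- function(x) length(x$term_id)

#' Read pathway gene sets in GMT format
#'
#' GMT is the standard gene-set exchange format: one term per line,
#' tab-separated as `term_id <TAB> description <TAB> gene <TAB> gene ...`.
#'
#' @param path path to the GMT file.
#' @return A [pathway_db()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort_validation(sprintf("%s: empty GMT file", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    abort_validation(sprintf("%s: GMT line %d has fewer than 3 fields", path, short[1]))
  pathway_db(
    term_id = vapply(fields, `[[`, "", 1L),
    term_name = vapply(fields, `[[`, "", 2L),
    genes = lapply(fields, function(f) f[-(1:2)])
  )
}

#' Write pathway gene sets in GMT format
#' @param db a [pathway_db()].
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "PathwayDB"))
  lines <- vapply(seq_along(db$term_id), function(i) {
    paste(c(db$term_id[i], db$term_name[i], sort(db$genes[[i]])), collapse = "\t")
  }, "")
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) abort_io(sprintf("cannot write %s: %s", path, conditionMessage(ok)))
  invisible(path)
}

#' Write a data frame as a deterministic TSV
#'
#' Rows are sorted by the columns left to right (the leading columns act as
#' the primary key) and written with a fixed column order, so two writes of
#' the same records — in any input row order — produce byte-identical files.
#' An empty table yields a header-only file.
#'
#' @param records a data frame.
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) abort_validation("'records' must be a data frame")
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(df) > 1) {
    ord <- do.call(order, c(unname(as.list(df)), list(method = "radix")))
    df <- df[ord, , drop = FALSE]
  }
  write_tsv_raw(df, path)
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    abort_validation(sprintf(
      "%s: missing required column(s): %s", path, paste(missing, collapse = ", ")
    ))
  df
}
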