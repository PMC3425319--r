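# Pathway over-representation: one-sided Fisher (hypergeometric upper tail)
# and its jackknifed EASE variant, against a custom background.

#' One-sided Fisher exact (hypergeometric upper tail) p-value
#'
#' P(X >= a) where X is hypergeometric with population `N`, `K` successes
#' and `list_size` draws. Evaluated through [stats::phyper()], which works in
#' log space for numerical stability.
#'
#' @param a observed overlap (successes drawn); vectorized.
#' @param list_size number of draws (size of the gene list).
#' @param K successes in the population (pathway size within the background).
#' @param N population size (background size).
#' @return Upper-tail probability in (0, 1\].
#' @export
fisher_one_sided <- function(a, list_size, K, N) {
  check_table(a, list_size, K, N)
  stats::phyper(a - 1, K, N - K, list_size, lower.tail = FALSE)
}

#' EASE score: jackknifed one-sided Fisher exact p-value
#'
#' The conservative DAVID variant: one success is removed from the overlap
#' cell before taking the hypergeometric upper tail,
#' `ease = fisher_one_sided(max(a - 1, 0), ...)`. A single-gene overlap
#' (a <= 1) therefore always scores 1.0, and `ease >= fisher` for every
#' table.
#'
#' @inheritParams fisher_one_sided
#' @return EASE p-value in (0, 1\].
#' @export
ease_score <- function(a, list_size, K, N) {
  check_table(a, list_size, K, N)
  fisher_one_sided(pmax(a - 1, 0), list_size, K, N)
}

check_table <- function(a, list_size, K, N) {
  if (any(a < 0) || any(list_size < 0) || any(K < 0) || any(N < 0) ||
      any(a > pmin(list_size, K)) || any(list_size > N) || any(K > N))
    abort_validation(paste(
      "inconsistent 2x2 counts: need 0 <= a <= min(list_size, K),",
      "list_size <= N and K <= N"
    ))
  invisible(TRUE)
}

#' Pathway over-representation of a gene list against a custom background
#'
#' Each pathway's gene set is intersected with the background before the
#' 2x2 table is built (the custom-background convention). List genes outside
#' the background are dropped with a warning. One result row is produced for
#' every pathway with at least `min_overlap` list hits, sorted ascending by
#' EASE score with ties broken by term id. No multiple-testing correction is
#' applied by default — significance is the raw EASE score below `alpha` —
#' but BH-adjusted EASE q-values are available via `adjust = TRUE`.
#'
#' @param gene_list character vector of genes of interest (case-insensitive).
#' @param background character vector: the gene universe the list was drawn
#'   from (e.g. all differentially expressed genes of the parallel mRNA
#'   study).
#' @param pathways a [pathway_db()].
#' @param alpha EASE significance threshold (strict: `ease_p < alpha`).
#' @param min_overlap minimum list hits for a pathway to be reported
#'   (default 2, since the EASE jackknife forces a = 1 to p = 1).
#' @param adjust if `TRUE`, add a BH-adjusted `ease_q` column (adjustment
#'   over the reported terms).
#' @return An `EnrichmentResult` data frame: `term_id`, `term_name`,
#'   `list_hits`, `list_size`, `background_hits`, `background_size`,
#'   `ease_p`, `fisher_p`, `significant`, `overlap_genes`
#'   (comma-separated, sorted).
#' @export
enrich_pathways <- function(gene_list, background, pathways, alpha = 0.05,
                            min_overlap = 2, adjust = FALSE) {
  stopifnot(inherits(pathways, "PathwayDB"))
  background <- unique(toupper(as.character(background)))
  if (!length(background)) abort_validation("empty background gene set")
  gene_list <- unique(toupper(as.character(gene_list)))
  outside <- setdiff(gene_list, background)
  if (length(outside)) {
    warning(sprintf(
      "%d gene(s) outside the background dropped from the list: %s",
      length(outside), paste(utils::head(sort(outside), 5), collapse = ", ")
    ))
    gene_list <- intersect(gene_list, background)
  }
  N <- length(background)
  n <- length(gene_list)

  rows <- lapply(seq_along(pathways$term_id), function(i) {
    pw <- intersect(pathways$genes[[i]], background)
    K <- length(pw)
    hits <- intersect(pw, gene_list)
    a <- length(hits)
    if (a < min_overlap) return(NULL)
    data.frame(
      term_id = pathways$term_id[i],
      term_name = pathways$term_name[i],
      list_hits = a, list_size = n,
      background_hits = K, background_size = N,
      ease_p = ease_score(a, n, K, N),
      fisher_p = fisher_one_sided(a, n, K, N),
      overlap_genes = paste(sort(hits), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(
      term_id = character(0), term_name = character(0),
      list_hits = integer(0), list_size = integer(0),
      background_hits = integer(0), background_size = integer(0),
      ease_p = numeric(0), fisher_p = numeric(0),
      overlap_genes = character(0), significant = logical(0),
      stringsAsFactors = FALSE
    )
    class(out) <- c("EnrichmentResult", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$significant <- out$ease_p < alpha
  out <- out[order(out$ease_p, out$term_id), , drop = FALSE]
  if (adjust) out$ease_q <- bh_stepup(out$ease_p)
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}
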