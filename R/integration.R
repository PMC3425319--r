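# Core integration: dual-database target consensus, anti-correlated
# miRNA:mRNA pairing against the parallel mRNA DE table, and the
# promiscuity/redundancy network summaries.

#' Consensus targets predicted by both databases
#'
#' Keeps the (miRNA, gene) edges that are predicted by the context-scored
#' database at or above the context-percentile cutoff *and* present in the
#' presence-only database, restricted to the miRNAs of interest. Star
#' (passenger-strand) miRNAs absent from the context-scored database simply
#' yield no edges; no special casing.
#'
#' @param db_a a [target_table()] with `source = "DB_A"` (context-scored).
#' @param db_b a [target_table()] with `source = "DB_B"` (presence-only).
#' @param mirnas character vector of miRNA identifiers to consider (usually
#'   the regulated set); `NULL` means all.
#' @param percentile_cutoff minimum context percentile, inclusive
#'   (default 50: the ">= 50th percentile" rule).
#' @return A `ConsensusTargetSet`: data frame of `mirna_id`, `gene_symbol`
#'   edges (sorted), with the cutoff as attribute `percentile_cutoff`.
#' @export
consensus_targets <- function(db_a, db_b, mirnas = NULL, percentile_cutoff = 50) {
  stopifnot(is.data.frame(db_a), is.data.frame(db_b))
  if (!all(db_a$source == "DB_A") || anyNA(db_a$context_percentile))
    abort_validation("db_a must be a DB_A table with context percentiles on every row")
  a <- db_a[db_a$context_percentile >= percentile_cutoff, c("mirna_id", "gene_symbol")]
  b <- db_b[, c("mirna_id", "gene_symbol")]
  if (!is.null(mirnas)) {
    a <- a[a$mirna_id %in% mirnas, , drop = FALSE]
  }
  key_a <- paste(a$mirna_id, a$gene_symbol, sep = "\r")
  key_b <- paste(b$mirna_id, b$gene_symbol, sep = "\r")
  edges <- a[key_a %in% key_b, , drop = FALSE]
  edges <- edges[order(edges$mirna_id, edges$gene_symbol), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "percentile_cutoff") <- percentile_cutoff
  class(edges) <- c("ConsensusTargetSet", "data.frame")
  edges
}

#' Anti-correlated miRNA:mRNA pairs
#'
#' Emits a pair (m, g) when m is regulated (UP or DOWN), the edge (m, g) is
#' in the consensus target set, g is in the mRNA DE table with
#' `q_value <= mrna_q_cutoff`, and g's fold sign is strictly opposite to m's
#' direction (up-regulated miRNAs pair only with down-regulated mRNAs and
#' vice versa — the repression-consistent pairing). Genes with a log2 fold
#' change of exactly 0 are never paired.
#'
#' @param cts a [consensus_targets()] edge set.
#' @param mirna_de a [call_regulated()] result, or any data frame with
#'   `feature_id` and `direction` columns (as from [regulated_features()]).
#' @param mrna_de a [mrna_de_table()].
#' @param mrna_q_cutoff FDR threshold on the mRNA side (inclusive).
#' @return A `PairTable` data frame: `mirna_id`, `gene_symbol`,
#'   `mirna_direction`, `gene_log2fc`, `gene_q`, sorted by miRNA then gene.
#' @export
anticorrelated_pairs <- function(cts, mirna_de, mrna_de, mrna_q_cutoff = 0.1) {
  stopifnot(is.data.frame(cts), is.data.frame(mrna_de))
  reg <- if ("contrast" %in% names(mirna_de)) regulated_features(mirna_de) else mirna_de
  stopifnot(all(c("feature_id", "direction") %in% names(reg)))
  reg <- reg[reg$direction %in% c("UP", "DOWN"), , drop = FALSE]
  genes <- mrna_de[mrna_de$q_value <= mrna_q_cutoff & mrna_de$log2fc != 0, , drop = FALSE]

  m <- merge(cts, reg, by.x = "mirna_id", by.y = "feature_id")
  m <- merge(m, genes, by = "gene_symbol")
  anti <- (m$direction == "UP" & m$log2fc < 0) | (m$direction == "DOWN" & m$log2fc > 0)
  out <- data.frame(
    mirna_id = m$mirna_id[anti],
    gene_symbol = m$gene_symbol[anti],
    mirna_direction = m$direction[anti],
    gene_log2fc = m$log2fc[anti],
    gene_q = m$q_value[anti],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$mirna_id, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("PairTable", "data.frame")
  out
}

#' Promiscuity / redundancy summary of the pair network
#'
#' Counts predicted targets per miRNA and predicting miRNAs per gene.
#' "Promiscuous" miRNAs regulate strictly more than `promiscuity_threshold`
#' genes (default: more than 5); "redundant" genes are hit by at least
#' `redundancy_threshold` miRNAs (default: >= 3 miRNA:mRNA matches).
#'
#' @param pairs a `PairTable` from [anticorrelated_pairs()].
#' @param promiscuity_threshold strict lower bound on targets per
#'   promiscuous miRNA.
#' @param redundancy_threshold inclusive lower bound on miRNAs per redundant
#'   gene.
#' @return A `NetworkSummary` list: `per_mirna_target_count`,
#'   `per_gene_mirna_count` (named integer vectors), `promiscuous_mirnas`,
#'   `redundant_genes` (character vectors), `n_pairs`.
#' @export
summarize_network <- function(pairs, promiscuity_threshold = 5, redundancy_threshold = 3) {
  stopifnot(is.data.frame(pairs))
  per_mirna <- table(factor(pairs$mirna_id))
  per_gene <- table(factor(pairs$gene_symbol))
  per_mirna <- stats::setNames(as.integer(per_mirna), names(per_mirna))
  per_gene <- stats::setNames(as.integer(per_gene), names(per_gene))
  structure(
    list(
      per_mirna_target_count = per_mirna,
      per_gene_mirna_count = per_gene,
      promiscuous_mirnas = sort(names(per_mirna)[per_mirna > promiscuity_threshold]),
      redundant_genes = sort(names(per_gene)[per_gene >= redundancy_threshold]),
      n_pairs = nrow(pairs),
      promiscuity_threshold = promiscuity_threshold,
      redundancy_threshold = redundancy_threshold
    ),
    class = "NetworkSummary"
  )
}

#' @export
print.NetworkSummary <- function(x, ...) {
  cat(sprintf(
    "NetworkSummary: %d pairs, %d miRNAs, %d genes; %d promiscuous miRNA(s) (> %d targets), %d redundant gene(s) (>= %d miRNAs)\n",
    x$n_pairs, length(x$per_mirna_target_count), length(x$per_gene_mirna_count),
    length(x$promiscuous_mirnas), x$promiscuity_threshold,
    length(x$redundant_genes), x$redundancy_threshold
  ))
  invisible(x)
}

#' Gene counts by pairing partition
#'
#' Distinct genes paired with up-regulated miRNAs (these genes are
#' down-regulated) and with down-regulated miRNAs (up-regulated genes).
#' Because a gene's fold sign is unique, the two partitions are disjoint and
#' sum to the distinct-gene total — the structural identity behind reporting
#' the two gene lists and their union.
#'
#' @param pairs a `PairTable`.
#' @return Named list: `n_genes_down_of_up`, `n_genes_up_of_down`,
#'   `n_genes_total`.
#' @export
partition_counts <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  down_of_up <- unique(pairs$gene_symbol[pairs$mirna_direction == "UP"])
  up_of_down <- unique(pairs$gene_symbol[pairs$mirna_direction == "DOWN"])
  overlap <- intersect(down_of_up, up_of_down)
  if (length(overlap))
    abort_validation(sprintf(
      "gene(s) paired with both miRNA directions (sign inconsistency): %s",
      paste(overlap, collapse = ", ")
    ))
  list(
    n_genes_down_of_up = length(down_of_up),
    n_genes_up_of_down = length(up_of_down),
    n_genes_total = length(unique(pairs$gene_symbol))
  )
}
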