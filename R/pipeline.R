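# End-to-end orchestration: one reproducible run of
# preprocess -> differential expression -> integration -> enrichment,
# with a machine-readable manifest and a human-readable summary.

#' Default pipeline configuration
#'
#' All thresholds of the analysis in one place. Any element can be
#' overridden; [run_pipeline()] also accepts a YAML file with the same keys.
#'
#' @param ... named overrides of the defaults.
#' @return A named list: `detection_alpha` (0.05), `min_detected` (3),
#'   `loess_span` (0.4), `loess_iterations` (3), `fdr_cutoff` (0.10),
#'   `fold_cutoff` (1.5), `fdr_scope` ("pooled"), `percentile_cutoff` (50),
#'   `mrna_q_cutoff` (0.1), `ease_alpha` (0.05), `min_overlap` (2),
#'   `promiscuity_threshold` (5), `redundancy_threshold` (3),
#'   `enrich_partition` ("combined", or "up"/"down" to enrich only the
#'   genes of one pairing partition), `skip_detection_filter` (FALSE),
#'   `skip_loess` (FALSE).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    detection_alpha = 0.05,
    min_detected = 3,
    loess_span = 0.4,
    loess_iterations = 3,
    fdr_cutoff = 0.10,
    fold_cutoff = 1.5,
    fdr_scope = "pooled",
    percentile_cutoff = 50,
    mrna_q_cutoff = 0.1,
    ease_alpha = 0.05,
    min_overlap = 2,
    promiscuity_threshold = 5,
    redundancy_threshold = 3,
    enrich_partition = "combined",
    skip_detection_filter = FALSE,
    skip_loess = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    abort_validation(sprintf("unknown configuration key(s): %s",
                             paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  cfg
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full integration pipeline
#'
#' Executes preprocessing (detection filter, loess normalization, log2),
#' differential expression (ANOVA contrasts, BH FDR, fold calling),
#' dual-database target consensus, anti-correlated miRNA:mRNA pairing with
#' network summaries, and EASE pathway enrichment, writing every stage's
#' table plus a manifest and a run summary to `out_dir`. Re-running with
#' identical inputs and config yields byte-identical outputs.
#'
#' @param expression an [expression_matrix()], or a path to its TSV.
#' @param design a [study_design()] or path.
#' @param mrna_de a [mrna_de_table()] or path.
#' @param targets_a,targets_b [target_table()]s (DB_A / DB_B) or paths.
#' @param pathways a [pathway_db()] or GMT path.
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()] list or a YAML path.
#' @param detection optional detection p-value TSV path (when `expression`
#'   is a path).
#' @return Invisibly, a list with every in-memory stage result
#'   (`normalized`, `de`, `regulated`, `consensus`, `pairs`, `network`,
#'   `partitions`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(expression, design, mrna_de, targets_a, targets_b,
                         pathways, out_dir, config = pipeline_config(),
                         detection = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.character(expression)) expression <- read_expression(expression, detection)
  if (is.character(design)) design <- read_design(design)
  if (is.character(mrna_de)) mrna_de <- read_mrna_de(mrna_de)
  if (is.character(targets_a)) targets_a <- read_targets(targets_a, "DB_A")
  if (is.character(targets_b)) targets_b <- read_targets(targets_b, "DB_B")
  if (is.character(pathways)) pathways <- read_gmt(pathways)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "stretchmir_stage_error", stage = name)
    })
  }

  em <- stage("preprocess", {
    em <- expression
    if (!isTRUE(config$skip_detection_filter))
      em <- detection_filter(em, config$detection_alpha, config$min_detected)
    if (!isTRUE(config$skip_loess))
      em <- loess_normalize(em, span = config$loess_span,
                            iterations = config$loess_iterations)
    em
  })
  nm <- stage("preprocess", log2_transform(em))
  norm_df <- data.frame(probe_id = rownames(nm$log2_intensity),
                        nm$log2_intensity, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write_table(norm_df, p("normalized.tsv"))

  de <- stage("de", {
    res <- anova_contrasts(nm, design)
    call_regulated(res, fdr_cutoff = config$fdr_cutoff,
                   fold_cutoff = config$fold_cutoff,
                   fdr_scope = config$fdr_scope)
  })
  write_table(as.data.frame(de), p("de.tsv"))
  regulated <- regulated_features(de)
  write_table(regulated, p("regulated.tsv"))

  pairs_out <- stage("integrate", {
    cts <- consensus_targets(targets_a, targets_b, regulated$feature_id,
                             percentile_cutoff = config$percentile_cutoff)
    pairs <- anticorrelated_pairs(cts, regulated, mrna_de,
                                  mrna_q_cutoff = config$mrna_q_cutoff)
    list(cts = cts, pairs = pairs)
  })
  pairs <- pairs_out$pairs
  write_table(as.data.frame(pairs), p("pairs.tsv"))
  network <- summarize_network(pairs, config$promiscuity_threshold,
                               config$redundancy_threshold)
  count_df <- function(entity, counts) {
    data.frame(entity = rep(entity, length(counts)),
               id = names(counts) %||% character(0),
               count = unname(counts), stringsAsFactors = FALSE)
  }
  net_df <- rbind(count_df("mirna", network$per_mirna_target_count),
                  count_df("gene", network$per_gene_mirna_count))
  write_table(net_df, p("network.tsv"))
  partitions <- partition_counts(pairs)

  enr <- stage("enrich", {
    glist <- switch(config$enrich_partition,
      combined = unique(pairs$gene_symbol),
      up = unique(pairs$gene_symbol[pairs$mirna_direction == "UP"]),
      down = unique(pairs$gene_symbol[pairs$mirna_direction == "DOWN"]),
      abort_validation("enrich_partition must be 'combined', 'up' or 'down'")
    )
    background <- mrna_de$gene_symbol[mrna_de$q_value <= config$mrna_q_cutoff]
    enrich_pathways(glist, background, pathways,
                    alpha = config$ease_alpha, min_overlap = config$min_overlap)
  })
  write_table(as.data.frame(enr), p("enrichment.tsv"))

  manifest <- list(
    package = "stretchmiR",
    version = as.character(utils::packageVersion("stretchmiR")),
    parameters = config,
    counts = list(
      probes_in = nrow(expression$intensity),
      probes_after_filter = nrow(nm$log2_intensity),
      de_rows = nrow(de),
      regulated_mirnas = nrow(regulated),
      regulated_up = sum(regulated$direction == "UP"),
      regulated_down = sum(regulated$direction == "DOWN"),
      consensus_edges = nrow(pairs_out$cts),
      pairs = nrow(pairs),
      genes_down_of_up = partitions$n_genes_down_of_up,
      genes_up_of_down = partitions$n_genes_up_of_down,
      genes_total = partitions$n_genes_total,
      promiscuous_mirnas = length(network$promiscuous_mirnas),
      redundant_genes = length(network$redundant_genes),
      significant_terms = sum(enr$significant)
    )
  )
  jsonlite::write_json(manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summary_lines <- c(
    "stretchmiR pipeline summary",
    sprintf("probes: %d in, %d after detection filter",
            manifest$counts$probes_in, manifest$counts$probes_after_filter),
    sprintf("regulated miRNAs: %d (%d up, %d down) at q <= %.2g and fold >= %.2g",
            manifest$counts$regulated_mirnas, manifest$counts$regulated_up,
            manifest$counts$regulated_down, config$fdr_cutoff, config$fold_cutoff),
    sprintf("anti-correlated pairs: %d covering %d genes (%d down-genes of up-miRNAs + %d up-genes of down-miRNAs)",
            manifest$counts$pairs, manifest$counts$genes_total,
            manifest$counts$genes_down_of_up, manifest$counts$genes_up_of_down),
    sprintf("promiscuous miRNAs (> %d targets): %d; redundant genes (>= %d miRNAs): %d",
            config$promiscuity_threshold, manifest$counts$promiscuous_mirnas,
            config$redundancy_threshold, manifest$counts$redundant_genes),
    sprintf("pathway terms with EASE < %.2g: %d",
            config$ease_alpha, manifest$counts$significant_terms)
  )
  writeLines(summary_lines, p("summary.txt"))

  invisible(list(
    normalized = nm, de = de, regulated = regulated, consensus = pairs_out$cts,
    pairs = pairs, network = network, partitions = partitions,
    enrichment = enr, manifest = manifest
  ))
}

#' Run the pipeline on a fixture directory
#'
#' Convenience wrapper: reads a [write_fixture()]-style directory and calls
#' [run_pipeline()].
#'
#' @param fixture_dir directory holding the fixture files.
#' @param out_dir output directory.
#' @param config a [pipeline_config()] or YAML path.
#' @return Invisibly, the [run_pipeline()] result list.
#' @export
run_pipeline_dir <- function(fixture_dir, out_dir, config = pipeline_config()) {
  b <- read_fixture(fixture_dir)
  run_pipeline(b$expression, b$design, b$mrna_de, b$targets_a, b$targets_b,
               b$pathways, out_dir, config = config)
}
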