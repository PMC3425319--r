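# Synthetic-data generator with planted truth. Emulates all four pipeline
# inputs — probe intensities + detection p-values, study design, a parallel
# mRNA DE table, two target-prediction databases, pathway gene sets — under
# the statistical structure the analysis assumes, so every stage can be
# checked against known ground truth.

#' Simulation configuration
#'
#' Defaults mirror the cyclic-stretch study design: 3 groups (control,
#' 1 h and 6 h of 25% delta-SA stretch) x 4 animals, ~1300 detected probes,
#' 34 up- and 8 down-regulated miRNAs with log2 effects in \[1.0, 1.6\]
#' (folds 2.0-3.0, matching the reported 1.5-2.9 range), Gaussian noise of
#' 0.25 log2 units, and a duration effect: all planted miRNAs respond at
#' 6 h, a single one already at 1 h.
#'
#' @param n_probes total probes on the array.
#' @param n_per_group samples (animals) per group.
#' @param n_true_up,n_true_down numbers of truly up-/down-regulated miRNAs
#'   (at 6 h).
#' @param n_s1_active how many of the true-up miRNAs are already regulated
#'   at 1 h.
#' @param effect_log2 range (low, high) of absolute planted log2 effects.
#' @param noise_sd within-group Gaussian noise SD on the log2 scale.
#' @param baseline_log2_range range of expressed-probe baseline log2
#'   intensities.
#' @param frac_absent fraction of probes that are truly absent (background
#'   intensity; detection p ~ Uniform(0, 1)).
#' @param detected_p_max expressed probes draw detection p ~ Uniform(0, this).
#' @param n_genes size of the mRNA gene universe.
#' @param targets_per_true_mirna range of planted target counts per true
#'   miRNA.
#' @param n_target_pool_down,n_target_pool_up sizes of the gene pools that
#'   planted targets of up-/down-regulated miRNAs are drawn from (shared
#'   pools create gene-level redundancy).
#' @param db_sensitivity probability that each database independently
#'   contains a planted edge.
#' @param db_decoy_rate decoy edges per database, as a fraction of the
#'   planted edge count.
#' @param mrna_de_fraction fraction of non-target genes that are
#'   differentially expressed anyway (q <= 0.1, random sign) — decoys for
#'   the anti-correlation filter.
#' @param n_pathways number of pathway terms.
#' @param pathway_size_range size range of the random terms.
#' @param planted_term_size size of the planted enriched term.
#' @param planted_term_frac fraction of the planted term drawn from planted
#'   targets of up-regulated miRNAs (the enrichment signal strength).
#' @param seed master seed; per-artifact sub-seeds are derived from it, so
#'   adding artifacts never perturbs existing ones (Mersenne-Twister
#'   throughout).
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(n_probes = 1300,
                       n_per_group = 4,
                       n_true_up = 34,
                       n_true_down = 8,
                       n_s1_active = 1,
                       effect_log2 = c(1.0, 1.6),
                       noise_sd = 0.25,
                       baseline_log2_range = c(6, 12),
                       frac_absent = 0.15,
                       detected_p_max = 0.01,
                       n_genes = 2000,
                       targets_per_true_mirna = c(3, 8),
                       n_target_pool_down = 150,
                       n_target_pool_up = 40,
                       db_sensitivity = 0.9,
                       db_decoy_rate = 0.1,
                       mrna_de_fraction = 0.3,
                       n_pathways = 20,
                       pathway_size_range = c(10, 40),
                       planted_term_size = 30,
                       planted_term_frac = 0.6,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(frac_absent, db_sensitivity, db_decoy_rate, mrna_de_fraction,
             planted_term_frac, detected_p_max)
  if (any(probs < 0 | probs > 1))
    abort_validation("all probabilities/fractions must lie in [0, 1]")
  if (n_true_up + n_true_down > n_probes)
    abort_validation("more true probes requested than probes")
  if (n_s1_active > n_true_up)
    abort_validation("n_s1_active cannot exceed n_true_up")
  n_expressed <- n_probes - floor(frac_absent * n_probes)
  if (n_true_up + n_true_down > n_expressed)
    abort_validation("true probes must fit among the expressed probes")
  if (max(targets_per_true_mirna) > min(n_target_pool_down, n_target_pool_up))
    abort_validation("more targets per miRNA requested than the target gene pools hold")
  if (n_target_pool_down + n_target_pool_up > n_genes)
    abort_validation("target gene pools exceed the gene universe")
  if (planted_term_size > n_genes || max(pathway_size_range) > n_genes)
    abort_validation("pathway sizes exceed the gene universe")
  if (noise_sd < 0) abort_validation("noise_sd must be >= 0")
  cfg$seed <- as.integer(seed)
  class(cfg) <- c("SimConfig", "list")
  cfg
}

# deterministic per-artifact sub-seed (Lehmer step on the master seed);
# stays below 2^31 - 1
sub_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 48271 + k * 9973 + 12345) %% 2147483647)
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

# sample one integer uniformly from [lo, hi] (safe when lo == hi)
sample_int_range <- function(lo, hi) {
  if (lo == hi) return(lo)
  sample(seq(lo, hi), 1)
}

#' Simulate a full experiment with planted truth
#'
#' Generates every pipeline input plus the ground truth: per probe and
#' sample, log2 intensity = baseline + group effect + Normal(0, noise_sd);
#' effects are nonzero only for planted probes in the stretch groups (all at
#' 6 h, a configurable subset already at 1 h). Planted target genes receive
#' mRNA log2 fold changes of sign opposite to their regulating miRNA with
#' q <= 0.1; each planted miRNA:gene edge enters each prediction database
#' independently with probability `db_sensitivity` (context percentile drawn
#' >= 50 for planted DB_A edges, Uniform(0, 100) for decoys); one pathway
#' term is over-populated with planted target genes.
#'
#' Fully reproducible: the same config (including its seed) yields identical
#' output.
#'
#' @param cfg a [sim_config()].
#' @return A list (`SimBundle`): `expression` ([expression_matrix()] with
#'   detection p-values), `design` ([study_design()]), `mrna_de`
#'   ([mrna_de_table()]), `targets_a`, `targets_b` ([target_table()]),
#'   `pathways` ([pathway_db()]), and `truth` (a `SimTruth` list with
#'   `true_up`, `true_down`, `effects_s6`, `effects_s1`, `absent_probes`,
#'   `planted_pairs`, `gene_effects`, `planted_term`).
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  groups <- c("CONTROL", "S1", "S6")
  n_samp <- 3 * cfg$n_per_group
  probe_id <- sprintf("rno-miR-sim-%04d", seq_len(cfg$n_probes))
  gene_id <- sprintf("GENE%04d", seq_len(cfg$n_genes))

  design <- study_design(
    sample_id = sprintf("%s_%d", rep(groups, each = cfg$n_per_group),
                        rep(seq_len(cfg$n_per_group), 3)),
    group = rep(groups, each = cfg$n_per_group),
    animal_id = sprintf("animal_%d", rep(seq_len(cfg$n_per_group), 3))
  )

  # --- truth: which probes are absent, which carry effects, and how big ---
  set.seed(sub_seed(cfg$seed, 1))
  n_absent <- floor(cfg$frac_absent * cfg$n_probes)
  absent <- sort(sample(cfg$n_probes, n_absent))
  expressed <- setdiff(seq_len(cfg$n_probes), absent)
  true_idx <- sample(expressed, cfg$n_true_up + cfg$n_true_down)
  up_idx <- sort(true_idx[seq_len(cfg$n_true_up)])
  down_idx <- sort(true_idx[cfg$n_true_up + seq_len(cfg$n_true_down)])
  eff_mag_up <- runif_range(cfg$n_true_up, cfg$effect_log2)
  eff_mag_down <- runif_range(cfg$n_true_down, cfg$effect_log2)
  effects_s6 <- numeric(cfg$n_probes)
  effects_s6[up_idx] <- eff_mag_up
  effects_s6[down_idx] <- -eff_mag_down
  s1_active <- if (cfg$n_s1_active > 0) sort(sample(up_idx, cfg$n_s1_active)) else integer(0)
  effects_s1 <- numeric(cfg$n_probes)
  effects_s1[s1_active] <- effects_s6[s1_active]

  # --- intensities and detection p-values ---
  set.seed(sub_seed(cfg$seed, 2))
  baseline <- numeric(cfg$n_probes)
  baseline[expressed] <- runif_range(length(expressed), cfg$baseline_log2_range)
  baseline[absent] <- stats::runif(n_absent, 2, 4)   # background-level signal
  effect_by_group <- cbind(CONTROL = numeric(cfg$n_probes),
                           S1 = effects_s1, S6 = effects_s6)
  mu <- baseline + effect_by_group[, as.character(design$group), drop = FALSE]
  noise <- matrix(stats::rnorm(cfg$n_probes * n_samp, sd = cfg$noise_sd),
                  cfg$n_probes, n_samp)
  lg <- mu + noise
  intensity <- 2^lg
  detection <- matrix(NA_real_, cfg$n_probes, n_samp)
  detection[expressed, ] <- stats::runif(length(expressed) * n_samp,
                                         0, cfg$detected_p_max)
  detection[absent, ] <- stats::runif(n_absent * n_samp)
  dimnames(intensity) <- dimnames(detection) <- list(probe_id, design$sample_id)
  em <- expression_matrix(intensity, detection)

  # --- planted miRNA:gene pairs ---
  set.seed(sub_seed(cfg$seed, 3))
  pool_down <- sample(gene_id, cfg$n_target_pool_down)            # targets of UP miRNAs
  pool_up <- sample(setdiff(gene_id, pool_down), cfg$n_target_pool_up)  # targets of DOWN miRNAs
  plant_edges <- function(mirnas, pool) {
    if (!length(mirnas))
      return(data.frame(mirna_id = character(0), gene_symbol = character(0),
                        stringsAsFactors = FALSE))
    do.call(rbind, lapply(mirnas, function(m) {
      k <- sample_int_range(cfg$targets_per_true_mirna[1], cfg$targets_per_true_mirna[2])
      data.frame(mirna_id = m, gene_symbol = sample(pool, k),
                 stringsAsFactors = FALSE)
    }))
  }
  pairs_up <- plant_edges(probe_id[up_idx], pool_down)
  pairs_down <- plant_edges(probe_id[down_idx], pool_up)
  planted_pairs <- rbind(pairs_up, pairs_down)
  planted_pairs <- planted_pairs[order(planted_pairs$mirna_id, planted_pairs$gene_symbol), ]
  rownames(planted_pairs) <- NULL

  # --- mRNA DE table ---
  set.seed(sub_seed(cfg$seed, 4))
  target_down <- unique(pairs_up$gene_symbol)   # repressed by up miRNAs
  target_up <- unique(pairs_down$gene_symbol)   # released by down miRNAs
  gene_lfc <- stats::rnorm(cfg$n_genes, 0, 0.2)
  gene_q <- stats::runif(cfg$n_genes, 0.1, 1)
  names(gene_lfc) <- names(gene_q) <- gene_id
  rest <- setdiff(gene_id, c(target_down, target_up))
  de_decoys <- sample(rest, round(cfg$mrna_de_fraction * length(rest)))
  gene_lfc[de_decoys] <- sample(c(-1, 1), length(de_decoys), replace = TRUE) *
    stats::runif(length(de_decoys), 0.5, 2)
  gene_q[de_decoys] <- stats::runif(length(de_decoys), 0, 0.1)
  gene_lfc[target_down] <- -stats::runif(length(target_down), 0.5, 2)
  gene_lfc[target_up] <- stats::runif(length(target_up), 0.5, 2)
  gene_q[c(target_down, target_up)] <- stats::runif(
    length(target_down) + length(target_up), 0, 0.1)
  mrna_de <- mrna_de_table(gene_id, unname(gene_lfc[gene_id]), unname(gene_q[gene_id]))

  # --- prediction databases ---
  set.seed(sub_seed(cfg$seed, 5))
  n_edges <- nrow(planted_pairs)
  in_a <- stats::runif(n_edges) <= cfg$db_sensitivity
  in_b <- stats::runif(n_edges) <= cfg$db_sensitivity
  decoy_pool <- function(n) {
    if (n == 0) return(planted_pairs[0, ])
    d <- data.frame(
      mirna_id = sample(probe_id, 3 * n, replace = TRUE),
      gene_symbol = sample(gene_id, 3 * n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    key <- paste(d$mirna_id, d$gene_symbol)
    pk <- paste(planted_pairs$mirna_id, planted_pairs$gene_symbol)
    d <- d[!duplicated(key) & !(key %in% pk), , drop = FALSE]
    utils::head(d, n)
  }
  n_decoy <- round(cfg$db_decoy_rate * n_edges)
  dec_a <- decoy_pool(n_decoy)
  dec_b <- decoy_pool(n_decoy)
  a_edges <- rbind(planted_pairs[in_a, , drop = FALSE], dec_a)
  b_edges <- rbind(planted_pairs[in_b, , drop = FALSE], dec_b)
  targets_a <- target_table(
    a_edges$mirna_id, a_edges$gene_symbol, "DB_A",
    context_percentile = c(stats::runif(sum(in_a), 50, 100),
                           stats::runif(nrow(dec_a), 0, 100))
  )
  targets_b <- target_table(b_edges$mirna_id, b_edges$gene_symbol, "DB_B")

  # --- pathway sets with one planted enriched term ---
  set.seed(sub_seed(cfg$seed, 6))
  term_id <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  planted_term <- sample(term_id, 1)
  genes <- lapply(term_id, function(tid) {
    if (tid == planted_term) {
      n_sig <- min(round(cfg$planted_term_frac * cfg$planted_term_size),
                   length(target_down))
      sig <- sample(target_down, n_sig)
      bg <- sample(setdiff(gene_id, sig), cfg$planted_term_size - n_sig)
      sort(c(sig, bg))
    } else {
      sz <- sample_int_range(cfg$pathway_size_range[1], cfg$pathway_size_range[2])
      sort(sample(gene_id, sz))
    }
  })
  pathways <- pathway_db(term_id, paste0("simulated pathway ", term_id), genes)

  truth <- structure(list(
    true_up = probe_id[up_idx],
    true_down = probe_id[down_idx],
    effects_s6 = stats::setNames(effects_s6, probe_id),
    effects_s1 = stats::setNames(effects_s1, probe_id),
    absent_probes = probe_id[absent],
    planted_pairs = planted_pairs,
    gene_effects = gene_lfc,
    planted_term = planted_term
  ), class = "SimTruth")

  structure(list(
    expression = em, design = design, mrna_de = mrna_de,
    targets_a = targets_a, targets_b = targets_b,
    pathways = pathways, truth = truth, config = cfg
  ), class = "SimBundle")
}

#' Write a simulated bundle to a fixture directory
#'
#' Emits every pipeline input in its on-disk dialect (`expression.tsv`,
#' `detection.tsv`, `design.tsv`, `mrna_de.tsv`, `targets_db_a.tsv`,
#' `targets_db_b.tsv`, `pathways.gmt`) plus the ground truth
#' (`truth.json`).
#'
#' @param bundle a `SimBundle` from [simulate_experiment()].
#' @param dir destination directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "SimBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression(bundle$expression, p("expression.tsv"), p("detection.tsv"))
  write_table(as.data.frame(unclass(bundle$design), stringsAsFactors = FALSE),
              p("design.tsv"))
  write_table(as.data.frame(bundle$mrna_de), p("mrna_de.tsv"))
  ta <- as.data.frame(bundle$targets_a)[, c("mirna_id", "gene_symbol", "context_percentile")]
  write_table(ta, p("targets_db_a.tsv"))
  tb <- as.data.frame(bundle$targets_b)[, c("mirna_id", "gene_symbol")]
  write_table(tb, p("targets_db_b.tsv"))
  write_gmt(bundle$pathways, p("pathways.gmt"))
  truth <- bundle$truth
  jsonlite::write_json(list(
    true_up = truth$true_up,
    true_down = truth$true_down,
    effects_s6 = as.list(truth$effects_s6[truth$effects_s6 != 0]),
    effects_s1 = as.list(truth$effects_s1[truth$effects_s1 != 0]),
    absent_probes = truth$absent_probes,
    planted_pairs = truth$planted_pairs,
    gene_effects = as.list(truth$gene_effects),
    planted_term = truth$planted_term
  ), p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture directory back into memory
#'
#' Inverse of [write_fixture()] (the `truth` component is reconstructed from
#' `truth.json`; it is `NULL` when that file is absent).
#'
#' @param dir fixture directory.
#' @return A `SimBundle`-shaped list (without `config`).
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  truth <- NULL
  if (file.exists(p("truth.json"))) {
    tj <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
    pp <- as.data.frame(tj$planted_pairs, stringsAsFactors = FALSE)
    pp <- pp[order(pp$mirna_id, pp$gene_symbol), ]
    rownames(pp) <- NULL
    truth <- structure(list(
      true_up = tj$true_up, true_down = tj$true_down,
      effects_s6 = unlist(tj$effects_s6), effects_s1 = unlist(tj$effects_s1),
      absent_probes = tj$absent_probes,
      planted_pairs = pp,
      gene_effects = unlist(tj$gene_effects),
      planted_term = tj$planted_term
    ), class = "SimTruth")
  }
  structure(list(
    expression = read_expression(p("expression.tsv"), p("detection.tsv")),
    design = read_design(p("design.tsv")),
    mrna_de = read_mrna_de(p("mrna_de.tsv")),
    targets_a = read_targets(p("targets_db_a.tsv"), "DB_A"),
    targets_b = read_targets(p("targets_db_b.tsv"), "DB_B"),
    pathways = read_gmt(p("pathways.gmt")),
    truth = truth
  ), class = "SimBundle")
}
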