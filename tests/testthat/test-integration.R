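toy_dbs <- function() {
  dba <- target_table(
    c("m1", "m1", "m2", "m3"),
    c("G1", "G2", "G3", "G4"),
    "DB_A", context_percentile = c(50, 80, 49, 90)
  )
  dbb <- target_table(
    c("m1", "m2", "m3"),
    c("G1", "G3", "G5"),
    "DB_B"
  )
  list(a = dba, b = dbb)
}

test_that("consensus requires both databases and the inclusive percentile cutoff", {
  db <- toy_dbs()
  cts <- consensus_targets(db$a, db$b, c("m1", "m2", "m3"))
  # hand enumeration: (m1,G1) at exactly 50 and in DB_B -> kept;
  # (m1,G2) absent from DB_B -> dropped; (m2,G3) percentile 49 -> dropped;
  # (m3,G4) not in DB_B, (m3,G5) not in DB_A -> dropped
  expect_identical(nrow(cts), 1L)
  expect_identical(cts$mirna_id, "m1")
  expect_identical(cts$gene_symbol, "G1")

  # monotone non-increasing in the cutoff, and subset of cutoff 0
  all0 <- consensus_targets(db$a, db$b, c("m1", "m2", "m3"), percentile_cutoff = 0)
  expect_true(all(pair_key(cts) %in% pair_key(all0)))
  expect_identical(sort(all0$gene_symbol), c("G1", "G3"))
  # restricting the miRNA set restricts the edges
  only2 <- consensus_targets(db$a, db$b, "m2", percentile_cutoff = 0)
  expect_identical(only2$gene_symbol, "G3")
})

test_that("anti-correlated pairing enforces direction opposition and the mRNA FDR", {
  cts <- consensus_targets(
    target_table(c("up1", "up1", "dn1", "up2"), c("GA", "GB", "GC", "GD"),
                 "DB_A", c(99, 99, 99, 99)),
    target_table(c("up1", "up1", "dn1", "up2"), c("GA", "GB", "GC", "GD"), "DB_B"),
    c("up1", "dn1", "up2")
  )
  reg <- data.frame(feature_id = c("up1", "dn1", "up2"),
                    direction = c("UP", "DOWN", "UP"), stringsAsFactors = FALSE)
  mrna <- mrna_de_table(
    c("GA", "GB", "GC", "GD"),
    log2fc = c(-0.8, 0.8, 1.2, -0.5),
    q_value = c(0.05, 0.05, 0.05, 0.5)
  )
  pairs <- anticorrelated_pairs(cts, reg, mrna, mrna_q_cutoff = 0.1)
  # up1:GA (gene down, q ok) kept; up1:GB gene up -> rejected;
  # dn1:GC gene up -> kept; up2:GD gene down but q = 0.5 -> rejected
  expect_identical(pair_key(pairs), pair_key(data.frame(
    mirna_id = c("dn1", "up1"), gene_symbol = c("GC", "GA"))))
  expect_identical(pairs$mirna_direction, c("DOWN", "UP"))

  # genes at exactly log2fc == 0 are never paired
  mrna0 <- mrna_de_table("GA", 0, 0.01)
  expect_identical(nrow(anticorrelated_pairs(cts, reg, mrna0)), 0L)
})

test_that("pairing is invariant to input row order", {
  set.seed(12)
  b <- simulate_experiment(sim_config(n_probes = 80, n_true_up = 6, n_true_down = 3,
                                      n_genes = 300, n_target_pool_down = 40,
                                      n_target_pool_up = 15,
                                      targets_per_true_mirna = c(2, 4), seed = 12))
  reg <- data.frame(feature_id = c(b$truth$true_up, b$truth$true_down),
                    direction = rep(c("UP", "DOWN"),
                                    c(length(b$truth$true_up), length(b$truth$true_down))),
                    stringsAsFactors = FALSE)
  cts <- consensus_targets(b$targets_a, b$targets_b, reg$feature_id)
  ref <- anticorrelated_pairs(cts, reg, b$mrna_de)
  for (i in 1:3) {
    cts_s <- cts[sample(nrow(cts)), ]
    reg_s <- reg[sample(nrow(reg)), ]
    mrna_s <- b$mrna_de[sample(nrow(b$mrna_de)), ]
    class(mrna_s) <- class(b$mrna_de)
    expect_equal(anticorrelated_pairs(cts_s, reg_s, mrna_s), ref)
  }
})

test_that("network summary counts satisfy the handshake identity and thresholds", {
  empty <- summarize_network(data.frame(mirna_id = character(0),
                                        gene_symbol = character(0),
                                        mirna_direction = character(0)))
  expect_identical(empty$n_pairs, 0L)
  expect_length(empty$promiscuous_mirnas, 0)
  expect_length(empty$redundant_genes, 0)

  # a miRNA with 6 targets is promiscuous ("> 5"); with 5 it is not
  p6 <- data.frame(mirna_id = rep("m6", 6), gene_symbol = paste0("G", 1:6),
                   mirna_direction = "UP", stringsAsFactors = FALSE)
  p5 <- data.frame(mirna_id = rep("m5", 5), gene_symbol = paste0("H", 1:5),
                   mirna_direction = "UP", stringsAsFactors = FALSE)
  expect_identical(summarize_network(p6)$promiscuous_mirnas, "m6")
  expect_length(summarize_network(p5)$promiscuous_mirnas, 0)
  # a gene hit by 3 miRNAs is redundant (">= 3")
  r3 <- data.frame(mirna_id = paste0("m", 1:3), gene_symbol = "GX",
                   mirna_direction = "UP", stringsAsFactors = FALSE)
  expect_identical(summarize_network(r3)$redundant_genes, "GX")

  set.seed(7)
  rnd <- data.frame(
    mirna_id = sample(paste0("m", 1:4), 10, TRUE),
    gene_symbol = sample(paste0("G", 1:6), 10, TRUE),
    mirna_direction = "UP", stringsAsFactors = FALSE
  )
  rnd <- rnd[!duplicated(rnd), ]
  ns <- summarize_network(rnd)
  expect_identical(sum(ns$per_mirna_target_count), nrow(rnd))
  expect_identical(sum(ns$per_gene_mirna_count), nrow(rnd))
})

test_that("gene partitions are disjoint and sum to the distinct-gene total", {
  pairs <- data.frame(
    mirna_id = c("u1", "u1", "u2", "d1"),
    gene_symbol = c("A", "B", "A", "C"),
    mirna_direction = c("UP", "UP", "UP", "DOWN"),
    stringsAsFactors = FALSE
  )
  pc <- partition_counts(pairs)
  expect_identical(pc, list(n_genes_down_of_up = 2L, n_genes_up_of_down = 1L,
                            n_genes_total = 3L))

  # random pair tables: verified against a brute-force set-union oracle
  set.seed(19)
  for (i in 1:20) {
    mirnas <- paste0("m", 1:8)
    dirs <- setNames(sample(c("UP", "DOWN"), 8, TRUE), mirnas)
    genes <- paste0("G", 1:15)
    gsign <- setNames(sample(c("UP", "DOWN"), 15, TRUE), genes)
    m <- sample(mirnas, 25, TRUE)
    g <- sample(genes, 25, TRUE)
    keep <- dirs[m] != gsign[g]      # opposite signs only, as the pairing emits
    df <- unique(data.frame(mirna_id = m[keep], gene_symbol = g[keep],
                            mirna_direction = unname(dirs[m[keep]]),
                            stringsAsFactors = FALSE))
    pc <- partition_counts(df)
    expect_identical(pc$n_genes_total, length(unique(df$gene_symbol)))
    expect_identical(pc$n_genes_down_of_up + pc$n_genes_up_of_down, pc$n_genes_total)
  }
})

test_that("planted pairs are recovered exactly when both databases are complete", {
  cfg <- sim_config(noise_sd = 0, db_sensitivity = 1, db_decoy_rate = 0, seed = 77)
  b <- simulate_experiment(cfg)
  reg <- data.frame(
    feature_id = c(b$truth$true_up, b$truth$true_down),
    direction = rep(c("UP", "DOWN"),
                    c(length(b$truth$true_up), length(b$truth$true_down))),
    stringsAsFactors = FALSE
  )
  cts <- consensus_targets(b$targets_a, b$targets_b, reg$feature_id)
  pairs <- anticorrelated_pairs(cts, reg, b$mrna_de)
  expect_setequal(pair_key(pairs), pair_key(b$truth$planted_pairs))
})
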