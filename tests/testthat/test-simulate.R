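small_cfg <- function(...) {
  sim_config(n_probes = 120, n_true_up = 8, n_true_down = 4, n_genes = 400,
             n_target_pool_down = 50, n_target_pool_up = 20,
             targets_per_true_mirna = c(2, 4), n_pathways = 10,
             pathway_size_range = c(5, 15), planted_term_size = 15, ...)
}

test_that("simulation is deterministic under a fixed seed and seed-sensitive", {
  b1 <- simulate_experiment(small_cfg(seed = 5))
  b2 <- simulate_experiment(small_cfg(seed = 5))
  expect_identical(b1$expression$intensity, b2$expression$intensity)
  expect_identical(b1$mrna_de, b2$mrna_de)
  expect_identical(b1$targets_a, b2$targets_a)
  expect_identical(b1$pathways, b2$pathways)
  expect_identical(b1$truth$planted_pairs, b2$truth$planted_pairs)

  b3 <- simulate_experiment(small_cfg(seed = 6))
  expect_false(identical(b1$expression$intensity, b3$expression$intensity))
})

test_that("truth sets have the configured sizes and signs", {
  b <- simulate_experiment(sim_config(seed = 3))
  expect_length(b$truth$true_up, 34)
  expect_length(b$truth$true_down, 8)
  expect_true(all(b$truth$effects_s6[b$truth$true_up] > 0))
  expect_true(all(b$truth$effects_s6[b$truth$true_down] < 0))
  expect_true(all(abs(b$truth$effects_s6[c(b$truth$true_up, b$truth$true_down)]) >= 1.0))
  expect_true(all(abs(b$truth$effects_s6[c(b$truth$true_up, b$truth$true_down)]) <= 1.6))
  # duration effect: a single miRNA is active already at 1 h, and it is up
  s1 <- names(b$truth$effects_s1)[b$truth$effects_s1 != 0]
  expect_length(s1, 1)
  expect_true(s1 %in% b$truth$true_up)
})

test_that("every planted pair is anti-correlated by construction", {
  for (seed in c(2, 9, 15)) {
    b <- simulate_experiment(small_cfg(seed = seed))
    pp <- b$truth$planted_pairs
    mdir <- ifelse(pp$mirna_id %in% b$truth$true_up, "UP", "DOWN")
    glfc <- b$truth$gene_effects[pp$gene_symbol]
    expect_true(all((mdir == "UP" & glfc < 0) | (mdir == "DOWN" & glfc > 0)))
    # planted target genes pass the mRNA FDR filter
    gq <- b$mrna_de$q_value[match(pp$gene_symbol, b$mrna_de$gene_symbol)]
    expect_true(all(gq <= 0.1))
  }
})

test_that("planted database edges obey the percentile and sensitivity rules", {
  cfg <- small_cfg(seed = 4, db_sensitivity = 1, db_decoy_rate = 0)
  b <- simulate_experiment(cfg)
  # full sensitivity, no decoys: DB_A rows == planted pairs, all percentile >= 50
  expect_setequal(pair_key(b$targets_a), pair_key(b$truth$planted_pairs))
  expect_setequal(pair_key(b$targets_b), pair_key(b$truth$planted_pairs))
  expect_true(all(b$targets_a$context_percentile >= 50))
})

test_that("simulated within-group spread matches the configured noise", {
  b <- simulate_experiment(sim_config(seed = 8, noise_sd = 0.25))
  lg <- log2(b$expression$intensity)
  grp <- b$design$group
  vars <- sapply(levels(grp), function(g) apply(lg[, grp == g, drop = FALSE], 1, var))
  expect_equal(sqrt(mean(vars)), 0.25, tolerance = 0.1)
})

test_that("fixtures round-trip through the on-disk dialects", {
  b <- simulate_experiment(small_cfg(seed = 13))
  tmp <- withr::local_tempdir()
  write_fixture(b, tmp)
  back <- read_fixture(tmp)
  expect_equal(back$expression$intensity, b$expression$intensity, tolerance = 1e-12)
  expect_equal(back$expression$detection_p, b$expression$detection_p, tolerance = 1e-12)
  expect_identical(as.character(back$design$group), as.character(b$design$group))
  expect_equal(as.data.frame(back$mrna_de),
               as.data.frame(b$mrna_de)[order(b$mrna_de$gene_symbol), ],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_setequal(pair_key(back$targets_a), pair_key(b$targets_a))
  expect_setequal(pair_key(back$targets_b), pair_key(b$targets_b))
  expect_identical(back$pathways$term_id, b$pathways$term_id)
  expect_identical(back$pathways$genes, b$pathways$genes)
  expect_identical(back$truth$planted_pairs, b$truth$planted_pairs)
  expect_identical(back$truth$planted_term, b$truth$planted_term)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(sim_config(n_probes = 10, n_true_up = 20), "true probes")
  expect_error(sim_config(targets_per_true_mirna = c(5, 500)), "pool")
  expect_error(sim_config(db_sensitivity = 1.2), "\\[0, 1\\]")
})
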