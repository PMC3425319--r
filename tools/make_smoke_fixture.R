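#!/usr/bin/env Rscript
# Regenerates the shipped smoke fixture (inst/extdata/smoke): a ~50-probe
# simulated experiment small enough for fast end-to-end runs.
library(stretchmiR)
cfg <- sim_config(
  n_probes = 50, n_true_up = 6, n_true_down = 3, n_s1_active = 1,
  n_genes = 200, targets_per_true_mirna = c(2, 4),
  n_target_pool_down = 40, n_target_pool_up = 15,
  n_pathways = 8, pathway_size_range = c(5, 15),
  planted_term_size = 12, planted_term_frac = 0.6,
  seed = 42L
)
write_fixture(simulate_experiment(cfg), "inst/extdata/smoke")
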