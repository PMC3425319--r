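# Shared drivers for the recovery/calibration studies: simulate, preprocess
# (detection filter + loess + log2) and call regulated miRNAs.

run_sim_de <- function(cfg) {
  b <- simulate_experiment(cfg)
  em <- detection_filter(b$expression)
  em <- loess_normalize(em)
  nm <- log2_transform(em)
  de <- call_regulated(anova_contrasts(nm, b$design))
  list(bundle = b, de = de, regulated = regulated_features(de))
}

# sensitivity and false-discovery proportion of the regulated call against
# the planted truth
de_confusion <- function(regulated, truth) {
  called <- regulated$feature_id
  true_set <- c(truth$true_up, truth$true_down)
  tp <- sum(called %in% true_set)
  list(
    sensitivity = if (length(true_set)) tp / length(true_set) else NA_real_,
    fdp = if (length(called)) (length(called) - tp) / length(called) else 0
  )
}
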