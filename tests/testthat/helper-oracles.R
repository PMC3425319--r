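# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately re-derive each quantity from its definition, never
# through the code path they check.

# literal Benjamini-Hochberg step-up: sort ascending, q_(i) = min_{j>=i}
# p_(j) * n / j clipped at 1, mapped back to the input order
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- q
  out
}

# hypergeometric upper tail by direct term-by-term summation of binomial
# coefficients (no distribution-function call)
fisher_oracle <- function(a, n_draw, K, N) {
  xs <- a:min(n_draw, K)
  if (a > min(n_draw, K)) return(0)
  sum(choose(K, xs) * choose(N - K, n_draw - xs)) / choose(N, n_draw)
}

# two-array fixture with a known smooth intensity-dependent distortion on
# the second array (for the loess-correction checks)
make_distorted_fixture <- function(n = 500, seed = 5, amp = 0.3, noise = 0.05) {
  set.seed(seed)
  base <- sort(stats::runif(n, 6, 12))
  lg1 <- base + stats::rnorm(n, sd = noise)
  g <- function(x) amp * sin(2 * pi * (x - 6) / 6)
  lg2 <- base + g(base) + stats::rnorm(n, sd = noise)
  x <- cbind(array1 = 2^lg1, array2 = 2^lg2)
  rownames(x) <- sprintf("probe%04d", seq_len(n))
  expression_matrix(x)
}

# hand-built 3-group x 4-sample log2 matrix wrapped as a NormalizedMatrix
make_norm_matrix <- function(values) {
  stopifnot(ncol(values) == 12)
  colnames(values) <- sprintf("%s_%d", rep(c("CONTROL", "S1", "S6"), each = 4),
                              rep(1:4, 3))
  if (is.null(rownames(values))) rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  structure(list(log2_intensity = values, provenance = list()),
            class = "NormalizedMatrix")
}

make_design_12 <- function() {
  study_design(
    sample_id = sprintf("%s_%d", rep(c("CONTROL", "S1", "S6"), each = 4), rep(1:4, 3)),
    group = rep(c("CONTROL", "S1", "S6"), each = 4),
    animal_id = rep(sprintf("a%d", 1:4), 3)
  )
}

smoke_dir <- function() {
  d <- system.file("extdata", "smoke", package = "stretchmiR")
  stopifnot(nzchar(d))
  d
}

pair_key <- function(df) paste(df$mirna_id, df$gene_symbol, sep = "\r")

# planted pairs that the pipeline can possibly recover under given DB
# tables: used for truth comparisons where db_sensitivity < 1
recoverable_pairs <- function(truth, targets_a, targets_b, cutoff = 50) {
  pk <- pair_key(truth$planted_pairs)
  ka <- pair_key(targets_a[targets_a$context_percentile >= cutoff, ])
  kb <- pair_key(targets_b)
  truth$planted_pairs[pk %in% ka & pk %in% kb, , drop = FALSE]
}
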