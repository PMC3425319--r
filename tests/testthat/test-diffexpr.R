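test_that("contrast statistics match a per-feature linear-model oracle", {
  set.seed(21)
  vals <- rbind(
    flat = rep(5, 12),                          # null feature
    planted = c(rep(8, 4), rep(8, 4), rep(9, 4)) + c(rep(0, 8), rep(0, 4)),
    noisy1 = rnorm(12, 7, 0.4),
    noisy2 = rnorm(12, 10, 0.2),
    shift = c(rnorm(4, 6, .3), rnorm(4, 6.8, .3), rnorm(4, 5.4, .3))
  )
  nm <- make_norm_matrix(vals)
  des <- make_design_12()
  res <- anova_contrasts(nm, des)

  g <- factor(rep(c("CONTROL", "S1", "S6"), each = 4), levels = c("CONTROL", "S1", "S6"))
  for (f in c("noisy1", "noisy2", "shift")) {   # oracle needs nonzero residual variance
    y <- vals[f, ]
    fit <- lm(y ~ g)
    mse <- summary(fit)$sigma^2
    for (ct in c("S1", "S6")) {
      row <- res[res$feature_id == f & res$contrast == paste0(ct, "_vs_CONTROL"), ]
      diff <- mean(y[g == ct]) - mean(y[g == "CONTROL"])
      tstat <- diff / sqrt(mse * (1/4 + 1/4))
      expect_equal(row$log2fc, diff, tolerance = 1e-12)
      expect_equal(row$df, 9)
      expect_equal(row$p_value, 2 * pt(-abs(tstat), 9), tolerance = 1e-12)
    }
  }

  # identical values in all samples: log2fc 0, p 1, flagged
  flat <- res[res$feature_id == "flat", ]
  expect_true(all(flat$log2fc == 0))
  expect_true(all(flat$p_value == 1))
  expect_true(all(flat$zero_variance))

  # planted noiseless 2-fold increase recovered exactly
  pl <- res[res$feature_id == "planted" & res$contrast == "S6_vs_CONTROL", ]
  expect_identical(pl$log2fc, 1)
})

test_that("BH step-up matches the literal step-up oracle on random vectors", {
  set.seed(31)
  worst <- 0
  for (r in 1:1000) {
    p <- runif(sample(50, 1))
    worst <- max(worst, max(abs(bh_stepup(p) - bh_oracle(p))))
  }
  expect_lte(worst, 1e-15)

  # all 24 orderings of a 4-element vector give order-consistent results
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  perms <- list(); k <- 0
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b)))
    perms[[k <- k + 1]] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  for (pr in perms) {
    expect_equal(bh_stepup(p4[pr]), bh_oracle(p4[pr]), tolerance = 1e-15)
  }
})

test_that("BH step-up agrees with frozen hand-derived examples", {
  # step-up on (0.01, 0.02, 0.03, 0.04): q_(i) = min_j>=i p_(j)*4/j = 0.04 for all
  expect_equal(bh_stepup(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_stepup(0.05), 0.05)
  expect_equal(bh_stepup(rep(0.3, 7)), rep(0.3, 7))
  expect_error(bh_stepup(c(0.2, 1.4)), "0, 1")
  # q is monotone in p
  set.seed(1)
  p <- runif(40)
  q <- bh_stepup(p)
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("signed fold follows the +/- magnitude convention", {
  expect_identical(signed_fold(1), 2)
  expect_identical(signed_fold(-1), -2)
  expect_identical(signed_fold(0), 1)
  expect_equal(signed_fold(0.765), 2^0.765)
  expect_equal(round(abs(signed_fold(-0.765)), 1), 1.7)  # magnitude convention, e.g. -1.7
  expect_true(all(abs(signed_fold(rnorm(50))) >= 1))
  expect_error(signed_fold(Inf), "finite")
})

test_that("regulated calls respect both the FDR and the fold boundary", {
  base <- data.frame(
    feature_id = c("m1", "m2", "m3", "m4"),
    contrast = "S6_vs_CONTROL",
    signed_fold = c(1.6, 1.4, 3.0, -1.5),
    p_value = c(0.001, 0.001, 0.2, 0.001),
    stringsAsFactors = FALSE
  )
  # fix q directly through a single-contrast pooled BH of designed p-values
  out <- call_regulated(base, fdr_cutoff = 0.10, fold_cutoff = 1.5)
  qs <- out$q_value
  expect_identical(out$direction[out$feature_id == "m1"], "UP")       # q<=.1, fold 1.6
  expect_identical(out$direction[out$feature_id == "m2"], "NONE")     # fold 1.4 < 1.5
  expect_identical(out$direction[out$feature_id == "m3"], "NONE")     # q above cutoff
  expect_identical(out$direction[out$feature_id == "m4"], "DOWN")     # boundary fold -1.5 inclusive
  expect_true(qs[base$feature_id == "m3"] > 0.10)
  expect_true(all(qs >= base$p_value))
})

test_that("regulated set is the union over contrasts and conflicts are dropped", {
  de <- data.frame(
    feature_id = rep(c("m1", "m2", "m3"), 2),
    contrast = rep(c("S1_vs_CONTROL", "S6_vs_CONTROL"), each = 3),
    direction = c("UP", "NONE", "UP", "NONE", "DOWN", "DOWN"),
    stringsAsFactors = FALSE
  )
  expect_warning(reg <- regulated_features(de), "conflicting")
  expect_identical(reg$feature_id, c("m1", "m2"))
  expect_identical(reg$direction, c("UP", "DOWN"))
})
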