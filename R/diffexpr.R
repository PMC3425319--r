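# Differential expression: per-probe one-way ANOVA with pooled-variance
# pairwise contrasts, BH step-up FDR, signed-fold convention, and the
# FDR + fold regulated-feature call.

#' Per-feature one-way ANOVA with pairwise contrasts
#'
#' For every feature a one-way fixed-effects ANOVA is fitted across all
#' design groups; each requested contrast's t statistic is the difference of
#' group means over the pooled-MSE standard error, with the ANOVA residual
#' degrees of freedom (N - k), and a two-sided p-value from the t
#' distribution. Fold changes are differences of group means on the log2
#' scale (geometric-mean ratios of the normalized intensities).
#'
#' Features with zero residual variance are flagged: their p-value is 1 when
#' the contrasted means are equal and the smallest representable double when
#' they differ (the t statistic is infinite).
#'
#' @param nm a `NormalizedMatrix` from [log2_transform()].
#' @param design a [study_design()]; every design sample must be a column of
#'   `nm`, and every contrasted group needs >= 2 samples.
#' @param contrasts list of `c(group, reference)` pairs; default is each
#'   stretch group versus control.
#' @return A data frame with one row per feature x contrast:
#'   `feature_id`, `contrast` (e.g. `"S6_vs_CONTROL"`), `mean_group`,
#'   `mean_ref`, `log2fc`, `signed_fold`, `p_value`, `df`,
#'   `zero_variance`. Per-group means for all groups are attached as the
#'   `"group_means"` attribute.
#' @export
anova_contrasts <- function(nm, design,
                            contrasts = list(c("S1", "CONTROL"), c("S6", "CONTROL"))) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  x <- nm$log2_intensity
  missing <- setdiff(design$sample_id, colnames(x))
  if (length(missing))
    abort_validation(sprintf(
      "design sample(s) absent from the matrix: %s", paste(missing, collapse = ", ")
    ))
  x <- x[, design$sample_id, drop = FALSE]
  grp <- droplevels(design$group)
  k <- nlevels(grp)
  n_tot <- ncol(x)
  n_per <- table(grp)
  for (ct in contrasts) {
    for (g in ct) {
      if (!g %in% levels(grp))
        abort_validation(sprintf("contrast group '%s' not present in the design", g))
      if (n_per[[g]] < 2)
        abort_validation(sprintf("group '%s' has fewer than 2 samples", g))
    }
  }
  # vectorized one-way ANOVA: group means and pooled residual variance
  gm <- vapply(levels(grp), function(g)
    rowMeans(x[, grp == g, drop = FALSE]), numeric(nrow(x)))
  resid <- x - gm[, as.character(grp), drop = FALSE]
  df_resid <- n_tot - k
  mse <- rowSums(resid^2) / df_resid
  zero_var <- mse <= .Machine$double.eps * rowMeans(x^2 + 1)

  res <- lapply(contrasts, function(ct) {
    g1 <- ct[[1]]; g0 <- ct[[2]]
    diff <- gm[, g1] - gm[, g0]
    se <- sqrt(mse * (1 / n_per[[g1]] + 1 / n_per[[g0]]))
    tt <- diff / se
    p <- 2 * stats::pt(-abs(tt), df_resid)
    p[zero_var] <- ifelse(diff[zero_var] == 0, 1, .Machine$double.xmin)
    data.frame(
      feature_id = rownames(x),
      contrast = paste0(g1, "_vs_", g0),
      mean_group = unname(gm[, g1]),
      mean_ref = unname(gm[, g0]),
      log2fc = unname(diff),
      signed_fold = signed_fold(unname(diff)),
      p_value = unname(p),
      df = df_resid,
      zero_variance = unname(zero_var),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "group_means") <- gm
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' The step-up adjustment: with p-values sorted ascending,
#' q_(i) = min over j >= i of p_(j) * n / j, clipped at 1, returned in the
#' original order (ties handled stably). Computed via
#' [stats::p.adjust()] with `method = "BH"` after range validation.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_stepup <- function(p) {
  if (!is.numeric(p)) abort_validation("p-values must be numeric")
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    abort_validation("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Signed fold change from a log2 fold change
#'
#' The microarray reporting convention: `2^log2fc` for increases and
#' `-2^(-log2fc)` for decreases, so a halving prints as -2.0 and
#' `|signed_fold| >= 1` always.
#'
#' @param log2fc numeric vector of finite log2 fold changes.
#' @return Numeric vector of signed folds.
#' @export
signed_fold <- function(log2fc) {
  if (any(!is.finite(log2fc)))
    abort_validation("log2 fold changes must be finite")
  ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc))
}

#' Call regulated features at an FDR and fold-change cutoff
#'
#' Adds BH q-values and a per-row `direction` call to an
#' [anova_contrasts()] result: `UP` when `q <= fdr_cutoff` and
#' `signed_fold >= fold_cutoff`, `DOWN` when `q <= fdr_cutoff` and
#' `signed_fold <= -fold_cutoff`, else `NONE`. A feature is *regulated* when
#' it has a non-`NONE` direction in at least one contrast
#' (see [regulated_features()]).
#'
#' By default the BH adjustment is pooled over all contrast p-values (one
#' 10% FDR over the analysis); `fdr_scope = "per-contrast"` adjusts each
#' contrast's p-values separately instead.
#'
#' @param results a `DEResult` data frame from [anova_contrasts()].
#' @param fdr_cutoff BH q-value threshold (inclusive).
#' @param fold_cutoff minimum absolute signed fold (inclusive: "at least
#'   1.5-fold").
#' @param fdr_scope `"pooled"` or `"per-contrast"`.
#' @return The input with `q_value` and `direction` columns added.
#' @export
call_regulated <- function(results, fdr_cutoff = 0.10, fold_cutoff = 1.5,
                           fdr_scope = c("pooled", "per-contrast")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(is.data.frame(results),
            all(c("p_value", "signed_fold", "contrast") %in% names(results)))
  if (fold_cutoff < 1) abort_validation("fold_cutoff must be >= 1")
  q <- if (fdr_scope == "pooled") {
    bh_stepup(results$p_value)
  } else {
    stats::ave(results$p_value, results$contrast, FUN = bh_stepup)
  }
  direction <- rep("NONE", nrow(results))
  direction[q <= fdr_cutoff & results$signed_fold >= fold_cutoff] <- "UP"
  direction[q <= fdr_cutoff & results$signed_fold <= -fold_cutoff] <- "DOWN"
  out <- results
  out$q_value <- q
  out$direction <- direction
  attr(out, "fdr_cutoff") <- fdr_cutoff
  attr(out, "fold_cutoff") <- fold_cutoff
  attr(out, "fdr_scope") <- fdr_scope
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Regulated features and their directions
#'
#' One row per feature with a non-`NONE` direction in at least one contrast.
#' The per-feature direction is taken from its significant calls; the rare
#' feature called `UP` in one contrast and `DOWN` in another is dropped with
#' a warning (its repression direction is undefined for pairing).
#'
#' @param results output of [call_regulated()].
#' @return Data frame with columns `feature_id`, `direction`.
#' @export
regulated_features <- function(results) {
  stopifnot(is.data.frame(results), "direction" %in% names(results))
  sig <- results[results$direction != "NONE", c("feature_id", "direction")]
  if (!nrow(sig))
    return(data.frame(feature_id = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  dirs <- tapply(sig$direction, sig$feature_id, function(d) unique(d))
  conflicted <- names(dirs)[lengths(dirs) > 1]
  if (length(conflicted)) {
    warning(sprintf(
      "feature(s) with conflicting directions across contrasts dropped: %s",
      paste(conflicted, collapse = ", ")
    ))
    dirs <- dirs[lengths(dirs) == 1]
  }
  out <- data.frame(
    feature_id = names(dirs),
    direction = vapply(dirs, `[[`, "", 1L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$feature_id), , drop = FALSE]
}
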