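---
title: "Methods: miRNA-mRNA anti-correlation integration for cyclic stretch"
author: "stretchmiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-mRNA anti-correlation integration for cyclic stretch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis this package implements

Alveolar epithelial cells subjected to cyclic equibiaxial stretch (25%
change in surface area, mimicking mechanical ventilation) remodel their
transcriptome. stretchmiR implements the integrative analysis for such an
experiment: a one-color miRNA microarray profiled across three groups —
unstretched controls, 1 hour of stretch (S1) and 6 hours of stretch (S6),
four animals per group — is filtered, normalized and tested for
differential expression; the regulated miRNAs are then linked to candidate
messenger-RNA targets through the consensus of two prediction databases;
candidate pairs are kept only when the mRNA moved in the direction opposite
to its miRNA in a parallel mRNA study (the repression-consistent,
"anti-correlated" pairs); and the resulting gene set is tested for pathway
over-representation with the conservative EASE variant of Fisher's exact
test against a custom background.

Every stage is an exported function, [run_pipeline()] chains them, and a
synthetic-data generator with planted truth (`simulate_experiment()`) makes
the whole chain testable without any array data.

## Preprocessing

**Detection filter.** One-color arrays report a per-probe, per-sample
detection p-value (probability that the signal is background). A probe is
kept when `p < alpha` (strict, default 0.05) in at least `min_samples`
samples (default 3 of the 12). The filter is idempotent and
order-preserving; its retained set shrinks as `min_samples` grows and grows
with `alpha`.

**Loess normalization.** Chip-to-chip bias on single-channel arrays is
intensity-dependent and smooth. We remove it with MA-loess against a median
pseudo-reference: `ref` is the per-probe median of log2 intensities across
arrays; for each array the log-ratio `M = log2(x) - log2(ref)` is regressed
on the mean log-intensity `A = (log2(x) + log2(ref))/2` by robust loess
(span 0.4, degree 2, Tukey-biweight "symmetric" family, 3 robustness
iterations, exact `surface = "direct"` evaluation), and the fitted curve is
divided out of the linear intensities. The reference-based single pass was
chosen over cyclic pairwise loess because it is deterministic, standard for
one-color arrays, and directly testable: on a two-array fixture with a
planted smooth distortion the trend amplitude drops by more than 90%, and a
constant scale factor between arrays is removed to below 0.01 log2 units.
The span and iteration count are exposed because no single value is
canonical; 0.4 is a common default that tracks a one-period sinusoidal
distortion across the 6-unit log2 intensity range without chasing noise.

Two degenerate inputs are handled explicitly. When an array is identical to
the reference the correction is skipped entirely, so identical arrays are a
bit-level no-op. When the median absolute deviation of `M` is zero (the
bulk of probes sits at one exact offset — which happens in noise-free
simulated data), the biweight robustness weights are undefined; the only
identifiable bias is then the constant shift, which is divided out, and no
curve is fitted.

**Log2 transform.** Applied after filtering and normalization, matching the
order filter → normalize → log2. Non-positive intensities are rejected with
their probe/sample coordinates.

## Differential expression

Each probe is fitted with a one-way fixed-effects ANOVA across the three
groups; each pairwise contrast against control uses the difference of group
means over the pooled-MSE standard error with the ANOVA residual degrees of
freedom (N − k = 9 for the default design) and a two-sided t p-value. The
pooled (rather than per-pair) variance follows the classical post-hoc
contrast construction; no empirical-Bayes moderation is applied, and no
animal random effect is modeled (the pipeline targets designs where no
array or animal effect is detectable; a moderated or mixed model is a
possible extension, not a default). Fold changes are differences of group
means on the log2 scale — geometric-mean ratios — reported in the signed
convention `2^lfc` / `-2^(-lfc)`, so a halving prints as −2.0.

Probes with zero residual variance are flagged: p = 1 when the contrasted
means are equal, the smallest representable double when they differ.

**FDR scope.** q-values come from the Benjamini–Hochberg step-up
adjustment. By default one adjustment is pooled over all contrast p-values
(a single 10% FDR governing the analysis); `fdr_scope = "per-contrast"`
adjusts each contrast separately. The pooled default is a calibration
choice: under a global null the BH procedure's chance of making any
rejection equals the nominal level (the Simes identity), so pooling keeps
the experiment-wise any-rejection probability at 0.10, whereas two separate
per-contrast adjustments push the union probability toward
1 − 0.9² ≈ 0.19. The suite verifies the pooled calibration empirically
(50 global-null simulations, observed fraction ≤ 0.15).

A miRNA is *regulated* when, in at least one contrast, q ≤ 0.10 **and**
|signed fold| ≥ 1.5 — both boundaries inclusive, reading "at least
1.5-fold" and a "10% cutoff" literally. Both thresholds are parameters of
`call_regulated()`.

## Integration

**Consensus targets.** An edge (miRNA, gene) survives when the
context-scored database predicts it at or above the 50th context percentile
(inclusive) *and* the presence-only database predicts it too. Star
(passenger-strand) miRNAs typically absent from the context-scored
database simply produce no edges; there is no special casing. Mapping array
probe names to database miRNA identifiers is the caller's responsibility —
the package requires pre-mapped identifiers.

**Anti-correlated pairing.** A pair is emitted when the miRNA is regulated,
the edge is in the consensus set, the gene is in the parallel mRNA DE table
with q ≤ 0.1, and the gene's fold sign strictly opposes the miRNA's
direction. Genes with a log2 fold change of exactly 0 are never paired.
Only the mRNA FDR condition is applied on the gene side (no additional
fold-change filter), because the gene list plays the role of "everything
that moved" — the same set later serves as the enrichment background.
Because a gene's sign is unique, the genes paired with up-miRNAs and those
paired with down-miRNAs are provably disjoint and sum to the distinct-gene
total; `partition_counts()` asserts rather than assumes this.

**Network summaries.** "Promiscuous" miRNAs target strictly more than 5
genes (the definitional threshold; reporting views at higher cutoffs, e.g.
"more than 25", are a presentation choice and the threshold is a
parameter). "Redundant" genes are matched by at least 3 regulated miRNAs.
The per-miRNA and per-gene counts satisfy the handshake identity (both sum
to the number of pairs).

## Enrichment

For each pathway, genes are first intersected with the background (the
custom-background convention), giving a 2×2 table of list hits `a`, list
size `n`, pathway-in-background size `K`, background size `N`. The
one-sided Fisher p-value is the hypergeometric upper tail P(X ≥ a),
computed in log space via `phyper`. The EASE score removes one gene from
the overlap first — `fisher(max(a − 1, 0), n, K, N)` — so a single-gene
overlap can never be significant and EASE ≥ Fisher always. Terms need at
least 2 list hits to be reported (a = 1 is forced to p = 1 by the jackknife
anyway), results are sorted by EASE score with ties broken by term id, and
significance is the raw EASE score < 0.05: no multiple-testing correction
is applied by default because the EASE convention reports raw scores, but
`adjust = TRUE` adds BH q-values. Enrichment can be run on the combined
pair-gene list or on either direction partition alone
(`enrich_partition`).

## The synthetic-data generator

`simulate_experiment()` plants a complete truth and emits every input the
pipeline reads. Its defaults *are* the study conditions: 1300 probes
(roughly the detected-probe count after filtering a genome-wide rodent
miRNA panel), 3 × 4 samples, 34 up- and 8 down-regulated miRNAs at 6 hours
with |log2 effect| uniform on [1.0, 1.6] (folds 2.0–3.0, the magnitude
range such stretch experiments report), exactly one of the up-miRNAs
already active at 1 hour (the duration effect), Gaussian noise of 0.25
log2 units (a typical within-group array SD), and 15% truly-absent probes
whose detection p-values are uniform. Planted target genes receive mRNA
fold changes of opposite sign with q ≤ 0.1; each planted edge enters each
prediction database independently with probability `db_sensitivity`
(default 0.9) with context percentiles drawn ≥ 50, plus decoy edges at 10%
of the planted count with uniform percentiles; 30% of non-target genes are
differentially expressed anyway, exercising the anti-correlation filter;
and one of 20 pathway terms is over-populated with planted target genes
(60% of a 30-gene term). Shared target pools (150 genes for up-miRNA
targets, 40 for down) create the redundancy structure the network summary
measures.

Randomness is R's default Mersenne–Twister with one deterministic sub-seed
per artifact (truth, intensities, mRNA table, databases, pathways), derived
from the master seed by a fixed integer recurrence — so adding an artifact
never perturbs the others, and a fixed config reproduces byte-identical
fixtures.

What the generator does *not* emulate: probe cross-hybridization, spatial
array artifacts, correlated probe noise, non-Gaussian heavy tails,
miRNA-family sequence structure in the databases, or annotation bias in
pathway membership. Passing recovery tests therefore demonstrates that the
pipeline's logic is correct under its own statistical assumptions, not that
those assumptions hold for any particular real array.

## Verification and problem sizes

The suite checks each primitive against an independent oracle: BH against a
literal step-up scan (1000 random vectors, all permutations of 4-element
vectors; agreement to one ulp), the hypergeometric tail against direct
binomial-coefficient summation (every valid table with N ≤ 60, ~1.2 million
tail values, max error ~3e−15), and the ANOVA contrasts against per-feature
`lm()` fits. Recovery studies use 20 simulated experiments at the default
conditions for differential expression (observed sensitivity ≈ 0.96 at
empirical FDR ≈ 0.02) and for enrichment rank recovery, 50 global-null
simulations for calibration, and 20 noise-free runs at database sensitivity
0.8 for the s² pair-recovery law. These sizes give binomial standard errors
comfortably inside the asserted margins while keeping a full run of the
suite to a few minutes. A ~50-probe fixture ships with the package
(`inst/extdata/smoke`) for fast end-to-end runs; it was generated by
`tools/make_smoke_fixture.R` with a fixed seed.

## Known limitations

- The pipeline consumes pre-mapped miRNA identifiers and pre-computed
  prediction tables; it does not re-implement the context-score or seed-match
  algorithms of the underlying databases, and database-version differences
  dominate any attempt to reproduce a specific historical target list.
- The per-contrast t-tests share the pooled MSE, so contrasts are not
  independent; the pooled FDR treats their p-values as one family, which is
  calibrated but slightly conservative under positive dependence.
- Loess normalization assumes most probes are unchanged between arrays;
  with a large fraction of truly regulated probes the median reference
  itself shifts and effects are mildly attenuated.
- The EASE score is reported without multiple-testing correction by
  default, mirroring the convention of functional-annotation tools; treat
  marginal scores accordingly or enable the BH option.
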