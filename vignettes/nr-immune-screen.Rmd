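---
title: "Screening nuclear receptors for tumor-intrinsic immune evasion"
author: "nrscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening nuclear receptors for tumor-intrinsic immune evasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrscreen)
```

## The scientific problem

Nuclear receptors (NRs) are ligand-regulated transcription factors that
act both inside tumor cells and in the immune compartment. In melanoma, a
tumor's responsiveness to immune checkpoint therapy (ICT) tracks with an
IFN-γ response signature — ten genes (IFNG, STAT1, CCR5, CXCL9, CXCL10,
CXCL11, IDO1, PRF1, GZMA and an HLA-DR family member standing in for
"HLA-D") whose joint expression marks immunologically "hot" tumors.
`nrscreen` implements a prioritization cascade that asks, for each of 48
candidate NRs, whether its expression pattern is consistent with a
tumor-intrinsic immune-evasion role:

1. **Signature correlation.** Is the NR's bulk expression correlated
   (Spearman) with the ten signature genes, and in which direction?
2. **Survival.** Do patients in the top expression quartile fare worse
   (or better) than the bottom quartile by Kaplan–Meier / log-rank?
3. **ICT response.** Is the NR expressed more highly in malignant cells
   of nonresponders than responders (Wilcoxon rank-sum on single cells)?
4. **Tumor-intrinsic expression.** Is the NR detected in more than 10% of
   malignant cells, so that a tumor-cell-autonomous mechanism is
   plausible?

An *immune-evasion* candidate must clear all four stages with coherent
directions: negative signature correlation, unfavorable survival, higher
expression in nonresponders, and above-threshold malignant-cell
expression. The mirrored pattern defines a *protective* candidate class,
reported separately. A companion module triages downstream effectors of a
candidate NR from knockout-versus-control differential expression in
three compartments (bulk tumor, sorted tumor cells, cultured cells),
keeping only direction-consistent genes and re-screening them for
signature correlation and survival (z > 2 high-expressor split).

## The statistics kernel

Every screening stage rests on a small self-contained kernel
(`averageRanks`, `rankPercentile`, `spearmanTest`, `wilcoxonRankSum`,
`bhAdjust`, `kmCurve`, `logRank`). Implementing these in one place keeps
the tie and boundary conventions identical across stages, and each is
verified in the test suite against an independent oracle (brute-force
enumeration, hand-computed contingency tables, or the corresponding
base-R / `survival` routine).

* **Ranks.** Ties always receive midranks (the mean of the spanned
  ranks). The rank percentile of a sample is its rank divided by the
  cohort size, a value in (0, 1] invariant under strictly increasing
  transforms of the measurement scale.
* **IFN-γ index.** The index of a sample is the mean of its ten
  signature-gene rank percentiles. Because only ranks enter, the index is
  bit-identical whether the matrix holds z-scores, log-TPM or any other
  monotone re-expression — this invariance is tested at bit level.
* **Spearman.** ρ is the Pearson correlation of the two midrank vectors.
  The default two-sided p uses the t approximation
  `t = ρ√((n−2)/(1−ρ²))` on n − 2 df, appropriate at cohort sizes in the
  hundreds. For n ≤ 7 an exact p is available by enumeration of all n!
  pairings; the cap exists because the enumeration grows factorially.
* **Wilcoxon.** The responder/nonresponder contrast uses the *unpaired*
  rank-sum form: the two patient groups (12 versus 23 in the melanoma
  cohort that motivated the defaults) are independent, so a paired
  signed-rank test would not apply. Exact enumeration of group
  assignments is used for pooled sizes up to 12, the tie-corrected normal
  approximation above that.
* **Kaplan–Meier / log-rank.** The product-limit estimate is taken over
  distinct event times, with events processed before censorings at tied
  times (the Mantel–Cox convention). The log-rank statistic accumulates
  hypergeometric expectations and variances per event time and refers
  (O − E)²/V to χ² with 1 df. With no censoring the KM curve equals
  1 − ECDF exactly, which the tests assert.
* **Benjamini–Hochberg.** The step-up adjustment is applied only where
  the upstream analysis specifies it — differential-expression filtering
  — not across the 48-NR correlation heatmap, which is read at raw p.

## Thresholds and conventions

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | per-pair significance for correlation, survival, response |
| `kMin` | 5 | signature genes that must be significantly concordant |
| `hiCut` / `loCut` | 0.75 / 0.25 | index strata (strict inequalities) |
| `lo` / `hi` | 0.25 / 0.75 | expression quartile cuts (inclusive) |
| `cutoff` | 2.0 | z-score defining "high expressors" |
| `tau` | 10% | malignant-cell percent-expression filter (strict) |
| `fcCut` / `qCut` | 1.5 / 0.05 | DE fold-change (linear scale) and FDR cuts |

Decisions that were genuinely open and how they were settled:

* **Aggregating ten correlations into one direction.** How many of the
  ten signature pairs must be significant is not dictated by the figures
  the screen mirrors; we require at least `kMin = 5` significant pairs of
  one sign and *no* significant pair of the opposite sign. The
  no-conflict condition is what keeps pure-noise genes out; both knobs
  are exposed and recorded in the output metadata.
* **Index strata are read literally.** "> 75% or < 25%" are strict
  inequalities on the index value; boundary samples fall in the excluded
  middle band.
* **Quartile boundaries are inclusive** (low: values ≤ the 25th
  percentile; high: ≥ the 75th), with the linear-interpolation (type 7)
  quantile convention, so heavy ties at a cut all land in the
  corresponding group. The grouping is invariant under monotone
  transforms of expression; the z-score grouping is not (it is invariant
  only to affine maps), which is why the two modes can disagree on
  re-expressed data.
* **Favorable versus unfavorable** is decided by restricted mean survival
  over the common follow-up horizon of the two arms, not by medians,
  which are undefined when more than half of an arm is censored. Medians
  are still reported.
* **Funnel order.** Correlation → survival → response → tumor-intrinsic.
  All stages are computed for all candidates (no short-circuiting), so
  the funnel counts are simple conjunctions and are re-derivable from the
  verdict table — the tests recount them independently.
* **Identifier matching is exact and case-sensitive**; no gene-symbol
  aliasing is attempted.
* **z-scores for the survival split** are computed across the whole
  cohort. Expression z-scores relative to copy-number-diploid samples
  require a copy-number reference that neither the synthetic cohorts nor
  most users' matrices carry.

## What the synthetic cohorts emulate

The generator exists so the whole cascade can be exercised and verified
at desk scale with known ground truth.

**Bulk cohort** (`simulateBulkCohort`). A latent per-sample
immune-activity factor *f* ~ N(0, 1) drives the ten signature genes
(loading 1, residual SD 1, so neighbouring signature genes correlate at
0.5). The planted evasion NR loads at −0.6, the planted protective NR at
+0.6, and the remaining 46 panel NRs are pure noise. All genes are
standardized to per-gene z-scores. Survival is exponential with
log-hazard `log(2)·z(evasion NR) − log(2)·f` (plus per-effector terms):
high evasion-NR expression doubles the hazard per SD, and high immune
activity halves it, so an unfavorable NR and a protective signature
co-occur as they do in real melanoma cohorts. Censoring is uniform on
(0, u) with u solved so the expected censored fraction hits the 20%
target. The default cohort size is 400 samples — the order of magnitude
of the TCGA melanoma cohort the cascade was designed around.

**Single-cell cohort** (`simulateScCohort`). 12 responder and 23
nonresponder patients, 100 cells each, spread over seven cell types
(half malignant). A gene is detected in a cell with a configured
detection fraction per gene × cell type × response group — the planted
evasion NR at 40% of nonresponder malignant cells versus 10% of
responder malignant cells, everything else at a 5% baseline — and
detected cells carry lognormal positive values. Stored values are
continuous log-scale expression; all screens threshold strictly at zero.

**DE fixture** (`simulateDETables`). Three tables over one 500-gene
universe. Planted common-direction genes (defaults: NACC1 and FKBP10
down, CXCL10 up, echoing the effector biology that motivated the
pipeline) sit beyond the 1.5× cut with p ≤ 1e-6 in all three
compartments; a planted inconsistent gene is strong but flips sign; null
genes stay inside the fold-change cut with uniform p. Because nulls can
never clear the fold-change cut, recovery of the planted common sets is
exact by construction — the corresponding test is a set-equality oracle,
not a power statement.

What the generator deliberately does **not** model: count noise and
library-size effects in the single-cell data (dropout is a plain
Bernoulli), batch effects, tumor purity, copy-number structure,
patient-level random effects, and non-exponential hazards. Passing tests
therefore demonstrate the correctness of the cascade's logic and its
calibration under clean assumptions, not robustness to every artifact of
real cohorts.

## Numerical choices and degenerate inputs

* Exact Spearman permutation p-values are refused above n = 7 (n!
  enumeration); exact Wilcoxon enumeration above a pooled size of 12.
* Comparisons against enumerated null statistics use a 1e-12 slack so
  that ties in the permutation distribution are counted as ties rather
  than lost to floating-point rounding.
* A log-rank test with zero accumulated variance (no informative event
  time) warns and reports p = 1 rather than dividing by zero.
* Constant gene rows make correlations undefined: the screen flags the
  row as degenerate and calls direction `none`; `quartileGroups` and
  `zscoreGroups` raise errors instead, since a survival split of a
  constant gene is meaningless.
* A candidate that is itself a signature gene has the self-pair excluded
  (and flagged) so a trivial ρ = 1 cannot carry the direction call.
* Genes absent from the bulk matrix during effector triage are flagged
  `absent_from_bulk` and given role `none` rather than aborting the run.

## Problem sizes used by the checks

The shipped verification uses 200 random vectors for the exact-Spearman
enumeration (n ≤ 7), 1000 random vectors for the BH oracle, 100 random
matrices for the percent-expressing recount, 2000 replicates at n = 60
with 20% censoring for null calibration, and 20 independently seeded
cohorts at the default generator sizes for end-to-end recovery. These
sizes give binomial standard errors around half a percentage point on
the calibration rates while keeping a full verification run in the
low minutes on one core.

## Known limitations

* The asymptotic χ² log-rank p-value is slightly anticonservative when an
  arm holds only a handful of subjects. This matters for the extreme-
  index contrast on small cohorts: at 60 samples the >0.75 / <0.25 index
  strata contain roughly 8 patients each, and the realized null
  rejection rate at α = 0.05 runs about 0.06–0.07 rather than 0.05. At
  cohort sizes in the hundreds the contrast is well calibrated. An exact
  or permutation log-rank would remove the inflation but is outside the
  scope of this package.
* Cell-level pooling in the response contrast treats cells from one
  patient as independent, which overstates the effective sample size;
  the `byPatient = TRUE` variant is the conservative alternative.
* The screen is correlational. A gene that clears all four stages has an
  expression pattern *consistent with* tumor-intrinsic immune evasion;
  causality requires perturbation experiments outside the scope of any
  expression screen.

## A minimal run

```{r example, eval = FALSE}
bulk <- simulateBulkCohort(bulkCohortConfig(seed = 1))
sc   <- simulateScCohort(scCohortConfig(seed = 1))
res  <- runScreen(bulk, sc)
res
verdicts(res)[verdicts(res)$final_call != "none", ]

fx     <- simulateDETables(deFixtureConfig(seed = 1))
common <- intersectConsistent(lapply(fx$tables, filterDE))
triageEffectors(common, bulk)
```
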