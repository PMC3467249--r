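---
title: "chemosig: methods, assumptions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chemosig: methods, assumptions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemosig)
cs_verbosity(0)
```

## The problem

Roughly a third of patients with advanced oropharyngeal squamous cell
carcinoma gain nothing from cisplatin/5-fluorouracil (PF) induction
chemotherapy except its toxicity and a delay of alternative treatment. The
clinical question this package models is whether a small tumor-expression
signature, measured before treatment, can identify those non-responders —
and whether the signature survives the jump from research microarrays to a
qRT-PCR assay a hospital lab could run. The package re-implements that
analysis as a reusable, fully tested pipeline and ships a synthetic-cohort
generator so every stage can be exercised, with known ground truth, without
any patient data.

The two cohort extremes are **CCR** (complete clinical response, more than
90% tumor-size decrease) and **NR** (less than 50% decrease, or
progression). `classify_response()` implements exactly this rule; both
inequalities are strict, so a 90% or 50% decrease falls in neither group
and returns `"excluded"` — the modeled study deliberately enrolled only the
two extremes, and we read its definitions literally.

## Expression measurement and normalization

Each two-channel array co-hybridizes Cy5-labeled tumor RNA against a
Cy3-labeled universal reference. Per spot, `M = log2(Cy5/Cy3)` and
`A = log2(Cy5*Cy3)/2`. Spots flagged *not found*, *bad* or *saturated* are
discarded, as are control probes; backgrounds are **never** subtracted.

The intensity-dependent dye bias is removed per array by subtracting a
loess fit of M on A — local **linear** fits with tricube weights, span
0.5, fitted on non-control spots only. Two numerical choices deserve
comment:

* **Robust fitting.** The fit uses Tukey-biweight robustness iterations
  (`family = "symmetric"`). With a plain least-squares fit, genuinely
  differential spots drag the trend toward themselves; with 2.5% of spots
  planted at +1.5 log2 units, the residual bias of the null spots exceeds
  0.05 in some intensity deciles, while the robust fit keeps every decile's
  median residual near 0.02. Robust local regression is also the standard
  for intensity normalization in the microarray literature. When the data
  admit an exact fit (zero residuals break the robustness iterations) the
  code falls back to the equivalent least-squares fit.
* **Idempotency.** Loess is a linear smoother but not a projection, so
  normalizing twice is *not* a no-op on noisy data: the second pass moves
  values by roughly `sd * sqrt(df/n)` (about 0.02 at n = 2000, sd = 0.3).
  The test suite asserts exact idempotency (to 1e-9) only where the local
  fit is a projection — M linear in A — and bounds the second-pass drift on
  noisy data at 0.05. Claiming 1e-6 idempotency in general would be
  mathematically false for any non-projection smoother.

Replicate probes of a gene are collapsed by median (robust to a single bad
probe); a gene discarded on one array keeps an explicit `NA` there, is
reported in differential expression, but is excluded from classifier
training (leave-one-out training needs a complete matrix). Normalization is
intra-array only; the modeled analysis describes no between-array scaling,
so we add none.

## Differential expression

Per gene, class means and SDs of M (`m_NR, m_CCR, s_NR, s_CCR`) are
computed on available values. The **signed fold change** maps the ratio
`r = 2^(m_NR - m_CCR)` to `+r` when `r >= 1` and `-1/r` otherwise, so a
gene at 31% of the responder level prints as −3.23, matching the published
orientation ("NR over responder").

The test statistic is a moderated t: gene-wise pooled variances are shrunk
toward a scaled inverse-chi-square prior whose hyperparameters `(d0, s0^2)`
are estimated by moment-matching on `log s^2` (digamma/trigamma
identities, trigamma inverted by Newton iteration). `d0 = 0` recovers the
ordinary pooled t exactly — the unit tests pin this against a hand-computed
oracle — and `d0 = Inf` fixes every variance at `s0^2`. P-values come from
the t distribution on `d0 + d` df and are adjusted by Benjamini–Hochberg
step-up (tested against an O(m²) brute-force definition). The filter is
applied to **adjusted** p by default (`use_raw_p = TRUE` is available and
logged), and a permutation-null alternative (`permutation_p_values()`,
gene-wise label permutation with a pooled null) preserves the ambiguity in
the modeled study's description of its test rather than guessing it away.

## The six-criterion filter

A gene is selected iff **all** of the following strict inequalities hold:

| # | criterion | default |
|---|-----------|---------|
| 1 | adjusted p | `< 0.025` |
| 2 | &#124;signed fold change&#124; | `> 1.3` |
| 3 | mean intensity A | `> 7` |
| 4 | `max(|m_NR|, |m_CCR|)` | `> 0.4` |
| 5 | `min(s_NR, s_CCR)` | `< 0.5` |
| 6 | separation score | `> -0.55` |

The separation score `|m_NR - m_CCR| - (s_NR + s_CCR)` is positive when
the one-SD bands of the two groups do not overlap; the −0.55 threshold
tolerates moderate overlap. Criterion 2 is evaluated on the log scale as
`|m_NR - m_CCR| > log2(1.3)` — the "fold change between the means" is the
antilog of the difference of log-means, because the group statistics are
defined on the `log2(sample/reference)` scale. Criteria 4 and 5 read "at
least one of the two" as max/min respectively, the only consistent
reading. The intensity criterion uses the cross-sample mean A (recomputed
inside each cross-validation fold from training samples only). The audit
table returned by `apply_selection_criteria()` records each criterion per
gene; tests verify the filter against a brute-force re-evaluation on 10,000
random gene records and at the exact boundary values (a separation score of
exactly −0.55, or p of exactly 0.025, fails).

The published 10-gene panel itself contains entries that violate the
printed thresholds (e.g. p = 0.246 or fold change 1.11); the published
description does not explain how they entered the final signature. We do
not attempt to reverse-engineer that step: `derive_final_signature()`
accepts an explicit gene-list override precisely so a published panel can
be imposed on real data.

## Classification

The classifier is a soft-margin linear SVM (cost 1 by default) on
per-training-fold z-scored features. No linear-SVM solver is available in
the target environment, so the package implements dual coordinate descent
(the liblinear L1-loss algorithm) directly: deterministic cyclic updates,
which makes repeated fits identical and label flips negate the solution
exactly. Zero-variance features get scale 1 and weight 0 with a warning.
The decision threshold is a score of 0, positive class NR; no probability
calibration.

Evaluation is **leave-one-out cross-validation with per-fold
re-selection**: for every held-out sample, differential expression and the
six-criterion filter are recomputed on the 22 training samples alone, the
SVM is trained on the fold's selected genes, and the held-out sample is
scored. Nothing from the held-out sample reaches selection or training;
tests corrupt a held-out sample and verify its fold is bit-identical. A
fold that selects nothing falls back to the top-k genes by |moderated t|,
with a logged warning.

The final signature ranks genes by cross-fold selection frequency, then by
mean |standardized weight| across folds, ties broken lexicographically
(logged); the top k (default 10, the published panel size) are refit on all
samples. This ranking is our interpretation of "the genes that give the
best prediction scores" — the published rule is not recoverable, hence the
override path above.

Two covariate facilities mirror the modeled study's negative clinical
results: `augment_with_covariates()` appends HPV status (positive = 1,
unknown samples dropped and counted), and `covariate_baseline()` runs a
Fisher linear discriminant (hand-rolled; pooled covariance with a 1e-6
ridge on singularity) under LOOCV on age, smoking, alcohol and hemoglobin.
On cohorts drawn with **no** class effect at the published pooled
covariate summaries, the baseline stays below the 70% bar in ≥90% of
seeds. Planting the published (all non-significant) between-class
differences as true population effects pushes mean accuracy to ~0.70 —
right at the bar — so the stricter "below 70% in ≥90% of seeds" claim is
only reproducible under the null reading; the tests assert the null-world
bound plus a mean-accuracy bound under planted differences.

## qRT-PCR quantification and transfer

TLDA wells carry two replicates per gene; replicate Ct values are averaged
(arithmetic mean, i.e. geometric mean of quantities). Then
`dCt = Ct_gene - Ct_GAPDH` within each sample,
`ddCt = dCt_sample - dCt_calibrator` against the universal-reference
calibrator, and `RQ = 2^-ddCt` — so the calibrator has RQ = 1 identically,
`log2(RQ) = -ddCt` exactly, and adding a constant to every Ct of a sample
cancels. **Undetermined** Ct (no amplification by cycle 40) is treated as
missing, never imputed as 40 — imputing the cycle cap fabricates
expression; if one replicate survives it is used (flagged), if none do the
well is `NA` and excluded pairwise.

Cross-platform transfer keeps the signature's **gene set** and refits the
SVM weights on `log2(RQ)` (the two platforms' scales differ, and the
modeled study's transfer procedure is unstated — this is the central
transfer decision). With labels, the transferred model is evaluated by
LOOCV with the gene set fixed (no re-selection: the signature is given);
the refit model, marked as TLDA-scale, can then be applied frozen to new
unlabeled samples — matching the workflow in which five new patients were
classified by an already-derived signature.

## Evaluation machinery

* `confusion_metrics()` — counts and eight rates (percent) with NR as the
  positive condition; zero-denominator rates are `NA`, never 0. The three
  complement identities (sensitivity+FNR, specificity+FPR, PPV+FDR = 100)
  are property-tested.
* `roc_auc()` — midrank AUC (equals Mann–Whitney U normalized by
  `n_pos * n_neg`; verified against concordant-pair counting).
* `mds_smacof()` — metric MDS by SMACOF majorization from a
  classical-scaling start. The per-iteration stress reported in `trace` is
  normalized by the fixed input dissimilarities, so majorization guarantees
  monotone non-increase; the final `stress` field is Kruskal stress-1
  (normalized by the configuration distances), the conventional summary.
  `variance_fraction` is the share of positive classical-scaling eigenvalue
  mass in the embedding dimensions.
* `fisher_exact()` — two-sided by the probability-mass rule (sum of
  fixed-margin tables no more probable than the observed one); this is the
  convention that reproduces the published HPV p-value of 0.03, and it is
  verified against full hypergeometric enumeration (17,732/646,646 for the
  HPV table). `fisher_rx2()` extends the rule to r×2 tables by exact
  enumeration (total n ≤ 50) or seeded Monte Carlo.
* `group_compare()` — Welch t (default for continuous covariates;
  reproduces the published hemoglobin p = 0.19), pooled t, and midrank
  Mann–Whitney with tie correction and no continuity correction
  (reproduces U = 95.5 and p ≈ 0.06 for age). Which variant produced each
  published value is not stated; these defaults are reverse-engineered to
  match and are flagged as such.

## The synthetic world

`simulation_config()` states the emulated design: 10 NR + 13 CCR samples;
arrays whose per-gene true `log2(sample/reference)` is
`0 + effect + N(0, sigma_gene)` with `effect = ±delta` in NR for the
planted genes (half up, half down); spot intensities back-computed from
`A ~ U(6, 14)` with dye bias `bias_amplitude * sin(A*pi/8)` and
`N(0, sigma_spot)` spot noise; ~1% of spots randomly flagged; control
probes at M = 0. Defaults: 2,000 probes with 100 controls (a scaled-down
array — pass 41,000/2,615 for the full-size design; tests scale down for
speed and say so), 10 planted genes at delta = 1 (2-fold), sigma_gene
= 0.3 — chosen to be compatible with the SD < 0.5 filter criterion, since
the modeled study never prints its within-group SDs — bias amplitude 0.5,
spot noise 0.1. Ct tables follow `Ct = 25 - ct_slope * M + N(0,
ct_noise_sd)` with two replicates, a reference gene at M = 0 everywhere
and a calibrator sample at M = 0 for every gene. One master seed drives
per-array substreams, so adding arrays never perturbs earlier ones.

What the generator does **not** emulate: probe-sequence effects, spatial
artifacts, print-tip structure, correlated gene modules, batch effects,
amplification-efficiency differences between TLDA wells, or any tumor
biology (HPV mechanism, survival). A green test therefore establishes that
the *machinery* — normalization, selection, leakage-free cross-validation,
ddCt transfer — behaves as specified on data with the assumed noise
structure; it says nothing about clinical validity on real tumors.

## Honest nulls and known limitations

Under label permutation, LOOCV with per-fold re-selection is *not* an
unbiased coin: folds share training samples, and selection-then-training
overfits noise, which is systematically pessimistic for the held-out
sample (we measure pooled null accuracy ≈ 0.45 with between-permutation
SD ≈ 0.19). The acceptance test therefore checks that the mean accuracy
over 20 permutations lies within the central 95% interval around 0.5 using
the empirical between-permutation spread — a naive pooled binomial band
would assume an independence that the design does not provide.

Other limitations: intra-array normalization only; equal-variance pooling
inside the moderated t (class SDs are still reported separately for the
filter); no multi-reference-gene qRT-PCR normalization; no kernels beyond
linear and no hyperparameter search; ordinal alcohol labels are encoded by
interval midpoints (`parse_alcohol()`); and the per-patient HPV column of
the bundled cohort sheet is a synthetic assignment consistent with the
published group totals, as its header states.
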