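# chemosig

Deriving and evaluating small gene-expression signatures that predict
whether a head-and-neck tumor will respond to cisplatin/5-fluorouracil (PF)
induction chemotherapy — and testing whether such a signature transfers
from two-channel microarrays to hospital-friendly qRT-PCR cards.

## Who this is for

Translational transcriptomics groups who have (or want to simulate) a small
two-arm cohort — complete clinical responders (CCR, >90% tumor-size
decrease) versus non-responders (NR, <50% decrease or progression) — with
per-patient two-channel microarrays hybridized against a universal RNA
reference, and optionally TaqMan low-density array (TLDA) Ct measurements
for a candidate gene panel.

## The model

Each array measures, per spot, `M = log2(Cy5/Cy3)` (tumor over universal
reference) at mean intensity `A = log2(Cy5 * Cy3)/2`. The pipeline:

1. **Preprocess** — discard flagged (not found / bad / saturated) and
   control spots, no background subtraction; remove the intensity-dependent
   dye bias by subtracting a robust loess fit of M on A (degree 1,
   span 0.5); collapse replicate probes by median.
2. **Differential expression** — per-gene moderated t between NR and CCR:
   the pooled variance `s_g^2` (df `d = n_NR + n_CCR - 2`) is shrunk toward
   an empirical-Bayes prior, `s~_g^2 = (d0 s0^2 + d s_g^2) / (d0 + d)`,
   with `(d0, s0^2)` moment-matched across genes;
   `t_g = (m_NR - m_CCR) / (s~_g sqrt(1/n_NR + 1/n_CCR))` on `d0 + d` df;
   Benjamini–Hochberg adjustment.
3. **Six-criterion filter** — a gene is selected iff (strict inequalities)
   adjusted `p < 0.025`, `|FC| > 1.3`, mean `A > 7`,
   `max(|m_NR|, |m_CCR|) > 0.4`, `min(s_NR, s_CCR) < 0.5`, and the
   separation score `|m_NR - m_CCR| - (s_NR + s_CCR) > -0.55`.
   Fold changes are signed: ratio `r >= 1` prints as `+r`, `r < 1` as
   `-1/r`, oriented NR over responder.
4. **Classifier** — soft-margin linear SVM on z-scored features, evaluated
   by leave-one-out cross-validation in which the filter is re-run on every
   fold's 22 training samples (leakage-free); genes are ranked by cross-fold
   selection frequency (then weight magnitude) into a final k-gene signature
   (default k = 10).
5. **qRT-PCR transfer** — TLDA Ct replicates are averaged,
   `dCt = Ct_gene - Ct_GAPDH`, `ddCt = dCt_sample - dCt_calibrator`,
   `RQ = 2^-ddCt`; the signature's gene set is kept and its weights refit on
   `log2(RQ)`, or a frozen TLDA-scale model is applied to new samples.
6. **Evaluation** — confusion-matrix rates with NR as the positive
   condition, midrank ROC/AUC, SMACOF metric MDS with Kruskal stress-1,
   Fisher exact (probability-mass rule) and Welch-t / Mann–Whitney cohort
   tests, and a Fisher-LDA clinical-covariate baseline.

A seeded generator (`generate_cohort()`, `generate_ct_table()`) produces
synthetic cohorts with planted differential genes, an intensity-dependent
dye bias and concordant Ct tables, so the whole pipeline is testable with
no external data.

## Worked example

```r
library(chemosig)
cfg <- pipeline_config(
  sim = simulation_config(n_genes = 2000, n_controls = 100, n_de = 10,
                          delta = 1, sigma_gene = 0.3),
  seed = 42, k = 10L)
report <- run_pipeline(cfg)
print(report)
#> <run_report 5cb56f8b: 1900 genes x 23 samples | LOOCV accuracy 100.0% (AUC 1.000) | 10 genes selected | MDS stress 0.0594>

head(report$de_table[order(report$de_table$q),
                     c("gene", "fc_signed", "t_mod", "p", "q")], 3)
#>    gene fc_signed t_mod        p        q
#>  G01327     -2.25 -8.47 2.45e-17 4.66e-14
#>  G00321     -2.12 -8.16 3.46e-16 3.29e-13
#>  G01098      2.07  7.91 2.66e-15 1.68e-12
```

The cohort has 23 samples (13 CCR, 10 NR) on 2,000-probe arrays with ten
2-fold genes planted between the groups. All ten pass the six-criterion
filter (`report$selected_genes`), the leave-one-out SVM classifies every
sample correctly, and the signature transfers to the simulated qRT-PCR
card with the same accuracy (`report$tlda$accuracy`).

Confusion summaries from published prediction counts — here the microarray
panel of the modeled study (7/10 NR and 12/13 CCR correct):

```r
confusion_metrics(tp = 7, fn = 3, tn = 12, fp = 1)
#> True condition = Non-responder
#>   tp 7  fn 3  tn 12  fp 1
#>   sensitivity 70.0%  specificity 92.3%  PPV 87.5%  NPV 80.0%
#>   FPR 7.7%  FNR 30.0%  accuracy 82.6%  FDR 12.5%
```

A transcription of the modeled study's clinical covariate table ships in
`inst/extdata/pf_cohort_clinical.tsv` (per-patient HPV is synthetic; only
group totals were published) and reproduces the published cohort
statistics — Fisher exact p = 0.03 for HPV, Welch p = 0.19 for hemoglobin,
Mann–Whitney p = 0.06 for age (see `tests/testthat/test-acceptance.R`).

## Command line

```sh
exec/chemosig simulate --config cfg.yaml --out simdir --seed 3
exec/chemosig run --config cfg.yaml --seed 3 --out rundir
exec/chemosig ddct --ct ct.tsv --out rq.tsv
exec/chemosig evaluate --pred pred.tsv --truth sheet.tsv --out report.json
```

## Documentation

See `vignettes/chemosig-methods.Rmd` for the model, the tunable
parameters, what the synthetic generator does and does not emulate, and
the numerical design decisions.
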