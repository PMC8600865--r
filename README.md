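# radsens

Screening gene panels for **radio-sensitive (RS) genes**: genes whose
expression level predicts *discrepant overall-survival benefit from
radiotherapy* in expression + survival cohorts (TCGA-style RNA-seq with
clinical follow-up). The intended user is a biostatistician or
computational biologist running treatment-biomarker interaction screens on
observational oncology cohorts.

## The method

For each gene, patients are split at the within-cohort median expression
(high H vs low L; ties low) and crossed with radiotherapy status to form
the HRT / LRT / HNRT / LNRT groups. Four adjusted Cox
proportional-hazards analyses are evaluated on a stack of multiply-imputed
clinical covariates (M = 10, weight 1/M, subject-clustered sandwich
variance):

| Scenario | Subset | Criterion |
|---|---|---|
| A | high expression | radiotherapy retained by AIC fast-backward selection with HR < 1 |
| B | low expression | same as A |
| C | radiotherapy arm | H-vs-L indicator: Wald p < α, fixed adjuster set |
| D | no-radiotherapy arm | same as C |

A gene is called RS when **(A or B) holds and exactly one of C or D
holds**:

- **Type I** (C only): expression is not prognostic on its own, but
  predicts differential radiotherapy benefit;
- **Type II** (D only): expression is prognostic without radiotherapy and
  radiotherapy erases the disadvantage;
- **RGH / RGL**: the high (A) or low (B) expression group captures the
  benefit.

Supporting machinery: eligibility filtering (missing survival/radiotherapy
removed, survival < 5 days excluded, TCGA tumor-barcode filtering), a
dataset-level screen requiring radiotherapy to be protective (univariate
HR < 1, p < 0.05), chained-equation imputation (PMM for continuous,
logistic/multinomial draws for categorical, outcome included as predictor)
with imputation stacking, exact AIC backward elimination, Kaplan-Meier /
log-rank / Wilcoxon / categorized Pearson utilities, hierarchical
clustering of patients on RS-gene panels, and a synthetic cohort generator
that plants known Type I / Type II / null interactions so the whole
pipeline can be scored against ground truth.

## Worked example

The `analysis/` scripts run the pipeline end-to-end on a simulated cohort
(1500 patients, 70 genes: 50 null, 10 Type I, 10 Type II):

```sh
Rscript analysis/01_simulate.R   # cohort + truth tables -> results/sim/
Rscript analysis/02_prep.R       # eligibility + RT screen -> results/prep/
Rscript analysis/03_discover.R   # RS calls + recovery score -> results/discover/
Rscript analysis/04_downstream.R # correlation, clustering, contrasts
Rscript analysis/05_recovery.R   # 10-cohort recovery experiment
```

A condensed run looks like:

```r
library(radsens)
coh <- generate_cohort(synthetic_config(seed = 1))
cohort <- apply_eligibility(coh$expression, coh$clinical, rs_config())
calls <- discover_rs(cohort, config = rs_config(seed = 1001))
score_recovery(calls, coh$truth)
```

On this seed the eligibility filter keeps 1247 of 1500 patients (253
removed by the 5-day rule; the planted hazards are strong), the screen
confirms radiotherapy is protective (HR 0.006, p < 1e-100 — the summed
planted interactions make the marginal treatment effect far stronger than
exp(β_RT)), the cohort-level selection retains age group, chemotherapy and
stage as adjusters, and discovery calls 24 RS genes: 19 of the 20 planted
effect genes — all with the correct Type I/II label — plus 5 of the 50
null genes, i.e.

```
$sensitivity    0.95
$fpr            0.10
$type_accuracy  1.00
```

`sensitivity` is the fraction of truly interacting genes called RS, `fpr`
the fraction of null genes called RS (the call requires a conjunction of
significances, so its theoretical null rate is ≈ 2α(1−α) ≈ 0.095), and
`type_accuracy` the fraction of true-positive calls assigned the correct
interaction type.

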