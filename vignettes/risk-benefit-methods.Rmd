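---
title: "Balancing malignancy probability against surgical risk in IPMN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balancing malignancy probability against surgical risk in IPMN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipmnbalance)
```

## The decision problem

Branch-duct and mixed-type intraductal papillary mucinous neoplasms (IPMN)
are premalignant pancreatic cysts with a wide spectrum of malignancy rates.
Resection removes the cancer risk but carries substantial morbidity — a
pancreaticoduodenectomy (PD) harms far more patients than a distal
pancreatectomy (DP) — so the operate/surveil decision is a trade between two
asymmetric errors:

* a **false negative**: a malignant lesion (high-grade dysplasia or invasive
  carcinoma) left under surveillance;
* a **false positive**: a benign lesion resected, exposing the patient to
  postoperative complications for no oncological benefit.

`ipmnbalance` implements a cohort-level balance rule and a per-patient direct
rule for this trade.

## The balance rule

Let `mp` be a patient's predicted malignancy probability (from a logistic
nomogram over age, sex, main pancreatic duct diameter, cyst size, mural
nodule, CA19-9 and CEA) and fix a cutoff `c` in percent: operate when
`mp * 100 >= c`. Over a cohort, each cutoff yields FN (malignant patients
below `c`) and FP (benign patients at or above `c`). Weighting FP by the
group's complication rate `r` converts unnecessary surgeries into expected
harmed patients, and the balance cutoff solves

```
FN = FP x r
```

On integer counts exact equality is rare, so `select_cutoff()` minimises
`|FN - FP x r|` over the grid. Ties break toward the **lower** cutoff,
favouring sensitivity (missing a malignancy is the graver error); when the
minimiser is the first or last grid point there is no interior crossing and
the result is flagged `boundary = TRUE`. This nearest-to-equality rule was
chosen over a first-crossing rule because only the former reproduces all
eight cutoffs of the bundled reference worksheets; a first-crossing rule
selects 33 rather than 32 for the PD group at the 18.1 % rate.

```{r}
select_cutoffs(reference_balance_table("PD"))
select_cutoffs(reference_balance_table("DP"))
```

Because complication rates differ by severity (Clavien–Dindo grade >= II,
>= IIIa, >= IIIb, >= IV) and by operation, the cutoff is computed per surgery
group and per severity threshold; higher rates push the cutoff up, a
monotonicity the test suite verifies on random cohorts.

Numerical conventions worth stating:

* A score exactly at the cutoff counts as operated (`>=`).
* Probabilities are carried in `[0, 1]` internally; percent appears only at
  I/O boundaries. The conversion rounds `mp * 100` to nine decimals before
  comparing, so `0.29` meets a cutoff of 29 despite binary floating point.
* The default grid is integer percents 1–99. A finer grid is configuration;
  continuous root-finding on smoothed error curves is out of scope.

## The direct rule

The per-patient arm compares each patient's malignancy probability against
their own predicted surgical risk `sc` (a serious-complication probability):
operate iff `mp > sc`, strictly — at a tie the rule stays with surveillance.
`summarize_direct()` reports the operated fraction, the surgery reduction,
and confusion metrics of the rule against pathology. A binary rule has a
single ROC point, so two AUC readings are emitted side by side: the
trapezoid point AUC `(sensitivity + specificity) / 2` and the AUC of the
continuous difference score `mp - sc`. Neither is claimed to equal the
other; which one a report means by "the AUC of the rule" is ambiguous in
the field, so both are given.

Since the logistic function is strictly increasing, shifting both scores by
a common constant on the logit scale preserves every `mp > sc` comparison;
what changes is the probability margin. The decision is therefore invariant
to common logit recalibration, and the test suite pins that property.

## Risk models

The published nomogram's fitted coefficients live behind a web calculator
and are not printed anywhere re-usable, and the ACS NSQIP serious-complication
model is proprietary. Both scorers are therefore **surrogates held in
configuration**, not reimplementations:

* `default_mp_spec()` — a logistic model with positive weights on duct
  diameter (0.25 per mm), mural nodule (1.0), `log1p(CA19-9)` (0.45) and
  smaller terms on age, sex, cyst size and `log1p(CEA)`. Tumour markers
  enter through `log1p` to tame their right skew. Calibrate before any
  clinical use.
* `default_sc_specs()` — baseline-only intercepts at the minimal
  serious-complication levels for pancreatic resections, `logit(0.122)` for
  PD and `logit(0.084)` for DP, plus logit-scale gaussian noise
  (`sc_noise_sd`, default 0.4) for patient-level dispersion. Covariate terms
  (age, comorbidity proxies) can be added through `logistic_model_spec()`.

Any model spec serialises to JSON (`write_model_spec()`), so institutional
coefficients drop in without code changes.

## The synthetic cohort

No patient-level data ship with the package; `generate_cohort()` emulates
the statistical structure the analysis assumes so every stage is testable.

* **Sizes.** Defaults `n_pd = 464`, `n_dp = 293`, the reference worksheet
  group sizes.
* **Features.** Age ~ normal(62, 10) truncated to [18, 95] years; duct
  diameter ~ log-normal(log 3, 0.5) truncated to (0, 10] mm (the upper bound
  encodes the eligibility rule: main-duct dilatation beyond 10 mm is a
  different disease and is excluded); cyst size ~ log-normal(log 28, 0.45)
  truncated to (0, 150] mm; CA19-9 and CEA ~ log-normal (medians 15 U/mL
  and 1.8 ng/mL); sex and mural nodule ~ Bernoulli (0.55, 0.35). Right-skewed
  positive labs and sizes are the standard clinical shape; every parameter is
  configuration.
* **Malignancy.** A Bernoulli draw on `plogis(linear predictor)` over the
  seven factors. The default intercept (−6.0) was set once so the default
  cohort's malignancy fraction (~23 %) matches the reference cohort's
  marginals (116/464 PD, 54/293 DP malignant). The latent probability is
  kept in `latent_p` for oracle checks.
* **Complications.** Ordinal Clavien–Dindo grades drawn so the configured
  exceedance rates hold exactly in expectation: category masses are
  differences of adjacent thresholds, the sub-grade-II remainder splits
  evenly between "none" and grade I (which no exceedance rate sees), and
  grades IV and V pool into the ">= IV" band because the reference rates
  stop at four thresholds.
* **Randomness.** One master seed, split into named substreams (features,
  pathology, per-group complications, score noise), so adding a stage never
  perturbs earlier draws and identical configs are bit-reproducible.

What the generator does **not** emulate: inter-feature correlation beyond
the shared logistic coupling (no stated correlations exist to copy),
measurement error between imaging modalities (each feature is a single
value, not a max over CT/MRI/EUS), informative surgery-type assignment
(group membership is independent of features), and late-versus-early
complication timing. Passing tests therefore certify the arithmetic and the
statistical machinery, not the clinical performance of any scorer on real
patients — the published cohort's AUCs (0.8033 for the nomogram, 0.6260 for
the risk calculator, 0.6588 for the direct rule) depend on an unavailable
800-patient dataset and are deliberately not targets.

## Diagnostics and calibration

`confusion_at_cutoff()` reports sensitivity, specificity, PPV, NPV and the
number under the cutoff; any empty denominator yields `NA`, never a silent
zero. `roc_auc()` computes the Mann–Whitney AUC with a DeLong confidence
interval (through pROC, orientation fixed so an inverted marker really
reports below 0.5); an independent all-pairs oracle in the test suite pins
its exactness.

`hosmer_lemeshow()` bins the cohort by quantiles of predicted probability —
10 bins for the 10 % scale, 5 for the 20 % scale — and refers
`sum((O - E)^2 / (E (1 - E/n)))` to chi-square with `bins - 2` degrees of
freedom. Two implementation notes:

* The `bins - 2` reference distribution is derived for probabilities fitted
  on the same data. The package's type-I-error simulation therefore refits
  the logistic model in each replicate before testing; testing the *true*
  generating probabilities against `bins - 2` over-rejects (about 10 % at
  the 5 % level in our simulations, consistent with theory that external
  probabilities need `bins` degrees of freedom).
* Quantile binning keeps ties together, merging duplicate breaks. When ties
  are so heavy that fewer than three usable bins remain (e.g. a constant
  predictor), binning falls back to equal-frequency rank bins with stable
  order and says so; zero-variance bins merge into a neighbour with a
  message rather than dividing by zero.

The type-I simulation uses 500 replicates of 1000 patients each — large
enough for the chi-square approximation and a 3-standard-error band around
the 5 % nominal level, small enough to run in seconds.

## Known limitations

* Both scorers are surrogates; nothing here reproduces the published
  nomogram's coefficients or the ACS NSQIP calculator's internals.
* The balance rule treats the complication rate as a scalar per
  group-severity pair; cost-utility extensions (QALYs, monetary costs) and
  smoothed continuous thresholds are out of scope.
* The grid selection inherits the grid's resolution: with integer percents,
  a true balance point between grid values is reported at the nearest grid
  cutoff.
* Per-patient comparison of `mp` against `sc` presumes both probabilities
  are on comparable scales; a poorly calibrated risk model (the published
  experience with the surgical-risk calculator outside its development
  population) degrades the direct rule first.
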