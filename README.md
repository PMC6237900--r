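# seprogadic

Serum-protein prognostic modules for resected gastric cancer from targeted
MRM proteomics.

After gastrectomy, TNM stage is the standard basis for deciding who gets
which adjuvant therapy, but a four-level stage is a blunt instrument.
This package implements, as a tested and reusable pipeline, an approach
that augments stage with a small panel of serum proteins quantified by
multiple reaction monitoring (MRM) mass spectrometry: replicate-based QC
of transition peak areas, normalization by endogenous reference proteins,
and cross-validated Cox feature selection feeding two classifiers — a
**prognosis module** (PM) that scores recurrence risk, and an
**adjuvant-therapy selection module** (AT) that scores expected benefit
from chemoradiation (CCRT) versus chemotherapy alone (CTX). It is aimed at
proteomics/biostatistics researchers who want to study, stress-test or
re-apply this class of serum-panel survival models.

## The method in brief

* Per-run **normalization scaling factor** from five screened normalizing
  peptides, `NSF_s = median_i(N_{i,s} / Nhat_i)`, followed by per-peptide
  ionization-exponent correction `PA / NSF^beta_j`, with `beta_j` the
  log2–log2 slope of peak area on NSF across the ten pooled-QC runs.
* **Endpoints** at 72 months: recurrence / censored early /
  recurrence-free, with the CTX arm's codes order-reversed for the AT
  module.
* **Stability selection**: 500 repeats of 8-fold cross-validated Cox
  backward elimination (stage forced for PM); a protein retained in >= 4
  of 8 folds counts one observation, and the selected set is the longest
  N.O.-ranked prefix passing

  `Z = (N.O.(s) - 500 p_s) / sqrt(500 p_s (1 - p_s)) >= 1.96`,
  `p_s = sum_{i=4..8} C(8,i) (s/n)^i ((n-s)/n)^(8-i)`.
* **Modules**: a full-data Cox fit on the selected proteins (+ ordinal
  stage for PM); the score is the linear predictor, the cutoff the median
  training score; evaluation by Kaplan–Meier, log-rank, hazard ratios and
  time-dependent ROC/AUC (cumulative-case/dynamic-control, KM-weighted)
  with BCa bootstrap intervals.

A synthetic-cohort generator reproduces the study design (227 patients, 10
batches with pooled QC runs and triplicated samples, 73 MD + 20 ND panel
proteins, 15 normalizing-peptide candidates, a spiked control,
proportional-hazards outcomes) with full ground truth, so every stage is
tested as a recovery or calibration study. See the methods vignette
(`vignettes/seprogadic-methods.Rmd`) for the model, assumptions and design
decisions.

## Worked example

```r
library(seprogadic)

co  <- simulate_cohort(sim_config())          # 227-patient synthetic cohort
res <- run_pipeline(co, panel = "ND", run_univariate = FALSE,
                    selection = selection_config(n_iterations = 50L,
                                                 seed = 202L))

res$pm$selection$selected
#> [1] "ND001" "ND002" "ND019"
res$pm$module
#> SEPROGADIC prognosis module, ND panel: 3 protein(s) + forced stage

cat(res$pm$stratification$overall$hr_low_vs_high,
    res$pm$stratification$overall$logrank_p, "\n")
#> 0.1141958 2.004939e-09
cat(res$pm$stratification$auc, res$stage_only$auc,
    res$stage_only$lrt_vs_pm$p, "\n")
#> 0.8107634 0.6238442 1.460228e-09
```

Reading this: the selection recovered both ND-panel proteins the generator
planted with real hazard effects (`ND001`, `ND002`) plus one
chance-correlated protein (`ND019` — the vignette discusses why the
binomial stopping rule admits a small noise floor). Splitting patients at
the median module score gives the low-risk group roughly a 0.11 hazard
ratio versus high risk (log-rank p ~ 2e-9), and the module's 6-year
time-dependent AUC of 0.81 improves on 0.62 for the stage-only model
(likelihood-ratio p ~ 1e-9).

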