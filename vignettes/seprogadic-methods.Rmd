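---
title: "Serum-protein prognostic modules from targeted MRM proteomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum-protein prognostic modules from targeted MRM proteomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`seprogadic` implements a serum-protein prognostic pipeline for resected
gastric cancer, from raw targeted-MS quantification to deployable risk
classifiers. The measurement side is multiple reaction monitoring (MRM):
each protein is represented by one proteotypic peptide and one quantitative
transition, measured as a raw chromatographic peak area across a cohort
acquired in analytical batches. The modelling side is survival analysis on
disease-free survival (DFS): Cox proportional-hazards models with a
cross-validated stability-selection step choose a small multi-protein panel
that, together with TNM stage, scores each patient's recurrence risk
(prognosis module, PM) or expected benefit from one of two adjuvant
therapies (AT-selection module).

Because the original cohort sera are not available, the package ships a
synthetic-cohort generator with known ground truth. Every analysis step is
exercised against that truth: the tests are recovery and calibration
studies, not comparisons against the original patient data.

# Quality control of replicate runs

Each analytical batch re-measures two randomly chosen samples in
triplicate. For every (peptide, sample) triplicate the coefficient of
variation is `sd/mean` of the raw peak areas, with the sample
(n − 1) standard deviation; the published account does not specify the
denominator and the sample sd is the common default. A peptide whose CV
exceeds 0.25 in strictly more than five samples is excluded. Peptides never
triplicated are flagged *not assessable* and retained: absence of evidence
of irreproducibility is not treated as evidence.

When a protein carries several monitored peptides, one representative is
chosen by lexicographic ordering on (1) interference score if supplied,
(2) median replicate CV, (3) highest median peak area, with an alphabetical
tie-break for determinism. Interference from neighbouring chromatographic
signals is not computable from peak areas alone, so it is an optional input
column defaulting to a constant; criteria (2)–(3) then decide, and the
published ordering is preserved whenever real interference scores exist.

# Normalization

## Scaling factors

Instrumental response drifts over a multi-batch acquisition. The correction
is anchored on endogenous normalizing peptides (NPs) screened by four
criteria: detected in every run; one-way ANOVA of log2 areas across the
three prognostic outcome groups (recurred within 6 years / censored earlier
/ recurrence-free) with p > 0.05; Pearson correlation > 0.5 with a spiked
constant exogenous protein; and, among survivors, the best (lowest)
stability scores. The screen uses raw areas because normalization is not
yet defined at that stage. The stability score is a variance-decomposition
metric on the log2 scale — pooled within-group variance plus the mean
squared deviation of group means from the grand mean — standing in for the
model-based NormFinder value, which is external software; only the ranking
contract matters downstream.

With five selected NPs, each run *s* gets a normalization scaling factor

$$\mathrm{NSF}_s = \mathrm{median}\left(\frac{N_{1,s}}{\hat N_1}, \ldots,
\frac{N_{5,s}}{\hat N_5}\right),$$

where $N_{i,s}$ is the raw area of NP *i* in run *s* and $\hat N_i$ its
median over clinical runs. By construction the median over runs of each
ratio is exactly 1. NSFs are computed per injection (each replicate run has
its own), since drift acts on injections, with batch structure entering as
a batch-level mean shift.

## Ionization exponents

Dividing by the NSF assumes drift multiplies all peptides equally. It does
not quite: each peptide responds with its own exponent. The pooled QC
sample — an equal-part mixture of every patient serum, run once per batch —
has identical content in every run, so for peptide *j* the slope
$\beta_j$ of $\log_2(\mathrm{PA}_{j,s})$ on $\log_2(\mathrm{NSF}_s)$ over
the ten QC runs isolates the response exponent. The corrected abundance is

$$\mathrm{PA}^{corr}_{j,s} = \mathrm{PA}_{j,s} / \mathrm{NSF}_s^{\beta_j},$$

the unique form that reduces to plain normalization at $\beta_j = 1$ and
inverts the log–log slope relation the exponent is estimated from.
Estimates are clamped to [0.5, 2] (with a warning) because ten points admit
occasional wild slopes; if all QC NSFs coincide the slope is undefined and
$\beta_j = 1$ is used with a warning.

Two identifiability points deserve emphasis. First, exponents are only
defined *relative to the reference set*: if the NPs themselves carried
non-unit exponents, every estimate would be scaled by roughly the median
NP exponent. The synthetic generator therefore gives NP candidates and the
spiked control exponents of exactly 1; on real data the assumption is that
the selected NPs respond like the bulk. Second, the slope's precision is
proportional to the spread of the QC log-NSFs: with little drift there is
nothing to regress on. The packaged β-recovery experiment runs at a batch
drift of 0.3 (log2), a realistic ±23% cross-batch response change, where
the ten-point slope has roughly 3-sigma margin inside ±0.05 at 1%
injection CV; at the cohort default drift of 0.15 the estimate is
correspondingly noisier, which the acceptance report shows as the mean
absolute β error at study conditions.

# Endpoints

At the 72-month horizon each patient receives a prognosis (PM) endpoint:
2 = recurred within the horizon (event at the observed DFS), 1 = censored
earlier (censored at DFS), 0 = recurrence-free through the horizon
(censored at 72). An event recorded after the horizon counts as endpoint 0
and is messaged.

The AT-selection endpoint encodes the working hypothesis that high-risk
chemotherapy-only (CTX) patients would have fared better under
chemoradiation (CCRT) and vice versa: CCRT patients keep their PM
endpoint; CTX patients get the reversed code 2 − PM. The published account
does not state how reversed codes map back to (time, event) pairs for Cox
fitting; the package's reading preserves each subject's information span:
a reversed event (AT = 2, originally recurrence-free) is an event at the
72-month horizon, and a reversed non-event (AT = 0, originally a
recurrence) is a censoring at the observed recurrence time. This is one
consistent interpretation and is deliberately isolated in
`assign_at_endpoints()` so it can be swapped.

# Feature selection

Selection repeats an 8-fold cross-validation 500 times (both counts are
configurable; reduced presets are used throughout the tests). Folds are
randomly partitioned, stratified by the event indicator, reseeded per
iteration from a root seed. On each 7/8 training split a Cox model over
all panel proteins is pruned by backward elimination on Wald p-values at
0.05 — Wald being the standard stepwise criterion, the source being silent
— with clinical stage forced (never dropped) for prognosis modules. A
protein scores a *fold hit* when retained in a converged fold model; an
iteration counts as one *observation* (N.O.) for the protein when it hits
at least 4 of the 8 folds. The "at least four" reading follows the formula
(the summation from 4 to 8) where the prose wavers between "at least" and
"more than". Non-convergent fold fits — iteration-limit hits or diverging
coefficients under monotone likelihood — count as non-selection.

After all iterations, proteins are ranked by descending N.O. and compared
against the chance of a randomly drawn feature reaching 4 of 8 folds,

$$p_s = \sum_{i=4}^{8} \binom{8}{i}\left(\frac{s}{n}\right)^i
\left(\frac{n-s}{n}\right)^{8-i},
\qquad
Z = \frac{\mathrm{N.O.}(s) - 500\,p_s}{\sqrt{500\,p_s(1-p_s)}} \ge 1.96,$$

with *n* the panel size and *s* the rank. The selected set is the longest
prefix of the ranking whose every rank passes the Z rule.

A calibration caveat the package's own simulations quantify: the binomial
null assumes independent random picks per fold, but the eight folds share
most of the cohort, so a noise protein that is outcome-correlated by
chance in the full data is retained in nearly every fold of nearly every
iteration. Under an all-null panel the procedure therefore selects one to
three proteins routinely rather than none — a property of the published
stopping rule itself. Treat the selected set as a stability ranking with a
liberal cutoff, not as a familywise-error-controlled discovery list; the
planted-signal recovery tests show true effects always rank ahead of this
noise floor.

# Modules, scores and stratification

The final module is a single full-data Cox fit (Efron tie handling, the
common default; the source is silent) on the selected proteins, with stage
as a forced ordinal covariate 1–4 for prognosis modules — the single
printed stage coefficient implies an ordinal, not categorical, encoding.
The module score is the linear predictor $\sum_k \hat\beta_k x_k$ with no
baseline term; the classification cutoff is the median training score.
Prognosis modules split the cohort at the median into low/high risk,
evaluated overall and per stage by Kaplan–Meier curves, log-rank tests and
the low-vs-high hazard ratio; empty or event-free strata report NA rather
than failing, as happens for sparsely populated stage-4 subgroups.
AT modules cross the median split with the actual arm: CCRT below the
cutoff is tCCRT ("true CCRT"), CCRT at/above is fCCRT, CTX below is fCTX,
CTX at/above is tCTX; the four groups partition the cohort.

Marker performance at a horizon *t* uses the cumulative-case /
dynamic-control time-dependent ROC with Kaplan–Meier weighting (the
Heagerty–Lumley–Pepe KM estimator, chosen over the nearest-neighbour
variant for determinism): cases are subjects with an event by *t*,
controls those event-free at *t*, and joint probabilities are estimated as
$(1 - S(t \mid X > c))\,P(X > c)$ with subset Kaplan–Meier curves. The raw
estimator can be locally non-monotone under censoring; a running-minimum
adjustment on the two joint terms restores monotonicity and is exactly a
no-op when no censoring precedes the horizon, where the estimator
coincides with the empirical ROC and its trapezoid AUC equals Mann–Whitney
concordance — the package's exactness oracle. Univariate screening
cutoffs maximise the Youden index (sensitivity + specificity − 1, ties
toward the smaller cutoff; the source does not state its cutoff rule).
Confidence intervals for AUCs are subject-resampled BCa bootstrap
intervals via the `boot` package; resamples with no cases by the horizon
are skipped and counted.

# The synthetic cohort generator

The generator emulates the study design: 227 patients in 10 analytical
batches, each batch one pooled QC run plus 21–24 clinical runs with two
samples re-measured in triplicate; TNM stages drawn with probabilities
(0.2555, 0.3877, 0.2687, 0.0881) and adjuvant arms (CTX, CCRT) with
(107, 120)/227, independently of every covariate as in a randomized trial;
73 MD-panel and 20 ND-panel proteins, 15 NP candidates and a spiked
constant control.

Event times are exponential with hazard
$h_0 \exp(\gamma\,(\mathrm{stage}-1) + \sum_p \beta_p z_p)$ — the simplest
proportional-hazards-consistent choice — where $z_p$ are standard-normal
log2 biological abundances. Defaults: four true prognostic proteins with
coefficients (0.8, 0.8, 0.7, 0.7) per SD, planted alternately in the MD
and ND panels so both support recovery tests; stage coefficient 0.6 per
step; baseline hazard 7e-4 per month and a 42% uniform-censoring fraction,
set so the realized outcome mix (49 recurred / 83 censored early / 95
recurrence-free at seed 1) matches the three-group composition of the
emulated cohort (44/80/103). Follow-up is administratively censored at 72
months.

The measurement model is
$\mathrm{PA}_{j,r} = A_{j,s}\,\mathrm{NSF}_r^{\beta_j}\,e^{\varepsilon}$:
lognormal biological abundances (a common assumption for protein
concentrations; the true distribution is unknown and this choice is an
explicit assumption of the generator), per-run response factors that are
log2-normal with a batch-level mean shift (sd 0.15) and within-batch run
drift (sd 0.075) so the NSF varies within a batch as real chromatography
does, per-peptide exponents uniform on [0.8, 1.2] for panel proteins and
exactly 1 for the reference set, and 7% lognormal injection noise, placing
the replicate CVs near the 5–7% the emulated study reports. Three of the
15 NP candidates carry an outcome-group-dependent mean shift (0.3 log2 per
group step) so the ANOVA screen has something to catch. The QC sample is
the pooled mean of all patient abundances. Ground truth (effects, per-run
NSF, per-peptide exponents, abundance matrix) is returned alongside the
tables.

What the generator does *not* emulate — and what passing tests therefore
do not certify on real data: missing values and detection limits,
chromatographic interference, retention-time drift, depletion-chemistry
artefacts, correlated protein co-regulation, non-proportional hazards, and
informative censoring.

# Problem sizes and numerical choices

The test and acceptance runs use reduced presets chosen as the package's
working scale: selection at 15–100 iterations of 8-fold CV on the
20-protein ND panel (the 73-protein MD selection at ~49 events per 199
training subjects is a near-saturated Cox problem and is exercised at
reduced scale), 200–500 bootstrap resamples, and recovery studies at
n = 300–1000. A full 500-iteration run on both panels is a matter of
minutes, not hours, and changes no schema.

Other numerical conventions collected in one place: Efron tie handling
everywhere; convergence flags on iteration-limit or |coef| > 20; the Z
rule applied with ≥ (boundary included); alphabetical tie-breaks in the
selection ranking and representative-peptide choice; degenerate
median splits (constant scores) flagged rather than silently emitted;
seeds fan out deterministically from a single root so reruns are
byte-identical.
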