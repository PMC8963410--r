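---
title: "Modeling usual care for vasopressor initiation in septic hypotension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling usual care for vasopressor initiation in septic hypotension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Septic shock is defined operationally: a septic patient is "in shock" once
vasopressors are started. But clinicians differ widely in *when* they start
vasopressors for a hypotensive septic patient rather than continuing
intravenous fluid (IVF) boluses or simply observing. "Usual care" for this
decision is therefore ill-defined, which complicates trials that compare an
intervention against usual care.

`dynpract` implements a quantitative *dynamic practice* model of this
decision. The idea: train a logistic model (the usual-care-for-vasopressors
score, UCV) to discriminate, at the final decision timepoint of each
emergency-department (ED) encounter, between patients whom clinicians
committed to sustained vasopressor therapy and patients whose hypotension
resolved without vasopressors. The fitted score estimates the probability
that a hypotensive observation belongs to a patient about to need sustained
vasopressors — an empirical description of the institution's practice, not a
claim about what *should* be done.

## Data model and outcome classes

An encounter is one ED visit: time-stamped vital-sign observations
(irregular cadence, missingness), IVF bolus events, vasopressor episodes
with start location, labs, demographics, comorbidity and symptom flags.
Times are hours since triage. Hypotension is a measured systolic blood
pressure (SBP) strictly below 90 mmHg; inclusion requires at least two such
readings.

Within a 48-hour horizon from presentation, five mutually exclusive outcome
classes are assigned from the vasopressor course:

* `NON_VP` — no vasopressors within the horizon;
* `VP_GT24` — ED start, total course > 24 h (multiple physicians across ED
  and ICU shifts implicitly corroborated the need);
* `VP_8_24`, `VP_LT8` — ED start, total course in [8, 24] h (closed
  interval) or < 8 h: quickly weaned, possibly unnecessary;
* `VP_ICU` — no ED vasopressors despite ED hypotension, but initiation in
  an ICU (rarely an operating room) within the horizon.

Patients on vasopressors within 12 h before arrival, or made
comfort-measures-only, are excluded. A multi-episode course is summed over
episodes (gaps ignored); the horizon is anchored at triage. Only `VP_GT24`
and `NON_VP` — the classes with the least ambiguous label — enter model
development; the other classes are reserved for the applications.

The *final decision time* `t_f` is the last observation with SBP < 90 mmHg
before ED vasopressor initiation (treated patients) or the last hypotensive
observation of the stay (untreated); `t_{f-k}` is the k-th vital-sign
observation before it. Encounters with no documented hypotension before
treatment have no valid `t_f` and are dropped. Timepoints at which the
carried-forward SBP has risen to 90 mmHg or above are likewise excluded
from analysis rows.

## Features

At an anchor time the package assembles, from data at or before the anchor
only: most-recent and exponentially weighted values for every vital and
lab, running extrema (minimum GCS, SpO2, SBP; maximum heart rate, pain),
cumulative IVF (total, and while hypotensive under carried-forward SBP
status), elapsed time from triage, demographics, comorbidity and
symptom-group flags — about 45 candidates. The exponential weighting gives
the current observation weight 1 and the j-th prior observation weight
2^-j (the third prior carries one eighth), normalized by the weight sum;
decay is per observation, not per hour, which is the only convention
consistent with that ratio. Missing values carry forward; a signal never
documented through the anchor takes the population median, computed on the
training split only and frozen (no leakage); provenance is recorded per
value. Covariates are z-scored with the population (n-denominator) SD —
an arbitrary but fixed convention that the tests also use.

## Model development

Development mirrors common clinical-prediction practice:

1. stratified 90/10 encounter-level split of `VP_GT24` + `NON_VP`;
2. an L1-regularized logistic screen over all standardized candidates, with
   the regularization strength chosen by 5-fold cross-validated ROC AUC on
   a 20-point log-spaced grid (ties resolved toward stronger
   regularization, i.e. sparser models);
3. stepwise forward selection among the survivors using Wald p-values,
   adding the best candidate while it enters below alpha = 0.05, followed
   by backward pruning of any covariate at or above alpha in the joint
   model, cycling until stable — so every final covariate is significant in
   the final joint fit;
4. a plain maximum-likelihood logistic fit on the selected set. Under
   quasi-separation the fit falls back to a tiny quadratic penalty (1e-4)
   and is flagged. Odds ratios are rescaled to natural unit increments
   (per 5 mmHg SBP, per 1000 mL IVF, per hour, ...) via
   `exp(beta_std * increment / SD)`.

A note on step 3: when candidates are strongly correlated the
add-and-prune rule can admit more than one *stable* subset (each member
significant jointly, no outsider able to enter). The greedy procedure
always lands in a stable subset; which one is path-dependent, and the test
suite checks it against an exhaustive enumeration of the stable family.

Evaluation uses the Mann-Whitney AUC (ties one half) with DeLong 95%
intervals, paired DeLong tests for AUC differences, and leave-one-out
cross-validation that refits coefficients with the covariate set frozen
(refitting the whole selection per fold is a different — and much more
expensive — estimand; the frozen-set variant matches how a single final
model is reported). Pooled held-out scores form one ROC, the only
construction well-defined for leave-one-out. The temporal experiment
rebuilds rows at `t_{f-1}` ... `t_{f-4}`, trains alternative models with
the identical two-stage pipeline at each timepoint, and compares them with
the fixed usual-care model by paired DeLong on the LOOCV scores; the
usual-care model applied as-is is reported alongside.

## Applications

* **Cohort comparison** — score any outcome class at `t_f` and compare
  score distributions (two-sample Kolmogorov-Smirnov; Gaussian KDE with
  Scott's-rule bandwidth for display). Both the test and the group
  quantiles are always reported, because a statistically significant
  difference can still be clinically unimportant.
* **Timing outliers** — choose the smallest score threshold achieving 90%
  specificity on observation-level negatives (all hypotensive observations
  of `NON_VP` encounters over their whole stays), find each encounter's
  first threshold crossing, and class treated encounters by the delay from
  crossing to vasopressor start: within 1 h, 1-2 h, over 2 h (boundaries to
  the smaller bin); a start with no prior crossing is an early start.
  Interim IVF is the bolus volume in the (crossing, start] interval, by
  bolus start time. Patient-level sensitivity is the fraction of ED-treated
  encounters crossing before their start; positive predictive value is the
  fraction of crossing encounters treated within the horizon, reported both
  over all classes and restricted to the development classes (the
  denominator the literature uses is ambiguous, so both variants are
  given).

## The synthetic cohort generator

Real encounter-level EHR data of this kind are not publicly releasable, so
the package ships a generator that emulates the statistical structure the
analysis assumes — and, crucially, embeds a *known* clinician decision
policy so the whole pipeline is testable for parameter recovery.

Severity is a latent per-encounter discrete-time random walk that
mean-reverts toward a phenotype asymptote: a "crashing" phenotype presents
early in its course (low severity at triage) and settles at a severe but
bounded state, while a "hovering" phenotype stays near its presenting
severity with a slow drift. Vitals load on severity with organ-specific
per-encounter offsets (respiratory rate and oxygenation vary partly
independently of the hemodynamic axis), which keeps the candidate pool
from collapsing onto a single collinear severity axis — as in real
patients, organ dysfunction is not perfectly concordant. Observations
arrive on a lognormal grid (median gap 0.5 h); non-SBP vitals are missing
with probability 0.15 after the fully documented triage row; labs are
missing entirely with probability 0.2. An IVF policy gives boluses while
the carried-forward SBP is below 90 mmHg, front-loaded in the stay, with a
per-encounter aggressiveness multiplier representing practice variation.

The decision policy is a logistic in the six published predictors —
exponentially weighted respiratory rate, fluids given while SBP < 90,
elapsed time from triage, minimum GCS, minimum SpO2, most recent SBP —
with log-odds per natural unit equal to the natural logs of the published
odds ratios divided by their increments, and an intercept placing the
firing probability at 0.5 when every predictor sits at its configured
marginal mean. The policy is evaluated *once per encounter*, at the
terminal hypotensive observation of the untreated trajectory — the
decisive moment at which escalation either happens or hypotension is about
to conclusively resolve or the patient leaves the ED. This makes the
probability of becoming a sustained-vasopressor case, given the feature
vector at the decision time, exactly logistic in those features, so the
development pipeline is a consistent estimator of the policy coefficients.
We deliberately did not model the decision as an independent draw at every
hypotensive observation: repeated trials along an autocorrelated
trajectory sharpen the realized case/control assignment well beyond the
per-observation logistic (we measured roughly a 1.35x inflation of all
log-odds ratios under that variant), which would make the published
coefficient set unrecoverable by construction.

Class identity is emergent, not forced: a fired policy leads to an ED
start with a lognormal course duration (weakly severity-dependent), whose
realized value is read back into `VP_GT24` / `VP_8_24` / `VP_LT8`; with
probability 0.12 a fired start is deferred past ED departure (the ICU
deferral route, producing the high-score mode of the `VP_ICU` group); a
small constant probability (0.05) of post-ED deterioration sends a
non-fired encounter to ICU initiation (the low-score mode — together the
two routes make the `VP_ICU` score distribution bimodal). Encounters are
then rejection-sampled toward the target class mix (Non-VP 0.26, VP>24
0.40, VP 8-24 0.10, VP<8 0.15, VP-ICU 0.09, echoing the published cohort
composition) — classes are read back from realized trajectories and only
the acceptance is quota-driven.

The vital-sign process constants were calibrated once so that the six
policy predictors, summarized at `t_f` over the development classes of a
default cohort (n = 2000), match the configured targets (means within a
quarter SD): exp-weighted RR 21 (4.7) min^-1, fluids while hypotensive
890 (1200) mL, elapsed time 6.4 (6.1) h, min GCS 13 (3.7), min SpO2 92
(5.7) %, SBP 80.0 (8.6) mmHg. These targets are jointly demanding — the
decision policy pins the case SBP distribution to its logit surface, so
the calibration is a genuine constraint satisfaction exercise, and two
structural features (descent-speed heterogeneity and the late
"hovering-dipper" control phenotype) exist precisely because the targets
cannot all be met without them.

What the generator does *not* emulate: physiologic feedback from
treatment (boluses do not raise SBP), pharmacokinetics, diurnal staffing
effects, charting idiosyncrasies, or any mortality process. Passing the
recovery tests therefore demonstrates that the pipeline estimates a
decision policy of this functional form without bias under realistic
observation structure — not that the fitted model would transport to any
particular hospital.

## Known estimand subtleties

Even with an exactly logistic policy, the development estimate carries a
small (~5% on the log scale) upward bias in the steep coefficients,
traceable to conditioning the case pool on sustained (> 24 h) courses and
to the outcome-balanced resampling of the cohort interacting with
maximum-likelihood logistic fitting at large standardized effects. We left
it in place rather than switching to bias-reduced (Firth) fitting, because
the plain fit is what the modeled practice literature reports, and the
published coefficient set being emulated is itself a plain fit.

## Numerical choices and degenerate inputs

Ties in CV-AUC go to stronger regularization; ties at delay-bin boundaries
go to the smaller bin; the duration interval [8, 24] h is closed on both
ends. Zero-variance features standardize to 0 with a warning and a
degenerate flag. A single-encounter marginal summary reports SD 0 with a
degenerate flag. An empty L1 survivor set or an empty stepwise result is a
no-model outcome (warning, `NULL`), not an error. Quasi-separation in the
final fit triggers the penalized fallback. All randomness flows from named
integer seeds (generation, split, fold assignment); leave-one-out is
deterministic. Times are compared with 1e-12 slack to absorb float jitter
in JSON round trips.

## Problem sizes in the test suite

Unit tests run on hand-built fixtures and small generated cohorts (n =
15-400). The recovery study uses 20 replicates of the default n = 2000
cohort through the full pipeline; the temporal study uses 20 cohorts of
n = 900 (chosen as the smallest size at which every timepoint down to
`t_{f-4}` retains enough rows per class for stable leave-one-out ROCs).

## Limitations

The model describes one synthetic institution's practice; usual care
varies by center, and the score is a description of behavior, not a
treatment recommendation. Elapsed time from triage enters the policy (and
recovers cleanly), but in observational data its coefficient partly
reflects survivorship in how `t_f` is defined — an interpretive caveat the
synthetic world shares with the real analysis. No outcome (mortality)
analysis is attempted anywhere in the package.
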