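---
title: "Modelling incident CKD under time-varying PPI exposure"
author: "ppickd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling incident CKD under time-varying PPI exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ppickd implements the full analysis chain of a primary-care cohort study
of proton-pump-inhibitor (PPI) exposure and incident chronic kidney
disease (CKD): phenotyping from longitudinal laboratory records,
prescription-based exposure construction, Andersen–Gill (AG)
restructuring, and a Bayesian piecewise-exponential hazard model with
individual frailty and a spatial Matérn random effect.  Because the
motivating data are a non-public clinical-administrative database, the
package ships a synthetic-cohort generator with known ground truth;
every methodological claim the package makes is backed by tests against
that truth or against independent oracles (closed forms, Poisson GLMs,
`survival` estimators).

## Phenotype definitions

eGFR is computed with the 2009 CKD-EPI creatinine equation; the race
term defaults to non-black, appropriate for the Spanish primary-care
setting the package emulates, but remains available.  Incident CKD is
eGFR < 60 mL/min/1.73m² and/or UACR ≥ 30 mg/g in two or more
determinations spanning at least 90 days.  Several operational choices
deserve to be explicit, all switchable in the API:

* **"3 months" is 90 days** (and a "month" 30 days everywhere).
  Calendar-month arithmetic depends on the entry date and would make
  phenotypes irreproducible across shifted cohorts.
* **Qualifying determinations need not be consecutive**: a normal value
  between two sub-threshold values does not reset the clock.  This is
  the most inclusive reading; the chronicity requirement is carried
  entirely by the 90-day span.
* **The event is dated at the confirming determination** (the earliest
  determination that completes the 90-day span), because chronicity is
  only established then.  `event_date_rule = "first"` dates it at the
  first qualifying determination instead — the synthetic-data
  round-trip tests use this rule, since the first qualifying visit is
  the earliest observable trace of the latent event.
* **Prevalent-CKD exclusion applies the same two-determination rule**
  inside the first study year.  A single-abnormal-value variant is
  provided (`rule = "single"`); which rule produced the original
  study's exclusion count is not documented, so symmetry with the
  incident definition was chosen.
* A determination day with both analytes counts once; either analyte
  may confirm the other ("and/or" at the determination level).

Covariate derivation follows the usual primary-care operational rules
(hypertension, high-normal blood pressure, type-2 diabetes, impaired
fasting glucose, obesity, dyslipidaemia components, metabolic syndrome
as ≥ 3 of its 5 components).  Flags are three-valued: a participant
with no relevant measurements is `NA`, never silently healthy.

## Exposure construction

Prescriptions carry either prescriber-recorded treatment days or a
dispensed quantity with a numeric daily dose; duration is the recorded
days when present, otherwise `ceiling(quantity / daily_dose)`.
Overlapping or contiguous prescriptions merge into exposure episodes.
The default **grace period is 0 days** (strict contiguity): "consecutive"
is not defined by the source methodology, and 0 is the only
assumption-free reading; a 30-day grace is one argument away and is the
common pharmacoepidemiological alternative.  Dose is standard/high per
drug (20 mg standard for omeprazole, esomeprazole and pantoprazole,
15 mg for lansoprazole, 10 mg for rabeprazole); a merged episode is
high-dose if any constituent is, and doses above the usual high range
are classified high with a message.  Cumulative duration is categorised
with half-open 30-day-month bins at 30/90/180/360/720 days, plus the
collapsed four-class scheme.  "Baseline user" means any episode
intersecting the first year after the participant's own entry
(an entry-anchored reading of the basal visit; the window length is an
argument).

## Counting-process design

`split_intervals()` turns a follow-up `[entry, exit]` into start–stop
intervals at every covariate change point: exposure starts/ends,
cumulative-duration category crossings, dose changes, the 70th
birthday, comorbidity/treatment onsets.  Delayed entry is kept as a
positive first start (left truncation), and analysis time is days since
study start — age enters as the time-varying ≥ 70 indicator rather than
as the time scale, which matches the staggered-entry design.  Ties
between an event and a change are resolved left-closed: the event
belongs to the state in force just before the change.  Death before CKD
is right censoring, not a competing risk; with CKD incidences around
30 % this overstates absolute risk slightly but leaves hazard ratios
interpretable, and a competing-risk treatment is out of scope.

## The hazard model

For expanded pieces $r$ (interval × baseline bin) with exposure time
$E_r$ and event indicator $d_r$, the log-likelihood is the Poisson
equivalence of the piecewise-exponential model,
$\sum_r d_r \eta_r - E_r e^{\eta_r}$, with
$\eta_r = \lambda_{b(r)} + x_r'\beta + u_{i(r)} + s_{l(r)}$:

* $\lambda$ — log baseline-hazard steps on (by default) 24 equal-width
  bins over the observed time range, under an improper first-order
  random-walk (RW1) prior.  There is no intercept: the steps carry the
  level, so no sum-to-zero constraint is needed and the RW1 penalises
  only differences.  24 bins is roughly quarterly for an 8-year window
  — fine enough to absorb shared time-varying risk, coarse enough that
  every bin sees events at the cohort sizes the package targets.
* $\beta$ — fixed effects, flat prior.  With random effects off and
  smoothing off the posterior mode therefore *is* the Poisson-GLM
  maximum-likelihood estimate, which the tests verify to $10^{-6}$.
* $u$ — iid Gaussian frailty per participant.
* $s$ — Gaussian with Matérn covariance
  ($\kappa = \sqrt{8\nu}/\rho$, $\nu = 1$ by default) over unique
  participant locations, solved densely.  A dense GP over a few hundred
  area centroids is exact and fast at desk scale; an SPDE mesh
  approximation would only pay off at much larger spatial problems.

Hyperparameters (RW1 SD, frailty SD, spatial SD and range) carry
penalising-complexity priors: exponential on each SD with
$P(\sigma > 1) = 0.01$, and the two-dimensional PC range prior with
$P(\rho < \rho_0) = 0.05$, $\rho_0$ defaulting to a tenth of the
maximal inter-location distance.  Inference is empirical-Bayes Laplace:
an inner Newton iteration (sparse Cholesky, analysed once and
refactorised per iteration) finds the latent-field mode, and the outer
optimisation maximises the Laplace-approximate log marginal posterior
over the hyperparameters — Brent for one, Nelder–Mead otherwise, on
log-scale coordinates for conditioning.  Full INLA-style numerical
integration over the hyperparameters is deliberately not attempted:
posterior modes coincide, and the empirical-Bayes fit keeps a
3 000-participant frailty model under a few seconds.

Two numerical choices matter enough to state.  First, the outer
objective is the posterior density in the **natural** $(\sigma, \rho)$
parameterisation.  Optimising the density of $\log\sigma$ instead would
add a Jacobian that moves the implied prior mode to
$\sigma_0/\ln(1/\alpha) \approx 0.22$ and defeats the PC prior's
shrinkage: with an uninformative likelihood the frailty SD would sit
near 0.2 instead of collapsing to its base value 0, which the tests
check directly.  Second, credible intervals are Gaussian
(mode ± 1.96 · posterior SD from the Laplace covariance), conditional
on the optimised hyperparameters; they do not propagate hyperparameter
uncertainty, and the parameter-recovery tests confirm their coverage is
nonetheless close to nominal at the package's target scales.

Degenerate fits are reported, not hidden: an SD collapsing below
$10^{-3}$ is listed in the fit's `degenerate` field, and a frailty SD
near zero simply reproduces the no-frailty model.  It is worth knowing
that with at most one event per participant a univariate frailty SD is
weakly identified — maximum likelihood (e.g. `lme4` with adaptive
quadrature) frequently returns exactly zero on data simulated with a
positive SD.  The PC-prior MAP behaves the same way by design,
shrinking to zero unless the data argue otherwise; fixed-effect
estimates are essentially unaffected, which the recovery tests
demonstrate by comparing against start–stop Cox fits.

## Reporting

Survival curves use the Kalbfleisch–Prentice weighted product-limit
estimator with risk sets honouring delayed entry; at unit weights it
equals the Kaplan–Meier estimator exactly (property-tested against
`survival::survfit` on a thousand random datasets, ties and truncation
included).  The log-rank test accumulates the hypergeometric
observed-minus-expected quadratic form with the same risk-set
convention.  Descriptive tables give mean (SD) or n (%) by stratum with
pairwise chi-squared tests, no continuity correction by default (a
toggle exists), flagged at the Bonferroni-corrected 0.01 level.
Exported curves state their time origin (days since study start).

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the analysis assumes, with
defaults frozen as the package's study conditions:

* 8-year window (2005–2012), staggered entry (60 % in the first year,
  the rest uniform), administrative censoring plus random loss
  (2 %/year).
* Confounding by indication: PPI initiation depends on age ≥ 70,
  hypertension, diabetes, obesity and NSAID use **as of entry**, scaled
  to give roughly a quarter baseline users and 7 % follow-up
  initiators — the strata proportions of the motivating cohort.  The
  entry-state convention matters: making initiation depend on *ever*
  having a comorbidity (including future onsets) builds in residual
  confounding that no time-varying adjustment can remove, and early
  versions of the generator showed exactly that upward bias.
* Event times drawn exactly by inverting the piecewise-exponential
  cumulative hazard along each subject's covariate path — no time
  discretisation; a 1-day discrete-time simulator serves as an
  independent oracle in the tests.
* Laboratory visits as a Poisson process (1.5/year by default — visit
  sparsity is not documented for the source cohort, so this is a free
  parameter, not an estimate).  Pre-event eGFR sits on a plateau
  clamped above the threshold, so phenotyping can never date the event
  early; post-event values descend linearly below 60 (or UACR rises
  above 30 for the 15 % of events that manifest through albuminuria).
  Creatinine is obtained by closed-form inversion of CKD-EPI at the
  visit age, so the pipeline's eGFR reproduces the latent trajectory.
* Frailty (SD 0.3) and a spatially structured confounder: a Matérn
  field over ~100 area centroids that loads on both PPI initiation and
  the hazard, off by default and switched on for the
  spatial-confounding study.

What the generator does **not** emulate — measurement batch effects,
drug switching, informative visit schedules, death as a competing risk,
coded-diagnosis noise — bounds what passing tests show: they validate
the estimator and pipeline logic under the stated data-generating
process, not robustness to every real-EHR pathology.

## Validation scales and what the tests compute

The test suite sizes simulations to desk scale as a design choice:
parameter recovery uses 20 replicates at n = 3 000 (credible-interval
coverage of a true HR 1.5) and 20 at n = 5 000 (mean log-HR bias);
the spatial study 20 replicates at n = 1 500 over 80 areas, fitting
with the spatial term on and off on the same seeds; product-limit and
conservation properties use 1 000 random small datasets each.  At these
scales the Monte-Carlo standard error of a single fitted log-HR is
about 0.13 (n = 3 000), so single-replicate discrepancies of ±0.2 are
expected noise; averaged criteria are the meaningful ones.  Recovery
tests build the counting table from the generator's ground truth
(`truth_counting_table()`), isolating the estimator from phenotyping
noise, whose fidelity is tested separately by the lab round-trip
property (the first qualifying determination is the first post-event
visit in ≥ 95 % of detectable events, and never precedes the event).

Running the laboratory-phenotyped route end to end instead gives a
visibly attenuated exposure effect, and that is a property of the
design, not a defect of the estimator: with sparse visiting
(1.5 visits/year) the confirmation-dated event lands many months after
the latent onset, by which time a typical 60-day episode has ended, so
events arising on exposure are often recorded in the unexposed state
while the delay itself adds exposed at-risk time.  Dating events at the
first qualifying determination (`event_date_rule = "first"`) roughly
halves the delay and moves the estimate towards the truth — the
acceptance script reports both.  This outcome-ascertainment bias is
intrinsic to surveillance-based CKD phenotypes and worth keeping
visible rather than papering over.

## Known limitations

Empirical-Bayes credible intervals ignore hyperparameter uncertainty;
the univariate frailty SD is weakly identified at one event per
subject; the spatial solve is dense and would need an SPDE or nearest-
neighbour approximation beyond a few thousand unique locations; the
phenotype depends on laboratory surveillance intensity, so incidence is
under-ascertained exactly as in the motivating design (participants
without post-event visits are censored); and over-the-counter PPI use
is invisible to prescription-based exposure by construction.
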