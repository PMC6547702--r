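---
title: "Pharmacopeia-wide case-crossover screening: models and design choices"
author: "pwascc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacopeia-wide case-crossover screening: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Prescription registers that record every dispensed drug for a whole
population make it possible to screen the entire pharmacopoeia, without a
prior hypothesis, for drugs that acutely trigger — or acutely protect
against — a clinical event with a well-defined onset, such as first acute
myocardial infarction (AMI). The obstacle is confounding by indication:
people who fill a prescription differ from people who do not, in ways no
covariate list captures.

The case-crossover design removes all stable within-person confounding by
using each patient as their own control. For a patient whose event occurs
on day $t$ (the *index date*), exposure to each drug in a *case window*
just before onset (by default, dispensings 1–7 days before $t$) is compared
with exposure in an earlier *control window* of equal length (15–21 days
before $t$), separated by a wash-out gap that limits pharmacological
carry-over. Day 0 — the index date itself — belongs to no window:
same-day dispensing is ambiguous between cause and consequence of the
event. Exposure is binary per window (any dispensing), because the
registers record dispensing occurrence, not ingestion.

## The conditional likelihood and its pair-difference reduction

With one case window and one control window per patient, the design is a
1:1 matched case-control study and the appropriate model is conditional
logistic regression. Writing $x^{(1)}_i, x^{(0)}_i \in \{0,1\}^p$ for
patient $i$'s case- and control-window exposure indicators over $p$ drugs,
the per-patient nuisance terms condition out and the likelihood depends on
the data only through the difference vectors
$d_i = x^{(1)}_i - x^{(0)}_i \in \{-1,0,1\}^p$:

$$\ell(\beta) \;=\; \sum_i \log \sigma(\beta^\top d_i),
  \qquad \sigma(u) = \frac{1}{1+e^{-u}},$$

an intercept-free logistic log-likelihood over the *informative pairs*
(patients with $d_i \neq 0$). $\exp(\beta_j)$ is the rate ratio of the
event while drug $j$ was dispensed within the preceding trigger window.
We implement this reduction directly rather than via stratified
bookkeeping; it is mathematically identical and an order of magnitude
faster. For a single drug the MLE is the classical discordant-pair ratio
$n_{10}/n_{01}$ with log-scale standard error
$\sqrt{1/n_{10} + 1/n_{01}}$, which the package exposes as
`univariable_estimate()` and uses as an internal consistency anchor.

Because informative pairs are discordant in very few drugs, the rows of
the difference matrix repeat a small set of distinct patterns. All
likelihood computations collapse to unique patterns with multiplicities —
exact, and the main reason bootstrap selection is feasible on one CPU.

## Penalized fit and selection

Screening hundreds of drugs jointly calls for sparsity. The package
maximizes

$$\ell(\beta) - \lambda \sum_j |\beta_j|$$

by cyclic coordinate-wise Newton steps with soft-thresholding, warm-started
down a geometric penalty path from $\lambda_{\max} = \max_j |\tfrac12
\sum_i d_{ij}|$ (the score at the origin; the smallest penalty whose
solution is exactly zero). Design notes:

* Columns are **not standardized**: every covariate is a same-scale binary
  difference, and unscaled penalties keep $\beta_j$ comparable across
  drugs. No covariate is exempted from the penalty.
* Each coordinate step is an exact one-dimensional Newton step on the
  current linear predictor, capped at $\pm 2$ per update — the local
  quadratic can overshoot where the logistic curvature collapses.
* Convergence is declared when the largest coefficient change in a sweep
  falls below `tol` ($10^{-8}$ by default); the largest violation of the
  stationarity (KKT) conditions is recorded on the fit as `kkt_gap`.
* Columns whose discordant pairs are all on one side (complete separation)
  have an infinite MLE; unpenalized fits flag them `degenerate`, report the
  sign, and exclude them from the joint Newton step and from interval
  reporting.

The penalty for each fit is chosen by $K$-fold cross-validation
(`cv_select_lambda()`): folds partition informative pairs, the path is fit
on the training pairs, and each $\lambda$ is scored by total held-out
conditional log-likelihood — the estimand's native scale, in preference to
classification error. Ties are broken toward the larger (sparser) penalty,
since stability of selection is the goal of the enclosing bootstrap.

## BOLASSO selection and the refit

`bolasso()` draws `n_bootstrap` resamples of whole informative pairs (the
independent sampling unit of the conditional likelihood; the two periods of
a patient are never separated), re-selects the penalty per resample,
refits the L1 path, and records each drug's support. Drugs selected in at
least a `consensus` fraction of resamples form the selected set. The
strict intersection (`consensus = 1`) is the classical rule; a soft
threshold (0.9) is exposed because intersection over many resamples is
conservative in finite samples. Final effect estimates always come from an
**unpenalized joint refit on the original data** restricted to the selected
drugs: estimates are mutually adjusted and free of shrinkage bias, and
their Wald intervals are labelled as refit intervals — they do not account
for the preceding selection step, which is known to make naive penalized
intervals unreliable.

Each bootstrap draws from a substream seeded by `(seed, b)`, so enlarging
`n_bootstrap` extends rather than reshuffles earlier resamples.

## Two countries and the fixed-effect combination

Running the screen independently per country and intersecting the selected
sets (`common_hits()`) is a replication filter: a drug must survive
selection against two independent national registers. For the common hits,
country log rate ratios are pooled by inverse-variance fixed-effect
meta-analysis (`fixed_effect()`): weights $w_c = 1/\mathrm{se}_c^2$,
pooled estimate $\hat\mu = \sum w_c \hat\beta_c / \sum w_c$, standard
error $(\sum w_c)^{-1/2}$. Published tables print ratios and 95% intervals
rather than standard errors, so `se_from_ci()` reconstructs
$\mathrm{se} = (\ln U - \ln L) / (2 \times 1.959964)$; reconstruction from
two-decimal print values matches only to print precision, and the package's
reproduction checks therefore use a tolerance of $\pm 0.01$. Cochran's
$Q$ and $I^2$ are computed and carried on every combination but never gate
it; only the fixed-effect estimate is reported.

## The synthetic registry

The registries this package targets are restricted-access national
registers, so validation rests on a generator
(`registry_config()` / `simulate_registry()`) with planted, known effects.
Per patient and drug, dispensings follow one of two processes:

* **acute/episodic** — a homogeneous point process at `acute_rate`
  dispensings per patient-year among users (prevalence `use_prevalence`);
  stationary, hence exactly exchangeable between case and control windows
  under the null;
* **chronic** — therapy initiates at a uniformly random day of the
  observation period and persists as refills every
  `refill_interval_days` $\pm$ jitter (a renewal process). Initiation
  during observation is deliberate: it is the mechanism of
  *persistent-user bias*, the upward distortion of case-crossover
  estimates for chronically refilled drugs, and the generator reproduces
  its direction when the refill period is commensurate with the spacing of
  the windows. A strictly stationary refill stream (active since before
  observation) would make the two windows exchangeable and hide the bias.

The daily event hazard is
$h(t) = h_0 \prod_j \mathrm{RR}_j^{\,[\text{drug } j \text{ dispensed in } (t-W,\,t-1]]}$
with $W$ = `trigger_window_days` = 7 by default, matching the analysis
case window so the planted $\mathrm{RR}_j$ *is* the estimand; $W$ is
configurable to study window misspecification, which biases estimates
toward the null. Patients enter the at-risk period at day 42, so the
longest default control window and wash-out always fit inside observed
history, and only the first event is kept — events are first episodes by
construction, not post-hoc filtering. Demographics (a Scandinavian-style
first-AMI age/sex mix) are sampled independently of drug use: self-matching
makes them nuisance variables, and a dependence knob is out of scope.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real registers: dose and package-size fields,
over-the-counter purchases, institutionalized-patient gaps, calendar
seasonality and day-of-week dispensing cycles, multi-event histories, and
correlation between drug use and demographics. Its role is ground truth
for the estimator and the selection machinery, not realism of the
pharmacoepidemiological landscape.

## Eligibility filters

Three filters mirror common register restrictions and sensitivity
analyses: hospital-ascertained events only; at least one dispensing within
365 days (inclusive) before the index date; and an age dichotomy at 80
years. Filters compose conjunctively. Note that since both analysis
windows lie inside the prior year, the prior-year filter cannot remove a
patient who would otherwise contribute an informative pair; it affects the
reported funnel (events and drug universe), which is also how the package
tests it.

## Validation scale and parameters that matter

Default solver settings: `tol = 1e-8`, `n_lambda = 100` penalties down to
`1e-3` of $\lambda_{\max}$, 5 CV folds, $z = 1.959964$ (two-sided 95%).
`bootstrap_spec()` defaults to 1000 resamples with strict consensus — the
register-scale profile; the package's own validation and the
`run_pwas()` default use the desk-scale profile of 100 resamples with
consensus 0.9.

The test suite validates at sizes chosen to finish on a single CPU while
keeping every planted drug well above 150 discordant pairs: recovery and
null-calibration screens use 8 000 patients over 3 years, 40 episodically
dispensed drugs with 5 effects planted at rate ratio 2, baseline hazard
$2.2\times10^{-4}$/day; recovery metrics are aggregated over 10 replicate
screens and estimator coverage is asserted at the nominal 2-SE level over
all recovered drugs; null calibration pools discordant counts over 20
seeds and two simulated countries. The persistent-user check uses a single
chronic drug with a 14-day refill period against the default 14-day window
spacing. All episodic-mode processes make the planted null exact in these
scenarios; chronic-refill distortion is demonstrated separately because
under this design it is a genuine (if artifactual) non-null signal, not an
estimator defect.

## Known limitations

* Refit Wald intervals ignore the preceding selection; they are honest
  about mutual adjustment, not about selection uncertainty.
* Dispensing date is a proxy for ingestion; misclassification of actual
  exposure biases toward the null, and nothing in the package corrects it.
* Chronically refilled drugs carry persistent-user bias by design of the
  case-crossover comparison; estimates for such drugs should be read as
  upper bounds on triggering.
* The cross-validated penalty rule is one defensible choice among several;
  with strict consensus the selected set is insensitive to moderate
  changes in the rule, which is the point of the bootstrap wrapper.
* Reproduction of printed tables is limited by two-decimal rounding of the
  inputs; one published row carries an interval inconsistent with its
  point estimate and is excluded from interval (not point) reproduction
  checks.
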