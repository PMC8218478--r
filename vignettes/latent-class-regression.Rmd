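---
title: "Latent class regression with concomitant covariates: model, estimation and design choices"
author: "lcreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent class regression with concomitant covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcreg)
```

## The model

`lcreg` fits a latent class regression (mixture-of-experts) model for a
3-category outcome $y$ (no, non-violent, violent reoffending within 12
months) given two sets of inputs with distinct roles:

$$
f(y \mid z^c, z^p) \;=\; \sum_{x=1}^{K} \pi(x \mid z^c)\; f(y \mid x, z^p),
$$

* $z^c$ — nine psychosocial/background **covariates** (age, SES,
  ethnicity, psychopathic-traits and problem-behaviour scale scores,
  criminal friends, substance-use category, treatment motivation,
  childhood trauma), dummy-coded into 17 design columns.  They act as
  *concomitant variables*: $\pi(x \mid z^c)$ is a $K$-class
  multinomial logit that forms the latent classes.
* $z^p$ — eight continuous **neurobiological predictors** (heart rate,
  pre-ejection period and log respiratory sinus arrhythmia, each at rest
  and as task reactivity, plus cortisol and testosterone).  Within each
  class, $f(y \mid x, z^p)$ is a multinomial logit of the outcome on
  these predictors.

The model is a one-step moderation analysis: classes are formed so that
they optimally moderate the predictor–outcome regressions, rather than
being formed first and related to the outcome afterwards.  Its free
parameters number $K(C-1)(1+8) + (K-1)(1+17)$ — 18, 54, 90 for
$K = 1, 2, 3$ — which pins both the dummy-coded column counts and the
`df = N - Npar` bookkeeping.

Fixed conventions (results are invariant up to reparameterisation):
outcome reference category "no reoffending"; membership reference class
$K$; after fitting, classes are relabelled so class 1 has the highest
class-conditional probability of not reoffending (ties to $10^{-9}$
break by class size).  The concomitant block must be re-anchored to the
new reference class when permuting, which `align_labels()` does by
permuting the full class-logit matrix and subtracting the new reference
row; the likelihood is unchanged.

Assumptions worth stating: outcomes are conditionally independent of the
covariates given the class ("local independence" at the level of this
model); analysis is complete-case — a record missing any covariate or
predictor is rejected with an id-level report, never imputed, matching
the behaviour of the deployed prediction prototype.

## Estimation

`fit_em()` maximises the observed-data log-likelihood by EM:

* **E step** — posterior class probabilities
  $W_{ik} \propto \pi(k \mid z^c_i)\, f(y_i \mid k, z^p_i)$.
* **M step** — two families of weighted multinomial-logit maximisations:
  the concomitant coefficients against the fractional targets $W$, and
  per class the outcome coefficients with case weights $W_{\cdot k}$.
  Both are solved by Newton iterations with a ridge ($\lambda = 10^{-6}$
  by default) added to the Hessian diagonal and step halving, which
  damps the steps under quasi-separation without changing any interior
  maximiser.  Because every inner step is an ascent step on the M-step
  objective, the observed-data log-likelihood is non-decreasing across
  EM iterations (asserted in the tests at tolerance $10^{-8}$).
* **Multi-start** — each start draws a per-case Dirichlet(1) posterior,
  applies one M step to obtain initial parameters, and runs EM to
  convergence (relative log-likelihood change below $10^{-8}$, at most
  500 iterations by default).  The best final log-likelihood wins; all
  per-start results are kept in `restart_diagnostics`.  Everything is
  driven by one integer seed, so identical data and configuration give
  bitwise-identical trajectories.

The E/M cycle is implemented in compiled code (RcppArmadillo); the
surrounding model algebra, standard errors and reporting are plain R.

**A structural caution on the membership block.** When the classes are
nearly deterministic functions of the covariates — which is the regime
the published application of this model reports (classification error
2%) — the concomitant logit sits near the separation boundary and its
maximum-likelihood coefficient *magnitudes* are unstable or unbounded,
exactly as in logistic regression under quasi-separation.  Class sizes,
the implied partition, modal assignments and coefficient *signs* remain
stable.  The recovery experiment therefore reports the membership and
outcome blocks separately (`gamma_rmse` vs `beta_rmse`) and judges the
membership block by sign recovery and class-size error, not magnitude.
A related consequence: fitting $K=2$ to data with *no* class structure
does not shrink to zero effects — the MLE carves a quasi-deterministic
partition of covariate space and fits noise, gaining far more
log-likelihood than the classical chi-square scale suggests.  Extra
classes must therefore be judged against the parametric-bootstrap null
distribution, never against naive asymptotics; this is exactly what the
bootstrap likelihood-ratio test provides.

## Standard errors and the Wald flag rule

`standard_errors()` inverts the observed information of the full
observed-data log-likelihood at the fitted parameters.  For $K=1$ the
analytic multinomial-logit Hessian is used; for mixtures the Hessian is
obtained by central finite differences of the analytic score (the
concomitant-mixture score has the standard closed form
$\sum_i (W_{ik} - \pi_{ik}) z^c_i$ and
$\sum_i W_{ik}(\mathbf{1}[y_i{=}c] - p_{ikc}) z^p_i$), with step
$10^{-5}\max(1, |\theta_j|)$ and symmetrisation.  Directions in which
the information matrix is singular (a duplicated column; the boundary
membership solutions discussed above) make the standard errors of the
parameters loading on them unavailable (`NA`) — they are flagged, never
fabricated — while identified parameters keep their generalized-inverse
standard errors.  In the near-deterministic regime this typically means
the concomitant block reports no usable Z statistics while the
within-class predictor block (the clinically interesting one) does.

Effects are screened with `wald_z_table()`: $Z = \hat\theta/\mathrm{SE}$,
flagged when $|Z| \ge 1.80$.  A two-sided level of 0.07 corresponds
exactly to $z = 1.812$; the threshold 1.80 is the rounded rule used in
published work with these models, so 1.80 is the default and both the
threshold and the nominal $\alpha = 0.07$ are configurable in
`fit_config()`.  Because a $K>1$ mixture with all effects zero is
unidentified, the nominal calibration of this rule is checked on the
$K=1$ model (`wald_null_calibration()`), where the slope Z statistics
are asymptotically standard normal.  Slope statistics within one fit are
correlated (they share the data), so the pooled flag count over all 16
slopes per fit is over-dispersed relative to a binomial; the calibration
therefore reports both the pooled rate and the rate of one pre-specified
statistic per replication, and the exact binomial acceptance interval
around $2(1-\Phi(1.80)) = 0.0719$ applies to the latter.

## Class enumeration

`selection_table()` fits $K = 1, \dots, K_{\max}$ and reports, per row:
`Npar`, the log-likelihood, $L^2$, five penalised indices on the $L^2$
scale, `df = N - Npar`, the upper-tail $\chi^2$ p-value of $L^2$, the
classification error $CE = \mathrm{mean}_i(1 - \max_k W_{ik})$, an
entropy-based pseudo-$R^2$, and the $-2LL$ difference against the
previous row.

With continuous covariates every case is its own covariate pattern, so
the saturated reference is taken as perfect per-case prediction
($\log L_{sat} = 0$), giving $L^2 = -2\log L$.  This convention
reproduces the published `df` bookkeeping exactly and leaves all
differences between models unchanged; it is recorded in the output
metadata.  The indices are penalised on the $L^2$ scale exactly as
published — $\mathrm{BIC}(L^2) = L^2 - \ln(N)\,df$,
$\mathrm{AIC}(L^2) = L^2 - 2\,df$, $\mathrm{AIC3}(L^2) = L^2 - 3\,df$,
$\mathrm{CAIC}(L^2) = L^2 - (\ln N + 1)\,df$,
$\mathrm{SABIC}(L^2) = L^2 - \ln\!\big(\tfrac{N+2}{24}\big)\,df$ — and
conventional $-2\log L$-scale versions are emitted alongside.  The two
scales differ by a constant for fixed $N$, so they always rank a set of
models identically; the table still carries a machine-checked
`ranking_agreement` attribute.  The pseudo-$R^2$ definition
($1 - \sum_i H_{model,i} / \sum_i H_{null,i}$ against the
outcome-marginal null) is this package's choice; commercial
implementations do not document theirs, so published $R^2$ values are
not comparison targets.

### Bootstrap likelihood-ratio test

`bootstrap_lrt()` simulates `B` datasets from the fitted small model
(covariates and predictors fixed, outcomes regenerated from the fitted
mixture), refits both class counts on each, and computes
$p = (1 + \#\{-2LL\mathrm{Diff}_b \ge -2LL\mathrm{Diff}_{obs}\}) / (B_{used} + 1)$.
The observed statistic and every replicate statistic are produced by the
*identical* refitting procedure — the same number of random starts, EM
iteration cap and tolerance (`refit_max_iter = 100`, `refit_tol = 1e-7`,
one Newton step per M step by default).  Under the null the observed and
replicate statistics are then exchangeable, so the Monte-Carlo test
holds its nominal size whatever the refit budget; a deliberately limited
budget costs only power, never validity.  Exhausting that shared budget
is part of the procedure, not a failure; a replicate is dropped (and
counted, with an `unreliable` flag above 20%) only when a refit returns
a non-finite likelihood.

## The prediction tool and external validation

`predict_case()` / `predict_batch()` implement the new-case tool: for a
case with unknown outcome the class posterior is the concomitant prior
$\pi(\cdot \mid z^c)$ (covariates only, the factorisation's prediction
mode; a post-hoc mode conditioning on an observed outcome exists for
internal validation), and the outcome distribution is the full mixture.
Modal outcome ties break toward the less severe category
(no < non-violent < violent) and are flagged when the top two
probabilities differ by less than `tie_tol`.

`build_confusion()` and `metric_report()` evaluate predictions against
observed outcomes.  Two metric conventions are first-class and tagged in
every output: the *standard* one-vs-rest definitions on the
observed-by-predicted table, and an *as-published* convention that
applies the same four formulas with the observed and predicted margins
exchanged (equivalently, the standard metrics of the transposed table).
The published external-validation table for this model family prints
values that match the latter, so both are provided; overall accuracy
(trace/$N$) is identical under either.  Zero-denominator metrics report
0 with a degeneracy flag rather than NaN, matching the published
display; display rounding is half-up to 2 decimals with raw values
retained.  `compare_predictor_blocks()` evaluates a full model against a
reduced one (within-class regressions on intercepts only — the minimal
reading of "without neurobiological markers" that keeps the mixture
structure) on the same holdout cases and reports the paired metrics and
their differences without assuming a direction.

## The synthetic cohort generator

No participant-level data from the motivating study are available, so
`generate_cohort()` provides the test bed: covariates and predictors are
drawn independently from marginals matching the published overall-sample
descriptives (means/SDs and category percentages; age truncated to the
12–24 recruitment range, non-negative scales truncated at zero, which
lifts the realised means of strongly truncated scores slightly above
their nominal values), the latent class is drawn from the concomitant
logit at the true parameters, and the outcome from the within-class
regressions.  True class labels travel in a separate `truth` object and
are never written into a cases table.

`default_study_spec()` encodes the emulated design: $K = 3$ with
marginal class sizes targeting (0.62, 0.21, 0.17), membership intercepts
calibrated against the covariate distribution by a fixed-seed
Monte-Carlo fixed-point iteration at construction time (20,000 draws;
the function is memoized and pure).  Class outcome profiles at mean
predictor values are (0.81, 0.14, 0.05) — the published low-risk
profile — and, by this package's design, (0.55, 0.35, 0.10) and
(0.15, 0.30, 0.55) for the medium/high-risk classes.  Within-class
predictor effects (cortisol, resting heart rate, RSA and PEP measures
in the medium-risk class; blunted heart-rate reactivity, testosterone,
cortisol and PEP reactivity in the high-risk class) have standardized
magnitudes of 1–2 and deliberately opposite signs across classes, so
that no pooled single-class regression can absorb them.  Membership
effects are likewise large (about 5 log-odds per SD).  Both choices
follow the published solution's signature rather than a generic "small
effects" convention: its 2% classification error implies nearly
deterministic classes, and its outcome pseudo-$R^2$ of 0.73 (against
0.03 for one class) implies strong class-specific outcome structure.
Under moderate effects the generated cohort would be far *less*
separated than the study this emulates, with a weakly identified
90-parameter likelihood and near-equivalent optima.  On cohorts of
$n = 2000$ the fitted three-class model shows classification error
about 0.04 and pseudo-$R^2$ about 0.3, and AIC/SABIC select three
classes, mirroring the published enumeration outcome.

What passing tests on this generator do **not** show about real data:
covariates are drawn independently (the real sample's correlations are
not emulated; an optional per-class predictor-shift hook exists but is
off by default), there is no measurement error model, no follow-up
censoring, and no missingness mechanism.  Parameter recovery here
demonstrates the estimator, not the clinical validity of any fitted
model.

## Problem sizes used by the test suite

The suite exercises the documented conditions at sizes chosen for a
single-CPU run: parameter recovery at $n = 2000$ over 3 seeds with 8
restarts; bootstrap type-I calibration with the full $B = 99$ over 200
outer replications at $n = 300$; Wald-rule calibration over 300
replications of $n = 400$; the deterioration and
power experiments at 5–6 seeded replications.  Where a published-scale
experiment (50 replications) is scaled down, the assertion keeps the
published proportion (e.g. at least 4 of 5 rejections where the full
experiment expects at least 90%).

## Known limitations

* One latent variable, nominal outcome link, no local-dependence
  (direct-effect) extensions.
* Membership coefficient magnitudes are not a stable reporting surface
  in the near-deterministic regime (see above); interpret the Wald table
  for the concomitant block with that caveat.
* The bootstrap test inherits the parametric assumption that the small
  model generates the data; it does not check the covariate model,
  which this likelihood leaves unspecified by design.
* Complete cases only, by design.
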