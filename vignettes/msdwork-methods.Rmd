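---
title: "Methods: developing and internally-externally validating the work-outcome models"
author: "msdwork"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developing and internally-externally validating the work-outcome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the models

Musculoskeletal disorders (MSDs) are a leading cause of work absence and of
reduced performance while at work (presenteeism).  `msdwork` implements a
complete pipeline for developing and validating individual risk-prediction
models for three outcomes in adults consulting primary care with an MSD:

* any work absence within 6 months of consultation (binary, primary outcome),
* presenteeism at 6 months (self-rated 0-10 score), and
* any work absence within 12 months (binary).

Ten baseline predictors are used: age, sex, multisite pain, baseline pain
score (0-10), pain duration (four ordered bands), job type (NS-SEC
three-class), anxiety/depression, any other comorbidity, work absence in the
previous 6 months, and baseline presenteeism.  The 12-month model omits
comorbidity and prior absence, which the contributing studies did not record
consistently, leaving 8 predictors.  With three dummy-coded levels for pain
duration and two for job type, the 6-month models carry 13 predictor
parameters and the 12-month model 11.

Outcomes are modelled with multilevel mixed-effects regression with a random
intercept per study,

$$ g\!\left(E[y_{ij}]\right) = \alpha + u_j + x_{ij}^{\top}\beta,
   \qquad u_j \sim N(0, \sigma_u^2), $$

where $g$ is the logit link for the absence outcomes and the identity for
presenteeism.  The linear model is fitted by REML, where that is the
standard estimator; for the logistic model REML is not defined in the same
sense, so it is fitted by maximum likelihood with adaptive Gauss-Hermite
quadrature (7 points, `nAGQ` tunable).  A random intercept is the only
random effect, so the "unstructured" random-effect covariance reduces to a
single variance.

## Overfitting control

Expected overfitting is pre-compensated by uniform heuristic shrinkage in
the Van Houwelingen-le Cessie sense:

$$ S = \frac{\chi^2_{\text{model}} - p}{\chi^2_{\text{model}}}, \qquad
   \chi^2_{\text{model}} = 2\,(\ell_{\text{model}} - \ell_{\text{null}}), $$

with $p$ the number of predictor parameters (13 or 11, fixed a priori; no
predictor selection takes place).  Both log-likelihoods come from the
multilevel fits (the null model keeps the intercept and the random
intercept), because the shrinkage targets overfitting of the fixed effects.
Every coefficient is multiplied by $S$ and the intercept is then
re-estimated holding the shrunken linear predictor fixed as an offset.

Two intercept conventions arise here and the package implements both:

* **Conditional (multilevel)**: the offset refit keeps the random intercept;
  the fixed intercept is the study-average conditional constant.  This is
  the default of `apply_shrinkage_and_reestimate()` and has the property
  that refitting with $S = 1$ reproduces the original fit.
* **Marginal (population-averaged)**: the offset refit is a pooled
  single-level fit, so that predictions made *with the random effect set to
  zero* — which is how every deployed model scores a new individual — have
  mean exactly equal to the observed outcome rate on the development data.

The development pipeline (`run_iecv()`, and the `develop` CLI verb) uses the
marginal convention for the constant it ships, because the deployed model is
scored at $u = 0$ and "re-estimated to keep predictions correct on average"
is then a statement about the marginal mean.  The random-intercept SD
reported alongside is always taken from the multilevel refit.

## Functional form

Fractional-polynomial transforms up to second order over the standard power
set $\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ are tested for each continuous
predictor in a complete-case analysis adjusted for all other predictors and
fixed study effects, using the closed test: best FP2 against linear (3 df),
then best FP2 against best FP1 (2 df), each at $\alpha = 0.05$ on deviance
differences.  Variables with non-positive values are shifted by
$-\min(x)$ plus the smallest observed increment.  On data generated with
linear effects the test keeps all three continuous predictors linear in
about 95% of runs, matching its nominal level.

# Internal-external cross-validation

With IPD from $K$ studies, each study is omitted in turn; the **full**
development procedure (multilevel fit, cycle-specific shrinkage, intercept
re-estimation, pooling across imputations) is run on the remaining studies,
and the cycle model is validated in the omitted study using the average
intercept (random effect at zero).  Performance is measured by:

* **C-statistic** — concordance over event/non-event pairs, ties counting
  one half, with a DeLong placement-variance SE;
* **calibration slope** — logistic regression of the outcome on the linear
  predictor (linear family: observed on predicted);
* **CITL** — intercept of that regression with the linear predictor as
  offset (linear family: mean observed-minus-predicted);
* **O/E** — observed events over the sum of predicted risks, with an SE of
  $\sqrt{(1-\bar y)/O}$ on the log scale (the publication behind this
  pipeline does not state its O/E interval formula; this standard
  approximation is a documented choice);
* grouped-plus-smoothed **calibration curves** (deciles, and a loess smooth
  of span 0.75, degree 2, on the probability scale over a 100-point grid).

Per-cycle statistics are combined by random-effects meta-analysis:
$\tau^2$ by REML with Hartung-Knapp t(k-1) intervals by default,
DerSimonian-Laird (with Wald intervals) as an option for comparability with
the classical estimator.  C-statistics enter on the logit scale and O/E on
the log scale, then are back-transformed for reporting; slope and CITL pool
on their natural scale.  Cycles whose validation set cannot support a
metric (e.g. no events) are reported as missing and excluded from that
metric's meta-analysis with a logged note; held-out studies with fewer than
10 events are flagged `unstable` but still computed.  With exactly two
studies IECV is refused and only apparent performance is computed, the same
fallback used for the 12-month model.  Apparent performance applies the
final model back to the pooled development data, ignoring clustering.

# Multiple imputation for clustered, systematically missing data

Primary-care IPD collections mix *sporadically* missing cells with
predictors that entire studies never recorded (*systematically* missing).
`impute_joint()` implements joint-model multiple imputation for this
setting: one latent-Gaussian model over all ten predictors plus the
available outcome columns,

$$ z_{ij} = \mu + u_j + \varepsilon_{ij}, \qquad
   u_j \sim N_q(0, \Psi), \quad \varepsilon_{ij} \sim N_q(0, \Sigma), $$

* continuous variables enter standardised;
* binary variables through a latent normal thresholded at 0;
* ordinal variables through a single latent normal with fixed interior
  thresholds $0, 1, \dots, L-2$ (free mean and variance), which preserves
  the category ordering; pain duration is ordinal by design, and the
  NS-SEC three-class job variable is treated as ordered on the same latent
  scale — an approximation we accept in exchange for a one-dimensional
  latent representation;
* outcomes are included as variables of the joint model, so imputations
  condition on the outcome (the congeniality argument: the analysis model
  uses the outcome, so the imputation model must too).

Estimation is a Gibbs sampler with conjugate updates: truncated-normal
draws for latent cells, Gaussian draws for missing cells and study effects,
and inverse-Wishart draws for $\Sigma$ (prior $IW(q+2, I)$) and $\Psi$
(prior $IW(q+2, 0.1I)$).  An inverse-Wishart prior on $\Psi$ keeps every
update conjugate; a half-Gaussian prior on the random-effect SDs would be a
natural alternative but breaks conjugacy, and with weakly informative
scales the two give similar imputations at these study counts.  A
non-positive-definite working covariance triggers a jittered restart, with
a logged message.  Defaults are $m = 10$ imputations, 1000 burn-in
iterations and thinning of 100; completed data sets copy every observed
cell bit-exactly and fill only the masked cells (bounded scores are rounded
and clipped to 0-10).

Systematically missing predictors are identified through the random-effect
distribution: the unrecorded study's mean for that variable is drawn from
$\Psi$ conditional on its other variables, i.e. information is borrowed
across studies.  A predictor observed in no study at all is unidentifiable
and raises an error.

Imputation runs once on the full stack before IECV by default; a
`reimpute_per_cycle`-style sensitivity analysis can be assembled from the
module functions, but the default mirrors a single imputation step ahead of
validation.  Supporting checks are `missingness_diagnostics()` (logistic
regressions of each missingness indicator on the other predictors, to
surface missing-at-random violations) and `imputation_consistency()`
(imputed-vs-observed summaries and standardized differences per predictor,
study and imputation, with plot-ready histogram tables).

# Minimum sample size

`riley_max_parameters()` evaluates the standard minimum-sample-size
criteria for prediction models.  Binary outcomes: (1) expected uniform
shrinkage at least $S$ via $n = p/((S-1)\ln(1-R^2_{CS}/S))$; (2) small
optimism in Nagelkerke $R^2$, the same formula with
$S = R^2_{CS}/(R^2_{CS}+0.05\,R^2_{CS,\max})$; (3) precise overall risk,
$n \ge (1.96/0.05)^2\phi(1-\phi)$.  Continuous outcomes use the shrinkage
criterion, the adjusted-$R^2$ optimism bound
$n \ge p(1-R^2)/0.05 + p + 1$, and $n \ge 234 + p$ for a precise residual
variance.  Anticipated $R^2_{CS}$ and the shrinkage target are inputs, not
constants, because the anticipated values behind the published allowance
are not recoverable from the publication.

# The synthetic multi-study generator

No IPD are distributable, so the package ships a generator
(`generate_multistudy()`) whose **defaults are the study conditions** every
simulation and test uses:

* five studies sized 214 / 747 / 432 / 232 / 554 (total 2179) for the
  6-month roster, three (432 / 232 / 554) for presenteeism and two
  (70 / 338) for the 12-month roster;
* per-study predictor marginals taken from the published population
  summaries: age as a Gaussian truncated to the working-age range 16-75;
  pain and presenteeism scores as Gaussians matched to the reported medians
  and quartiles (SD = IQR/1.349), rounded and clipped to 0-10; categorical
  proportions as printed, renormalised where a study's breakdown does not
  sum to one because of missing recording;
* where a study never recorded a predictor, the pooled value is used
  (prior absence 0.30 for the two non-recording studies, within the
  reported 28-40% range); "any comorbidity" is derived from the reported
  component conditions assuming independence (union probability), giving
  0.44-0.65 by study;
* outcomes drawn from a stored coefficient set (`published_truth()`): a
  Bernoulli draw on the inverse-logit linear predictor, or a Gaussian draw
  (assumed residual SD 2.5, consistent with the spread of observed 6-month
  presenteeism given the predictors) clipped to 0-10 with the clipping
  fraction recorded;
* study intercepts drawn as $N(0, \sigma_u^2)$ with $\sigma_u$ from the
  stored model (0.794 for 6-month absence), each study generated under a
  derived sub-seed so output is byte-identical for a fixed seed.

Missingness is layered on separately (`apply_missingness()`): sporadic
MCAR, sporadic MAR driven by an observed predictor with a calibrated
logistic intercept, and systematic (study, predictor) pairs.

**What the generator does not emulate.**  Predictors are sampled
independently by default — the publication reports no inter-predictor
correlations — with a Gaussian-copula hook for sensitivity analyses; score
distributions are symmetric around the median where the real ones are
skewed; study-specific outcome models beyond a random intercept are not
represented; trial interventions, cluster randomisation and loss to
follow-up are out of scope.  One visible consequence: the frozen 6-month
scorer's mean predicted risk on synthetic cohorts (about 0.19) exceeds the
real development prevalence (215/2179 = 0.099), because the printed
marginal means combined with the published coefficients already imply a
mean linear predictor around -1.9, and no correlation structure can lower
the mean risk below the inverse-logit of that mean.  Passing simulation
tests therefore demonstrates the *pipeline's* statistical properties
(recovery, calibration self-consistency, shrinkage behaviour), not that
the synthetic cohorts reproduce the real joint distribution.

# Frozen published scorers

`load_published_model()` returns the three published coefficient sets as
strict scorers.  The stored coefficients are treated as final
(post-shrinkage) values, because the constants and random-effect terms were
re-estimated after the optimism adjustment; a loader flag supports the
alternative reading (multiplying by the stored shrinkage) for sensitivity
analysis.  `predict_risk()` scores only complete, in-range profiles (labels
or integer codes for categorical predictors), warns when age falls outside
the 16-75 development range, clips presenteeism predictions to the 0-10
instrument and flags the clip.  The 12-month model always carries its
caveat: developed below the minimum sample size, poorly calibrated on
validation, and not ready for practice.

# Numerical choices

* Design matrices are standardised inside `fit_multilevel()` and estimates
  (with their covariance) back-transformed exactly; this removes
  scale-induced convergence warnings at large n without changing the model.
* Coefficients larger than 15 on the standardised scale trigger a
  complete-separation error naming the term; a non-zero optimiser code is
  an error carrying the optimiser messages.
* Identical meta-analysis inputs return $\tau^2 = 0$ exactly (the REML
  iteration is bypassed); metafor's informational "Fisher scoring" warning
  about flat profiles is muffled.
* Rubin pooling uses Barnard-Rubin degrees of freedom, with $B = 0$ mapped
  to infinite df; pooled C-statistics are back-transformed from the logit
  scale and therefore always lie in (0, 1).
* Model JSON is written with 17 significant digits so round trips are
  bit-exact.

# Problem sizes used by the validation suite

The shipped test-suite checks run at sizes chosen to keep Monte-Carlo error
well inside each tolerance: parameter recovery and IECV self-consistency on
one five-study stack of total n = 20,000 (between-study SD 0.794, fixed
seed); shrinkage behaviour on stacks of total n = 500 / 2,000 / 8,000 /
32,000 with 10 / 6 / 4 / 3 replicate seeds; imputation validity on six
replicates of n = 5,000 with m = 5 imputations (burn-in 200, thinning 20
for sporadic MCAR, which mixes quickly; burn-in 800, thinning 40 for the
systematically-missing recovery run, whose study-level component is weakly
identified and mixes slowly); degenerate-case agreement on n = 20,000.  The acceptance script reruns development, IECV,
imputation and scoring end-to-end at n = 10,000 / 5,000 / 3,000 under a
caller-supplied seed.  Where a check's condition is a five-study draw
(the between-study SD estimate, the pooled CITL and O/E), its sampling
spread is dominated by the five realised study intercepts, so individual
seeds can legitimately fall outside narrow bands even under a correct
implementation; the suite documents rather than hides this.

# Known limitations

* The latent-normal imputation model approximates the four-level duration
  and three-level job variables with fixed-threshold latent normals; with
  strongly non-normal category profiles the imputed distribution can be
  mildly distorted.
* The heuristic shrinkage factor is a global multiplier; penalised or
  Bayesian alternatives are out of scope.
* Meta-analysis is of performance statistics only; no meta-regression on
  study-level covariates.
* The generator's marginals-only realism means absolute risk levels in
  synthetic cohorts differ from the development data (see above); relative
  and calibration properties are unaffected.
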