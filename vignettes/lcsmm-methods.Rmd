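---
title: "Trajectory mixtures of depressive symptoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory mixtures of depressive symptoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcsmm)
```

# The scientific problem

Longitudinal panels of depressive-symptom sum scores (here: the PHQ-9,
nine items scored 0–3, sum 0–27, with the conventional cutoffs at
5/10/15/20) typically show modest *average* change over time while hiding
sharply different individual courses: stable low symptoms, stable high
symptoms, deterioration, and shock-then-recovery patterns. `lcsmm`
implements the modeling chain used to separate such courses in a
nine-wave general-population panel observed over two years:

1. a **latent change score model** (LCSM) for population-level change,
2. its finite-mixture extension (**LCSMM**) in which discrete latent
   classes carry all systematic between-person variability,
3. **class enumeration** diagnostics over a range of class counts,
4. **bias-adjusted 3-step** regressions linking the latent classes to
   baseline covariates and to binary end-of-study outcomes.

A synthetic-cohort generator reproduces the statistical structure this
chain assumes, so every stage can be exercised, tested, and powered
without access to individual-level data.

# The latent change score model

For waves $t = 1, \dots, T$ the true score of subject $i$ evolves as
$\eta_{it} = \eta_{i,t-1} + \delta\eta_{it}$, and the observed score is
$y_{it} = \eta_{it} + \varepsilon_{it}$ with
$\varepsilon_{it} \sim N(0, \theta_t)$. Collecting the latents
$(\eta_{i1}, \delta\eta_{i2}, \dots, \delta\eta_{iT})$ with mean vector
$\mu_\eta$ and covariance $\Psi$, the implied observed moments are

$$\mathrm{E}(y) = L\mu_\eta, \qquad \mathrm{Cov}(y) = L \Psi L^\top + \Theta,$$

where $L$ is the lower-triangular cumulative-sum loading matrix and
$\Theta = \mathrm{diag}(\theta_t)$. The wave-$t$ mean is therefore the
initial-level mean plus the cumulative sum of the change means — the
arithmetic that `class_mean_curve()` exposes directly.

`lcsm_spec()` makes every structural choice explicit: which latent means
and variances are free, whether the level–change and change–change
covariances are estimated or fixed to zero, and whether residual
variances are constant or wave-specific. The default is a parsimonious
growth-type specification (free means, free latent variances, zero
latent covariances, constant residual variance). We deliberately expose
the specification rather than hard-coding one: published applications of
this model family rarely report enough detail to pin down the exact
free-parameter set, and reasonable choices differ in degrees of freedom.

Estimation maximizes the **full-information** Gaussian likelihood: each
subject contributes the density of exactly their observed waves, so
records with partially missing data are retained rather than dropped.
Fit indices (chi-square, RMSEA with 90% CI, CFI, TLI, SRMR) are computed
against a saturated model — free mean vector and covariance matrix,
fitted by the standard EM for the multivariate normal under the same
missing-data likelihood — and an independence baseline with closed-form
per-wave MLEs. The RMSEA interval inverts the noncentral chi-square
distribution in its noncentrality parameter by bisection (tolerance
1e-8); RMSEA uses the $n - 1$ convention; SRMR is the root mean square
of standardized covariance residuals.

# The mixture extension

The LCSMM replaces graded individual differences with $K$ discrete
classes: within a class the latent variance is fixed to zero, so each
class is a prototypical mean trajectory $\mu_c$ (built by cumulative
summation of class-specific $\eta_{t1}, \delta\eta_t$ means) plus
independent residual noise $\theta_{ct}$. The observed-data likelihood is

$$\ell = \sum_i \log \sum_{c=1}^{K} \pi_c \prod_{t \in \mathrm{obs}(i)}
N(y_{it};\, \mu_{ct},\, \theta_{ct}),$$

computed with log-sum-exp stabilization. The E-step yields posterior
responsibilities; the M-step is closed form (responsibility-weighted
means of observed wave scores per class, differenced to recover
$\eta/\delta\eta$; responsibility-weighted residual mean squares under
the chosen variance tying). The likelihood is non-decreasing at every
iteration, which `em_control(debug = TRUE)` asserts.

Key estimation choices, all tunable through `em_control()`:

* **Residual-variance tying** — default class-specific and
  time-constant (`"class"`), since in this model family all estimated
  parameters are conventionally class-specific; `"class_wave"` and
  `"global"` are available. Variances are floored at `1e-3` to prevent
  degenerate likelihood spikes at collapsing classes.
* **Multi-start protocol** — default 50 random starts seeded from
  observed subject trajectories spread k-means++-style in trajectory
  space, 40-iteration exploratory runs, the best 10 refined to full
  convergence (relative log-likelihood change below `1e-8`, at most 1000
  iterations). The best refined log-likelihood must be matched within
  `1e-3` by at least one other start, otherwise the fit warns that the
  solution did not replicate: non-replicated solutions should not be
  interpreted.
* **Empty classes** — an initialization whose class receives less than
  one subject of responsibility mass is redrawn (up to 3 times) rather
  than silently dropping a class.
* **Label switching** — the likelihood is invariant to permuting class
  labels; `align_labels()` resolves this by exact optimal assignment
  (total squared distance between class mean curves, enumeration up to
  K = 8).
* **Determinism** — all randomness flows through the single seed in
  `em_control()`/`generator_config()`; refitting with the same seeds
  reproduces results bit-for-bit.

Standard errors (`mixture_se()`) invert the numerically evaluated
observed information at the ML solution, with variances on the log scale
and proportions on the multinomial-logit scale, mapped back by the delta
method. They do not account for model misspecification.

# Class enumeration

`enumerate_classes()` fits $K = 1, \dots, K_{max}$ with the full
multi-start protocol and reports, per $K$: the best log-likelihood and
whether it replicated, AIC, BIC, and the sample-size-adjusted BIC
(penalty $\log((n+2)/24)$ per parameter), relative entropy

$$E = 1 - \frac{-\sum_i \sum_c p_{ic} \ln p_{ic}}{n \ln K},$$

the smallest class proportion against a minimum-size threshold (default
5%), and IC first differences (the scree). In large samples ICs keep
decreasing as classes are added, so the report highlights — but never
applies — the "diminishing returns" point: the smallest $K$ after which
every later BIC improvement falls below a configurable fraction (default
20%) of the largest drop. Final selection also requires substantive
judgement about whether added classes capture clinically meaningful
differences, which no program can automate; the report is
decision support, not a decision.

# Bias-adjusted 3-step analyses

Relating classes to external variables by simply regressing on modal
assignments is biased toward the null whenever classification is
imperfect, and including covariates directly in the mixture lets them
redefine the classes. The 3-step approach avoids both: (1) fit the
unconditional mixture; (2) assign classes (modal by default; a
proportional pseudo-draw variant is provided) and quantify assignment
error as
$Q_{ks} = \Pr(\text{assigned } s \mid \text{true } k)$, estimated by
$\sum_i p_{ik} 1[a_i = s] / \sum_i p_{ik}$; (3) fit the external model
with the assignment entering through $Q$:

* **Membership regression** (`step3_multinomial()`): maximizes
  $\sum_i \log \sum_k P(X = k \mid z_i; \gamma)\, Q_{k, a_i}$ over
  multinomial-logit coefficients, reference class fixed. BFGS with
  analytic gradients plus Newton polishing; with $Q = I$ this reduces
  exactly to ordinary multinomial logistic regression. Predictors enter
  jointly by default; a univariable mode fits one model per predictor,
  since either convention appears in applied reports. Subjects missing a
  covariate are dropped listwise with a reported count.
* **Distal outcomes** (`step3_distal()`): maximizes
  $\sum_i \log \sum_k \pi_k\, \rho_k^{y_i} (1-\rho_k)^{1-y_i} Q_{k, a_i}$
  by EM, giving class-specific outcome probabilities with
  observed-information Wald intervals on the logit scale.

Step-3 standard errors treat the step-1 posterior (and hence $Q$) as
known — the standard limitation of the method; they do not propagate
step-1 sampling uncertainty.

# The synthetic cohort generator

`generator_config()` encodes, as defaults, the conditions of a nine-wave
pandemic-period depression panel of $n = 4361$ adults with five
trajectory classes:

* **Trajectory means** — class-specific initial levels and eight latent
  change means; e.g. the mild-deterioration class starts at 5.99 and
  accumulates +2.77 points to end at 8.76, while the shock-to-resilience
  class starts at 17.33 and drops by 13.50 within the first interval.
* **Mixing proportions** — 6.77 / 8.50 / 29.04 / 13.17 / 42.52 percent
  for the strong-deterioration, consistently-high, mild-deterioration,
  shock-to-resilience, and consistent-resilience classes.
* **Covariate-driven membership** — eleven baseline covariates with
  published odds-ratio effects (log-OR coefficients) on membership
  relative to the consistent-resilience reference class; intercepts are
  calibrated by `calibrate_intercepts()` (fixed-point iteration on a
  200,000-draw Monte-Carlo covariate sample, deterministic internal
  seed) so the marginal class probabilities hit the target proportions
  within 0.005 despite the covariate effects.
* **Covariate marginals** — sex, age bands, education, relationship,
  ethnic-minority status, and preexisting-diagnosis rates follow the
  published demographic table of that cohort; rates not published
  (living alone 0.20, binge drinking 0.05, binomial models for the
  0–7/0–6 frequency scales) are fixed package defaults chosen to be
  realistic for a general adult population. Covariates are drawn
  independently: the joint distribution is not published, and the
  membership model only requires the marginals to be right.
* **Retention** — per-wave observation probabilities from the published
  wave coverage (4361 at intake down to 1110–2239 later), intermittent
  (the final wave exceeds the one before it), missing completely at
  random by default, matching the absence of systematic attrition in the
  source cohort; a missing-at-random hook (`mar_slope`) makes dropout
  depend on the current score for robustness studies.
* **Distal outcomes** — class-specific Bernoulli probabilities for
  end-of-study treatment seeking and diagnosis, ordered strong
  deterioration > mild deterioration > consistently high > the two
  resilient classes. The exact values are package defaults (the source
  figures are not printed as numbers) and fully configurable. Outcomes
  are observed only for subjects present at the final wave, as in a real
  panel.
* **Residual noise** — a single time- and class-constant SD, default
  **4.6**. This value was fixed once by calibration: it is the value at
  which the five-class fit to a large default cohort separates classes
  with relative entropy of about 0.71, the level reported for this model
  family on comparable data, and it is committed as a constant rather
  than re-tuned.

Scores are rounded and clipped to the integer 0–27 scale by default.
This realism has a known modeling cost: the consistent-resilience class
has mean scores near 3, so with residual SD 4.6 roughly a quarter of its
score mass clips at 0. A Gaussian mixture fitted to such data absorbs
the clipping by shrinking that class's variance and shifting the
boundary toward the adjacent mild-deterioration class, moving fitted
proportions by several percentage points and biasing the recovered
shock-to-resilience first change score by more than half a point.
`integer_scores = FALSE` switches the generator to the continuous scale
for clean parameter-recovery experiments, where the fitted family
matches the generating process exactly; the package's recovery tests and
the acceptance script use this switch, and the residual-SD calibration
was performed under the same conditions. Passing recovery tests on the
continuous scale therefore demonstrates correctness of the estimator,
not robustness to scale coarsening — the integer-scale default is the
honest stress test, and the discrepancy it induces is a feature of real
sum-score data that users should expect.

## What the generator does and does not emulate

The generator reproduces: class-conditional Gaussian trajectories built
from cumulative change means, covariate-dependent class membership with
realistic effect sizes, non-monotone MCAR wave coverage, class-dependent
binary outcomes observed at the final wave, and an attention-check
failure rate of 2.2%. It does not emulate: recruitment or sampling bias,
poststratification weighting, regional structure, covariate
correlations, item-level measurement (only sum scores are modeled),
within-class continuous heterogeneity, or measurement non-invariance.
Results on synthetic cohorts speak to the estimator under the stated
assumptions, not to the robustness of the original substantive findings.

# Problem sizes and runtime choices

The package's test suite exercises full-scale recovery (one cohort of
n = 4361 with the complete 50-start protocol, about half a minute) and
scales everything else down: property tests use two-class configurations
with a few hundred subjects, enumeration trend checks use 5 replicates,
coverage checks 20 replicates, and Monte-Carlo oracles 200,000 draws
(tolerances widened proportionally to the larger Monte-Carlo error,
e.g. the contingency-table odds-ratio check uses 0.08 on the log scale
at 200,000 draws where 0.05 would suit a million). These sizes are the
package's own trade-off between statistical resolution and a test suite
that stays fast enough to run on every change.

# Known limitations

* The LCSM spec cannot express a fully saturated latent structure; fit
  indices always compare against the separately fitted saturated model.
* `align_labels()` enumerates permutations and is limited to K ≤ 8.
* Step-3 intervals ignore step-1 uncertainty (see above).
* The within-class zero-variance restriction means classes absorb *all*
  systematic heterogeneity; mixtures with free within-class variances
  (growth mixture models) are a possible extension, not provided here.
* Observed-information SEs for the mixture require a full numerical
  Hessian and are intended for final models, not for use inside loops.
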