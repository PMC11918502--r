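# lcsmm

Latent change score mixture models for longitudinal symptom panels.

`lcsmm` is for epidemiologists and clinical researchers who follow a
cohort's symptom sum-scores (such as the PHQ-9, 0–27) across repeated
waves and want to know *who* changed, not just whether the average did.
It implements:

* the **latent change score model** (LCSM): each wave's true score is
  the previous true score plus a latent change, observed with error, so
  the implied wave means are cumulative sums,
  `E(y_t) = η_t1 + Σ_{s≤t} δη_s`, and the implied covariance is
  `L Ψ Lᵀ + Θ` for the cumulative-sum loading matrix `L` — fitted by
  full-information maximum likelihood with SEM fit indices (RMSEA with
  90% CI, CFI, TLI, SRMR);
* the **mixture extension** (LCSMM): `K` discrete trajectory classes
  carry all systematic between-person variability (within-class latent
  variance fixed to zero), estimated by multi-start EM on
  `Σ_i log Σ_c π_c Π_{t observed} N(y_it; μ_ct, θ_ct)`, retaining
  subjects with partially missing waves;
* **class enumeration** reports (AIC/BIC/aBIC scree, relative entropy,
  5% minimum class size, log-likelihood replication across starts);
* **bias-adjusted 3-step** analyses: multinomial regression of class
  membership on covariates and class-specific distal-outcome
  probabilities, both weighted by the classification-error matrix
  `Q[k,s] = P(assigned s | true k)` so imperfect class separation does
  not attenuate the external relationships;
* a **synthetic-cohort generator** whose defaults reproduce the
  structure of a nine-wave, two-year pandemic-period depression panel
  (n = 4361, five classes from 6.8% strong deterioration to 42.5%
  consistent resilience, covariate-driven membership, non-monotone
  retention, class-dependent end-of-study outcomes).

## Worked example

Simulate a cohort, fit the five-class model, align labels to the
generating classes, and relate the classes to covariates and an
end-of-study outcome:

```r
library(lcsmm)

cfg <- generator_config(n = 1200, seed = 2024)
sim <- generate_cohort(cfg)
sim$data
#> panel_dataset: 1200 subjects x 9 waves (T1..T9)
#>   observed cells: 4898 of 10800 (45.4%)
#>   covariates: age_band, sex, living_alone, relationship, education, ...
#>   outcomes: treatment_seeking, diagnosis_T9

fit <- em_fit(sim$data, 5, em_control(n_starts = 20, refine_top = 5, seed = 1))
fit <- permute_classes(fit, align_labels(fit$params,
         t(sapply(1:5, class_mean_curve, config = cfg))))
fit
#> fitted_mixture: K = 5, n = 1200, logLik = -14947.28 (54 parameters)
#>   AIC 30002.6 | BIC 30277.4 | aBIC 30105.9 | entropy 0.734
#>   converged: TRUE | best LL replicated: TRUE
#>   class proportions: 0.0680, 0.1060, 0.3573, 0.1170, 0.3517
```

The proportions sit near the generating 0.0677 / 0.0850 / 0.2904 /
0.1317 / 0.4252 (classes: strong deterioration, consistently high, mild
deterioration, shock-to-resilience, consistent resilience), and entropy
0.734 says classification is informative but not clean — exactly the
regime in which the 3-step corrections below matter.

```r
asn <- modal_assignment(fit$posterior)
ct  <- classification_errors(fit$posterior, asn$assignments)
m3  <- step3_multinomial(asn$assignments, ct$Q, sim$data$covariates,
                         reference = 5)
m3$table[m3$table$predictor == "living_alone", ]
#>     predictor class      coef        se       or  ci_lower ci_upper     p_value
#>  living_alone     1 0.9946747 0.3578912 2.703845 1.3407217 5.452866 0.005448188
#>  living_alone     2 0.8993587 0.3891258 2.458026 1.1464522 5.270078 0.020820233
#>  living_alone     3 0.6065065 0.2718239 1.834013 1.0765178 3.124522 0.025664744
#>  living_alone     4 0.5236407 0.3728948 1.688163 0.8128302 3.506136 0.160241831
```

Living alone roughly doubles to triples the odds of the deteriorating
and consistently-high classes relative to consistent resilience
(generating odds ratios 2.98 / 3.13 / 2.36 / 2.03). Class-specific
probabilities of seeking treatment at the end of the study:

```r
step3_distal(asn$assignments, ct$Q, sim$data$outcomes$treatment_seeking)
#> three_step_result (distal outcome): 370 subjects used, 830 dropped
#>  class   prob ci_lower ci_upper
#>      1 0.3864   0.1628   0.6709
#>      2 0.3432   0.1719   0.5680
#>      3 0.1910   0.1220   0.2862
#>      4 0.1228   0.0464   0.2869
#>      5 0.0234   0.0026   0.1807
```

The deteriorating classes carry the highest treatment-seeking
probabilities; subjects unobserved at the final wave have no outcome and
are excluded with a reported count.

`full_pipeline(run_config(...))` chains all stages (simulate or load →
enumerate → fit → 3-step) and writes each stage's artifact as a CSV.

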