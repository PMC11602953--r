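---
title: "Reference-base centred imputation for retrieved dropout data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-base centred imputation for retrieved dropout data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdrcmi)
```

## The estimation problem

In a longitudinal trial analysed under a treatment-policy strategy, the
estimand compares randomised arms at the final visit regardless of whether
patients stayed on treatment. Patients who withdraw from randomised
treatment at visit $D$ ("deviation") may continue to be observed off
treatment up to a last study visit $S \ge D$ — the *retrieved dropout*
data — or may leave the study, creating genuinely missing off-treatment
outcomes. Two families of methods exist for the missing part:

* **Reference-based imputation (RBI)** borrows the mean structure of a
  reference arm (e.g. jump-to-reference, J2R) and typically ignores the
  observed off-treatment data during imputation, merging them back
  afterwards. It makes a strong assumption and uses none of the
  off-treatment evidence when forming the imputation model.
* **Retrieved dropout (compliance-model) imputation** models the observed
  off-treatment outcomes directly, with means indexed by arm, visit and
  on/off status. It is assumption-light but breaks down whenever a
  stratum of deviators has no observed off-treatment data at all — a
  *perforated* layout — because the corresponding mean parameters are
  non-estimable.

This package implements the combination of the two: the compliance model
is re-parameterised so that its off-treatment means are written as a
reference-based *core* mean plus *deviation* parameters, and the deviation
parameters receive mildly informative zero-centred Gaussian priors. With
little observed off-treatment data the posterior stays near the core
(RBI-like behaviour, with honest extra uncertainty); with plenty of
off-treatment data the likelihood overwhelms the priors and the fit
approaches the unpenalised compliance model. Perforated strata are no
longer a failure mode: their deviation parameters simply keep their prior.

## Model

Outcomes $Y_{i1},\dots,Y_{iJ}$ (here change from baseline) follow a
multivariate normal with unstructured covariance $\Sigma$ (optionally one
per arm). With $\mu_{tj}$ the on-treatment mean for arm $t$ at visit $j$
and $k = D_i$ the deviation visit, the core model states the off-treatment
mean for $j > k$:

| core | off-treatment mean |
|------|--------------------|
| J2R | $\mu_{0j}$ |
| CIR | $\mu_{0j} + \mu_{tk} - \mu_{0k}$ |
| CR  | $\mu_{0j}$ on the cells imputed here (coincides with J2R: the on-treatment cells CR would also replace are observed) |
| LMCF | $\mu_{tk}$ |
| RTB | the baseline mean (pooled or within arm) |
| MAR | $\mu_{tj}$ |
| MAR + $\delta$ | $\mu_{tj} + \delta_t(j-k)$ |

The extended model adds, on off-treatment cells only, compliance-model
deviation terms: one coefficient per arm-and-visit under the *current*
model ($\alpha^*_{tj}$, on/off status only), or one per
arm-deviation-visit-and-visit cell under the *historic* model
($\gamma^*_{tkj}$). In model-formula notation the complete design is
`J2R*Visit + OffT*Trt*Visit*Pattern + Baseline*Visit*Trt`, where `OffT`
is the quantitative on/off indicator and `Pattern` the running
deviation pattern. The deviation block is identically zero while a
patient is on treatment, so the on-treatment fit always reduces to the
$\mu_{tj}$ structure.

**Nesting.** The diffuse-prior limit must recover the chosen compliance
model, which requires the core to be nested within it: a core whose
off-treatment mean depends on the deviation visit $k$ (CIR, LMCF, MAR +
$\delta$ with nonzero $\delta$) cannot be absorbed by the *current*
model's deviation terms, which are shared across $k$. `check_nesting()`
tests this numerically — each on-treatment mean parameter's footprint on
the off-treatment cells, and any fixed core constant, is projected onto
the deviation columns and the residual compared against a relative
tolerance of $10^{-8}$ — and `build_design()` refuses violating
combinations. History-free cores (J2R/CR, MAR, RTB) pass with both
compliance models.

**Priors.** Core and baseline coefficients get independent zero-mean
normals with variance $10^6 \times$ the sample outcome variance —
effectively flat but proper, keeping every full conditional conjugate.
Deviation coefficients get variance $v$ (outcome units squared), zero
mean, optionally with correlation `adjacent_corr` between visit-adjacent
coefficients within an arm-by-deviation-visit group (deviations at
neighbouring visits plausibly point the same way; values up to about 0.5
are reasonable). $\Sigma$ gets an inverse-Wishart prior with $J+2$
degrees of freedom and identity-times-sample-variance scale, the weakest
proper conjugate choice.

**Choosing $v$.** The default (`default_prior_variance`, route
`mmrm_residual`) is the final-visit diagonal element of the unstructured
covariance from an MMRM fit (via `nlme::gls`, REML, `corSymm` +
per-visit variance weights) to the on-treatment data: a zero-centred
prior with that variance adds roughly one patient-visit worth of
likelihood in favour of the core model. A cruder alternative (`range`)
squares one sixth of the observed final-visit range. Whether the
published analyses derived their value from the marginal final-visit
variance or a baseline-adjusted residual variance is not stated; we use
the baseline-adjusted MMRM fit as the default and expose both routes.

## Fitting and imputation

`gibbs_fit_impute()` runs a conjugate Gibbs sampler. One sweep draws
(i) every missing cell from its conditional normal given the patient's
observed cells, grouped by missingness pattern for speed; (ii) the
coefficient vector from its multivariate-normal full conditional;
(iii) $\Sigma$ from its inverse-Wishart full conditional. All draws are
direct, so serial correlation of the parameters informed by data is
minimal and `thin = 1` is the default. The stored missing-cell draws
*are* the imputations (parameter estimation and imputation models are
identical), so `K` stored sweeps give `K` completed datasets with all
observed values preserved bit-for-bit. Each is analysed by the minimal
treatment-policy ANCOVA (final-visit outcome on arm and baseline) and
pooled by Rubin's rules with Barnard–Rubin small-sample degrees of
freedom against the complete-data $n-3$ (the published account cites
Rubin's rules without naming a df rule; trial sizes here are modest, so
the small-sample form is the safer default and second-decimal
differences in standard errors between df rules are possible). The
Monte Carlo standard error of the pooled estimate is reported as
$\sqrt{B/K}$.

Numerical choices worth noting:

* **Initialisation** comes from the on-treatment MMRM fit (deviation
  coefficients at zero, missing cells at conditional means); if `gls`
  fails to converge on a degenerate input, moment-based estimates
  (per-cell means, pairwise-complete residual covariance ridged to
  positive definiteness) stand in.
* **Baseline centring.** The baseline covariate enters the design centred
  at its overall mean. With an uncentred baseline, the J2R mean for an
  active deviator combines the reference-arm *intercept at baseline zero*
  with the active-arm baseline slope — an extrapolation of many baseline
  units that inflates imputed values dramatically whenever the two arms'
  slope estimates differ by noise. Centring removes the extrapolation:
  the implied off-treatment mean becomes the reference cell mean at the
  average baseline plus the patient's own-arm slope times their baseline
  deviation, while the on-treatment model space is unchanged.
* **The $v \to 0$ limit** (`pin_deviation = TRUE`) is implemented by
  dropping the deviation columns, not by a tiny variance, avoiding
  conditioning problems. Combined with `include_off_treatment = FALSE`
  (off-treatment observations masked from the likelihood and analysed as
  imputed) it reproduces classic RBI exactly: `run_classic_rbi()`
  assembles that configuration independently and the two paths yield
  bit-identical chains under the same seed.
* **Degenerate draws** are handled by escalating jitter on failed
  Cholesky factorisations, with a hard failure after a bounded number of
  retries.
* **Reproducibility**: one root seed drives a single R RNG stream;
  identical configurations give bit-identical draws.
* **Never-observed deviation cells** are kept in the design and reported
  (`never_observed`); their posterior equals their prior, which is
  exactly the mechanism that keeps perforated layouts estimable. Their
  draws mix more slowly than everything else (the only information loop
  runs through the imputed cells; lag-one autocorrelation near 0.9), so
  posterior summaries of those particular coefficients deserve thinning.
* **Missing baseline** is an error by design: the model conditions on
  baseline throughout. Interim (pre-$S$) missing outcomes are fine and
  are drawn under MAR inside the sampler; observations after an explicit
  last study visit are rejected as inconsistent.

## The one-visit calculator

For the single-visit two-arm setting, `bias_rmse()` computes the exact
bias and RMSE of the infinite-imputation point estimate. Each arm splits
into observed-on, observed-off and missing groups; the missing group
shares the off-treatment mean. The centred model sets
$\mu_{\text{off},t} = \mu_{\text{on},0} + \gamma_t$ with
$\gamma_t \sim N(0, \sigma^2/\rho)$, $\rho$ the prior precision relative
to the residual precision ("number of extra patients' worth of
information"), $\sigma^2$ known and fixed at 1 in the published runs —
the calculator targets those exact curves, whereas the Gibbs engine
samples $\Sigma$.

Conditional on the group counts, the posterior mean of
$(\mu_{\text{on},0}, \gamma_0, \gamma_1)$ is a $3\times3$ linear solve
with closed-form solution; the treatment-policy estimate is then linear
in the four independent Gaussian group means, so its conditional bias
and MSE are exact. `bias_rmse()` sums these over the joint binomial
distribution of deviation and missingness counts by full enumeration
(patterns below $10^{-13}$ joint probability are dropped; the mass lost
is far below double precision of the reported numbers).
Two posterior conventions are provided:

* `joint` (default): the reference on-treatment mean is estimated
  jointly from all groups that carry information on it, including both
  arms' observed off-treatment data — this matches the actual Bayesian
  model, where the mild priors feed a little off-treatment information
  back into $\mu$.
* `plugin`: the shrinkage is centred on the reference arm's on-treatment
  mean alone.

The two differ only in fine detail, but the detail is instructive: under
`plugin`, a scenario that is symmetric in the two arms has *exactly* zero
bias at every $\rho$, and swapping arm labels negates the bias exactly.
Under `joint` the reference arm is privileged, so those symmetries hold
only approximately (at the $10^{-4}$ scale for the symmetric no-effect
scenario, versus an RMSE of about 0.15). Tests assert exactness for
`plugin` and the approximate version for `joint`. `mc_oracle()`
validates the enumeration by brute-force simulation of whole trials with
the same estimator.

The four named scenarios (`scenario_preset`) use means
$(\mu_{\text{off},0}, \mu_{\text{on},0}, \mu_{\text{off},1},
\mu_{\text{on},1})$ of $(1,1,1,1)$, $(1,2,1,2)$, $(1,1,1,2)$ and
$(1,1,2,2)$, with $\gamma_t = \mu_{\text{off},t} - \mu_{\text{on},0}$
derived from the means — for the effect-under-deviation scenario that
gives $\gamma = (0, 1)$, the nonzero $\gamma_1$ being what drives the
bias growth as the prior gains precision.

## What the synthetic generator emulates

`generate_trial()` draws full multivariate-normal trajectories, assigns
the deviation visit by a per-arm discrete hazard (independent of the
residuals by default — deviation completely at random, the setting the
analytic calculator assumes), applies an off-treatment truth rule
(jump to the reference profile, track parallel to it, stay on the
on-treatment profile, or a custom deviation table), then has each
deviator either stop observation at deviation (probability `q_stop`) or
continue fully observed, mirroring the all-or-nothing layout of the
motivating public example data. The `example_trial` preset matches that
layout's scale: 88 + 84 patients, four visits, deviation hazards
calibrated to its visit-wise on-treatment counts, `q_stop = 0.5`, mean
declines of about one unit per visit under reference and two under
active, final-visit residual variance 40 (which is also why the default
prior variance lands near 40 on such data), baseline around 18 (SD 4)
with a mild negative per-visit effect. A perforation option forces
chosen arm-by-deviation-visit strata to have no observed off-treatment
data, and a `dnar_coef` toggle makes the hazard depend on the current
outcome for stress tests — outcome-dependent *withdrawal* is outside the
method's guarantee and is exactly what such tests probe. A
`partial_followup` mode generates patients with some but not all
off-treatment data ($D < S < J$); the published example files contain no
such patients, but the loader, design and sampler handle them, with
imputation conditioning on both on- and off-treatment observations.

What the generator does **not** emulate: site effects or any covariate
beyond one baseline, irregular visit times, outcome-dependent study
withdrawal beyond the DNAR toggle, non-Gaussian outcomes, and
covariance switching at deviation. Passing tests on this generator
therefore demonstrate correctness of the machinery under the model's own
assumptions, not robustness of the method on real data.

## Study sizes used by the tests

The shipped checks run at deliberately modest sizes chosen to keep the
whole suite desk-scale while leaving Monte Carlo error well inside each
tolerance: trials of 50–80 patients per arm with a few hundred thinned
draws for the pipeline comparisons, 200 replicates of a 40-per-arm trial
for confidence-interval coverage (pass bound 93% for a nominal 95%),
$10^6$-replicate oracle runs for the analytic calculator, and a
60-sweep-per-draw thinned chain for the posterior-equals-prior check in
the perforated layout. The published analyses the package mirrors used
10,000 imputations for two-decimal stability; `K` is a configuration
knob, and the reported $\sqrt{B/K}$ tells you what your choice bought.

## Known limitations

* The `current` compliance model is available only with history-free
  cores, by construction (nesting).
* `full_pattern` compliance coincides with `historic` here because the
  deviation design exists only on off-treatment rows, where the running
  pattern equals the subject-level pattern; it is provided as an alias
  behind a flag.
* Covariance switching at deviation, per-reason core mixtures,
  non-Gaussian outcomes and imputation of the withdrawal process itself
  are out of scope.
* With grouped covariances and very small arms the inverse-Wishart
  updates can be poorly conditioned; the sampler jitters and ultimately
  errors rather than returning silently unstable results.
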