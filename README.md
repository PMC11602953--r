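# rdrcmi — retrieved dropout reference-base centred multiple imputation

`rdrcmi` estimates treatment-policy effects in two-arm longitudinal
trials with Gaussian outcomes when patients withdraw from randomised
treatment ("deviation") and some post-deviation outcomes are missing.
It is aimed at trial statisticians who would otherwise choose between
reference-based multiple imputation (strong assumptions, ignores the
observed off-treatment data during imputation) and retrieved dropout /
compliance-model imputation (assumption-light, but non-estimable when a
stratum of deviators has no observed off-treatment data — a "perforated"
layout).

## The model

Outcomes `Y_i1..Y_iJ` follow a repeated-measures multivariate normal
with unstructured covariance. On-treatment means are `mu[t, j]` (arm
`t`, visit `j`). For a patient off treatment after visit `k`, the
imputation mean at visit `j > k` is written as

    core(t, k, j)  +  deviation term

where the *core* is a reference-based rule — jump to reference
`mu[0, j]`, copy increments in reference `mu[0, j] + mu[t, k] - mu[0, k]`,
last mean carried forward, return to baseline, MAR, or MAR plus a fixed
per-visit delta — and the *deviation terms* complete a retrieved-dropout
compliance model (`current`: one per arm and visit; `historic`: one per
arm, deviation visit and visit). The deviation coefficients get mildly
informative zero-centred Gaussian priors with variance `v`; the core and
covariance get effectively flat conjugate priors. The whole design, in
model-formula notation, is
`J2R*Visit + OffT*Trt*Visit*Pattern + Baseline*Visit*Trt`.

With little observed off-treatment data the fit behaves like
reference-based imputation with honest extra uncertainty; with plenty it
approaches the unpenalised compliance model; perforated strata simply
keep their prior. A conjugate Gibbs sampler draws coefficients,
covariance and missing cells jointly; the stored missing-cell draws are
the `K` imputations, each analysed by final-visit ANCOVA (outcome on arm
and baseline) and pooled by Rubin's rules with Barnard–Rubin degrees of
freedom.

The package also ships an exact bias/RMSE calculator for the one-visit
setting (closed-form conditional moments integrated over the binomial
deviation/missingness patterns, with a Monte Carlo oracle) and a
synthetic trial generator with covered and perforated layouts.

## Worked example

```r
library(rdrcmi)

cfg   <- scenario_preset("example_trial")   # 88 + 84 patients, 4 visits
gt    <- generate_trial(cfg, seed = 2026)
trial <- gt$data
print(trial)
#> trial_data: 172 patients (88 reference, 84 active), 4 visits
#>   deviators: 34; missing outcome cells: 29 (4.2%)

pattern_summary(trial)$visit_counts
#>         arm visit on off_obs off_miss
#> 1 reference     1 88       0        0
#> 2 reference     2 82       3        3
#> 3 reference     3 79       5        4
#> 4 reference     4 71      10        7
#> 5    active     1 84       0        0
#> 6    active     2 81       1        2
#> 7    active     3 75       4        5
#> 8    active     4 67       9        8

v <- default_prior_variance(trial)   # final-visit MMRM residual variance
round(v, 1)
#> [1] 37

res <- run_rdrbc_mi(trial, core_spec("J2R"), compliance_spec("historic"),
                    v = v, gibbs = gibbs_config(n_burn = 500, n_draws = 200,
                                                seed = 1))
print(res)
#> MI treatment-policy difference: -3.534 (SE 1.026), K = 200
#>   95% CI [-5.561, -1.506], df = 147.8, p = 0.0007448, MC-SE 0.0237
```

The pooled difference estimates the treatment-policy contrast at the
final visit (negative = larger score reduction under active treatment);
the MC-SE line says how much of the reported precision is Monte Carlo
noise from `K = 200` imputations. The classic J2R comparator with
observed off-treatment data merged back gives `-3.286 (SE 0.993)` on the
same data, and the generating truth for this configuration is `-3.05` —
a single simulated trial scatters around it with SE about 1.

The one-visit calculator reproduces the prior-sensitivity analysis:

```r
bias_rmse(scenario_preset("effect_dcar"), rho = c(0.01, 1, 100))
#>     rho          bias      rmse coverage_mass
#> 1 1e-02 -0.0001054664 0.1685982             1
#> 2 1e+00 -0.0100004396 0.1664028             1
#> 3 1e+02 -0.1677050940 0.2155175             1
```

— when the core model is wrong (`gamma != 0`), bias grows as the prior
gains precision; `mc_oracle()` checks any of these numbers by brute
force.

A thin command-line wrapper over the same functions lives at
`inst/cli/rdrcmi.R` (`simulate`, `impute`, `compare`, `check-nesting`,
`bias-curve`).

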