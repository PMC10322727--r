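# dichobias

Complete-case logistic regression is famously robust to missing outcome
data: the exposure odds ratio is unbiased unless the log probability of
being a complete case depends on exposure, outcome *and* their
interaction. `dichobias` quantifies how that robustness fails when the
analysed binary outcome D is a dichotomised version of an underlying
continuous measure Y (a symptom score, blood glucose) and missingness
tracks the continuum — missing not at random — and how much of the
resulting bias multiple imputation with a misclassified proxy of the
outcome removes. It is aimed at biostatisticians and epidemiologists
studying missing-data mechanisms in cohort analyses with thresholded
outcomes.

## The model

- X ~ Bernoulli(π_X), Y | X = x ~ N(δx, 1), D = 1{Y > c} (or a logistic
  link in Y); (c, δ) are calibrated so that P(D = 1) and the
  full-population exposure log OR hit their targets (defaults 0.15 and
  0.405, i.e. OR 1.50, with π_X = 0.25).
- Selection model: P(R = 1 | y, x) = expit(γ₀ + γ_x x + γ_y y + γ_xy xy)
  (or a capped log link). The complete-case odds ratio is computed
  analytically from

  P(D = 1 | X = x, R = 1) = ∫ P(D=1|y) π(y,x) φ(y−μ_x) dy
                            / ∫ π(y,x) φ(y−μ_x) dy

  by adaptive quadrature, together with its bias against the
  full-population log OR.
- A binary auxiliary proxy A of D (sensitivity 25%/75%, specificity
  97.5%) feeds proper multiple imputation — chained equations when A is
  itself partially missing — pooled by Rubin's rules with the fraction
  of missing information.
- A factorial runner reproduces the full simulation study (20
  scenarios: % missing outcome × proxy sensitivity × interaction ×
  % missing proxy) and reports bias, empirical SE, Monte Carlo error,
  FMI and the precision gain of MI over complete case.

## Worked example

```r
library(dichobias)

pm <- calibrate_dichotomisation()   # prev 0.15, log OR 0.405, pi_x 0.25
pm
#> Latent-outcome population model
#>   P(X = 1) = 0.25;  Y | X ~ N(0 + 0.2241 X, 1)
#> Dichotomisation rule: threshold, D = 1(Y > 1.097)
#>   P(D=1|X=0) = 0.1362, P(D=1|X=1) = 0.1913, marginal = 0.1500
#>   full-population exposure log OR = 0.4050

# selection against high scorers, observation OR 0.75 per SD, 40% missing
ms <- missingness_model(gy = log(0.75))
ms$g0 <- solve_missingness_intercept(pm, ms, target_frac_observed = 0.6)
complete_case_log_or(pm, ms)
#> Complete-case bias (analytic)
#>   full-population log OR : 0.405000
#>   complete-case  log OR : 0.413485
#>   bias                  : 0.008485  (2.10%)
#>   fraction observed     : 0.6000
```

The complete-case analysis overstates the exposure log OR by 2.1% here;
`bias_curve(pm, gy_or = c(0.9, 0.75), frac_missing = c(0.2, 0.4, 0.6,
0.8))` sweeps the whole grid (at observation OR 0.90/SD the bias stays
under 2% even with 80% missing). The simulation side mirrors it:

```r
sp  <- scenario_spec(n = 20000, seed = 3, frac_missing = 0.4)
coh <- impose_missingness(draw_cohort(sp))
complete_case_estimate(coh)
#> Logistic fit (n = 11954): exposure log OR = 0.4530 (SE 0.0609)
mi_estimate(coh, m = 10)
#> Rubin's-rules pooled estimate (m = 10): 0.4855 (SE 0.0526), FMI 0.309
```

A desk-scale factorial study (200 replicates, 20 imputations) runs with
`run_study(expand_design(), n_sim = 200, m = 20, seed = 1)`; the shipped
`inst/extdata/reference.yaml` holds the reference-scale configuration, and
`inst/cli/dichobias.R` exposes `analytic-bias`, `simulate`, `estimate`,
`run-study` and `table3-check` subcommands for shell use.

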