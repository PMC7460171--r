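# bicopreg

Bivariate copula regression for correlated, right-skewed questionnaire
outcomes — built around the joint analysis of internet-addiction (Y-IAT)
and smartphone-addiction (SAS) total scores in adolescents, and usable for
any pair of positive outcomes whose dependence should not be ignored.

Internet and smartphone addiction scores are strongly correlated within
subjects, yet they are usually regressed on risk factors (depression,
anxiety, behavioral inhibition, ADHD symptoms, aggression, usage hours)
one outcome at a time, as if independent. `bicopreg` fits both regressions
*jointly*: parametric margins coupled by a copula, estimated in one
maximum-likelihood pass.

## The model

By Sklar's theorem, the joint distribution of the two outcomes given
covariates decomposes as

    F(y1, y2 | x) = C[ F1(y1 | x; b1), F2(y2 | x; b2); theta ]

with marginal regressions `F1`, `F2` (normal, log-normal with a linear
log-scale location, or gamma with a log link; constant dispersion) and an
elliptical copula `C` — Gaussian with correlation `rho`, or Student-t with
`(rho, nu)` adding tail dependence. All parameters maximize the joint
log-likelihood

    sum_i [ log c(F1(y_i1), F2(y_i2); theta) + log f1(y_i1) + log f2(y_i2) ]

with observed-information standard errors, normal-reference Wald p-values,
and a Fisher-z confidence interval for `rho`. Around that core the package
provides the full workflow: iid marginal-family comparison by AIC/BIC,
copula-family selection on rank pseudo-observations, a parametric-bootstrap
Cramér–von Mises goodness-of-fit test, AIC comparison against
independence-assuming linear/GLM baselines, backward elimination of
covariates by joint-model AIC, and a seeded synthetic-study generator with
known generative truth.

## Worked example

Simulate a study-like cohort (n = 555, published descriptive statistics as
generative truth) and fit the full t-copula regression:

```r
library(bicopreg)

cfg   <- generative_config()                  # study-like defaults
study <- simulate_study(cfg, seed = 1)
fit   <- fit_copula_regression(study$data, default_regression_spec(cfg))

glance(fit)
#> # A tibble: 1 × 9
#>   logLik   AIC   rho rho.lower rho.upper    df  nobs n.params n.clamped
#>    <dbl> <dbl> <dbl>     <dbl>     <dbl> <dbl> <int>    <int>     <int>
#> 1 -4681. 9417. 0.376     0.288     0.458     3   555       28         0

dplyr::filter(tidy(fit), term %in% c("GENDER", "BAI", "AQ", "rho"))
#> # A tibble: 7 × 6
#>   margin term   estimate std.error statistic  p.value
#>   <chr>  <chr>     <dbl>     <dbl>     <dbl>    <dbl>
#> 1 y1     GENDER -0.143    0.0282       -5.07 3.92e- 7
#> 2 y1     BAI     0.00650  0.00221       2.94 3.29e- 3
#> 3 y1     AQ      0.00292  0.000947      3.08 2.05e- 3
#> 4 y2     GENDER  0.0688   0.0285        2.41 1.59e- 2
#> 5 y2     BAI     0.00710  0.00224       3.16 1.56e- 3
#> 6 y2     AQ      0.00501  0.000959      5.22 1.78e- 7
```

The cohort was generated with copula correlation 0.364 and a BAI (anxiety)
coefficient of 0.0089 on the log-scale IAT margin: the fit recovers
`rho = 0.376` with 95% CI (0.288, 0.458) covering the truth, and every
coefficient lands within its Wald interval. Being female predicts lower
internet-addiction but higher smartphone-addiction scores, anxiety and
aggression predict both — the qualitative pattern encoded in the
generative model. Effects are on the log/link scale: BAI's 0.0065 means
about +0.65% IAT score per anxiety point.

Choosing the marginal family for one outcome (AIC favors the log-normal,
matching how the scores were generated):

```r
fit_marginals(study$data, "y1")
#> # A tibble: 6 × 6
#>   family      AIC   BIC term    estimate std.error
#>   <chr>     <dbl> <dbl> <chr>      <dbl>     <dbl>
#> 1 lognormal 4436. 4445. meanlog    3.46     0.0174
#> 2 lognormal 4436. 4445. sdlog      0.411    0.0123
#> 3 gamma     4458. 4466. shape      6.02     0.352
#> 4 gamma     4458. 4466. rate       0.173    0.0106
#> 5 weibull   4533. 4542. shape      2.43     0.0737
#> 6 weibull   4533. 4542. scale     39.3      0.729
```

Other entry points: `select_copula_family()` + `gof_copula_cvm()` for the
copula stage, `compare_models()` for the AIC grid against independence
baselines, `backward_eliminate()` for covariate selection,
`conditional_mean()` / `predict()` for fitted outcome means,
`autoplot(fit)` for a coefficient forest plot, and `run_pipeline()` to
execute the whole workflow on one dataset. See the methods vignette
(`vignettes/copula-regression-methods.Rmd`) for the model, numerics and
generator design.

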