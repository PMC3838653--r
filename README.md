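# skewtlmm

Bayesian multilevel (random-intercept) regression with **skew-t
within-subject errors**, for longitudinal biomedical outcomes such as
repeated blood-pressure examinations of an occupational cohort.  Routine
multilevel models assume normal errors; blood-pressure residuals are
right-skewed and heavy-tailed, and a normal error model can mislead
inference about covariate effects.  `skewtlmm` is for biostatisticians
and epidemiologists who want that analysis as reproducible code rather
than a BUGS script: a native data-augmentation MCMC sampler, the
familiar posterior summary table, residual diagnostics, and a synthetic
cohort generator so the whole pipeline can be validated by parameter
recovery without access to any confidential cohort.

## Model

For worker *i* at examination *j*:

```
y_ij = x_ij' beta + b_i + e_ij
b_i  ~ N(0, sigma_b^2)                     (between-subject variance)
e_ij ~ ST(0, omega, lambda, nu)            (within-subject error)
```

where ST is the Azzalini-type skew-t with density
`f(z) = (2/omega) t_nu(x) T_{nu+1}(lambda x sqrt((nu+1)/(nu+x^2)))`,
`x = z/omega`.  Covariates: age, BMI, sex, marital status, education,
shift schedule, job type (treatment-coded against female / married /
diploma-or-lower / day-shift / white-collar references).  Priors are
vague: Normal(0, 100) on the reported coefficients, Gamma(0.001, 0.001)
on the precisions, Exponential(0.1) on `nu`, Normal(0, 100) on
`lambda`.  The sampler is a blocked Metropolis-within-Gibbs scheme on
the normal scale-skew mixture representation; the default chain keeps
every 100th draw of an 11,000-iteration run after a 1,000-iteration
burn-in (100 retained draws).  See the methods vignette
(`vignettes/skewt-multilevel-model.Rmd`) for the full scheme and design
rationale.

## Worked example

```r
library(skewtlmm)

# a small synthetic cohort at the default study conditions
cfg <- cohort_config(n_workers = 300)
cohort <- simulate_cohort(cfg, seed = 5)

fit <- skewt_lmm(cohort, config = chain_config(3000, 1000, 20, seed = 9))
fit$summary
```

```
       Variable MCMC Beta MCMC SD MCMC SE 95% CI lower 95% CI upper P value
      intercept    80.896   4.558   0.539       72.147       88.972  < 0.01
            age     0.400   0.013   0.002        0.376        0.426  < 0.01
            bmi     0.589   0.072   0.007        0.446        0.730  < 0.01
           male     9.966   3.693   0.479        2.823       16.824  < 0.01
         single     5.736   1.245   0.125        3.545        8.001  < 0.01
 educ_associate    -0.443   1.078   0.159       -2.585        1.378    0.68
  educ_bachelor    -2.615   1.140   0.114       -4.576       -0.645    0.02
   shift_weekly     0.007   1.670   0.167       -3.005        2.991    0.98
  shift_routine     1.113   0.879   0.097       -0.717        2.716    0.22
    blue_collar    -1.431   1.675   0.260       -4.108        2.017    0.44
    between_var    58.582   4.727   0.473       49.535       68.936  < 0.01
     within_var     5.320   0.590   0.113        4.022        6.350  < 0.01
      resid_var     5.569   0.329   0.037        5.008        6.257  < 0.01
         lambda     1.279   0.212   0.041        0.818        1.655  < 0.01
             nu     5.516   0.737   0.128        4.262        6.784  < 0.01
```

Each row is a posterior summary over the retained draws: `MCMC Beta` is
the posterior mean (mmHg per covariate unit), `MCMC SD` the posterior
SD, `MCMC SE` the Monte-Carlo standard error of the mean (SD/sqrt(ESS)),
the 95% interval is equal-tailed, and `P value` is the two-sided
Bayesian tail probability of the coefficient's sign ("< 0.01" means no
retained draw crossed zero).  At these generating values (age 0.42, BMI
0.67, male 10.60, single 7.28; `sigma_b^2` 67.05; `omega^2` 5.65,
`lambda` 1.14, `nu` 7.5) every coefficient and variance component lies
inside its interval; the degrees of freedom (truth 7.5, interval
4.3–6.8) falls just outside in this particular replicate, as a 95%
interval occasionally will — `recover_experiment()` quantifies exactly
that coverage across replicate cohorts.  `fit$ks` holds the Kolmogorov–Smirnov residual normality
check (here D = 0.076, p = 3.7e-10: normal errors are firmly rejected
for skew-t data, which is the point of the model).

Command-line wrappers over the same functions live in
`inst/cli/skewtlmm.R` (`simulate`, `fit`, `recover` subcommands).

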