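# uaextract

Design, optimization and kinetic modelling of solid–liquid extraction of
plant bioactive compounds, for process and food chemists who run
design-of-experiments studies on extraction yields. The package implements
the complete workflow around a three-factor Box–Behnken design (BBD):

* **Response-surface regression** — the second-order polynomial on coded
  factor levels,
  `y = β0 + Σ βi xi + Σ βii xi² + Σ βij xi xj`,
  fitted by OLS to run means, with per-term t-tests, lack-of-fit ANOVA
  (pure error from the replicated centre), model reduction, and both the
  coefficient and the doubled "effect" parameterization that DoE software
  commonly prints.
* **Derringer desirability optimization** — larger-is-better transforms
  `d = ((y − L)/(T − L))^s` combined by weighted geometric mean and
  maximized over the coded cube by grid search plus L-BFGS-B polish.
* **Extraction kinetics** — the three classical two-stage, two-parameter
  models (film theory `c(t) = c_seq[1 − (1−b)e^(−kt)]`, unsteady diffusion
  `q(t) = q0(1−b′)e^(−k′t)`, Ponomaryov `1 − q/q0 = b″ + k″t`), fitted by
  their exact linearizations (with a nonlinear cross-check), plus the
  liquid/solid mass-balance conversion.
* **Spectrophotometric assays** — Beer–Lambert total anthocyanin
  (cyanidin-3-glycoside basis) and Folin–Ciocalteu total phenolics via a
  gallic-acid standard curve.
* **Synthetic data and a bundled worked dataset** — seeded generators for
  every input the workflow consumes, and the complete design/response table,
  reduced equations, kinetic parameters and validation means of an
  ultrasound-assisted extraction (UAE) study on purple-fleshed sweet potato.

## Worked example

```r
library(uaextract)

des <- pfsp_design()                       # 17-run BBD with TA and TPC responses
ta  <- fit_quadratic(des, "TA")            # full second-order OLS fit
rescale_parameterization(ta, "effect")$coefficients
#> (Intercept)          x1          x2          x3        x1^2        x2^2
#>     9.68160     5.61225     1.67575     1.78900    -0.06010     1.34290
#>        x3^2       x1:x2       x1:x3       x2:x3
#>     2.90940     0.67700     4.12850     0.19650

anova_lack_of_fit(ta, des)
#> Regression:  SS 103.8589 (df 9)  F = 32.788, p = 6.621e-05
#> Residual:    SS 2.4637 (df 7)
#> Lack of fit: SS 1.7625 (df 3)  F = 3.352, p = 0.1366
#> Pure error:  SS 0.7012 (df 4)

run_pipeline(fit_kinetics = FALSE)
#> Extraction analysis report
#>   TA: R2 = 0.9768
#>   TPC: R2 = 0.9967
#>   Optimum (actual): time_min = 75, temperature_C = 70, solvent_mL = 75
#>   TA: +81% vs conventional, +2% vs predicted
#>   TPC: +93% vs conventional, +7% vs predicted
```

Reading: the doubled linear time effect on total anthocyanin is 5.612
mg/100 g across the 5→75 min range, the time-by-volume interaction 4.129,
and the regression is significant with a non-significant lack of fit
(p = 0.137). Joint desirability of the two fitted surfaces is maximized at
75 min, 70 °C and 75 mL per 5 g (a 1:15 solid-to-liquid ratio), and the
bundled validation means show UAE recovering 81 % more anthocyanin and 93 %
more phenolics than the 24 h conventional maceration.

Kinetics, on simulated reference curves:

```r
sp  <- pfsp_kinetic_spec("film", "UAE", "TA")   # b = 0.297, k = 1.126e-3 min^-1
ser <- simulate_kinetics(sp, kinetic_schedule())
fit_linearized(ser, "film", c_seq = 8.923)
#> film fit (linearized): b = 0.297, k = 0.001126 1/min, R2 = 1.0000 (8 points)
```

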