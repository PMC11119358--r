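---
title: "Response-surface optimization and kinetic modelling of ultrasound-assisted extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface optimization and kinetic modelling of ultrasound-assisted extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaextract)
```

# The problem

Extracting pigments and phenolics from plant material is governed by a small
number of process factors — contact time, temperature, and the
solid-to-liquid ratio — whose joint effect on yield is smooth but nonlinear.
`uaextract` implements the standard engineering workflow for characterizing
and optimizing such a process: a three-factor Box–Behnken design (BBD),
second-order response-surface regression, multi-response desirability
optimization, and two-stage solid–liquid extraction kinetics. The bundled
worked dataset is an ultrasound-assisted extraction (UAE) of total
anthocyanin (TA, mg cyanidin-3-glycoside equivalents / 100 g) and total
phenolic content (TPC, mg gallic-acid equivalents / 100 g) from
purple-fleshed sweet potato, with extraction time (5–75 min), bath
temperature (30–70 °C) and solvent volume (25–75 mL per 5 g of material,
i.e. solid-to-liquid ratios 1:5 to 1:15 m/v) as factors.

# The response-surface model

Each factor is coded onto $[-1, +1]$ by $x = (X - X_{mid}) / (\Delta X / 2)$.
The 17-run BBD (12 mid-edge runs plus 5 centre replicates) supports the full
second-order polynomial

$$ y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2
     + \sum_{i<j} \beta_{ij} x_i x_j, $$

fitted by ordinary least squares to the per-run response means
(`fit_quadratic()`). The fit is unweighted: replicate standard deviations are
carried in the design table and a `weights` argument exists, but the
canonical analysis regresses run means, which is how mean ± SD design tables
are conventionally analysed when the replicate-level data are unavailable.
Per-term p-values are two-sided t-tests on the residual degrees of freedom,
without multiplicity correction. `anova_lack_of_fit()` splits the residual
sum of squares into pure error (from the replicated centre) and lack of fit.

Two parameterizations of the same surface are supported
(`rescale_parameterization()`). On the *coefficient* scale the terms are the
OLS regression coefficients of the coded polynomial; on the *effect* scale
every non-intercept term is doubled — the change in response across the full
$-1 \to +1$ range, which is what several DoE programs print. Predictions are
identical under both: effect-scale models are halved internally before
evaluation. A separate `literal = TRUE` mode in `predict_response()` plugs
the stored terms in as-is, reproducing the arithmetic a reader performs with
a printed effect-scale equation.

Two reproducibility findings about the bundled dataset are worth stating
plainly, because the package deliberately does not paper over them:

* The doubled OLS coefficients reproduce the published linear-time and
  time-by-ratio terms and both interaction terms for TA and TPC to within
  0.001, and all six quadratic terms in magnitude. The published quadratic
  terms, however, carry the *opposite sign* to the OLS fit (the source
  software evidently used a different quadratic contrast convention).
  `uaextract` reports OLS signs — positive means upward curvature — and the
  test suite compares quadratic terms by magnitude only.
* The published X2 and X3 linear terms and the intercepts are not
  reproducible from the bundled run means by OLS under any parameterization
  we tested, and consequently neither are the published p-values for those
  terms. One visible effect: our TA fit finds the linear solvent-volume term
  significant (p ≈ 0.004), so `reduce_model(..., 0.05)` retains it, whereas
  the published reduced TA equation omits it. The published reduced
  equations are therefore shipped verbatim as fixtures
  (`pfsp_published_models()`) rather than re-derived.

`reduce_model()` keeps the intercept plus all terms with $p \le$ threshold
(ties at the threshold are retained; the threshold lives in $(0, 1]$ so that
1 means "keep everything"). On the orthogonal BBD, dropping terms leaves the
retained linear and interaction estimates unchanged.

# Desirability optimization

Each response $y_r$ is mapped to $[0,1]$ by the larger-is-better transform
$d_r = ((y_r - L_r)/(T_r - L_r))^{s}$ clamped to $[0,1]$, and responses are
combined as the weighted geometric mean
$D = (\prod_r d_r^{w_r})^{1/\sum w_r}$, maximized over the closed coded cube
$[-1,1]^3$ only — no extrapolation beyond the studied ranges.
`optimize_desirability()` evaluates a regular grid (default 21 points per
axis), breaks exact ties toward the lexicographically smallest coded triple,
and polishes the best grid point with box-constrained L-BFGS-B. A test
verifies the polished optimum dominates an exhaustive 101-per-axis
verification grid.

Anchor policy is the one genuinely open design choice, since the source
analysis does not state its anchors. The default sets $L_r$ and $T_r$ to the
model-predicted minimum and maximum over the evaluation grid — a
data-independent choice; `anchors = "observed"` uses the observed response
range instead. Defaults are $s = 1$ and equal weights, as no shape
parameters are reported.

Running the pipeline on the bundled design (models fitted from the data)
places the joint optimum at the corner $(+1,+1,+1)$: 75 min, 70 °C, 1:15 —
the reported optimal conditions. An instructive subtlety appears when the
*published reduced equations* are optimized instead: their negative
quadratic temperature term ($-13.891\,x_2^2$ in the TPC equation) pulls the
temperature coordinate slightly inside the cube, to $x_2 \approx 0.86$
(≈ 67 °C, overall $D = 0.9835$ versus $0.9826$ at the corner). No
monotone anchor choice moves that argmax to the corner, so the corner
temperature is reproduced by fitting the data, not by optimizing the printed
equations. The acceptance suite records this discrepancy rather than hiding
it.

# Extraction kinetics

Three classical two-parameter, two-stage models describe the curves; $b$
captures the fast initial washing stage and $k$ (min$^{-1}$) the slow
diffusion-limited stage:

| model | curve | linearization |
|---|---|---|
| film theory | $c(t) = c_{seq}\,[1 - (1-b)e^{-kt}]$ | $\ln(1 - c/c_{seq}) = \ln(1-b) - kt$ |
| unsteady diffusion | $q(t) = q_0 (1-b') e^{-k't}$ | $\ln(q/q_0) = \ln(1-b') - k't$ |
| Ponomaryov | $1 - q/q_0 = b'' + k'' t$ | already linear |

$c$ is the liquid-extract concentration (mg/L), $q$ the residual solid
content (mg/100 g); the references are the equilibrium concentration
$c_{seq}$ and initial content $q_0$, bundled for the worked dataset as 8.923
/ 252.00 mg/L and 54.333 / 305.521 mg/100 g (TA / TPC). The two phases are
linked by the batch mass balance
$q = q_0 - c \cdot (V/1000)/m \cdot 100$ (`content_concentration_convert()`,
5 g in 75 mL by default); "per 100 g" refers to material as used, with no
moisture correction.

`fit_linearized()` is the canonical estimator, matching how the bundled
parameter table was produced: OLS on the linearized form, with $R^2$
reported on the regression (linearized) scale. Numerical choices:

* $t = 0$ points are included whenever the transform is finite (it is, for
  $b < 1$).
* Points where the log is undefined ($c \ge c_{seq}$, or $q \le 0$) are
  *dropped and recorded*, never clipped — clipping would bias the slope.
  Fewer than 3 usable points is an error.
* Ponomaryov's linear law is unbounded, so simulated residual contents are
  floored at 0 with a warning; the fit itself never floors.

`fit_nonlinear()` refits on the original scale (Levenberg–Marquardt,
initialized from the linearized fit; bounds $b \in [0,1)$, $k \ge 0$) as a
cross-check — the two estimators weight measurement error differently and
agree to $10^{-6}$ on noise-free data. A flat series degenerates to the
closed form $k = 0$, $b = c(0)/c_{seq}$. `compare_models()` ranks fits by
$R^2$, the comparison criterion of the bundled study.

One caveat the package surfaces deliberately: the bundled $c_{seq}$ and
$q_0$ are *separate measurements* and are not mass-balance consistent with
each other (extracting to $c_{seq}$ removes only ≈ 13 mg/100 g of the
54.3 mg/100 g TA pool). Converting a content-scale series generated under
one model into concentrations can therefore exceed $c_{seq}$ and be dropped
by the film fit. Fits use each model's natural scale wherever possible.

# Assays

`anthocyanin_concentration()` is the single-wavelength Beer–Lambert formula
$C\,[g/L] = A \cdot MM/(\varepsilon b)$ with cyanidin-3-glycoside defaults
($MM = 449.2$ g/mol, $\varepsilon = 26900$ L mol$^{-1}$ cm$^{-1}$, 1 cm
path, 535 nm), times an explicit dilution factor (the source protocol's
aliquot volumes are not recorded, so dilution is a parameter). Absorbances
above 1.2 are flagged as outside the reliable photometric range.
`tpc_concentration()` inverts a gallic-acid calibration line fitted by
`fit_standard_curve()`; readings below the blank floor at 0 with a warning.
`extract_content()` applies the batch mass balance to express concentrations
as mg/100 g.

# Synthetic data

`generate_bbd_responses()` and `generate_kinetic_series()` simulate design
tables (replicate mean ± SD per run) and kinetic curves from known surfaces
and kinetic specs under additive Gaussian noise — the only error structure
the mean ± SD summaries of the bundled study support. Generation is
deterministic for a fixed `synthetic_config()` (seed, noise SD, replicate
count; replicate count defaults to 3, the value assumed — and flagged as
assumed — for the bundled design). What the generator does *not* emulate:
heteroscedastic or multiplicative error, anthocyanin degradation at long
times, run-order or batch effects, and instrument drift. Passing the
parameter-recovery tests therefore demonstrates correctness of the
estimators under the assumed error model, not robustness to real-data
pathologies.

Test problem sizes were chosen to make the statistical assertions sharp but
quick: noise-free inversions for all 12 bundled parameter sets, a 500-replicate
Monte-Carlo recovery study at 2 %-of-$c_{seq}$ noise on the 8-point sampling
schedule (median relative error of $k$ and $b$ below 15 %), and
1000-replicate runs where a standard-error bound is asserted.

# Pipeline

`run_pipeline()` chains fit → ANOVA → reduce → optimize → kinetics →
comparison and can write a JSON report (numbers at 6 significant digits)
plus a per-factor desirability trace CSV. With no measured kinetic series it
fits the three models to reference curves simulated from the bundled
parameter sets (noise-free by default; a seed and noise SD are exposed). The
comparison block reports the percent increase of UAE over conventional
yields (+81 % TA, +93 % TPC from the bundled validation means) and the
percent difference of validated versus predicted yields (+2 % TA, +7 % TPC),
rounded to integers as in the source.

# Known limitations

* Only the 3-factor BBD is constructed; no central-composite or general
  $n$-factor designs.
* Desirability shapes are larger-is-better only; no target-value or
  smaller-is-better goals.
* No second-order/Peleg/Elovich kinetic models, no Arrhenius temperature
  dependence, and no diffusivity estimation from particle geometry.
* The anthocyanin assay is the single-wavelength variant; no pH-differential
  method and no turbidity correction.
* The published intercepts, X2/X3 linear terms, overall $R^2$ values
  (0.978/0.981) and predicted-at-optimum contents (18.372/151.160) of the
  bundled study are not reproducible from its printed tables; the package
  reports its own computed values and documents the gap rather than forcing
  agreement.
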