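---
title: "Methods: reaction norms, mixed models and hierarchical contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reaction norms, mixed models and hierarchical contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`plastinorm` analyses phenotypic plasticity of fungal growth: a genotype's
reaction norm is its growth rate expressed as a function of an
environmental parameter (temperature, NaCl, sucrose, pH). Differences in a
norm's *elevation* (average rate across settings) reflect a main genotypic
effect; differences in its *shape* constitute genotype-by-environment
(G×E) interaction — the statistical signature of altered plasticity. This
vignette documents the models, the tunable parameters, the synthetic world
used for validation, and the numerical choices.

## Growth rates from race tubes

A race-tube assay yields front positions (mm) marked on an alternating
8 h/16 h schedule for typically 104 h (up to 152 h under osmotic stress).
The growth rate is the OLS slope of position on time, using marks from the
first clearly visible front onward. Trimming the pre-visibility interval
removes the transient caused by inoculum size; on a noise-free lagged tube
the trimmed slope equals the true rate while the untrimmed slope
underestimates it (this is asserted as a test invariant). Tubes in which no
growth ever occurred are assigned rate 0 and carry no R². The linear model
is a good description of these data: simulated tubes with realistic mark
noise (SD 0.5 mm) give a median R² above 0.99, and the QC summary
(`qc_summary()`) reports the 2.5/50/97.5% R² quantiles with type-7
(interpolated order statistic) quantiles.

*Visibility*: raw data rarely say when the experimenter first judged the
front visible. When a series lacks `first_visible_index`, the estimator
uses the first mark above a 1 mm threshold (configurable). The simulator
defines visibility by the expected front position turning positive;
defining it from the noisy marks instead would include pre-growth marks
whose floor-at-zero noise biases the slope (measured +0.05 mm/hr at noise
SD 0.4).

## Reaction norms, natural splines, optima

Per-genotype norms are means ± SE over non-missing replicates at each
setting (zero-growth assays count as 0). Because the norms are strongly
nonlinear, optima are estimated from a natural cubic spline fitted by least
squares to the *replicate-level* rates (preserving weighting under
missingness; fitting setting means instead is equivalent on balanced data
and available via `use_replicates = FALSE`).

Conventions that matter:

* **Degrees of freedom** count *total free parameters* (intercept
  included): `df = 2` is a straight line, `df = 6` interpolates six
  settings. The default `df = 5` equals a 4-df `splines::ns()` basis plus
  intercept — the most flexible fit that still leaves residual df on a
  six-setting grid when fit to means. Interior knots sit at quantiles of
  the distinct settings, boundary knots at the extremes.
* **Axis transform**: sucrose spans 0.015–30% (three orders of magnitude),
  so its spline is fitted on log10(setting); other parameters are linear.
  Optima are reported in original units.
* **No extrapolation**: natural splines are linear beyond their boundary
  knots and are not evaluated outside the data range; consequently
  critical thresholds where growth reaches zero outside the tested range
  cannot be estimated.
* **Optimum by dense grid search** (default step = range/1000, ties to the
  lower setting) rather than root-finding on the derivative: robust to
  flat or multimodal fits (some strains have nearly flat salt norms). The
  `at_boundary` flag marks optima at the range ends, e.g. the 0 M NaCl
  optimum that all healthy genotypes share.

**What optimum recovery can and cannot establish.** The recovery experiment
(acceptance criterion: control peak 33.7 vs mutant peak 25.3, five
replicates, residual SD 0.2) requires care about identifiability. A
symmetric, shallow parabola consistent with the control's printed rates
(3.29 mm/hr at 25°, optimum near 33.7°) has curvature ≈ 0.008 mm/hr/°²;
at that flatness the argmax is not statistically identifiable at SD 0.2
(empirical argmax SD ≈ 1°) for *any* estimator. Real temperature tolerance
curves, however, are left-skewed — shallow rise below the optimum, steep
collapse above it — and it is the steep flank that localizes the peak.
`spline_peak_norm()` therefore builds the recovery world from such an
asymmetric curve *projected into the natural-spline function space*, with
the underlying peak calibrated so the spline-space argmax sits exactly at
the stated optimum. With truth inside the estimator's model class,
noise-free fits are unbiased and noisy recovery reflects sampling variance
only (~95% of runs within ±0.5°). A green recovery test therefore
establishes variance behaviour, not robustness to misspecified shapes: for
truths outside the spline space the estimand is the spline-smoothed
optimum, which can sit up to ~1° from the raw functional peak on this
grid.

## Mixed-model G×E ANOVA

The overall model treats mechanism (M), environmental parameter (S) and
setting-within-parameter (E(S)) as fixed, and genotype (G, nested in M)
with its S×G and E(S)×G interactions as independent random intercepts.
Settings enter as unordered factors because the norms are nonlinear. The
per-parameter model keeps M, E, M×E fixed and G, E×G random. All factors
use sum-to-zero contrasts, making the "all coefficients of the term are
zero" hypothesis the Type III (marginal) hypothesis.

* **F-tests**: Wald F from the contrast selecting a term's coefficients.
  Denominator df use the Satterthwaite method: the contrast covariance is
  eigendecomposed into 1-df contrasts; each contrast variance is
  differentiated with respect to the variance parameters (θ, σ) by
  Richardson-extrapolated central differences; the parameter covariance is
  twice the inverse Hessian of the REML criterion (itself finite-differenced
  with a larger step, since second differences amplify roundoff); the
  per-contrast dfs are pooled. After a Newton polish of θ (generic
  optimizers stop ~1e-8 from the optimum, which is visible in the df),
  balanced-design F and df agree with closed-form ANOVA to ≈1e-12 and
  ≈1e-9 respectively.
* **Random effects**: χ² likelihood-ratio tests, χ² = difference of REML
  criteria between the full fit and the fit without the component, 1 df.
  When a variance sits on the boundary (estimate 0) the naive χ²₁
  reference is conservative; the test is reported as-is.
* **Pairwise control-vs-mutant tests** fit the two-genotype
  `rate ~ genotype * setting` model per environment as a fixed-effects lm
  (with two genotypes the genotype variance component is not meaningfully
  estimable) and Holm-adjust the interaction p-values across mutants. The
  interaction targets *shape* changes: a pure elevation shift leaves the
  interaction p-value uniform under the null (tested by KS).
* **Missing data**: complete-case per fit, mirroring the ~19/3120 missing
  assays such experiments produce.

## Hierarchical Bayesian contrasts

Per environmental cell (one parameter at one setting), growth rates are
modelled as `y_i ~ N(β₀ + β_j, 1/τ_j)` with genotype-specific precisions —
the heteroscedasticity is the point, as mutants differ visibly in
replicate scatter. Data are standardized so β₀ = 0 and Σβ_j = 0; effects
are reported back in mm/hr via the data SD.

Priors: `β_j ~ N(0, σ_β²)` with a folded-t(ν=2, scale 1) prior on σ_β
(weakly informative on the standardized scale); `τ_j ~ Γ(m²/d², m/d²)` so
the precision prior has mean m and SD d, with Γ hyperpriors on m and d
whose mode is 1 and SD 10 (vague but proper). The original analysis left
these hyperconstants unstated; ours are declared defaults, configurable in
`hier_spec()`.

Sampling is Metropolis-within-Gibbs: conjugate normal updates for (β₀, β),
conjugate gamma updates for τ_j, and log-scale random walks for σ_β, m, d
(m and d are strongly correlated a posteriori, so their single-site moves
are repeated and complemented by a joint scaling move). Proposal scales
adapt toward 44% acceptance during burn-in only and are frozen afterwards
to preserve detailed balance. After every iteration the mean of β is swept
into β₀, enforcing the sum-to-zero constraint exactly in every saved draw.
Defaults: 5 chains, 10,000 burn-in, 2,000 saved draws per chain at thin 5
(the source description "sampled 10,000 iterations while thinning by 750"
is internally inconsistent, so the saved-draw count is a package default).
Convergence is checked with rank-normalized split R-hat (< 1.01) and
effective sample size (> 400); the β contrasts mix far better than the
(m, d) hyperparameters, which sit near the thresholds on hard cells.

A contrast is significant when the 95% HPD interval — the shortest window
containing 95% of the sorted draws — of the rescaled difference
β_mutant − β_control excludes zero. Two calibration facts, both verified
by simulation: with true zero differences the HPD covers 0 in ≈94% of
runs, and shrinkage makes the procedure conservative for multiplicity (no
extra correction is applied, by design). The flip side is equally real:
with few genotypes the hierarchy shrinks *nonzero* contrasts toward zero
(≈0.07 mm/hr on a true −0.4 at J=3, n=12), so HPD coverage of nonzero
truths drops to ≈83% there. That is a property of the model, not of the
sampler; with the full 26-genotype panel shrinkage per genotype is far
weaker.

## The synthetic world

`default_sim_config()` emulates the screening experiment: 26 genotypes
(control 4200 plus 25 knockouts grouped by epigenetic mechanism), the
published setting grids, five replicates (3120 assays), rate =
shape(genotype, parameter, setting) + elevation(genotype) + N(0,
σ²_genotype) truncated at 0, missingness 19/3120 completely at random
("failed inoculations"), and forced zero-growth cells for the weakest
strains in their worst environments. Base shapes are smooth unimodal
curves anchored to the control's benchmarks (≈3.3 mm/hr under standard
conditions; temperature optimum near 33.7°; salt optimum at 0 M; sucrose
fitted on the log axis); designated strains carry shape overrides
(temperature optima at 25.3/31.9/32.0°, pH optima at 4.0–5.0, an
attenuated salt decline, a flat salt norm) so the G, S×G and E(S)×G
variance components are genuinely nonzero. Elevation shifts are small for
most strains and −1.2 to −1.8 mm/hr for the three severely impaired ones;
residual SDs range 0.15–0.30 mm/hr. Reproducibility: one master seed draws
a 31-bit sub-seed per assay row, so any subset of rows regenerates
identically.

What the generator does *not* emulate: circadian banding, non-linear
growth of the slowest strains, block/chamber effects (supported only as an
optional fixed covariate), correlated missingness, and measurement error
on the setting axis. Green tests on this world establish correctness of
the estimators under the stated model, not robustness to those phenomena.

## Known limitations

* Satterthwaite df rely on finite differences; on severely singular fits
  the Hessian is pseudo-inverted with a warning and df may be unstable.
* The χ²₁ reference for boundary variance components is conservative.
* The Bayesian model shrinks small-panel contrasts (see above); contrasts
  from 2–3 genotype fits should be read as conservative.
* Optima are only defined within the tested setting range, and for truths
  outside the spline space the estimand is the smoothed optimum.
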