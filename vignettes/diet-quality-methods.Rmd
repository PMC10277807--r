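---
title: "Estimating diet-quality scores from heterogeneous surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diet-quality scores from heterogeneous surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`dietquality` estimates mean dietary intakes for 264 demographic strata
(2 sexes × 22 age bands × 3 education levels × 2 urbanicity levels) per
country and year from heterogeneous survey summaries, converts them into
three diet-quality pattern scores, and aggregates draw-level scores into
population-weighted estimates with 95% uncertainty intervals (UIs). This
vignette documents the model, its assumptions, the tunable parameters, and
the design choices made where the design was genuinely open.

## 1. The intake model

Each survey record is a stratum-level summary of one dietary factor:
an observed mean `x̄`, SD `s` and sample size `n`. Individual intakes are
treated as log-normal within a stratum, so the model works on the log
scale. Two numerical points matter more than they look:

* **Log-transform bias.** `E[log x̄] = log μ − Var(x̄)/(2μ²)` to second
  order, and with the delta-method variance
  `v = s²/(n x̄²)` the correction is material relative to posterior
  interval widths once hundreds of records inform a country-year. The
  likelihood therefore uses `y = log(x̄) + v/2`.
* **Variance pooling.** Within a survey, every stratum record shares `n`
  and (for log-normal intakes) the coefficient of variation, so `v` is
  theoretically constant across a survey's records. Using per-record
  estimated `v` in inverse-variance weights is biased — in skewed intake
  data a low sample mean arrives together with a low sample SD, so
  "lucky-low" records get overweighted. Observation variances are pooled
  within survey × factor before weighting.

The observation model, per record `i` of one factor:

```
y_i ~ Normal( x_i'β + r_region(i) + c_country(i) + η_survey(i), v_i )
```

Fixed effects `x` comprise an intercept, sex, two education contrasts,
urbanicity, a natural cubic age spline evaluated at the record's age-band
midpoint (interior knots at every third midpoint, boundary knots at the
first and last midpoints: 7 basis columns), indicator terms for the
assessment method (24-hour recall is the reference, so method coefficients
are log-scale multiplicative biases of FFQ/DHS/HBS), and the country-year
availability covariate. Region and country intercepts are mean-zero normal
random effects.

**Overdispersion is a study-level effect.** Every survey carries a random
effect `η_s ~ N(0, τ₀² + ω²·flagged_s)`, where a survey is flagged when it
is not nationally representative or not fully stratified. The excess SD
`ω` is the overdispersion term. The shape matters: between-survey error is
*shared* across all (up to 264) records of a survey. Inflating per-record
variances instead would let that shared deviation be averaged down by the
record count and absorbed into country effects — in recovery experiments
that design collapses interval coverage; the study-level form restores it.

**Priors.** Weakly informative throughout, editable via `model_spec()`:
`β ~ N(0, 10²)` on the log scale; half-normal(1) on the region and country
SDs; half-normal(0.3) on `τ₀`; half-normal(0.5) on `ω`.

**Sampler.** The model is conditionally Gaussian: all location effects
(fixed, region, country, *and* study effects — appended as indicator
columns) are drawn jointly from their multivariate-normal full
conditional by one Cholesky solve per iteration; the crossproduct of the
augmented design is precomputed once because only the prior diagonal
changes between iterations. The four scale parameters take a few
random-walk Metropolis sub-steps on the log scale per scan. Four chains ×
1,000 retained draws after 1,000 warmup iterations give the 4,000
posterior draws that every downstream stage carries — any other draw count
is treated as a pipeline error. Split-R̂ and a simple
initial-positive-sequence effective sample size are reported per
parameter; any R̂ above 1.05 raises a warning (weakly identified variance
components occasionally sit near the limit; a longer warmup tightens
them). One test cross-checks the posterior against the identical model
expressed in JAGS.

**Collapsed strata.** A survey reported without, say, education enters as
the population-weighted average of its constituent strata's *log-scale*
linear predictors. The generative truth averages on the natural scale; the
Jensen gap between the two is of order half the weighted variance of the
constituent log-means (~10⁻³ for the default effect sizes), well below
observation noise.

**Percentile convention.** All medians and 95% UIs interpolate order
statistics at plotting position `k/(n+1)` (`quantile(..., type = 6)`); the
test suite pins this against an independently coded sort-based oracle.

## 2. The second-stage time model

Country-year mean log intakes from the first stage feed a varying-slopes
model: country intercepts and per-year slopes are partially pooled through
a bivariate normal whose covariance (hence the intercept–slope correlation
ρ ∈ [−1, 1]) has an inverse-Wishart prior; an availability covariate can
enter as a shared coefficient. Gibbs updates are conjugate except for a
Metropolis step on the residual SD. `apply_time_adjustment()` replaces, per
draw, each country-year's mean log intake with the time-model fit while
preserving all within-country stratum contrasts and the draw alignment.
Countries with incomplete covariate series are excluded from the fit and
keep their first-stage draws.

## 3. Energy standardization

Scores should reflect dietary composition, not quantity, so intakes are
rescaled to a 2,000 kcal/day basis before scoring. The density method is
applied *per draw*: each absolute-unit factor draw is multiplied by
`2000 / energy_draw` of its own stratum, so energy uncertainty propagates;
energy itself maps exactly to 2,000 and energy-relative units (`% energy`,
`ratio`) are untouched. Sodium is treated as an absolute-unit factor,
consistent with scoring it per 2,000 kcal. Whether to standardize draws or
stratum summaries was an open choice; draw-wise scaling is used because it
is the only form that preserves uncertainty propagation and within-draw
composition ratios exactly. Strata lacking energy draws are excluded from
scoring with a message, never scored silently.

## 4. Score definitions and cutpoints

Patterns are data, not code: `score_definition()` objects (serializable to
YAML) list components with a direction and one of three rules.

* **AHEI** — nine `cutpoint_linear` components, each 0–10 (0 at/below the
  worst intake, 10 at/above the optimal, linear between; mirrored for
  unhealthy components), summed to 0–90 and rescaled by exactly 100/90.
  Default cutpoints follow the published AHEI-2010 intake cutpoints for
  these components; sodium is scored linearly between editable bounds
  (1,500–5,500 mg/day) rather than by cohort deciles, because decile
  scoring is cohort-relative. Alcohol and trans fat are not part of the
  pattern here.
* **DASH** — eight quintile components (fruits, vegetables, nuts/legumes,
  whole grains, low-fat dairy, sodium, red/processed meat, SSBs), 1–5
  points by ascending sex-specific quintile, reversed for unhealthy
  components; total 8–40.
* **MED** — eight median-binary components (vegetables, legumes/nuts,
  fruit, whole grains, fish, MUFA:SFA ratio, with meat and dairy
  reversed); total 0–8.

Quantile cutpoints are computed from the **2018** distribution of
stratum-level median intakes, population-weighted, pooled across all
countries within sex (the pooling level was an open choice; pooling keeps
cutpoints comparable across countries), and the identical cutpoint set is
reused for every other year. The weighted quantile is the smallest
observed value whose cumulative weight reaches the target probability.
Ties at a quantile boundary take the **lower** point value, for both
directions; degenerate (tied-boundary) distributions warn.

## 5. Aggregation

Per posterior draw, an aggregate is the population-weighted mean of the
included strata's scores; the 4,000 aggregated draws are then summarized.
Consequences that the test suite verifies exactly: aggregates are
invariant to weight rescaling, and the global aggregate equals the
population-weighted mean of regional aggregates draw by draw.

Contrasts (sex, education, urbanicity) are formed at the matched-stratum
level per draw, then weight-aggregated with the summed persons of each
pair; the education contrast uses ≥12 y vs <6 y only, dropping the middle
level. Age-class contrasts (adults ≥20 y vs children ≤19 y) have no
one-to-one stratum pairs, so each class is aggregated per draw within the
scope group and the aggregated draws are differenced. Changes between 1990
and 2018 difference matched strata per draw and weight with 2018
populations only, which removes demographic drift from the estimate.
Draw-wise differencing assumes draw `d` indexes the same joint posterior
sample in every object — a contract the prediction and IO layers preserve
(draw order round-trips losslessly).

Inter-pattern relationships use Spearman correlations across strata of the
stratum-level median scores (a per-draw variant is available).

## 6. The synthetic world

`build_world()` generates the study frame the estimators assume: regions →
countries, a per-factor truth surface on the log scale (global mean,
mean-zero normal region and country intercepts, country time slopes
correlated with the intercepts, additive sex/education/urbanicity effects,
and a smooth age curve stored as 22 midpoint values and interpreted
piecewise-linearly), population weight tables covering all 264 strata of
every country-year, and country-year availability covariates. All
ground-truth parameters are kept in the returned object for recovery
tests. Defaults (all editable via `effect_config()`): region SD 0.25,
country SD 0.15, slope SD 0.004/year with correlation 0.5, demographic
effects of a few percent, age-curve scale 0.15 — magnitudes chosen once as
plausible log-scale contrasts for dietary factors; real instrument-bias
magnitudes are unknown, and the method-bias defaults (FFQ 0.95, DHS 0.90,
HBS 0.85, with larger between-survey noise for the household-derived
methods) are placeholders, not estimates.

Two generator choices deserve emphasis:

* The **age curve** is drawn from the same natural-spline family the model
  uses (then treated as piecewise-linear over midpoints) — the simplest
  shape the model can represent, so age-effect recovery is a test of the
  sampler rather than of spline approximation error.
* The **covariate** equals the country's true intercept-plus-trend path
  exactly by default (`covariate_noise_sd = 0`): an idealized availability
  index, and the condition under which the first-stage model spans the
  generative truth. With covariate noise the model is misspecified for
  country-year deviations and coverage degrades — realistic, but then
  recovery tests would measure the noise setting, not the code.

The generator deliberately does **not** emulate: zero-inflated or episodic
consumption (the model operates on strictly positive means), seasonality,
real FFQ instruments or food-composition tables, biomarker calibration,
within-survey design effects, or correlated nonresponse. Passing recovery
tests therefore show that the pipeline recovers the truth *under its own
generative assumptions* — they do not certify calibration on real surveys,
where method biases, variance structures and covariate quality are less
benign.

How education should be assigned to child strata is not settled; the
generator gives children the same marginal education distribution as
adults, and the model treats education uniformly across ages.

## 7. Validation suite and problem sizes

The suite exercises every stage against independent oracles: sort-based
percentile checks, brute-force draw-by-draw aggregation oracles (agreement
to 1e-12 on random 50-stratum instances), closed-form quantile recovery
for cutpoints, a JAGS cross-check of the intake posterior, and end-to-end
parameter recovery. The recovery harness uses the package's default desk
scale — 3 regions × 4 countries each × 10 factors × 4 years, one
representative 24-hour-recall survey per country-year plus
non-representative FFQ/DHS/HBS surveys with collapsed strata — checking
that ≥85% of true stratum log-means fall inside their 95% posterior
intervals and that a planted FFQ bias of ×1.2 is recovered within ±0.05 on
the log scale. Cross-validation (5 folds × 20% holdout × 5 repeats) runs
on a smaller 2-region × 2-country near-noiseless world and checks
predicted-vs-observed correlation above 0.95. These sizes are the
package's chosen validation conditions; larger worlds sharpen the same
checks at proportional cost.

## 8. Known limitations

* Method-bias and noise defaults are placeholders; real magnitudes must be
  supplied by the user.
* The overdispersion excess is a single factor-level parameter; it does
  not distinguish *why* a survey is flagged.
* The first stage has no country-specific time terms beyond the covariate;
  trend strength comes from the second stage.
* Quantile cutpoints pool countries within sex; country-relative scoring
  is not implemented.
* Draw-wise differencing requires draw alignment; mixing objects from
  different fits breaks the UI interpretation (totals remain valid).
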