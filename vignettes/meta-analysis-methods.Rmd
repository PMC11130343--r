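---
title: "Methods: multilevel meta-analysis of biodiversity effects on invasion resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilevel meta-analysis of biodiversity effects on invasion resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbemeta)
```

This vignette is the package's own account of the statistics it implements:
the effect-size model, the covariance structure, the multilevel estimator,
the inference and diagnostic machinery, the synthetic-data generator used to
validate all of it, and the design decisions taken where more than one
reasonable choice existed.

## Data model

The unit of input is a *community cell*: the reported mean, standard
deviation and sample size of either invader performance or resident
productivity, for one study under one environmental condition (ambient or
manipulated) and one diversity role (resident monoculture, or mixture of a
given species richness). Studies additionally carry the moderators the
models adjust for: resident species richness (1–60 species), experimental
duration (0.25–24 years) and experimental unit size (0.01–47.5 m²), and
label their manipulation with one of eight single environmental change
factors or a two- or three-factor combination.

Statistical variation may be reported as an SD, an SE, or a 95% CI
half-width; `read_cells()` converts the latter two (`sd = se√n`,
`sd = ci95·√n/1.96`, assuming a symmetric normal interval) and records the
conversion per row. Cells with `mean = 0` are kept at ingest but excluded
from any log ratio with a diagnostic: a log ratio is simply undefined there,
and silently adding an offset would invent data (no offset is applied unless
a user supplies one deliberately). Where a study reports both biomass and
cover for invaders, the pipeline keeps biomass by default
(`metric_preference`), the more comparable quantity across studies.

One modelling assumption is baked into the schema: each study × condition ×
response contributes a single (pre-aggregated) monoculture control cell.
Source compilations that grew several monocultures per study must average
them before ingest; the schema documents rather than hides this step.

## Effect sizes and their variances

All effect sizes are natural-log response ratios with first-order
(delta-method) variances, using the standard result
Var[ln X̄] ≈ S²/(n X̄²):

* net biodiversity effect, `NBE = ln(X_mono/X_mix)`, variance the sum of
  the two cells' terms — positive when mixtures suppress invaders more than
  monocultures;
* its change under environmental manipulation,
  `ΔNBE = NBE_M − NBE_A`, paired per diversity level, variance `v_M + v_A`
  (the two NBEs share no cells);
* the factor effect on invasion resistance, `ln(X_A/X_M)`, computed within
  a stratum (monocultures, or mixtures at equal richness);
* the factor effect on monoculture productivity, `ln(Y_mono,M/Y_mono,A)` —
  orientation deliberately reversed, so that a positive value means the
  factor *favours* plant growth and a negative value marks a stressful
  environment. No variance formula is in common circulation for this
  reversed form; we use the same delta-method expression as for the other
  ratios, which is the unique first-order answer and identical in structure.

No small-sample bias correction is applied to the log ratio, and no
standardized-mean-difference variants are offered: the response ratio is the
estimand.

Every effect records its *signed provenance* — the list of cells it was
built from and the sign of each cell's log-scale contribution (`+1` for
numerator, `−1` for denominator; four signed cells for ΔNBE). The value
always equals the signed sum of log cell means, a property the test suite
asserts to machine precision.

## The shared-control covariance

Comparing several mixture diversity levels against the same monoculture
control makes those NBEs correlated. To first order the covariance induced
by a shared cell `c` entering effects `i` and `j` with signs `s_ic`, `s_jc`
is

    cov(i, j) = Σ_c  s_ic · s_jc · S²_c / (n_c X̄²_c),

i.e. each cell contributes a rank-one term `v_c s_c s_cᵀ` to the matrix.
This makes the construction positive semidefinite *by construction*; the
tests also verify it numerically (minimum eigenvalue ≥ −10⁻¹⁰ × the largest
variance). The same rule is applied uniformly to every sharing pattern —
NBEs sharing monoculture controls, and ΔNBEs sharing ambient components or
control cells — rather than special-casing one pattern; uniformity is the
defensible default when the sharing structure, not its origin, determines
the first-order covariance. A Monte-Carlo oracle (simulating cell means
from their sampling distributions and computing the empirical covariance of
the log ratios at 10⁵ draws) confirms both variances and covariances within
three Monte-Carlo standard errors.

## The multilevel estimator

Effect sizes from the same study are not exchangeable with effects from
different studies even after the sampling covariance is accounted for.
`fit_meta()` therefore fits the standard three-level meta-analytic model:
study-level random intercepts plus observation-level random intercepts,

    Σ(θ) = V + σ²_study Z_s Z_sᵀ + σ²_obs I,

with `V` the known sampling VCV. Variance components maximise the
restricted log-likelihood

    ℓ_R(θ) = −½[(k−p)·ln 2π + ln|Σ| + ln|XᵀΣ⁻¹X| + rᵀΣ⁻¹r],

and fixed effects are generalised least squares at the optimum, so effect
precision is weighted by the inverse of the full covariance. "Observations
nested in study" is interpreted as this two-component structure — the
standard reading in the multilevel meta-analysis literature when the model
matrices are not printed.

Numerical choices:

* **Optimiser.** Bounded quasi-Newton (`nlminb`) directly on the variance
  scale with lower bounds at zero, from a 4×4 multi-start grid
  θ ∈ {10⁻⁴, 10⁻², 10⁻¹, 1}². ℓ_R can be multimodal near zero components;
  the multi-start is cheap insurance. We optimise on the variance scale
  rather than the log scale because exact zeros are attainable boundary
  optima of REML and the log scale can only approach them.
* **Convergence** at relative tolerance 10⁻¹², far below the 10⁻³
  component agreement the validation demands against an independent
  grid-search oracle (a 50×50 grid over [0, 2]², refined three times around
  the running optimum).
* **Centring.** Continuous moderators are centred at their observed means.
  This affects only the intercept — slopes, Q_M statistics and marginal
  means are invariant — but makes intercepts interpretable and the
  optimisation better conditioned.
* **Coding.** Categorical moderators use treatment coding with the
  alphabetically first level as reference. All reported quantities
  (marginal means, Q_M, contrasts) are invariant to this choice, and the
  suite checks Q_M invariance under recoding.
* **Degenerate inputs.** Rank-deficient designs are rejected with the
  collinear columns named; fits require at least `p + 2` effects; a
  non-positive-definite Σ at a proposal is treated as ℓ_R = −∞ rather than
  an error, so the optimiser simply avoids the region.

The implementation is validated three ways: closed forms (with components
pinned at zero and a diagonal VCV the fit must equal the inverse-variance
weighted mean to machine precision), the grid-search oracle, and — as an
independent cross-check only — agreement of coefficients, standard errors
and variance components with `metafor::rma.mv` on identical inputs.

## Inference

* **Q_M** is the Wald chi-square `βₛᵀ Cov(βₛ)⁻¹ βₛ` on a coefficient
  subset, with df the subset size. Inference is Wald throughout; no
  Knapp–Hartung small-sample adjustment is applied, matching the default
  behaviour of the standard multilevel meta-analysis toolchain this
  package's results are meant to be comparable with.
* **Marginal means** are predictions per level of a categorical moderator
  with continuous covariates at their observed means and any other
  categorical moderators averaged over their observed distribution. Their
  95% CIs are Bonferroni-corrected at level `1 − 0.05/k`. The family `k`
  defaults to the number of means reported together (the levels of the
  summarised factor, or the number of factor-category strata in the
  per-factor summary) — the "per displayed family" convention; `k` is an
  argument, so a per-analysis family is one call away.
* **Pairwise contrasts** are Wald z tests on differences of marginal means,
  Bonferroni-corrected over the number of pairs.

## Publication bias and influence

Funnel asymmetry is assessed on residuals (not raw effects), pairing each
effect's meta-regression residual with its sampling SE, and tested by
Egger's method: the sampling SE is appended as a moderator and its Wald z
is the test. In the pipeline the Egger refit keeps the full covariate set
of the analysis model — the natural reading of "added as a moderator to the
model" — while `egger_test()` itself accepts any base formula.

Influence is screened by case deletion: each effect is removed in turn, the
model *fully refitted* (variance components re-estimated, the VCV row and
column dropped), and the coefficient displacement measured through the
full-fit precision, `D_i = (β̂−β̂₋ᵢ)ᵀ (XᵀΣ̂⁻¹X) (β̂−β̂₋ᵢ)`. Re-estimating
the components is costlier than holding them fixed but matches the
semantics of "refit without the observation". The flagging threshold is the
conventional screening rule `4/k`, overridable, since the influence
literature offers no single canonical cut-off. Flagged effects are removed
and the model refitted (`sensitivity_refit()`); the refit, not the flag, is
the sensitivity result.

## The synthetic-data generator

`generate_dataset()` is first-class, tested code, not a fixture: it is the
ground-truth instrument every downstream stage is validated against. It
emulates a 25-study compilation with the structure real invasion
experiments produce — monoculture controls plus 2–3 mixture richness levels
drawn from {2, 4, 8, 16, 60}, both conditions, log-uniform durations
(0.25–24 y) and plot sizes (0.01–47.5 m²), eight single factors plus two-
and three-factor combinations, and a productivity subset (16/25 studies).

Generative defaults are fixed once, as the study conditions the validation
runs under: ambient mean NBE 0.4 (a typical grassland log-ratio magnitude;
the compiled literature reports a significantly positive ambient effect but
no single pooled number to copy), true ΔNBE shifts of +0.8 under warming,
−0.5 under drought, +0.16 and +0.64 for two and three co-acting factors
(the headline pattern the analysis is designed to detect), zero for the
remaining factors, heterogeneity τ²_study = 0.04 and τ²_obs = 0.02, and
cell replicates drawn from a lognormal with CV 0.3 at n = 5. The lognormal
is the natural choice for a log-ratio estimand: means stay positive and the
log response ratio is unbiased to first order. Monoculture productivity
shifts (+0.3 warming, +0.4 eutrophication, −0.4 grazing, −0.5 three-factor,
−0.2 drought) reproduce the favorable/stressful sign pattern the factor
classification targets. Factor categories are allocated to studies by
expected count first (each category gets `floor(prob·n_studies)` studies,
the remainder at random), so no category is empty by chance under the
default equal weights. All draws come from one generator seeded once per
dataset; the output is byte-identical across runs at a fixed seed and the
caller's RNG state is restored.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: selective publication, correlated moderators
(duration confounded with factor type, say), non-lognormal measurement
error, shared species pools between studies, digitisation error from
figure-extracted means, or any taxonomic structure. The recovery results
certify the estimator under the model's own assumptions, nothing more.

## Validation problem sizes

The test suite exercises: exact formula checks at 10⁻¹²; the Monte-Carlo
covariance oracle at 10⁵ draws; grid-search agreement on 8–12-effect
instances; parameter recovery over 100 replicate meta-datasets of 150
effects in 25 studies (bias within two Monte-Carlo SEs for the mean and
both variance components); an Egger type-I-error check over 200 null
replicates (rejection rate required to sit in [0.02, 0.10] at α = 0.05);
and end-to-end coverage — in at least 90% of 50 replicate synthetic
compilations the Bonferroni-corrected per-factor marginal ΔNBE interval
must cover the generative shift for warming, drought and the three-factor
combination. These sizes were chosen to give the bias and coverage checks
enough Monte-Carlo resolution to be meaningful while remaining quick to run
on a laptop.

## Known limitations

* Wald-only inference; no likelihood-ratio or robust (sandwich) variants.
* No trim-and-fill, selection models, or fail-safe N; Egger plus influence
  screening is the full bias toolkit here.
* The monoculture control is assumed pre-aggregated per study × condition.
* Leave-one-out influence is O(k) full REML refits; for compilations far
  larger than the ~100-effect scale this was built for, expect minutes, not
  seconds.
* The interaction analysis (condition × invader type) needs several studies
  per invader type; on small subsets the pipeline records the failure and
  carries on, by design.
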