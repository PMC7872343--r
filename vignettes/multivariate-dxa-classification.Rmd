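---
title: "Multivariate classification of osteoporosis from DXA T-scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate classification of osteoporosis from DXA T-scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvbmd)
```

## The diagnostic problem

A screening DXA study measures areal BMD at the L1–L4 lumbar spine, the
femoral neck and the total hip, and standardises each against a
sex-matched young-adult reference: `T = (BMD − μ_young) / σ_young`. The
WHO/ISCD rule then uses only the lowest of the three T-scores:
osteoporosis at `min(T) ≤ −2.5` (inclusive), osteopenia at
`−2.5 < min(T) < −1` (both strict), normal otherwise — so a T-score of
exactly −1.0 is normal. `mvbmd` implements these conventions literally in
`site_classify()` and `who_classify()`.

Because the three measurements probe the same skeleton, they are strongly
correlated (around 0.6–0.75 between sites in adult cohorts). The package's
central object is the joint rule that uses all three scores: with `R` the
3×3 between-site correlation matrix, a patient's Mahalanobis radius is
`d = sqrt(t' R⁻¹ t)`, and the diagnostic ellipsoids are the level sets of
`d` whose boundary radii are constrained to the univariate threshold
magnitudes, 2.5 and 1.0.

## The ellipsoid rule and the low-BMD gate

`ellipsoid_classify()` diagnoses osteoporosis when `d ≥ 2.5` and
osteopenia when `1 < d < 2.5`, mirroring the WHO boundary conventions
(inclusive at the osteoporosis radius, strict at both osteopenia
boundaries), **restricted to the low-BMD half-space** `t₁ + t₂ + t₃ < 0`.
The gate is a design choice this package had to make: a level set of `d`
is symmetric, and a patient far outside the 2.5-ellipsoid because all
three T-scores are *high* should clearly not be called osteoporotic. We
gate on the unweighted T-score sum because of two properties:

- **Elliptical symmetry.** The hyperplane `t₁ + t₂ + t₃ = 0` passes
  through the center, so exactly half of the probability mass of every
  shell `{d ≥ r}` lies on each side. The rule's population rates are then
  `P(osteoporosis) = P(χ²₃ ≥ 2.5²)/2 = 5.00%` and
  `P(osteopenia) = [P(χ²₃ ≥ 1) − P(χ²₃ ≥ 6.25)]/2 = 35.06%`, independent
  of the correlations — the defining behaviour of the statistics-based
  rule, whose rates do not move across the correlation grid.
- **Invariance under common random numbers.** The sum direction `(1,1,1)`
  is an eigenvector of every equicorrelated matrix, so with the symmetric
  square-root generator (below) both `d²` and the gate's sign are
  literally the same numbers at every correlation level.

A patient at exactly `sum = 0` is classified normal; the event has
probability zero under every continuous model and the choice mirrors no
published convention either way.

One consequence is surfaced rather than hidden: WHO-osteoporosis is *not*
mathematically contained in ellipsoid-osteoporosis. A profile like
(−2.5, +2, +2) is WHO-osteoporotic but sits on the high-BMD side of the
gate. Such discordant profiles are clinically odd (one very low site with
two high sites) and essentially absent in correlated cohorts — in the
emulated screening cohort the WHO-only cell of `compare_rules()` is
typically zero — but `compare_rules()` reports the discordance table
instead of forcing containment.

## Distribution theory

When the young-adult reference mean and SD are treated as known
(`reference_n = Inf`, the default everywhere), the T-score vector is
modelled as trivariate normal with correlation matrix `R`. When the
reference was estimated from a finite sample of size `m`, standardising by
the estimated mean and SD makes each T-score a location/scale Student-t
quantity; `tscore_distribution()` adopts the classical reconstruction
ν = m − 1 with scale matrix ((m + 1)/m)·R, which recovers the normal
model as m → ∞. The exact constants one would attach to a particular
densitometer's reference panel are not published per vendor; the (m+1)/m
choice is the standard sampling-theory one and is flagged here as a
modelling decision, not an external fact.

On top of this family the package provides the textbook closed forms,
hand-written because they are three-line formulas at p = 3:

- `dtscore()` — the trivariate t/normal density;
- `marginal_distribution()` — univariate t (same ν) with scale
  `sqrt(scale[i,i])`;
- `conditional_distribution()` — univariate t with ν + 2 degrees of
  freedom, regression location `μ₁ + Σ₁₂Σ₂₂⁻¹(x₂ − μ₂)`, and scale
  inflated by `(ν + d₂²)/(ν + 2)`, `d₂²` the Mahalanobis radius of the
  observed pair; the normal-theory conditional at ν = ∞.

These are mutually consistent (joint = conditional × block marginal), and
the test suite verifies the identity pointwise to 1e−8 relative error, the
marginal against 2-D quadrature of the joint to 1e−5, and the trivariate
density's normalisation by Simpson product quadrature. `category_coverage()`
converts the radii into analytic category probabilities via the χ²₃ law
(scaled-F at finite ν) and is exactly correlation-free.

## The synthetic-data generator

`simulate_cohort()` draws `z ~ N(0, I)` and correlates via
`t = means + sds ∘ (S z)`. Its defaults are the simulation study's
conditions: n = 1000 patients per cohort, T-scores marginally **standard
normal** (the simulated elderly population set equal to the young-adult
reference), and one equicorrelation ρ ∈ {0, 0.2, 0.4, 0.6, 0.8} across
the grid that `run_table3()` sweeps. The standard-normal choice is pinned
by the study's own numbers: at ρ = 0 the expected WHO-normal fraction is
Φ(1)³ = 59.55%, matching the reported 59.5%.

Two generator decisions matter:

- **Transform.** The default is the symmetric (eigendecomposition) square
  root `S = R^{1/2}`, not Cholesky. Any square root gives the same `d²`
  under common random numbers (`S' R⁻¹ S = I`), but only the symmetric
  root also keeps the low-BMD gate invariant across equicorrelation
  levels, which is what makes the statistics-based counts *identical*
  column-to-column in the grid report. Cholesky is available
  (`transform = "cholesky"`) for contrast and breaks exactly and only the
  gate invariance — the suite tests both facts.
- **Seeding.** One integer seed drives one generator; the same seed
  produces bit-identical cohorts, and reusing it across correlation
  levels *is* the common-random-numbers design. The seed save/restore
  wrapper leaves the caller's RNG stream untouched.

`emulate_real_cohort()` produces a synthetic stand-in for a screening
population of 65-year-old women: means (−0.90, −1.54, −0.97), SDs
(1.50, 0.93, 1.04), correlations (0.6558, 0.6145, 0.7508), plus Bernoulli
covariates (diabetes 7.1%, prior fracture 2.4%, supplementation 60.3%).
Its optional FRAX columns are synthetic by construction — log-normal in
the femoral-neck T-score, calibrated to land near clinically familiar
means (~12% major, ~1.7% hip) — because FRAX is a proprietary calculator
whose outputs this package only consumes.

What the generator does **not** emulate: non-normal tails, measurement
error and inter-scanner calibration drift, age/sex structure,
treatment-induced site-specific BMD changes (e.g. corticosteroid effects
on the spine), or any dependence between the covariates and the T-scores.
Passing tests on synthetic cohorts therefore demonstrate the statistical
machinery and the rules' relative behaviour under the stated model, not
clinical performance on real patients.

## Numerical and interface choices

- Mahalanobis forms go through `stats::mahalanobis()`; positive
  definiteness is enforced at `correlation_model()` construction (smallest
  eigenvalue > 1e−10), so downstream solves cannot silently run on
  degenerate matrices.
- Quadrature oracles in the tests truncate at the point where the
  neglected t/normal tail mass is below the asserted tolerance (±20 scale
  units for ν = 5), with adaptive `integrate()` at rel.tol 1e−9 to 1e−10
  for the 1-D/2-D checks.
- McNemar's statistic is `(b − c)²/(b + c)` with **no continuity
  correction**, referred to χ²₁; the paired tests that motivated it are
  reported per dichotomisation (osteoporosis vs not; osteopenia-or-worse
  vs normal). With `b + c = 0` the test is undefined and
  `compare_rules()` reports the degenerate case explicitly.
- For real cohorts without an external correlation estimate,
  `classify_cohort()` defaults `R` to the cohort's own Pearson
  correlations of the T-scores (unit variances in reference scale).
- Cohort CSVs require the header
  `patient_id,t_l1l4,t_fneck,t_thip[,...]`; T-score and `frax_*` columns
  must parse as numbers (violations name the column and data line),
  other covariates are type-guessed, and Unicode minus signs are
  normalised on input.
- Problem sizes: the test suite runs its distributional checks at
  n = 10⁵ draws (moment recovery, χ²₃ goodness of fit), the Monte-Carlo
  coverage oracle at 10⁶ draws, and the study-grid checks at the study's
  own n = 1000 per column; these sizes put the Monte-Carlo error well
  below each assertion's tolerance while keeping the whole suite in the
  tens of seconds.

## Known limitations

- The ellipsoid rule's center is fixed at the T-score origin (the
  young-adult mean); no re-centering on an elderly population is offered.
- Only the three standard sites are exercised; forearm or trabecular
  extensions would need a larger correlation model (the internals do not
  hard-code p = 3 in the density formulas, but the interfaces do).
- No estimation of ν from data; `reference_n` is user-supplied.
- The equicorrelated grid and the emulated cohort are the only built-in
  study designs; arbitrary correlation models are supported everywhere
  but the reported invariances (identical statistics-based columns) are
  specific to equicorrelation with common random numbers.
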