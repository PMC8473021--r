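---
title: "Methods: metric age estimation with dentage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metric age estimation with dentage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentage)
```

`dentage` estimates the chronological age of children and adolescents
(48–144 months) from metric measurements on pantomograms. This
vignette documents the model, its parameters and defaults, the
synthetic cohort that makes the pipeline testable, and the numerical
and design choices behind the implementation.

## From landmarks to indicators

The measurement unit is a *landmark set*: up to 36 named points, in
pixel coordinates, on the crowns, root apices, cemento-enamel
junctions, mandibular-border projections and reference projections of
teeth 13, 15, 16, 17 and 43, 45, 46, 47 (FDI numbering). From these,
21 dimensionless indicators are formed as ratios of Euclidean segment
lengths (`indicator_definitions()` lists all endpoint pairs). Three
families:

* **X01–X06** — mutual ratios of the four cross-arch crown distances
  (canine, second premolar, first and second molar), tracking arch
  proportions;
* **X07–X14** — root length and cemento-enamel crown width against
  projected reference segments, tracking root and crown maturation of
  each lower tooth;
* **X15–X21** — crown and apex heights above the mandibular border and
  their cross-tooth ratios, tracking eruption and root elongation.

Ratios make the representation invariant to translation, rotation and
uniform scale of the image (asserted to 1e-9 in the tests), so
magnification and head positioning never enter the model. An indicator
whose denominator segment degenerates to zero length is returned as
missing with a warning rather than an error; models require complete
feature vectors, so such cases are excluded from training, with a
logged reason.

The assumption that gives the method its power is biological
monotonicity: between 4 and 15 years each indicator changes
monotonically with dental maturation, so a smooth regressor can invert
the relationship.

## The RBF regression model

Feature vectors are the 21 indicators, optionally followed by `SEX`
encoded 0 (F) / 1 (M) — 22 inputs for the combined-sex model, 21 for
sex-specific ones (a constant `SEX` column would be degenerate there).
The network has one hidden layer of `H` Gaussian units and a linear
output neuron; topologies are written `RBF I:I-H-1:1`.

Fitting proceeds in fixed stages, all deterministic given a seed:

1. **Scaling.** Inputs and the target are min–max scaled to [0, 1]
   with bounds from the *training partition only*. Reported errors are
   RMSE on this scaled output, so an error of 0.036 corresponds to
   about 3.5 months over a 96-month range. A constant target is
   handled with unit span (the fit degenerates cleanly to a constant
   predictor); a constant input column is an error.
2. **Centers.** Seeded k-means with `k = H` on the scaled training
   inputs. If k-means degenerates (empty clusters, or `H` at least the
   number of distinct points) the centers fall back to sampling
   distinct training points. This keeps the fit defined up to the
   interpolation limit `H = n_train`.
3. **Widths.** Each unit's width is its nearest-other-center distance
   (for a single unit, the data's maximum distance to the center),
   floored at 1e-8, times the `spread` factor (default 2.0). Widths of
   this form are standard RBF practice: broad enough to overlap,
   narrow enough to stay local.
4. **Output layer.** Weights and bias solve the ridge-regularised
   least-squares problem on the activation matrix augmented with a
   bias column; the penalty (default `ridge = 1e-8`) applies to unit
   weights only, never the bias. With `ridge = 0` the solve switches
   to a minimum-norm SVD least-squares path: the bias-augmented system
   at `H = n_train` is rank-deficient yet consistent, and the SVD
   route preserves the exact-interpolation property (training RMSE
   below 1e-6 in the tests). A fully degenerate activation matrix
   raises an error advising `ridge > 0`.

**Quality** is the Pearson correlation between predicted and observed
age on a partition. The agreement measure is specified only as
"closeness to 1"; correlation is the standard such measure for
regression and matches the magnitude of published values (0.96–0.999),
so the package adopts it as its definition.

### Protocol

The cohort is split 2:1:1 at random (train `floor(n/2)`, validation
`floor(n/4)`, test the remainder — the deterministic allocation closest
to 50/25/25 for n not divisible by 4). The *automatic designer*
(`designer_search()`) trains `n_test = 20` candidates with hidden
counts drawn over a grid (pipeline default {5, 10, 15, 20, 25}) and
per-candidate center seeds, ranks them by validation RMSE, and retains
up to `n_retain = 10` under a diversity rule: at most
`ceiling(n_retain/2)` retained networks may share one hidden count, so
the kept set balances error against architectural variety.

### Sensitivity analysis and tuning

For each input `k`, the *sensitivity quotient* is

```
q_k = RMSE(model with input k mean-substituted) / RMSE(full model)
```

with the substitution value being the input's training-partition mean
(the model object carries these means, so a persisted model remains
analysable). Quotients are evaluated on the validation partition by
default — the partition that drives tuning; training would be
meaningless for an interpolating model (baseline error zero, which is
refused), and the test partition is reserved for final reporting.
Ranking is by descending quotient with *stable* tie-breaking: of two
equal quotients, the variable listed first keeps the smaller rank. The
reference tables shipped in `inst/extdata/` contain such a tie and
reproduce under this rule.

`prune_and_retrain()` drops inputs with `q_k` below a threshold
(default 1.0 — the conventional "quotient above 1 means important"
reading) and refits with the same `H` (reduced only if it exceeds the
training size). Published final models retain some inputs with
quotients slightly below 1, so the threshold is an exposed parameter,
not a constant. In the composite pipeline, if pruning would drop
*every* input — possible when many correlated inputs are individually
redundant — the unpruned model is kept as final and the decision
logged; the low-level function instead refuses, so the caller decides.

## The synthetic cohort

No public cohort of annotated pantomograms exists, so the package
generates one (`generate_cohort()`). Defaults emulate the study
population: 296 female and 323 male cases (619 total), integer ages
uniform on 48–144 months, and for each indicator a monotone
age-response curve plus Gaussian noise with s.d. 5% of the curve's
range — low noise, chosen as the regime in which a metrically faithful
annotation process should operate, and under which the pipeline
attains the published 96–99% quality band.

Two curve families:

* **Direct logistic trajectories** for X07–X18: maturation ratios rise
  from a start to an asymptote with per-indicator midpoints (78–104
  months; later-developing teeth mature later) and steepness
  0.06–0.07 per month, mimicking progressive apex closure and
  eruption.
* **Latent linear trajectories** for the segment lengths behind
  X01–X06 and X19–X21. These nine indicators share segment endpoints
  and are therefore algebraically dependent (for example
  `X04 = X02/X01` and `X21 = X20/X19` hold exactly in any real
  geometry). Drawing them independently would produce vectors no
  landmark configuration can realize. The generator instead simulates
  the eight underlying lengths (four cross-arch crown distances, four
  apex-to-border distances) as linear growth curves with relative
  growth rates deliberately spread apart, and derives the ratios; the
  identities then hold by construction. Latent noise is applied at
  half the relative level (2.5% of each length's range) so each
  derived ratio's dispersion stays near the 5%-of-range default.

Sex enters as a −3 month midpoint shift for girls (earlier
maturation), configurable. With zero noise every indicator is strictly
monotone in age within sex; at the default noise every indicator
retains |cor(age, X)| > 0.8 at n = 619 (both are tested).

`generate_landmarks()` inverts the indicator computation: it places
the 36 points on a parametric jaw template so that
`compute_indicators()` recovers a given vector to 1e-6. Per tooth the
crown, apex and border points form a triangle with the apex–border
side fixed by the template, the crown–border side set by the
X15-family ratio, and the crown–apex side chosen strictly inside the
triangle-inequality interval (`max` of the other two sides), after
which the projected reference realizes the X07-family ratio; upper
crown points sit at the required cross-arch distances. Vectors
violating the shared-segment identities beyond 1e-6 are refused as
geometrically unrealizable, as are non-positive ratios. The template
scale cancels exactly (tested at 0.25x–7.5x).

**What the generator does not emulate:** annotation error structure
(real landmark noise is spatially correlated within an image, not
independent per indicator), population covariance between teeth beyond
the shared-age signal, missing or unmeasurable landmarks, secular
trends, and any pathology. Passing the pipeline on synthetic data
therefore demonstrates that the machinery recovers age when the
monotone-development premise holds at low noise — it does not validate
clinical accuracy, which requires real cohorts.

## Numerical choices and degenerate inputs

* Interpolation tolerance 1e-6 (scaled RMSE); weight-solution
  agreement with brute-force normal equations 1e-8; similarity
  invariance 1e-9; scaling round trip 1e-12; landmark reconstruction
  1e-6.
* k-means: `nstart = 2`, 50 iterations, seeded; any failure falls back
  to sampling distinct points, so fitting never aborts on unlucky
  initialisation.
* The sensitivity baseline refuses RMSE below 1e-12 (an interpolating
  model analysed on its own training set).
* Ages outside 48–144 months are rejected at ingestion unless
  explicitly overridden; predictions are unclamped by default with an
  optional clamp to the validity window.
* Model persistence is schema-versioned JSON at full precision; saves
  are byte-deterministic, and a reloaded model predicts identically to
  1e-12.

## Problem sizes

The test suite exercises full-size cohorts (619 cases) where the
property under test concerns the cohort itself, and 40–600-case
cohorts with reduced candidate counts for model-fitting tests; the
end-to-end accuracy check runs the complete 20-candidate search on the
full 619-case cohort for five seeds, which completes in a few seconds
on one CPU.

## Known limitations

* The anatomical placement rules for the projected reference points
  (`P`, `PCeM`, `PCeD`) are not machine-readable from the source
  figures; the package treats all labels as opaque geometric
  identifiers, which is sufficient for every computation it performs.
* Only the single 2:1:1 split protocol is provided; no
  cross-validation.
* One prune–retrain cycle per invocation; iterate via the CLI or API
  if desired.
* The RBF engine is dense and unaccelerated — appropriate for cohorts
  of hundreds to thousands of cases, not for very large designs.
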