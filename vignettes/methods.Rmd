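---
title: "Methods: simulating trauma prevalence estimation under skeletal incompleteness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating trauma prevalence estimation under skeletal incompleteness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical design of `traumasim`: the data
model, the two estimators, the Monte-Carlo harness, and the numerical and
design choices a user should know before trusting (or modifying) its output.

## The data model

**Recording schema.** A skull is a vector of 48 elements over 14 bones —
frontal, occipital, and paired parietal, temporal, maxilla, mandible,
zygomatic and nasal bones; four regions per bone except two for each nasal
and zygomatic. Element order is fixed (anatomical, left before right) and
all package vectors use it; `cranial_schema()` documents the within-bone
region conventions (e.g. mandible region 1 = body, 4 = condylar area).
Completeness of a specimen is the percentage of its 48 elements present.

**Trauma assignment.** Sample A receives trauma on exactly 10% of its
specimens and sample B on exactly 30% — fixed fractions, not binomial
draws, so the benchmark the estimators chase is exact by construction.
Affected specimens take an injury pattern drawn uniformly *with
replacement* from a 40-case pool of real-life blunt-force cranial trauma
(interpersonal violence, falls from a height, animal encounters, arrow
shots, clinical cases), ranging from a single injured element to 34.
Element-level vectors were reconstructed from each case's published verbal
fracture description and injured-element count; where a description names a
bone but not the specific region, the schema's fixed region conventions
decide. The pool ships as an editable CSV and is re-validated on every
load: 40 cases, pattern sums equal to declared counts, injured elements
only on declared bones.

**Missingness.** Per specimen, a missing-data percentage is drawn from
Normal(μ, σ), clipped to [0, 100] (values below 0 become 0, above 100
become 100), and converted to an element count with half-away-from-zero
rounding — elements are atomic, so percent missingness is necessarily
discretized in units of 100/48 ≈ 2.08%. The count is allocated to elements
by successive weighted draws without replacement, weights renormalized
after each draw (base R's `sample(prob =, replace = FALSE)` implements
exactly this scheme). Surviving elements keep their trauma scores, so
multi-element fractures can be partially preserved. Element weights derive
from bone-level effective sample sizes (ESS): Walker-style fractional bone
counts, high for vault bones and the mandible, low for nasals and
zygomatics. The default transform is inverse (`1/ESS`, shared by all
elements of a bone, normalized to sum to one); `max_complement` and `rank`
alternatives are available because the literature motivates only the
direction of the weighting, not its functional form. The shipped ESS table
is a synthetic stand-in that reproduces the published qualitative ranking
of Upper Paleolithic cranial preservation; only its ratios matter, and it
is a plain CSV meant to be replaced when better counts are available.

Clipping makes the realized missingness mean differ from μ near the bounds
(`clipped_normal_mean()` gives the closed form; at μ = 80, σ = 20 the
realized mean is below 80). This is intentional: the generator emulates a
bounded preservation process, not an unbounded normal one.

**What the generator does not emulate.** Breakage is spatially independent
given the weights — adjacent elements are not lost together, there are no
specimen-level taphonomic covariates, no healed-versus-perimortem
distinction, and the trauma pool is blunt-force-only. Passing tests
therefore certify estimator behavior under this missingness mechanism, not
under every archaeological deposition history.

## The estimators

**Crude frequency (CF).** `cf_estimate()` computes
`100 · #(trauma, completeness ≥ t) / #(completeness ≥ t)` with t = 75% by
default, excluding all less complete specimens with and without trauma. If
no specimen passes, the estimate is *undefined* — a legitimate outcome the
harness tracks separately, never an error.

**Binomial GLM.** `glm_fit()` fits trauma ~ sample + completeness with a
binomial distribution and log link, so coefficients are multiplicative in
prevalence and the model can use every specimen regardless of completeness.
Completeness enters on its raw 0–100% scale, uncentered. The log link is
not variance-stabilizing at high probabilities and can fail to converge;
the fit uses a three-stage ladder that keeps the stated link primary:

1. log link started from flat prevalence `(log ȳ, 0, 0)`;
2. log link restarted from a log-Poisson working fit (the standard
   log-binomial device), intercept shifted so initial fitted probabilities
   stay below 1;
3. logit link fallback, recorded as a flag and counted per scenario in the
   summary and run manifest.

`glm_predict()` emulates posterior prediction from a frequentist fit: it
draws 10,000 coefficient vectors from MVN(β̂, Σ̂) — the canonical
interpretation of "sets of model parameters" for a likelihood fit —
evaluates response-scale prevalence on a 1%-step completeness grid over
75–100%, averages each draw over the grid, and reports the mean of these
draw-averages (point estimate) and their 2.5th–97.5th percentiles
(compatibility interval). Predicting over 75–100% makes GLM output
commensurable with a ≥ 75% CF; the 50–75% range is exposed as a
configuration for sensitivity analysis of largely incomplete samples, where
it yields lower absolute predictions whenever the completeness slope is
positive.

Numerical details: predictions are clipped at 1 by default (the log link
does not bound them; the clip is configurable); a numerically
non-positive-definite Σ̂ is repaired by flooring its eigenvalues at 1e-10;
coefficients aliased by a rank-deficient design (completeness constant at
zero missingness) are treated as exactly 0 with zero variance; a grid step
of 1% is the default because grid-mean averaging is insensitive to finer
steps. A fit degenerate at every ladder stage (e.g. an all-zero response)
is recorded as a *model failure* for that iteration — estimates `NA`,
experiment continues.

## The harness and its metrics

`run_experiment()` crosses sample size × missingness scenarios ×
iterations. Child seeds for every scenario–iteration cell are drawn from
the master seed *before* any work runs, so the experiment is bit-for-bit
reproducible and any single iteration can be replayed with
`run_iteration(cfg, scenario, seed)`; parallel dispatch would not change
results.

Per scenario × estimator × sample the summary reports:

* **median** of defined estimates (accuracy against the 10/30% benchmarks);
* **95% interpercentile range**, 2.5th–97.5th percentiles of defined
  estimates with linear interpolation between order statistics (R quantile
  type 7) — the differences between percentile definitions are far below
  Monte-Carlo noise at 1000 iterations;
* **pct_produced**: share of iterations with a defined estimate, all
  iterations as denominator;
* **pct_zero**: share of *defined* estimates equal to exactly 0%, plus
  `pct_zero_all` with all iterations as denominator — both conventions are
  reported because the denominator materially changes the number in
  high-missingness scenarios, where many iterations are undefined;
* **pct_correct** (per scenario × estimator): share of iterations whose
  estimates strictly order A < B, with *all* iterations as denominator and
  undefined estimates or ties counted as incorrect — an undefined or tied
  pair has not reproduced the generating truth, and this is the only
  denominator rule under which pattern maintenance can fall below the
  production rate, as it visibly does for CFs at 80% missingness.

`verify_raw_pattern()` checks the simulated data themselves (all specimens,
no threshold): prevalence should never hit 0% and should order A < B every
iteration at n = 500, so estimator pattern failures are attributable to the
estimators. At n = 100 and 80% mean missingness the raw data occasionally
do lose every trauma in a sample (a handful of iterations per thousand with
this pool): with only ten affected specimens in sample A, mostly carrying
one- or two-element injuries, complete loss is possible. The check is
therefore asserted at n = 500.

**Retention of empty specimens.** A clipped draw of 100% missingness
produces a 0%-complete specimen with trauma vacuously 0. These are retained
by default — capping at 100% and keeping the specimen is the literal
reading of the generating process — and `drop_empty = TRUE` exposes the
exclusion alternative for sensitivity analysis, since either convention is
defensible and they shift the GLM's completeness slope slightly.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_per_sample` | 500 | specimens | large-sample design; 100 = small-sample design |
| `prevalence_A`, `prevalence_B` | 10, 30 | % | average vs elevated cranial trauma rates; must give whole specimen counts |
| `scenarios` | 20, 40, 60, 80 | % mean missing | low → excessive incompleteness |
| `missing_sd` | 20 | % | preservation heterogeneity between specimens |
| `iterations` | 1000 | — | Monte-Carlo SE ≈ 1.6 pp on a 50% proportion |
| `cf_threshold` | 75 | % | the field's most common inclusion threshold |
| `glm_draws` | 10,000 | draws | interval stability ≪ simulation noise |
| `predict_range` | 75–100 | % | comparability with the CF threshold |
| `grid_step` | 1 | % | averaging insensitive to finer grids |
| `weight_transform` | inverse | — | under-represented bones lose elements first |

## Problem sizes used by the test suite

The unit and property tests run reduced designs chosen to keep analytic
and Monte-Carlo error bounds meaningful: 250 iterations per scenario for
the crude-frequency production-rate checks against the clipped-normal
closed form (3 standard-error bands), 2×10⁵ draws for distributional
checks, 3–4×10⁴ replicates against the exhaustive enumeration oracle on a
6-element schema, and n = 500 per sample for GLM parameter recovery. The
acceptance script runs the full 1000-iteration design.

## Known limitations

* Absolute GLM predictions over 75–100% completeness extrapolate when few
  near-complete specimens remain and then overshoot the benchmarks; under
  heavy missingness only relative patterns between samples are
  trustworthy, and the summary's interpercentile ranges make that plain.
* The element-level trauma vectors and ESS weights are faithful
  reconstructions of, respectively, published case descriptions and a
  published preservation ranking — not the original element-resolution
  data, which are unavailable. Both ship as editable CSVs so exact values
  can be dropped in; results that depend on fine pattern details (e.g.
  exactly how often a one-element fracture survives 80% missingness) carry
  that approximation.
* Between-sample hypothesis testing, mixed-model extensions (random
  effects for multiple fractures per individual), additional covariates,
  and the post-cranial skeleton are out of scope.
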