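# traumasim

Estimating trauma prevalence from skeletal remains is biased by preservation:
lesions on missing bone cannot be observed, so the less complete a sample,
the more once-present trauma goes undiagnosed. Bioarchaeologists commonly
respond by computing **crude frequencies (CF)** only over specimens above a
minimum completeness threshold (most often ≥ 75%), discarding everything
else. An alternative keeps every fragment and instead models trauma with a
**binomial generalized linear model (GLM)** that carries specimen
completeness as a covariate.

`traumasim` provides both estimators for real per-specimen data and a
Monte-Carlo harness that measures how each behaves as completeness decays —
for method researchers, and for practitioners who want to know how far to
trust a prevalence estimate from a fragmentary cranial sample.

## The model

Each specimen is a vector of 48 cranial recording elements over 14 bones
(four regions per bone; two for the small nasals and zygomatics). A
simulated dataset holds two samples, A and B, of *n* once-complete specimens
with benchmark prevalences of exactly 10% and 30%; affected specimens get an
injury pattern drawn uniformly with replacement from a pool of 40 real-life
blunt-force trauma cases (violence, falls, animal encounters, arrow shots,
clinical cases), so simulated fractures follow realistic biomechanical
patterns rather than random scatter.

Missingness is then imposed per specimen: a missing percentage is drawn from
Normal(μ, 20) with μ ∈ {20, 40, 60, 80}, clipped to [0, 100], converted to a
count of the 48 elements, and allocated by successive weighted draws without
replacement. Element weights are inverse to their bone's *effective sample
size* (Walker's fractional bone count), so taphonomically fragile mid-facial
bones vanish first and vault bones and the mandible persist — the pattern
seen in Upper Paleolithic cranial samples.

From the summarized data (completeness %, trauma 0/1 per specimen) each
iteration computes:

* **CF**: `100 · #(trauma & completeness ≥ 75%) / #(completeness ≥ 75%)`,
  undefined if no specimen qualifies;
* **GLM**: binomial regression with log link,
  `log p = β₀ + β₁·[sample=B] + β₂·completeness`, then 10,000 coefficient
  draws from the fitted MVN(β̂, Σ̂), predictions averaged over the 75–100%
  completeness grid (point estimate = draw mean, 95% compatibility interval
  = 2.5th–97.5th draw percentiles).

Over 1000 iterations per scenario the harness reports medians (accuracy),
95% interpercentile ranges (precision), the share of iterations keeping the
true ordering A < B, and the share producing an estimate at all.

## Worked example

```r
library(traumasim)
cfg <- experiment_config(n_per_sample = 100, scenarios = c(20, 80),
                         iterations = 200, seed = 42)
ex <- run_experiment(cfg)
ex
```

```
Trauma-prevalence simulation experiment
  n per sample: 100  benchmarks: 10 / 30 %
  scenarios: 20%, 80%  iterations: 200 

  scenario estimator sample median     lo     hi pct_produced pct_zero
1       20        cf      A  9.677  4.615  14.55        100.0     0.00
2       20        cf      B 29.009 21.429  35.73        100.0     0.00
3       20       glm      A 10.134  7.623  12.05        100.0     0.00
4       20       glm      B 29.114 24.823  33.62        100.0     0.00
5       80        cf      A  0.000  0.000 100.00         34.0    89.71
6       80        cf      B  0.000  0.000 100.00         20.5    63.41
7       80       glm      A 32.499  8.209  71.29        100.0     0.00
8       80       glm      B 70.653 34.292  98.98        100.0     0.00
...
  scenario estimator pct_correct
1       20        cf         100
2       20       glm         100
3       80        cf           1
4       80       glm         100
```

At 20% mean missingness both estimators sit on the benchmarks (medians ≈ 10
and 29–30%) and always keep A < B. At 80% the CF collapses: it produces an
estimate in only a fifth to a third of iterations, is 0% in most of those
(while the underlying data never are), spans the full 0–100% range, and
keeps the correct ordering in 1% of iterations. The GLM always produces a
positive estimate and always preserves A < B, though its absolute medians
overshoot the benchmarks — with this little bone left, relative patterns are
the only trustworthy output.

For real data, `estimate_prevalence("specimens.csv")` (columns `sample`,
`completeness`, `trauma`) returns both estimators with the GLM's
compatibility interval. A command-line front end with `run`, `estimate`,
`validate-fixtures` and `make-pool-template` subcommands lives at
`inst/cli/traumasim.R`.

The trauma-case pool (`inst/extdata/trauma_pool.csv`) and the bone
effective-sample-size table (`inst/extdata/bone_ess_synthetic.csv`, a
synthetic stand-in reproducing the published completeness ranking) are plain
CSVs, validated on load, and can be swapped for your own via
`experiment_config(pool_path=, ess_path=)`.

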