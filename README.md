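# milieu

Health behaviors happen inside a milieu of other lifestyle activities that can
facilitate or conflict with them. `milieu` is an R package for two-wave
questionnaire studies that asks, for a set of focal health behaviors measured
as two-week frequency counts: how much do cognitions about, and performance
of, *other* ongoing lifestyle activities add to the prediction of health
behavior beyond behavior-specific cognitions (intention, attitude, subjective
norm, perceived behavioral control), personality, and past behavior — and for
*whom* do these lifestyle factors matter most?

It is written for health-psychology and behavioral-epidemiology researchers
working with theory-of-planned-behavior-style instruments.

## What the package computes

The analysis target is the **health-behavior index**
*y<sub>i</sub>* = mean of the z-scored follow-up frequencies of the five
health behaviors, with risk behaviors (smoking, getting drunk, fast food)
reversed by multiplying by −1.

1. **Prediction waves.** A small feed-forward network (5 tanh hidden units,
   linear output, MSE loss, patience-based early stopping on a stratified
   validation split, best of 5 seeded restarts) is trained once per predictor
   block — health cognitions (20 columns), personality (5), lifestyle
   cognitions (92), ongoing lifestyle activities (23), baseline health
   behaviors (5) — and once on all blocks (the *saturated model*), each
   producing per-participant estimates of *y*.
2. **Incremental validity.** Hierarchical OLS of *y* on the wave estimates in
   four steps (health cognitions; + personality; + lifestyle cognitions and
   activities; + baseline health), reporting *r*, adjusted R², raw and
   adjusted ΔR², F-change = ((R²−R²₋)/q) / ((1−R²)/(n−p−1)), and
   standardized betas per step.
3. **Two-stage clustering.** Ward (ward.D2) tree over the standardized
   predictors plus the saturated estimate; k chosen by the largest relative
   jump in merge heights (2..8); k-means refinement from the cut centroids;
   groups ordered and labeled by mean index (high … very_low).
4. **Salience profiling.** For every group and variable, Cohen's
   *d* = (mean<sub>group</sub> − mean<sub>rest</sub>) / s<sub>pooled</sub>
   against all other groups combined; |d| ≥ 0.50 flags a salient variable.
   The report blanks sub-threshold cells; the full d matrix is written
   alongside.

Because participant-level data of this kind are rarely deposited, the package
ships a seeded **synthetic questionnaire generator** (`generate_dataset()`)
with a 4-group latent mixture (default sizes 92/50/64/5 at n = 211),
block-specific signal, a planted lifestyle-conflict mechanism and
nonlinearity, count-valued behaviors, and ground-truth labels — plus a
planted-increment mode whose population step-wise ΔR² are set analytically.

## Worked example

```r
library(milieu)

cfg <- run_config(sim_config = default_study_config(seed = 1),
                  out_dir = "run1", seed = 1, verbose = FALSE)
res <- run_pipeline(cfg)

res$waves
#> prediction waves (r with target):
#>   health_cognitions      +0.835
#>   personality            +0.193
#>   lifestyle_cognitions   +0.594
#>   lifestyle_activities   +0.526
#>   baseline_health        +0.908
#>   saturated              +0.876

res$regression
#> hierarchical regression (n = 211)
#>  step            predictor     r adj_r2 adj_r2_change r2_change f_change
#>     1    health_cognitions 0.835  0.695         0.695     0.697   479.78
#>     2          personality 0.193  0.694        -0.001     0.000     0.17
#>     3 lifestyle_cognitions 0.594     NA            NA        NA       NA
#>     3 lifestyle_activities 0.526  0.698         0.004     0.007     2.44
#>     4      baseline_health 0.908  0.823         0.125     0.123   146.33
#>  ...
#> final model: adj R2 = 0.823, F(5, 205) = 196.24, p = 4.28e-76

res$solution
#> two-stage cluster solution: k = 4, sizes 92/49/65/5
#> engagement order: high > moderate > low > very_low
#> engagement d: 0.8, 0.29, -0.88, -2.83
```

Reading the output: each wave's *r* is the correlation between the network's
estimate of the index from that predictor block alone and the actual index
(here baseline behavior is the strongest single predictor, personality the
weakest). The regression steps show what each block adds: on this simulated
sample the health cognitions already explain most of the predictable
variance, lifestyle adds little *on top of the estimates' overlap*, and
baseline behavior adds a further 12.5% adjusted. The clustering recovers the
four planted groups (sizes 92/49/65/5 against the planted 92/50/64/5), ordered
from high to very-low engagement with group-vs-rest effect sizes 0.80 / 0.29 /
−0.88 / −2.83. A salience excerpt for the low-engagement group shows the
planted social signature — visiting friends d = 2.08 and (further down the
table) clubbing — flagged at |d| ≥ 0.5:

```r
salience_table(res$salience)[c("section", "variable", "low")] |> head()
```

All tables are also written to `run1/` as TSV and JSON together with the
serialized saturated network, cluster assignments, ground truth, and a
manifest echoing seeds and configuration; identical configurations reproduce
the bundle byte-for-byte.

## Package layout

- `R/catalog.R`, `R/core_data.R` — behavior catalog, CSV schema, validation,
  standardization, index, predictor blocks
- `R/simulate.R` — synthetic-data generator and study configurations
- `R/network.R` — network training, early stopping, prediction waves
- `R/regression.R` — correlations and hierarchical regression report
- `R/cluster.R` — two-stage clustering, engagement ordering, Cohen's-d
  salience profile
- `R/pipeline.R` — end-to-end orchestration, seeding, artifact bundle
- `vignettes/milieu-methods.Rmd` — the methods notes: model assumptions,
  parameter choices, generator design, numerical decisions, limitations
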