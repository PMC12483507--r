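# hoverwing

Evolutionary allometry of hovering flight: do flying insects keep supporting
their body weight across a large size range by changing their **wing
morphology** or their **wingbeat kinematics**?

In hovering flight the wingbeat-average vertical aerodynamic force of a
flapping wing is, in quasi-steady form,

```
F̄ = ½ ρ S₂ ω̄² C̄_F ,        C̄_F = sin(ᾱ) C̄_Fα ,
```

where `S₂ = ∫ c(r) r² dr` is the wing's second-moment-of-area about the
hinge, `ω̄ = 2 f A_φ` the wingbeat-average angular speed (frequency `f`,
peak-to-peak stroke amplitude `A_φ`), and `ᾱ` the mid-stroke angle-of-attack.
Decomposing `S₂ = S₂* R³ c̄` (wingspan `R`, mean chord `c̄`, dimensionless
shape factor `S₂* = S₂ / (R³ c̄)`) separates wing size, wing shape, and
kinematics:

```
F̄ = ½ ρ R³ c̄ S₂* (2 f A_φ)² sin(ᾱ) C̄_Fα .
```

Under geometric similarity lengths scale as `m^(1/3)`, so `S₂ ~ m^(4/3)` and
flapping-based force falls faster than body weight as size shrinks — small
species must compensate. For each metric the package derives two baselines
against body mass `m`: the similarity exponent `a_sim` (e.g. 4/3 for `S₂`,
1/3 for `R`, 0 for `f`) and the single-metric weight-support exponent `a_ws`
that the metric alone would need, everything else at similarity, to keep
`F̄ ∝ m` (1 for `S₂`, 2/9 for `R`, 0 for `c̄`, −1/3 for `S₂*`, −1/6 for `f`,
`A_φ`, `ω̄`). A fitted allometric exponent `a_allo` is then located between
the two baselines by the **relative allometric scaling factor**

```
a* = 100 · (a_allo − a_sim) / (a_ws − a_sim)  [%] ,
```

0% meaning "scales at similarity, contributes nothing to weight support" and
100% meaning "this metric's allometry alone maintains weight support".

The package provides, for users in comparative biomechanics:

* **Wing morphometrics** — `S`, `R`, `c̄`, `S₂`, `S₂*`, `R*` from outline
  polygons (`morphology_from_outline`), equidistant semi-landmark resampling,
  generalized Procrustes alignment, and phylogenetic PCA of wing shape.
* **Wingbeat kinematics** — fourth-order Fourier fits of stroke/deviation/
  rotation angle traces, wingbeat-average summaries (`f`, amplitudes, `ω̄`,
  mid-stroke `ᾱ`, peak rates), and body kinematics (speed, climb angle,
  stroke-plane pitch `β_sp = β_body − 45°`, advance ratio `J = U/(ω̄R)` with
  the hovering criterion `J < 0.1`).
* **Quasi-steady aerodynamics** — the force model above, weight-support
  ratios `F̄_total/(m g)`, force-coefficient calibration, and
  frequency rescaling `F (f/f̄)²`.
* **Scaling statistics** — log–log OLS and phylogenetic GLS under Brownian
  motion (`scaling_fit` objects with `print`/`summary`/`coef`/`confint`/
  `predict` methods), CI-based allometry classification, Blomberg's K with
  permutation tests, covariate-adjusted regressions, and the a*
  decomposition with its component sum.
* **Synthetic data** — pure-birth phylogenies with Brownian-motion body
  masses, Beta-profile wing outlines with analytically known `S₂*`, and
  periodic wingbeat traces, under three scaling scenarios (isometry,
  morphology-compensated, kinematics-compensated), so the entire pipeline is
  testable end to end without flight recordings.

## Worked example

Run the full pipeline on a synthetic 28-species clade in which wing
morphology alone compensates for size (`S₂ ~ m`), with 0.02 log10 residual
trait noise:

```r
library(hoverwing)
cfg <- scenario_config(n_species = 28, scenario = "morphology_compensated",
                       noise_sd_log10 = 0.02, seed = 2026)
report <- run_pipeline(pipeline_config(mode = "synthetic", scenario = cfg,
                                       seed = 2026))
report$fits_mass$S2
#> Allometric scaling fit (PGLS-BM): S2
#>   n = 28, slope = 0.9979 [0.9025, 1.0933], intercept = 1.5532
#>   R^2 = 0.947, p = 4.432e-18 (slope vs 0)
```

The PGLS slope of `log10 S₂` on `log10 m` is 0.998 with 95% CI
[0.903, 1.093]: the CI excludes the similarity exponent 4/3 (negative
allometry) and covers the generative weight-support exponent 1. The
decomposition locates the compensation in the morphology metrics:

```r
report$decomposition_mass
#> Weight-support contribution decomposition
#>   S2         slope   0.998  a_sim  1.333  a_ws  1.000  a*  101% *
#>   R          slope   0.212  a_sim  0.333  a_ws  0.222  a*  109% *
#>   c_bar      slope   0.305  a_sim  0.333  a_ws  0.000  a*    9% *
#>   S2_star    slope   0.058  a_sim  0.000  a_ws -0.333  a*  -17%
#>   f          slope   0.017  a_sim  0.000  a_ws -0.167  a*  -10%
#>   ...
#>   component sum (f + R + c_bar + S2_star): 91%
```

`S₂`'s allometry carries ~100% of weight support (a* = 101%); the kinematic
metrics sit near 0%, and the four component metrics sum to 91% (100% up to
trait noise). Feeding reported regression estimates in directly works the
same way — with the published eight-species force-regression slopes:

```r
dec <- contribution_decomposition(list(
  f       = scaling_fit(-0.037, -0.238, 0.164, n = 8, metric = "f"),
  R       = scaling_fit( 0.272,  0.173, 0.371, n = 8, metric = "R"),
  c_bar   = scaling_fit( 0.271,  0.147, 0.394, n = 8, metric = "c_bar"),
  S2_star = scaling_fit(-0.031, -0.061, 0.000, n = 8, metric = "S2_star")))
dec$component_sum
#> [1] 105
```

i.e. contributions of 22% (frequency), 55% (wingspan), 19% (chord) and 9%
(wing shape), summing to 105%.

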