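---
title: "Allometric weight support in hovering flight: models, baselines, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allometric weight support in hovering flight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoverwing)
```

## The problem

Hovering insects support their body weight entirely with flapping-wing
aerodynamics. The quasi-steady wingbeat-average vertical force of one
beating wing is

$$\bar F = \tfrac12\,\rho\, S_2\, \bar\omega^2\, \sin(\bar\alpha)\,
\bar C_{F\alpha},$$

with the decomposition $S_2 = S_2^{*} R^3 \bar c$ and
$\bar\omega = 2 f A_\phi$ separating wing shape ($S_2^*$), wing size
($R$, $\bar c$) and wingbeat kinematics ($f$, $A_\phi$, $\bar\alpha$).
Under geometric similarity every length scales as $m^{1/3}$, hence
$S_2 \sim m^{4/3}$: as species get smaller, flapping-based force shrinks
faster than weight, and some trait must deviate from similarity. This
package quantifies *which* trait does, and by how much.

### Assumptions of the force model

* Quasi-steady: wingbeat-average forces only; unsteady mechanisms,
  rotational lift and wake capture are absorbed into the empirical
  coefficient $\bar C_{F\alpha}$, which is assumed shared across species.
* Reynolds-number effects on the force coefficient are neglected — over a
  hoverfly-sized clade Re spans roughly one decade, within which
  force coefficients change little.
* The wing is a rigid flat plate; $\sin(\alpha)$ captures the
  angle-of-attack dependence of the force coefficient.
* Both wings contribute: total force is twice the per-wing force. The
  per-wing/paired-wing bookkeeping only shifts $\bar C_{F\alpha}$, which is
  either supplied or calibrated (below), so no conclusion about scaling
  depends on the factor of two.

## Scaling baselines and the relative allometric scaling factor

For each metric `expected_exponents()` returns the similarity exponent
$a_{\rm sim}$ and the single-metric weight-support exponent $a_{\rm ws}$ —
the exponent the metric alone must follow (all other metrics at similarity)
for $\bar F \propto m$. These follow symbolically from the force model:
e.g. for wingspan, $\bar F \sim R^3\, m^{1/3} \sim m$ gives
$R \sim m^{2/9}$; for frequency, $m^{4/3} f^2 \sim m$ gives
$f \sim m^{-1/6}$.

| metric | $a_{\rm sim}$ | $a_{\rm ws}$ |
|---|---|---|
| $S_2$, $S_2\bar\omega^2$ | 4/3 | 1 |
| $R$ | 1/3 | 2/9 |
| $\bar c$ | 1/3 | 0 |
| $S_2^*$ | 0 | −1/3 |
| $f$, $A_\phi$, $\bar\omega$ | 0 | −1/6 |
| $\bar\alpha$ | 0 | −1/3 |

A fitted exponent $a_{\rm allo}$ is normalized to
$a^{*} = 100\,(a_{\rm allo} - a_{\rm sim}) / (a_{\rm ws} - a_{\rm sim})$,
the percentage of single-metric weight-support compensation. $a^*$ is linear
in $a_{\rm allo}$, so contributions of the multiplicative components of the
force model can be compared on one scale; the component sum over
$\{f, R, \bar c, S_2^*\}$ is near 100% when the joint allometry fully
maintains weight support. When reproducing printed percentage tables the
package rounds half away from zero (`round_half_away()`), with a ~1.5e-8
guard at the half boundary so decimal half-values survive binary arithmetic.

## Statistical machinery

**Log–log fits.** `ols_loglog()` and `pgls_loglog()` fit
$\log_{10} y \sim \log_{10} x$ and return a `scaling_fit` object. PGLS fixes
the Brownian-motion covariance $V_{ij} = $ shared root-to-tip path length
(no Pagel's λ estimation), profiles the BM rate out by ML for the
coefficients, and uses Wald t confidence intervals on GLS standard errors
with $n-2$ degrees of freedom and the residual variance estimated with the
$n-2$ denominator (the convention of standard GLS summaries; the CI
construction for the reported estimates is not otherwise constrained, so
Wald/t was chosen and is used consistently). On a star phylogeny PGLS
reduces exactly to OLS; this is asserted in the tests at $10^{-10}$.

**Allometry verdicts.** `allometry_classify()` compares the 95% CI of the
slope with $a_{\rm sim}$, with inclusive bounds: a CI touching the
similarity exponent is called isometry.

**Blomberg's K.** Implemented from its definition: observed
$\mathrm{MSE}_0/\mathrm{MSE}$ around the GLS phylogenetic mean, divided by
its Brownian-motion expectation
$(\operatorname{tr} C - n/\mathbf 1'C^{-1}\mathbf 1)/(n-1)$, so $K = 1$ is
the BM calibration point. Significance uses tip-shuffling permutations with
the plus-one correction; the default 999 permutations is a convention, not a
derived value. The implementation is cross-checked against an independent
reference implementation in the test suite, and its permutation test is
verified to hold the 5% level under the exchangeable null.

**Phylogenetic PCA.** GLS-centred, $C^{-1}$-weighted covariance
eigen-decomposition; on a star tree it reproduces ordinary PCA. Used on
Procrustes-aligned semi-landmarks flattened to a species × (2·landmarks)
matrix.

**Covariate adjustment.** Wingbeat kinematics can covary with residual
flight behaviour; `covariate_adjustment()` reports the mass effect on a
kinematic trait after regressing out flight speed and climb angle, with a
drop-one partial $R^2$ and a condition-number collinearity warning.

## Morphometrics choices

* **Span axis.** The axis convention is not dictated by the data formats, so
  the package defines it as hinge → farthest outline point. When several
  points tie for farthest (the two tip corners of a rectangular test wing),
  the axis aims at their centroid, which resolves the degeneracy
  symmetrically and makes the closed-form fixtures (rectangle
  $S_2^*=1/3$, triangle $S_2^*=1/2$) exact.
* **Chord at station r** is the *total* intersection length of the outline
  with the perpendicular at $r$ — real outlines are not single-valued
  functions of span. $S_2$ uses midpoint strip integration (default 2000
  strips); the strip-integrated area is cross-checked against the shoelace
  polygon area and a >0.5% discrepancy raises a warning.
* **Semi-landmarks** are placed equidistantly by arc length (default 300)
  after a fixed base landmark, traversal normalized counter-clockwise.
  Sliding (by bending energy or Procrustes distance) is deliberately *not*
  implemented: no criterion is specified for these data, and for smooth wing
  outlines without discrete landmarks the equidistant parameterization is
  already a consistent correspondence. This is a documented deviation.
* **Generalized Procrustes** alignment is iterative (centre, unit centroid
  size, rotation-only SVD superimposition onto the running mean) with a
  $10^{-8}$ mean-shape convergence tolerance; reflections are not allowed,
  so left wings should be mirrored to right-wing convention upstream.

## Kinematics choices

* **Period identification.** No segmentation rule is imposed by the data, so
  the wingbeat period is estimated by a coarse least-squares scan over
  integer cycle counts (fundamental-only Fourier fit), then polished by
  minimizing the order-4 Fourier residual; noiseless sinusoids are recovered
  to solver tolerance and 2° angle noise leaves frequency recovery within
  1%.
* **Angle conventions.** Angles are degrees at I/O and radians internally.
  The stroke plane is fixed at 45° below the body long axis, so
  $\beta_{\rm sp} = \beta_{\rm body} - 45°$. Rotation $\theta = 0$ places
  the wing plane in the stroke plane; with small deviation this makes the
  mid-stroke angle-of-attack equal $|\theta|$.
* **Angle-of-attack** is the angle between the wing plane and the velocity
  of a reference spanwise station (default: the wingtip direction,
  configurable as a fraction of $R$); $\bar\alpha$ averages the two
  mid-stroke phases (the extrema of $\dot\phi$), where force production
  peaks. At stroke reversals the construction is undefined (zero velocity)
  and is not evaluated.
* $\bar\omega = 2 f A_\phi$ exactly; for a pure sinusoid this equals the
  cycle mean of $|\dot\phi|$ (the $\int|\cos| = 2/\pi$ identity), asserted
  analytically in the tests.

## The synthetic-data generator: study conditions

The generator defines the conditions under which the pipeline is validated;
its defaults are fixed, not tuning knobs.

* **Clade**: 28 species (the size of the morphology dataset emulated),
  pure-birth topology rescaled to unit depth — only the covariance structure
  matters, not branching-time realism. Log10 body mass evolves by BM and is
  affinely mapped onto [3, 132] mg, preserving the BM correlation structure
  while guaranteeing the documented mass range.
* **Reference traits** at 30 mg: $R$ = 9.6 mm, $\bar c$ = 3.2 mm,
  $S_2^*$ = 0.34, $f$ = 186 Hz, $A_\phi$ = 100°, $\bar\alpha$ = 42° —
  mid-sized hoverfly values.
* **Scenarios**: `isometry` ($R, \bar c \sim m^{1/3}$, kinematics constant);
  `morphology_compensated` ($R \sim m^{2/9}$, others isometric, so
  $S_2 \sim m$); `kinematics_compensated` (morphology isometric,
  $f \sim m^{-1/6}$).
* **Noise**: intraspecific/residual trait variances are not documented for
  these data, so the residual SD is a free parameter, default 0.02 on log10
  traits (≈5% multiplicative scatter — small relative to the 1.6-decade
  mass range, as species means should be) and 2° additive angle noise on
  traces. These defaults are deliberate choices, stated here, and are not
  revisited.
* **Wing outlines** are Beta(p, q)-density chord profiles: area
  $= R\,\bar c$ exactly and $S_2^{*} = p(p+1)/((p+q)(p+q+1))$ analytically,
  giving closed-form oracles for the morphometrics. `beta_shapes_for_s2star()`
  inverts the relation for a target $S_2^*$.
* **Traces**: sinusoidal stroke, second-harmonic deviation, and a flat-top
  two-harmonic rotation template ($\sin x + \sin 3x / 6$, scaled so the
  mid-stroke value equals the target angle-of-attack). The template is
  band-limited to the third harmonic, hence exactly representable by the
  order-4 Fourier fit — noiseless round trips recover $f$, $A_\phi$ and
  $\bar\alpha$ to solver tolerance by construction.

What passing tests on these data do **not** show: correctness under
digitization artefacts, wing deformation, asymmetric or manoeuvring
wingbeats, non-Brownian trait evolution, or measurement error correlated
with size. The generator emulates the statistical structure the analysis
assumes, not the failure modes of video tracking.

## Numerical and interface choices

* `C_Fα` defaults to 1.8 (revolving-wing measurements at fruit-fly scale);
  `calibrate_cfalpha()` instead sets it so the mass-weighted mean
  weight-support ratio of a dataset equals 1, which is how the pipeline
  runs by default. Calibration rescales all forces by one constant and
  leaves every slope, CI and $a^*$ unchanged.
* Units: mm/mg/deg/Hz at CSV I/O; SI (m, kg, s, rad) inside the aerodynamic
  module only.
* Force-path equivalence: the decomposed force path substitutes
  $\bar\omega = 2 f A_\phi$ exactly, so the two factorizations agree to
  machine precision (asserted at $10^{-12}$ relative).
* Determinism: every stochastic function takes a seed; the pipeline derives
  per-stage seeds from one master seed, and output CSVs are formatted to 6
  significant digits so identical runs are byte-identical.
* Degenerate inputs raise typed errors: self-intersecting or zero-area
  outlines, undersampled traces (< 20 samples per wingbeat), singular
  phylogenetic covariance (duplicated tips at zero distance), zero-variance
  traits, unknown scenarios or metrics.

## Validation problem sizes

The test suite validates the estimators at sizes chosen to balance
Monte-Carlo resolution against a laptop-scale run: OLS CI coverage with
5000 replicates at $n = 8$; PGLS slope recovery with 1000 replicate
28-tip clades; scenario parameter recovery (PGLS CI covering the generative
exponent ≥ 90%) with 200 replicates per scenario; Blomberg's K calibration
with 1000 BM replicates for the mean and 2000 permutation tests (199
permutations each) for the 5% level, on a fixed 16-tip tree. The full suite
runs in well under a minute.

## Known limitations

* PGLS is bivariate with fixed BM covariance: no λ/OU transformations, no
  multivariate PGLS, no measurement-error model.
* The force model is wingbeat-average only; no time-resolved forces.
* Semi-landmark sliding and venation landmarks are out of scope.
* The hovering filter uses the body track alone; induced-flow corrections
  to the angle-of-attack are not modelled (the geometric definition is
  configurable via the spanwise reference station).
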