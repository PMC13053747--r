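---
title: "Methods: Zernike lid-wiper biomarkers for epithelial thickness maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Zernike lid-wiper biomarkers for epithelial thickness maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidwiper)
```

# Scientific background

During every blink the upper eyelid's tarsal margin — the *lid wiper* —
sweeps down across the cornea along a slightly oblique, temporally
rotated path. Over time this repeated shear remodels the corneal
epithelium: it is thicker where the wiper lands first (inferonasally)
and thinner where the stroke exits (superotemporally). The remodeling is
subtle, a fraction of a micrometre per millimetre across the central
cornea, and is invisible on a raw thickness map dominated by the
~53 µm epithelial baseline.

`lidwiper` extracts this signature by decomposing each eye's epithelial
thickness map into Zernike polynomials and reducing the decomposition to
two scalar biomarkers per eye: the **lid-wiper gradient** (µm/mm, the
linear thickness slope along the population blink axis) and the
**lid-wiper coma** (µm, the S-shaped third-order asymmetry along the
same kind of axis). Both are signed, so hypothesis tests against zero
are meaningful at the population level.

# Conventions and coordinate frame

All computations take place in the **right-eye frame**: +x points
nasally, +y superiorly, and angles are measured in degrees
counter-clockwise from +x, reported in [0, 360). Left-eye (OS) maps are
mirrored once across the vertical midline (x → −x) before any fitting,
so nasal/temporal anatomy is aligned across eyes and laterality never
cancels population effects. `mirrorToRightFrame()` enforces single
application: a map already in the right-eye frame refuses to be
mirrored again.

Under the mirror x → −x a Zernike term Z(n, m) maps to ±Z(n, m): terms
with m > 0 flip sign iff m is odd, terms with m < 0 flip iff m is even,
and rotationally symmetric terms (m = 0) are invariant. The package's
mirroring operates on the raw samples, so this parity law is a *derived
property* that the test suite verifies for all 21 terms rather than a
hard-coded table.

# Zernike decomposition

Polynomials are indexed by the ANSI Z80.28 single index
j = (n(n + 2) + m)/2 and normalized to unit RMS over the unit disk,

N(n, m) = sqrt( 2(n + 1) / (1 + δ(m, 0)) ),

so every coefficient is directly interpretable as the RMS contribution
of its mode in micrometres. The default expansion runs to radial order
n = 5 (21 terms) over a 5 mm diameter analytical zone; samples are
scaled by the zone radius r₀ = 2.5 mm, ρ = r / r₀, before evaluation.

Key slots (1-based R index = j + 1):

| term | (n, m) | j | meaning |
|------|--------|---|---------|
| c_j1 | (1, −1) | 1 | Y-tilt (vertical thickness slope) |
| c_j2 | (1, 1)  | 2 | X-tilt (horizontal thickness slope) |
| c_j7 | (3, −1) | 7 | Y-coma |
| c_j8 | (3, 1)  | 8 | X-coma |

Coefficients are obtained by ordinary least squares on the masked,
in-zone samples (`fitMap()`). No weighting is applied: OCT epithelial
segmentation noise is approximately homoscedastic across the central
zone. A fit requires strictly more valid samples than terms and a
full-rank design; both failure modes raise immediate, specific errors
rather than returning silently degraded coefficients. `fitMaps()`
exploits shared geometry — when all maps in a batch sample identical
(x, y) positions with identical masks, one QR factorization solves
every eye at once, which is what makes cohort-scale Monte-Carlo
validation affordable. The fit RMSE (root-mean-square residual over the
fitted samples) is retained per eye as a quality metric.

# From coefficients to biomarkers

## Per-eye vectors

Each eye contributes two vectors in the right-eye frame:

* **tilt vector** t = (c_j2, c_j1) — the gradient of the first-order
  surface; it points toward *thickening*;
* **coma vector** k = (−c_j8, −c_j7) — the primary-coma pair with both
  components sign-flipped, so that it, too, points toward the thickened
  lobe and is directly comparable to the tilt vector.

The sign flip is a convention choice: for a pure coma mode, the
third-order surface is thick on the side *opposite* the coefficient
vector's nominal direction, and flipping both components makes the two
biomarker families share one geometric interpretation.

## Population axes

The population **lid-wiper axis** (LWA) is the direction of the *mean*
vector across eyes — not the circular mean of per-eye angles. Averaging
the Cartesian components first means low-magnitude, noisy eyes
contribute proportionally little to the axis, whereas a circular mean
of angles would weight them equally.

```{r axes}
means <- zernikeCoefficients(
  replace(numeric(21), c(2, 3, 8, 9), c(-1.13, 0.60, 0.16, -0.14)))
angleDegrees(tiltVector(means))
angleDegrees(comaVector(means))
```

The axis points toward thickening (inferonasal); its antipode
(axis − 180°) is the thinning direction (superotemporal).

## Scalar biomarkers

Projecting each eye's vector onto the population axis gives one signed
scalar per eye:

* lid-wiper gradient = |t| · cos(θ_t − LWA_tilt) / r₀  (µm/mm),
* lid-wiper coma = |k| · cos(θ_k − LWA_coma)  (µm).

Division by the zone radius converts the tilt coefficient (µm RMS over
the zone) into a physical thickness slope. Because the axis is the
direction of the mean vector, the mean of the per-eye projections
equals the magnitude of the mean vector — the *centroid magnitude*
reported by `populationSummary()` — an identity the tests verify to
1e-9.

# Circular and bivariate statistics

* **Circular SD** uses Mardia's definition sqrt(−2 ln R̄) with R̄ the
  mean resultant length of the per-eye unit direction vectors. It is
  rotation invariant and undefined (an error, not NA) when R̄ ≈ 0.
  Reference value used in testing: angles {0°, 90°} give 47.70187°.
* **Confidence ellipses** come from the bivariate normal model: the
  level-γ ellipse has semi-axes sqrt(χ²₂(γ) · λᵢ) along the
  eigenvectors of the sample covariance S (data ellipse) or S/n
  (ellipse of the mean). Orientation is reported modulo 180°.
  Collinear clouds raise an error rather than returning a degenerate
  ellipse.

An important interpretive caveat: the package (matching common practice
in this literature) pools both eyes of each subject as independent
observations when computing population axes, ellipses and one-sample
tests. Inter-eye correlation within subjects makes nominal confidence
levels slightly anti-conservative; the generator models eyes of one
subject as draws from the same population, so this caveat applies to
simulated cohorts too.

# Statistical battery

`cohortStats()` applies, per coefficient of interest:

1. Shapiro–Wilk normality at α = 0.05;
2. a one-sample t-test against 0 if normal, otherwise a Wilcoxon
   signed-rank test (exact for n ≤ 25);
3. Bonferroni correction over the family of 4 tilt/coma terms.

`deviceCompatibility()` runs the analogous *paired* battery on
coefficient differences between two devices measured on the same
subject-eye, and reports which terms are poolable. Terms whose paired
differences are identically zero are treated as trivially poolable.

Regressions (`biomarkerRegression()`) are ordinary least squares of a
response (e.g. coma magnitude, RSS astigmatism, RSS higher-order
aberrations excluding coma) on the lid-wiper gradient; slope,
intercept, r, R² and p are reported together so effect size and
significance cannot be quoted in isolation.

# Synthetic cohort generator

`populationSpec()` + `generateCohort()` replace clinical OCT data. The
generator's **defaults are the study conditions**, not tuning knobs:

| parameter | default | rationale |
|-----------|---------|-----------|
| subjects / eyes / scans | 69 / 135 / 2 | the normative-cohort design: both eyes where possible, two repeated scans averaged per eye-date |
| mean coefficients (µm) | c_j0 = 53, c_j1 = −1.13, c_j2 = 0.60, c_j7 = 0.16, c_j8 = −0.14 | published population means; the piston is the central epithelial thickness |
| coefficient SDs (µm) | 1.55, 0.76, 0.62, 0.38 on the four key slots | published population SDs |
| tilt–coma correlation | 0.27 between corresponding components | the reported tilt-vs-coma association; encoded as a −0.27·σσ raw covariance so the *sign-flipped* coma vector correlates positively with tilt |
| pixel noise SD | 0.5 µm per scan | chosen so that after averaging two scans the residual fit RMSE lands near the reported ~0.35 µm level |
| grid | 6 × 6 mm, 0.05 mm spacing | typical OCT epithelial-map export |

Coefficients are drawn from a multivariate normal
(`MASS::mvrnorm`); maps are rendered from the 2.5 mm-normalized basis
(polynomially extended outside ρ = 1 so the 6 mm raster is defined
everywhere), white pixel noise is added per scan, and OS eyes are
stored in their native (un-mirrored) frame so the pipeline's mirroring
step is genuinely exercised. Seeds are applied via an isolated RNG
scope that restores the caller's `.Random.seed`.

What the generator deliberately does **not** model: spatially
correlated segmentation error, eyelid-position covariates, age or
refractive-error structure, within-subject inter-eye correlation beyond
shared population membership, and longitudinal change. It is a
validation instrument for the *pipeline*, not a physiological
simulator.

`degradeWithArtifacts()` optionally corrupts a fraction of scans with a
90° angular wedge offset (+50 µm by default), emulating a segmentation
failure; a wedge of that size shifts the affected eye's tilt terms by
roughly ten population SDs, which the 3-SD outlier screen
(`flagOutliers()`) must flag.

# Numerical choices and validation sizes

* Basis orthonormality is verified on a 500 × 500 grid: the Gram matrix
  of the 21 normalized terms matches the identity to 1e-3 (the residual
  is pure quadrature error of the pixel sum).
* Noiseless in-span round-trips (coefficients → map → fit) must agree
  to 1e-8; linearity of the fit is checked to 1e-9.
* White-noise propagation is checked against the analytic OLS
  covariance σ²(BᵀB)⁻¹ with 200 replicate noise draws.
* The normality-gated test's type-I error is measured over 1000 null
  replicates and must fall inside the exact binomial 99% envelope.
* End-to-end recovery runs 300 replicate cohorts (135 eyes, one scan,
  0.25 mm grid for speed) through the *full* pipeline; the recovered
  tilt axis and gradient centroid must cover the generating truth
  within 2 delta-method standard errors at ≥ 90% rate. These sizes are
  the package's own validation choices, balancing statistical
  resolution against a single-CPU time budget.

# Resolved ambiguities

Decisions the package takes a documented stand on:

1. **Normalization**: ANSI/OSA unit-RMS normalization, so coefficients
   are µm RMS. Unnormalized conventions would rescale every coefficient
   by N(n, m) and change nothing structurally.
2. **Circular SD**: Mardia's sqrt(−2 ln R̄), not the wrapped-normal
   estimator; reference values in the tests pin the definition.
3. **Ellipses**: eigendecomposition of the sample covariance with
   χ²₂ quantiles; both the data ellipse and the ellipse of the mean are
   exposed, since published dispersion figures can refer to either.
4. **Axis dispersion ±56°**: a reported axis of ~298° ± 56° is
   compatible with two readings — circular SD of per-eye directions, or
   the data-ellipse angular half-width. The package computes both
   (`circularSD()` on biomarker angles; `confidenceEllipse()` on the
   vectors) and reports them side by side in `populationSummary()`.
5. **Pooled eyes**: both eyes per subject enter as observations (see
   caveat above); the roster generator mirrors that design.

# Session info

```{r session}
sessionInfo()
```
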