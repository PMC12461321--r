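---
title: "Modelling DES properties from sigma profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DES properties from sigma profiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desgp)
```

This vignette records the model, the numerical choices, and the design
decisions behind `desgp`, in the spirit of a methods section: what is
computed, under which assumptions, and what the test suite does and does
not demonstrate.

## The descriptor

A sigma profile is a compound's unnormalised polarity histogram: the
surface area of its COSMO cavity carrying each screened charge density σ.
The package fixes the standard COSMOtherm discretisation of 61 bins from
−0.030 to +0.030 e·Å⁻² in 0.001 steps. This is the only common convention
with exactly 61 bins, and pinning it package-wide lets every profile file,
generator output and feature vector be validated against one grid. Profiles
are consumed as data (two-column text files); computing them from molecular
structure is a quantum-chemistry task outside this package's scope.

A DES descriptor concatenates up to three component profiles, each
multiplied by its mole fraction, into a 183-entry vector; for
temperature-dependent properties (density, viscosity) the temperature in
Kelvin is appended raw as entry 184. Two conventions had to be fixed
where the construction is underdetermined:

* **Slot order.** Which component occupies which 61-entry block is
  arbitrary, so components are canonically ordered by descending mole
  fraction, ties broken lexicographically by compound id. The descriptor is
  therefore invariant to how the user lists the components — a property the
  test suite checks by permutation. The cost is that the descriptor is only
  piecewise smooth in composition: when two mole fractions cross, blocks
  swap. Mixtures equal under relabelling still map to one point.
* **Unary/binary systems.** Unused slots are zero blocks, equivalent to a
  component with x = 0, so unary, binary and ternary systems share one
  feature space and can be trained jointly.

Temperature is appended in raw Kelvin deliberately: scaling is the model's
concern, and the normaliser puts the temperature dimension on the same
footing as the profile bins so a single kernel length scale is meaningful.

## The Gaussian process

Labels are modelled as a zero-mean joint Gaussian with covariance from one
of three isotropic kernels of Euclidean descriptor distance — RBF,
rational quadratic (which tends to RBF as α → ∞), and Matérn 3/2 — always
supplemented with an index-diagonal White noise term σ_W²δ(i,j) for
observation noise. The White term is index-based: two distinct mixtures
with coincident descriptors share no noise covariance, and cross-covariance
blocks never carry it. Predictions use the standard conditional-Gaussian
identities via a cached Cholesky factorisation; a dedicated test compares
them, at 10⁻⁸, against explicit dense inversion of the partitioned
covariance.

**Normalisation.** Features and labels can be standardised or
log-standardised, z′ = (log z − ⟨log z⟩)/s. Both use the *sample* standard
deviation (divisor n−1); the choice is immaterial at the data sizes used
but must be fixed for reproducibility. Log mode adds a 10⁻³ buffer before
the logarithm so legitimately zero entries (empty sigma bins, empty
component slots) stay finite. Constant dimensions would have s = 0 and are
given s = 1, mapping them to exactly zero. Normaliser moments are computed
from the training split only — validation and test rows never enter them,
which a poisoning test asserts directly.

**Fitting.** The three-to-four hyperparameters (σ², ℓ, α for RQ, σ_W²) are
fitted by maximising the log marginal likelihood with L-BFGS-B on
log-hyperparameters, bounds [10⁻⁶, 10⁶] on each parameter, using analytic
gradients (verified against central finite differences at 10⁻⁴ relative).
Besides a data-driven start (ℓ = median pairwise distance, σ² = label
variance, σ_W² = 0.1), five restarts are drawn log-uniformly in
[10⁻³, 10³] under a fixed seed and the best final likelihood is kept; the
fitted likelihood is never below the starting one. A single shared length
scale is used across all dimensions — normalisation makes the scales
comparable, and per-dimension length scales (ARD) are an explicit
non-goal.

**Numerics.** The Gram matrix gets a diagonal jitter of 10⁻⁸ × mean
diagonal, escalated tenfold (to at most 10⁻²) on Cholesky failure. The
predictive variance includes σ_W² by default — the reported uncertainty is
what a new *measurement* would scatter by; `include_noise = FALSE` gives
the latent-function variance instead, since the convention genuinely
admits both readings.

**Back-transformation.** Under identity or standardising label normalisers
the posterior stays Gaussian and means/variances map exactly. Under
log-standardisation the label posterior is log-normal; the package reports
its median (buffer-corrected) as the point prediction, the multiplicative
95% band exp(μ ± 1.96s), and the exact log-normal variance. The median
rather than the mean keeps the point prediction equal to the
back-transformed posterior mean in log space, which is how log-scale fits
are read in practice.

## Splitting, metrics and the benchmark

Datasets are split 70/20/10 by stratified sampling: labels are cut into 10
equal-frequency quantile bins and the fractions applied within each bin
with largest-remainder rounding, so realised counts are exact to one row
per stratum and each split reproduces the full label distribution (checked
with a Kolmogorov–Smirnov statistic on 1000 synthetic labels). Ten bins is
a compromise: enough resolution to pin the distribution tails, while
keeping several rows per stratum at the dataset sizes used here.

Metrics are R², MAE in label units, and — for viscosity — the mean
absolute logarithmic error in log₁₀ units. Because viscosity spans many
orders of magnitude, its R² is computed on log₁₀ values: on the raw scale
the sum of squares is dominated by the one or two largest labels, and a fit
with excellent multiplicative accuracy can score an arbitrary raw-scale R²
(we measured −0.27 on a fit with MALE 0.23). Log base 10 is used
throughout for viscosity since the quantity of interest is "orders of
magnitude".

The benchmark grid crosses the three kernels with the three label
normalisations (nine fits per property), trains each on the training split
only and ranks by validation R². Feature normalisation is held at
log-standardisation — the configuration retained for final models — with a
27-cell grid behind `extended = TRUE`. A failed fit is recorded as a failed
cell rather than aborting the grid. On synthetic viscosity data spanning
six-plus decades, only the three label-log-standardisation cells reach
validation R² above 0.5; every other cell fails outright. That the choice
matters for viscosity and little else is exactly the behaviour seen on
real DES data.

## Screening and ranking

The screen enumerates all unordered pairs of distinct precursors
(C(n, 2); 58,311 for the 342-precursor library size used in the field),
featurises each at equimolar composition, and predicts density and
viscosity at 298 K and melting temperature from composition alone.
Evaluation is batched but contractually identical (10⁻¹⁰) to one-at-a-time
prediction. Liquidity gates are hard thresholds on predicted melting
temperature: below 275 K for the low-density/low-viscosity search, below
300 K for the high/high search. Gating uses the predictive mean; a
conservative mode gates on mean + 1.96 sd for users who want candidates
that are liquid with high confidence.

How to rank "minimal density AND minimal viscosity" jointly is genuinely
open. The default is the rank sum of the two objectives with viscosity
ranked on the log scale — scale-free, robust to the multi-decade viscosity
range, and returning a strictly dominating candidate first. A Pareto-front
mode (`method = "pareto"`) is available when the user prefers the
non-dominated set to a scalarisation. Ties break on pair ids so rankings
are deterministic and input-order-invariant.

## Chemical-space maps

The 183-D descriptor cloud is mapped to 2-D with probabilistic PCA: the
maximum-likelihood solution W = U_q(Λ_q − σ²I)^{1/2}, with σ² the mean
discarded eigenvalue, computed by closed-form eigendecomposition (via SVD
of the centred data, since d can exceed n). An EM route is retained for
cross-checking; its log-likelihood is monotonically non-decreasing, and
both routes agree on the recovered subspace. PCA signs are arbitrary, so
each component is flipped to make its largest-magnitude loading positive —
without this, maps would not be reproducible across runs.

Projections are posterior-mean latent positions rescaled by the component
standard deviations. With the ML solution the posterior precision is
exactly diag(λ₁, λ₂), so the coordinates are classical PCA scores shrunk
by √(1 − σ²/λ); in the zero-noise limit they *are* classical PCA scores,
which the tests assert. Only the 183-entry composition descriptor is ever
projected — temperature is not part of the map, so all temperatures of one
mixture share an xy point. Property surfaces are built by inverse-distance
weighting on a regular grid spanning the coordinate bounding box, with
exact value reproduction when a grid node coincides with a data point.

## The synthetic-data generator

The generator exists so that every stage — file IO, featurisation,
splitting, fitting, screening, mapping — is testable with known ground
truth and no downloads. Its defaults are fixed once, to values a DES
data set plausibly exhibits:

* **Profiles** are sums of Gaussian bumps on the 61-bin grid: one dominant
  bump near σ = 0 (nonpolar surface) plus 1–3 smaller wing bumps within
  ±0.018 e·Å⁻², scaled to total areas of 40–250 Ų — the range typical of
  small organic molecules. All values are nonnegative by construction.
* **Mixtures** sample 1–3 components (10/65/25%, binary-dominated as in
  real DES databases) with Dirichlet(2) mole fractions; temperatures are
  uniform on 278–372 K for density and viscosity.
* **Labels** come from a documented latent function of the descriptor plus
  Gaussian noise. The default ("moments") family drives properties with
  three interpretable summaries of the aggregated profile: total area,
  polarity spread, and the wing fraction (mass at |σ| > 0.01, a
  hydrogen-bonding proxy). Coefficients are fixed so density falls around
  0.85–1.5 g/mL with a −7×10⁻⁴ K⁻¹ thermal slope, log₁₀ viscosity spans
  roughly −2 to +6 (several orders of magnitude, with a −0.022 per-K
  slope), and melting temperatures fall around 200–550 K. Viscosity noise
  is additive in log₁₀ space (default 0.05), density noise 0.005 g/mL,
  melting noise 3 K — of the order of experimental scatter. A second
  ("rbf") family is a smooth RBF mixture in descriptor space for tests
  that want no moment structure at all.

The latent functions are deliberately simple so that a pipeline failure
localises to the model, not the fixture. All randomness flows from the
spec's single seed; identical specs generate bit-identical data.

What the generator does *not* emulate: real thermodynamics (no eutectic
point, no activity model), correlated measurement error, the heavy
curation noise of literature databases, or the true geometry of quantum-
chemistry sigma profiles. Passing tests therefore demonstrate that the
machinery is correct and that the modelling choices behave as they do on
real data (e.g. the log-normalisation effect), not that any particular
real-data accuracy will be achieved.

## Problem sizes and simulation design in the test suite

The suite runs entirely on synthetic data at sizes chosen to make each
property sharply testable:

* The end-to-end pipeline checks use 500 mixtures from a 30-compound
  library — enough coverage for the GP to reach held-out R² above 0.9 on
  noisy multi-decade viscosity, mirroring on a smaller scale the
  train/validation/test pattern seen with thousands of literature points.
* The zero-noise learnability check uses a 5-compound library with 200
  training mixtures: with so few distinct combinations the training data
  densely covers the combination space, and held-out R² reaches 0.999.
  With a 15-compound library at the same n, most precursor combinations
  are never seen in training and *no* regressor can interpolate them —
  sparse combination coverage, not model error, dominates.
* The hyperparameter-recovery simulation draws from a known Matérn 3/2 GP
  (σ² = 1, ℓ = 0.5, σ_W² = 0.01, 100 training points) over 5-D features
  lying on a 2-D latent manifold, and scores predictions against the
  latent function. The manifold mirrors the low intrinsic rank of real
  sigma-profile descriptors, and matters for identifiability: with iid
  uniform 5-D inputs at this sample size, typical point spacing exceeds
  the length scale, the draw is nearly uncorrelated noise, and held-out
  R² above 0.9 is unattainable for any method. On the manifold the check
  is robust across seeds (R² 0.96–0.99; noise variance recovered well
  within a factor of three).

## Known limitations

* The descriptor's slot-swap discontinuity means two near-identical
  mixtures can sit far apart in feature space when the majority component
  changes; the GP must learn the symmetry from data.
* Exact dense GP algebra scales as O(n³); the package targets the
  thousands-of-points regime of DES property databases, not larger. Sparse
  approximations are out of scope.
* Melting-temperature labels of mixtures that never crystallise cleanly
  are noisy in real databases; the model treats all labels at face value.
* The screen fixes 1:1 binary composition at 298 K. The models accept any
  composition and temperature, but composition grids and ternary screens
  are intentionally not enumerated.
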