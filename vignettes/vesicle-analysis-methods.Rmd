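---
title: "Shape, orientation and spatial interaction of synaptic vesicles: methods"
author: "vesicle3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape, orientation and spatial interaction of synaptic vesicles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesicle3d)
```

## The model

Synaptic vesicles reconstructed from isotropic volume electron microscopy
(FIB-SEM, ~5 nm voxels) are idealized as ellipsoids: each vesicle is the
best algebraic least-squares fit of a general quadric to its annotated
boundary voxels, constrained to be an ellipsoid (positive-definite matrix
part). The collection of vesicle centers inside the pre-synaptic
compartment, with the fitted ellipsoids as marks, is a 3D *marked point
pattern* confined to an irregular domain: the membrane surface, minus any
mitochondria or lysosome.

The analysis has two stages:

1. **Univariate statistics** of each vesicle: surface area, elongation,
   fractional anisotropy and mode of anisotropy of the radii; the axial
   angles between each ellipsoid axis and the shortest straight path from
   the vesicle center to the active zone, tested for uniformity on
   [0°, 90°]; and the vesicle density in 50 nm iso-distance bands from the
   active zone, modelled by a quasi-Poisson log-linear regression.
2. **Interaction statistics** of the pattern: the un-edge-corrected
   K-function (and its L transform) and mark variograms, compared against a
   *hard-core null model* — vesicles located uniformly and independently,
   subject only to non-overlap with each other, the membrane and the
   organelles — simulated by Markov chain Monte Carlo in the actual domain.

## Shape descriptors

With ordered radii $a \ge b \ge c$, the package computes:

* surface area $A = 4\pi\left(\frac{(ab)^{1.6} + (ac)^{1.6} +
  (bc)^{1.6}}{3}\right)^{1/1.6}$ — a closed form whose maximum relative
  error against the exact elliptic-integral area is about 1.04% over
  aspect ratios $a/c \le 20$ (the package carries
  `ellipsoid_area_exact()`, an adaptive-quadrature evaluation of the
  Legendre form, as the independent reference);
* elongation $E = a/c$ and the ratios $a/b$, $b/c$;
* fractional anisotropy $FA = \sqrt{3\mu_2 / (2(\mu_1^2 + \mu_2))}$ and
  mode of anisotropy $MO = \sqrt{2}\,\mu_3\,\mu_2^{-3/2}$, where
  $\mu_1, \mu_2, \mu_3$ are the mean, variance and third central moment of
  the three radii with *population* normalization (divide by 3), the
  convention of the diffusion-tensor shape literature. $MO$ runs from $-1$
  (planar/oblate) through $0$ (orthotropic) to $+1$ (linear/prolate), and
  is undefined (returned `NA`) for an exact sphere.

```{r shape}
shape_summary(c(40, 10, 10))[, c("E", "FA", "MO")]  # prolate limit
```

## Orientation and its null hypothesis

For each vesicle the shortest straight path from its center to the
active-zone mesh defines a direction; the smallest (axial) angle between
that direction and each ellipsoid axis lies in [0°, 90°]. Under the
package's uniformity test the null is *angles uniform on [0, 90]*, checked
with a one-sample Kolmogorov–Smirnov test. Note a genuinely isotropic
random *axis* makes a sin-weighted (not uniform) angle with a fixed
direction; the uniform null is the conventional reading of "completely
random orientation" in this analysis and is what the test implements. The
distinction matters only for interpreting a rejection, not for the
test's calibration, which the suite verifies by simulation under the
uniform null.

A vesicle whose center lies exactly on the active zone has no defined
direction; such records are flagged `degenerate` and excluded from the
tests, with a warning.

## Density profile

The free interior (membrane interior minus organelles) is partitioned into
contiguous 50 nm bands of Euclidean distance to the active-zone surface —
iso-distance shells, the same metric as the orientation paths. Band
volumes are voxel counts on the domain's interior mask; vesicle centers
are binned by the same distance rule, so
$\sum_i \mathrm{count}_i$ equals the number of covered vesicles and
$\sum_i V_i$ plus the organelle volume reproduces the total interior
volume exactly. The count model is
$E[\mathrm{count}_i] = V_i e^{\alpha + \beta d_i}$, fitted as a GLM with
log link and $\log V_i$ offset under quasi-likelihood: the dispersion is
the Pearson $\chi^2$ over $n - 2$ degrees of freedom, and inference on
$\beta$ uses the $t$ reference. The band covariate $d_i$ is the band
mid-distance by default (`d_covariate = "lower"` selects the lower edge;
the choice is a convention, not a claim).

## Second-order and mark statistics

With $N$ centers in free volume $V$ and $N_i(t)$ the number of other
centers within distance $t$ of center $i$,
$$\hat K(t) = \frac{1}{N\hat\lambda}\sum_i N_i(t), \qquad
  \hat\lambda = N/V, \qquad
  \hat L(t) = \left(\tfrac{3}{4\pi}\hat K(t)\right)^{1/3}.$$
**No edge correction is applied**: vesicles cannot exist outside the
synapse, so the pattern is fully observed and the usual corrections
(which assume a partially observed stationary process) would be wrong
here. Consequence: against the *unconfined* Poisson benchmark
$\hat L(t) = t$ there is a small negative boundary bias (about 2% at
$t = 100$ nm in a 1 µm box), which is irrelevant when curves are compared
with null-model simulations in the same domain — the comparison the
package is built around. $V$ excludes organelle volume by default,
consistent with the density-profile convention (`volume = "total"`
switches this).

The mark variogram at distance $t$ averages a mark dissimilarity over all
unordered pairs with inter-center distance in $[t - \Delta, t + \Delta]$
(default $\Delta$ = 10 nm, grid 5–300 nm): squared difference for scalar
marks (surface area, elongation; no geostatistical ½ factor), and the
axial angle $v(m, m') = \arccos|m \cdot m'|$ in degrees for axis marks
(long, middle or short axis). Empty bins are reported `NA` with
`n_pairs = 0`.

## The hard-core null model and envelopes

The null model states that, given the vesicle count and their shapes,
centers and orientations are uniform over all configurations in which no
ellipsoid overlaps another, the membrane, or an organelle. The simulator
is a fixed-$N$ Metropolis relocation chain started at the observed
configuration: a proposal picks one vesicle uniformly, draws a new center
(uniform in the domain bounding box by default, or a Gaussian step of
scale `proposal_sd`) and, by default, a fresh uniform orientation
(`reorient = TRUE` — the null randomizes orientations, since vesicles are
placed independently), and accepts iff every constraint holds. Both
proposals are symmetric, so the stationary law is exactly the stated
uniform distribution; the suite verifies this against closed-form and
rejection-sampling references.

Overlap is decided by the algebraic separation condition for two
ellipsoids: the quartic $\det(\lambda A + B) = 0$ of the pencil of their
homogeneous quadric matrices has two distinct positive real roots iff the
ellipsoids are disjoint (a positive double root is external tangency).
This is exact up to floating point, dependency-free, and fast enough for
the chain's inner loop (bounding-sphere prechecks short-circuit most
pairs). A conservative tolerance treats surface gaps below 0.1 nm as
overlap — inconsequential at 5 nm voxel resolution, and a guard against
floating-point tangencies. Ellipsoid–mesh contact maps space so the
ellipsoid becomes the unit ball and compares each triangle's distance to
the origin with 1; interior membership uses ray parity on the watertight
membrane.

Envelopes are pointwise empirical 2.5%/97.5% quantiles
(linear-interpolation convention) of the statistic across null samples.
Two numerical facts shape their use:

* an interpolated quantile from `n_sim` simulations exceeds its nominal
  tail mass by roughly $0.95/(n_\mathrm{sim}+1)$ per tail, so the default
  `n_samples = 1000` makes the band essentially exact, 40 is the accepted
  minimum, and the package's own calibration experiments use 199;
* distances entirely inside the hard-core exclusion zone give
  $\hat L = 0$ for data and simulations alike — the band is degenerate
  there and exceedance is impossible, so calibration is assessed on the
  informative part of the grid.

## The synthetic generator

`generate_configuration()` emulates the study conditions so the whole
pipeline is testable without the original annotations: a
600 × 600 × 400 nm box compartment (the scale of the reconstructed
synapse blocks) with a centered active-zone patch on one face; vesicle
equivalent diameters from a truncated normal, mean 40 nm, sd 2.5 nm,
truncated at ±3 sd — reading the reported "40 ± 5 nm" as an approximate
range; aspect ratios log-normal with mean elongation 1.96 (oblate mode,
matching the asymmetric-synapse average) or 2.60 (cigar mode, the
symmetric-synapse value), with the log-elongation split between $a/b$ and
$b/c$ in fixed fractions (0.41 / 0.70) so the two modes land on negative
and positive $MO$ respectively. The spreads are chosen to look like
published shape histograms; they are knobs, not claims.

Placement is sequential random insertion under the chosen interaction
(plain hard core, or an extra repulsion gap implemented by inflating the
overlap margin) followed by 50·N Metropolis relaxation proposals, which
equilibrate the pattern to the uniform hard-core law from the biased
sequential start. Orientation alignment draws the long axis from a von
Mises–Fisher field of chosen concentration — a test fixture for the
envelope's power, not a mechanistic model. A density gradient thins
candidate positions with probability $\propto e^{\beta d}$; gradient
patterns skip relaxation (which would erase the trend).

`voxelize()` rasterizes a configuration into the same kind of label stack
the annotations provide (5 nm voxels by default), with per-instance
boundary labels and a closed one-voxel shell per vesicle, and
`fit_configuration_from_stack()` closes the loop: voxelize → extract
boundary voxels → fit recovers centers and radii to within half a voxel.

**What passing tests do not show.** The generator produces box domains,
ellipsoidal organelles and noise-free labels; real synapses have curved
membranes, imperfect annotations and fitting noise, perforated or multi-
active-zone morphologies are out of scope, and nothing here validates the
biological interpretation of a detected interaction — only that the
estimators, the null simulation and the envelope machinery are correct
and powerful enough to detect planted effects of the reported kind
(extra repulsion at 1.5× the vesicle diameter; strong orientation
alignment) in ≥ 90% of replicates at N = 100.

## Numerical choices and problem sizes

* Voxel convention: 0-based indices, world position at the voxel center,
  `world = (index + 0.5) * voxel_size`; arrays indexed `[x, y, z]` in
  memory, TIFF pages are z-slices with rows y — the conversion is
  centralized in `stack_pages_to_array()`.
* Axis signs are canonicalized (first nonzero component positive); all
  angle computations are axial, so signs never affect results.
* Ellipsoid fitting centers and scales the points before the SVD-based
  quadric solve; the fit is exact (residual < 1e-8) on noise-free
  samples.
* Ties: radii sorted by stable order; nearest-triangle ties broken by
  lowest index; distances exactly at a grid value count as inside the
  closed ball.
* The test suite scales simulation sizes to run on a single CPU in
  minutes: calibration uses 40 experiments × 199 null samples at N = 60,
  power uses 50 replicates × 40 samples at N = 100, chain-correctness
  checks use 10,000 emitted samples. The package defaults
  (`n_samples = 1000`) correspond to full-scale analyses.

## Worked example

```{r example, fig.width = 6, fig.height = 4.5}
spec <- generator_spec(n_vesicles = 80, interaction = "repulsive",
                       repulsion_range = 20, seed = 42)
cfg <- generate_configuration(spec)
grid <- seq(20, 150, by = 10)
obs_L <- l_function(k_function(cfg, grid))
nulls <- sample_null(cfg, mcmc_settings(n_samples = 99, seed = 42))
env <- envelope(obs_L, nulls, function(x) l_function(k_function(x, grid)))
plot(env, main = "planted repulsion: L below the null band at small t")
subset(as.data.frame(env), exceed_lo)
```

The observed curve falls below the 2.5% quantile at short distances —
the envelope detects the planted extra repulsion, the synthetic analogue
of vesicle interaction beyond physical extent.
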