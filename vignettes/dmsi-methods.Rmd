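---
title: "Distributed MEG source imaging and its spatial validation: models, parameters, and design choices"
author: "dmsi package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed MEG source imaging and its spatial validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsi)
```

## The problem

Interictal spikes recorded with MEG can be localized on the cortical
surface by distributed source imaging: a fixed set of dipolar sources, one
per vertex of a cortical mesh and oriented along the local surface normal,
is related to the sensor measurements by a linear forward operator (the
gain matrix $G$), and an inverse method estimates the per-vertex current
amplitudes $\hat\jmath$ from the averaged spike at its peak. Different
inverse methods make different prior assumptions and therefore produce maps
with very different spatial character, even when their maxima agree. This
package implements four standard distributed methods, a consensus map, and
the quantitative spatial metrics used to compare them against a known
reference region, together with a synthetic cohort generator so that the
entire comparison runs end to end with no external data.

## The inverse methods

All methods start from the measurement model $m = G j + e$ with sensor
noise $e \sim \mathcal N(0, C)$, $C$ estimated from a spike-free baseline.

**Depth-weighted minimum norm (wMNE).** The Tikhonov-regularized estimate
$\hat\jmath = R G^\top (G R G^\top + \lambda C)^{-1} m$, where $R$ is a
diagonal prior whose entries $\lVert g_i \rVert^{-2w}$ compensate the bias
of the plain minimum-norm solution toward superficial sources. Defaults:
depth exponent $w = 0.5$; weights clipped at their 99.9th percentile
(magnetically near-silent sources would otherwise receive enormous prior
variance) and normalized to unit mean; $\lambda =
\mathrm{tr}(G R G^\top) / (\mathrm{tr}(C)\,\mathrm{snr}^2)$ with an assumed
amplitude SNR of 3. These are conventional defaults in MEG source analysis
software; the package exposes all of them.

**dSPM.** The minimum-norm estimate divided per source by its noise
standard deviation, $z_i = |w_i m| / \sqrt{w_i C w_i^\top}$ ($w_i$ = row
$i$ of the kernel). The map is dimensionless and noise-normalized.

**sLORETA.** The minimum-norm estimate standardized by the diagonal of its
model-variance matrix $S = W G R$:
$s_i = |\hat\jmath_i| / \sqrt{S_{ii}}$. Because $S$ is symmetric positive
semi-definite, $S_{ji} \le \sqrt{S_{jj} S_{ii}}$ with equality at $j = i$,
so for noiseless single-source data the standardized map attains its
maximum at the true source for *any* regularization level and any diagonal
prior — the zero-localization-error property the package verifies by
simulation.

**cMEM.** A maximum-entropy-on-the-mean solver. The cortex is partitioned
into connected parcels grown around data-ranked seeds; in parcel $k$ the
reference law makes sources inactive (a point mass at zero) with
probability $1 - \alpha_k$ and active with probability $\alpha_k$, the
active law a zero-mean Gaussian whose covariance couples neighbouring
vertices. The posterior maximizes entropy relative to this reference
subject to reproducing the whitened peak data in expectation, and is
computed through the smooth concave dual over one multiplier per channel
(damped Newton iteration with analytic gradient and Hessian; gradient
tolerance $10^{-8}$ relative to the data scale, at most 500 iterations,
typically fewer than 10). Parcels whose posterior activation falls below
$\varepsilon = 10^{-3}$ are set exactly to zero ("switched off"), which is
what gives MEM maps their characteristic high contrast and compactness.

**Ave.** Each of the four maps is min-max rescaled to $[0, 1]$ and the
per-vertex arithmetic mean is taken. The rescaling makes the dimensionless
(dSPM, sLORETA) and dimensional (wMNE, cMEM) maps commensurable.

### cMEM hyperparameters

The MEM family leaves several quantities to the implementer; this package
fixes them as follows and exposes each in `parcellate_cortex()` /
`solve_cmem()`:

* **Parcel score**: normalized projection (cosine) of the whitened peak
  data onto each whitened gain column. Parcels are grown to graph
  neighbourhood order 4 (order 0 degenerates to one parcel per vertex).
* **Activation prior** $\alpha_k$: the ratio of the parcel's median score
  to the best parcel's, raised to the 12th power. The strong contrast is
  deliberate: a single-time-sample MEG topography correlates appreciably
  with gain columns tens of millimetres away, so a gentle mapping leaves
  every parcel active and no switch-off ever occurs. With the contrasted
  prior, parcels weakly supported by the data start near
  $\alpha \approx 0$ and are switched off unless the dual optimization
  needs them.
* **Active-law covariance**: within a parcel, the identity smoothed by a
  one-step neighbour average with weight 0.5 (spatially coherent activity);
  its global variance is set so the prior predictive sensor power equals
  one quarter of the sensor power of an internal wMNE reconstruction of
  the same data. The factor below unity is a conservative prior that
  maximizes parcel contrast while keeping the posterior residual within a
  few percent of the wMNE residual (measured during development: at these
  defaults the whitened cMEM residual stayed below 1.05x the wMNE residual
  while distant parcels, more than 30 mm from a simulated focus, carried
  less than 5% of map energy).
* **Depth weighting** enters cMEM only through the internal wMNE solution
  used for the energy scale, not through the active-law covariance itself:
  weighting the active law by inverse column norms systematically amplified
  magnetically near-silent vertices inside active parcels (argmax errors of
  tens of millimetres in development simulations), so it is off by default
  (`active_depth = FALSE`).

## The forward model

The conducting-head forward model is the closed-form field of a current
dipole in a homogeneous sphere, evaluated at point magnetometers oriented
radially on a helmet-like spherical cap (275 channels by default).
Properties of this model that the package exploits and tests: radially
oriented dipoles and dipoles at the sphere centre are magnetically silent;
for radially oriented sensors the volume currents contribute nothing, so
the sensed field equals the free-space field of the primary dipole — an
exact independent oracle for the implementation. Conductivity does not
enter the magnetic field of this model and is carried as metadata. Users
with realistic (BEM-based) head models can import a gain matrix with
`load_gain()`; all solvers are invariant to a global gain rescale with
matched data rescale (tested).

Because normals on a perfect sphere are radial — and therefore silent in
this model — the synthetic cortex is a *bumpy* sphere: the radius is
modulated by smooth low-order angular terms, tilting vertex normals by
~15–25 degrees so that normally-constrained dipoles are visible while a
minority of near-radial vertices remain, as on a real cortex where gyral
crowns and sulcal walls differ in orientation. The surface is built as two
poles plus latitude rings with equal-area vertex allocation, which realizes
any requested vertex count exactly with vertex degrees 5–7.

## Preprocessing

Simulated (or imported) recordings pass through DC-offset removal, a
zero-phase second-order Butterworth notch (60 Hz, ±2 Hz) and bandpass
(0.3–70 Hz), and resampling to 600 Hz where needed. The filter family is
not contractual; the tested contract is ≥26 dB attenuation of the line
tone and near-unity in-band gain. Epochs are cut on the half-open window
$[-1, +1)$ s around each marked spike peak — exactly $2 f_s$ samples with
the peak at index $f_s + 1$ — chosen over the closed window for integer
sample counts and unambiguous concatenation. Epochs overlapping declared
artifact intervals are dropped; a study with fewer than 5 usable epochs is
rejected, the standard clinical exclusion bound.

The noise covariance is the sample covariance of the averaged signal over
the baseline $[-1.0, -0.1)$ s relative to the peak: the window is inside
the epoch and guarded 100 ms away from peri-spike activity. A nominal
"1 s" baseline cannot simultaneously fit in the pre-peak half of a 2 s
epoch and respect the guard, so the 0.9 s window is used and documented.
Diagonal loading of 0.1x the mean diagonal (a common default for
rank-deficient MEG covariances) guarantees positive definiteness; the
estimate is computed from the averaged baseline (a flag for per-epoch
pooling is a possible extension, not currently implemented).

## Spatial-accuracy metrics

All metrics compare a map against a reference region $\Theta$ (the
synthetic focus patch) using straight-line (chord) distances in mm, not
geodesics.

* **Dmin** — distance from the map's maximum-amplitude vertex to the
  nearest vertex of $\Theta$; ties break to the lowest vertex index
  (deterministic, and ties have measure zero on real-valued maps).
* **Reproducibility** — within-patient, within-method interquartile range
  of Dmin (linear-interpolation quantiles), over patients with at least
  two studies.
* **Inter-method distance** — for each method, the mean distance between
  its maximum and the maxima of the other methods for the same study.
* **Spatial dispersion (SD)** —
  $\sqrt{\sum_i d_i^2 \hat\jmath_i^2 / \sum_i \hat\jmath_i^2}$ with
  $d_i = \min_{j\in\Theta} D_{ij}$. The square root is applied so the
  measure is in millimetres. On a thresholded map only surviving
  amplitudes carry weight; whether zeroed vertices are formally included
  is moot because zero amplitudes contribute nothing to either sum.
* **Map size** — the number of *active* vertices after thresholding at
  $t\%$ of the map maximum (rule: retain $v \ge (t/100)\max v$). A vertex
  is active if it survives with a strictly positive value: on a strictly
  positive map, size runs from the full vertex count at 0% down to exactly
  1 at 100% (all tied maxima survive in the degenerate tie case). cMEM
  maps contain exact zeros (switched-off parcels), which are never counted
  as active — a switched-off source is not an active one.
* **Map_Dmin** — the distance from the nearest active vertex of the
  binarized thresholded map to $\Theta$; unlike Dmin it credits the spatial
  extent of the imaged generator.
* **Threshold curves** — SD, Map size and Map_Dmin at thresholds 0, 10,
  …, 100%. Map size is nonincreasing and Map_Dmin nondecreasing in the
  threshold by construction, and at 100% SD degenerates to Dmin — both
  identities are tested.

## Group statistics

Per-study values are compared across the five maps with the Friedman test
(complete blocks, df = methods − 1) and pairwise Wilcoxon signed-rank
tests with Bonferroni correction (factor $\binom{k}{2}$, 10 for five
methods). The signed-rank statistic uses Pratt's treatment of zero
differences — zeros are ranked with the rest and then dropped — with a
normal approximation carrying both tie and zero corrections; exact ties
across methods are common for discrete metrics such as Dmin on a mesh, so
the zero-handling convention matters and is fixed explicitly.

Threshold curves are compared with a Gaussian generalized estimating
equation: metric ~ method × threshold, study as the cluster variable,
exchangeable working correlation, robust (sandwich) standard errors, Wald
chi-square per term. With five methods and the three thresholds 30/60/90%
the term dfs are 4, 2 and 8. The GEE estimator is implemented in the
package (estimating equations with a moment estimator for the working
correlation); under an independence working correlation the coefficients
reduce exactly to ordinary least squares, and the robust covariance
matches the standard clustered sandwich estimator — both reductions are
used as cross-checks in the test suite. When a design leaves the sandwich
matrix rank-deficient (very few clusters), the Wald statistic falls back
to a pseudo-inverse with a warning.

## The synthetic cohort

`cohort_spec()` fixes the study conditions: 28 patients; a truncated
geometric distribution of studies per patient with mean 7.36 (expected
total ≈ 206 studies; the distribution itself is a modelling choice, as
only the totals are typically reported for clinical cohorts); 275 radial
sensors at 600 Hz; an 8,000-vertex cortex for full runs and 2,000 for
desk-scale ones; one focal generator per patient — a connected patch of
10 mm radius grown around a magnetically visible seed (tangential gain
column norm above the median); 20 spikes per study (minimum 5). Each spike
is a smooth biphasic pulse (difference of Gaussians, ~70 ms, unit peak
exactly at the marker) with amplitude tapering from the patch seed
(Gaussian taper, scale half the patch radius). Sensor noise is white, with
variance set so that the RMS of the noiseless signal within ±25 ms of the
peaks over the noise RMS equals the target SNR (default 5). The SNR of a
single epoch is thus defined at the sensor level; since averaging ~20
epochs gains a further factor ~4.5, the peak-sample SNR entering the
solvers is substantially higher.

What the generator deliberately does not emulate: ongoing background brain
rhythms and correlated sensor noise (noise is white; a whitening step makes
the solvers indifferent to this at matched covariance, but real covariance
estimation error is not represented), multiple concurrent spike types or
propagation, realistic coil geometry and gradiometer baselines, head
movement, and the irregular folded geometry of a real cortex. Passing
tests therefore demonstrate the internal consistency and the *relative*
behaviour of the methods under controlled conditions — not clinical-grade
absolute accuracy.

## Determinism and problem sizes

Every randomized quantity derives from a single master seed; per-study
child seeds are drawn once at cohort generation, so any study can be
re-materialized independently and a rerun with the same configuration is
bit-identical (tested). The package's own validation uses a 500-vertex /
80-channel fixture for the solver oracles, 2,000 vertices / 275 channels
for the study-scale properties (sLORETA zero error over 50 single-source
simulations; a 10-patient × 5-study cohort for the directional
comparisons), and the full 8,000-vertex map size semantics where the
vertex count itself is the contract. These sizes were chosen so the whole
validation runs comfortably on a laptop while keeping every property at a
scale where the geometry is non-trivial.

## Known limitations

* The spherical forward model is analytically exact but anatomically
  idealized; imported gains are supported but untested against a BEM
  reference here.
* cMEM's activation prior is data-dependent and deliberately aggressive;
  on data with several simultaneous generators of similar strength the
  12th-power contrast may suppress secondary sources. The exponent is a
  single exposed parameter.
* The GEE implementation covers the Gaussian/identity case with
  exchangeable or independence working correlation — exactly what the
  threshold-curve comparison needs — and nothing more.
* Only the spike peak sample is imaged; time-resolved imaging and
  beamformers are out of scope.
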