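---
title: "Models and methods behind luquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind luquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(luquant)
```

## What the package models

`luquant` characterizes quantitative Lu-177 SPECT/CT imaging entirely in
silico: digital phantoms are forward-projected into noisy dual-window
projection data, reconstructed with in-house OSEM and BSREM-RDP algorithms,
and analysed with the standard phantom metrics — image calibration factor
(ICF), activity quantification error, coefficient-of-variation (CV) noise,
matched-filter spatial resolution and recovery coefficients (RC) — plus a
clinical stage (noise-matched protocol selection, isocontour lesion
segmentation, paired Wilcoxon statistics).

Lu-177 emits a 208 keV gamma (10.4 % intensity) suitable for quantitative
SPECT.  The workflow mirrors a phantom-based characterization of a
CZT-camera reconstruction protocol: a uniform ~5.8 L cylinder filled with
541 MBq calibrates counts to activity, a second 700 MBq cylinder measures
quantification accuracy and noise, and a NEMA IEC sphere phantom
(10–37 mm spheres at 1.6 MBq/mL, cold or ~10:1 hot background) measures
resolution and recovery.

## The forward model

The acquisition is emulated as parallel-beam: for each of the `n_views`
angles the activity and attenuation volumes are rotated into the detector
frame (bilinear in-plane interpolation, zero outside the field of view) and
projected along rays with

* **attenuation** `exp(-integral of mu)` accumulated toward the detector
  (half-voxel self-attenuation convention), with `mu_water = 0.0136 / mm`
  at 208 keV;
* **distance-dependent collimator response**: a Gaussian with
  `FWHM(d) = sqrt(intrinsic^2 + (offset + slope * d)^2)` at distance `d`
  from the collimator face.  Planes are accumulated from the far side with
  incremental blurring (Gaussian variances add), flushing pending variance
  lazily once it exceeds `(0.25 * pitch)^2` — each plane's applied variance
  is within that threshold of nominal, and the adjoint replays the same
  schedule so forward and back projection are exact adjoints (verified to
  machine precision in the tests);
* **septal penetration**: a fraction `pen_fraction` (default 0.20) of the
  geometric counts is diverted into a very broad Gaussian tail
  (`pen_fwhm = 250 mm`, wider than the imaged bodies).  CZT systems with a
  dual-channel low/medium-energy collimator show long-range 208 keV
  penetration streaks across the field of view;
* **scatter/tailing**: the scatter window records
  `scatter_alpha * Gauss(scatter_fwhm)` of the geometric projection; the
  photopeak is contaminated by the same spatial component scaled by the
  window width ratio (24.96 keV / 18.5 keV = 1.349), which a
  dual-energy-window (DEW) estimate with `k = 1` removes exactly in
  expectation (the closed loop the self-calibration oracles exploit).

Counts are scaled so that a source of activity `A` in air produces
`sensitivity * A * T_acq` expected geometric counts over the full
acquisition (default sensitivity 136 cps/MBq, `T_acq` 900 s).  Poisson
noise is drawn independently per bin and window; decay is applied between
phantom preparation and acquisition start (half-life 6.6475 d), while decay
within the 15-minute acquisition (< 0.2 %) is neglected.

Simplifications relative to real hardware: no Monte-Carlo photon transport,
no energy spectra, no dead time, a single fixed detector radius instead of
body-contoured sweeping heads, and rotation-based interpolation instead of
ray tracing.  Because reconstruction shares the projector, pure inverse
crime is controlled by the default `psf_mode = "mismatched"`, which gives
the reconstruction a 20 % narrower collimator model than the simulator
(while penetration and the scatter tail are never modelled by the
reconstruction system matrix — they are either removed by DEW or remain as
genuine model mismatch, as on a console).

## Reconstruction

**OSEM** is the classic ordered-subsets EM on the Poisson likelihood with
the DEW estimate as an additive term, initialized uniform with total counts
equal to total measured counts, no post-filter.  Subsets partition views by
stride and must divide `n_views`.

**BSREM** maximizes `L(x) - beta * U(x)` with the relative difference
prior over unordered 26-neighbour pairs,

`U(x) = sum w_jk (x_j - x_k)^2 / (x_j + x_k + gamma |x_j - x_k| + eps)`,

`w_jk` inverse centre distance (voxel units), `eps = 1e-9 * mean(x)`.  The
update is relaxed block ascent, `alpha_n = alpha0 / (1 + eta * n)` per full
pass (defaults 1 and 0.05), with one-step-late preconditioning:

`x <- x + alpha_n * x / (s_sub + beta * grad U / S) * (penalized subset gradient)`

where `s_sub` is the subset sensitivity.  At `beta = 0` this is
algebraically identical to the OSEM update (the equivalence oracle in the
tests holds to 1e-6 relative).  We chose the one-step-late denominator over
the plain `x / s_sub` preconditioner because the RDP gradient saturates at
body edges; with the plain preconditioner the factory-strength
regularization (`beta = 0.08`) drives a growing limit cycle at desk-scale
counts, while the one-step-late form is stable across
`beta` 0.005–0.08 and leaves the ascent direction unchanged.  The
denominator is clamped below at `0.5 * s_sub`; nonnegativity uses a
`1e-12` floor.  `by_sens = TRUE` weights `beta` voxelwise by the
attenuation-derived sensitivity map `S_j / mean(S)`, so deep (strongly
attenuated) voxels are regularized less.

The emulated factory protocol is BSREM 20i10s with RDP `gamma = 1`,
`beta = 0.08` and sensitivity weighting on.

## Analysis conventions

* **ICF**: total counts in a large cylindrical VOI (23 cm x 22 cm) around
  the calibration cylinder divided by `T_acq` times the decayed prepared
  activity.  Its uncertainty combines `sqrt(C)/C` with the 2 % activity
  uncertainty; applying the square-root counting model to reconstructed
  counts is a deliberate convention although reconstructed voxels are not
  independent Poisson variables.
* **Quantification error**: `(measured - truth) / truth` with the
  matching-protocol ICF, activity in the 22 x 20 cm outer VOI and
  concentration in the 14 x 12.6 cm inner VOI.  VOIs are concentric with
  the phantom axis (offsets unspecified in the source protocol).
* **CV**: sample (n-1) standard deviation over mean in the inner VOI; the
  sample convention is a documented choice.
* **Matched-filter resolution**: blur the known digital phantom with an
  isotropic 3D Gaussian over a 1–30 mm FWHM grid (0.2 mm step), normalize
  both images to unit total inside the analysis mask (body bounding box
  dilated 2 cm) and minimize the sum of squared differences.
* **RC**: reconstructions are trilinearly resampled to the CT grid
  (1.0 x 1.0 x 2.5 mm) treating voxel values as densities and rescaling by
  the voxel-volume ratio so totals are conserved; sphere VOIs are geometric
  masks rendered from the known centres and diameters (the synthetic
  equivalent of manual CT delineation).
* **Lesions**: peak 1-mL mean by convolution with a 6.2 mm-radius sphere
  kernel, 30 % isocontour, 26-connected component containing the seed; the
  mask is frozen and reused across protocols.  A search mask around each
  lesion is required explicitly.
* **Statistics**: Wilcoxon matched-pairs signed-rank with zero differences
  dropped and mid-ranks for ties; exact two-sided p (null distribution by
  rank-sum convolution, equivalent to enumerating all 2^n sign
  assignments) up to n = 25, normal approximation with tie correction
  beyond.  Quartiles use linear interpolation (type 7).

## The penetration mechanism and the interior bias

Septal penetration is the one genuinely free piece of physics: the true
penetration point spread of a ring CZT camera is unpublished, so the
simulator uses a declared surrogate whose parameters were chosen to
reproduce the *documented* behaviour of such systems rather than derived
from first principles.  The chain of effects is:

1. the photopeak contains, besides the collimated counts, a penetration
   tail far broader than the body and a scatter/tail component with the
   scatter window's shape;
2. the reconstruction's DEW correction is calibrated (default
   `k = 1 + pen_fraction / (width_ratio * scatter_alpha)`), console-style,
   to remove the *total* contamination — but necessarily with the scatter
   window's narrower spatial shape;
3. the shape mismatch over-subtracts under the core of a large body and
   under-subtracts at its periphery, so reconstructions show a faint
   halo/streak surplus around the body and a deficit toward its core.

A calibration VOI drawn around the whole phantom integrates over both, so
the calibration factor is nearly unbiased; an interior VOI sees only the
core deficit.  With the defaults (`pen_fraction = 0.20`,
`pen_fwhm = 250 mm`, `sensitivity = 136 cps/MBq`, chosen once so the
simulated calibration factor lands near the mid-90s cps/MBq scale and the
converged interior concentration bias near -5 %), the outer-VOI activity
error stays within about 0.5 % while the interior error converges to
about -4 to -6 % for the one-subset protocols, shrinking below 1 % when
penetration is disabled.  Simpler surrogates fail qualitatively: a tail
narrower than the body reconstructs *inside* it (interior bias comes out
positive), and without the calibrated-DEW shape mismatch the bias largely
cancels between calibration and measurement whatever the tail width —
both dead ends are documented in the package's development history and
motivated this design.

The emulated factory protocol inherits an additional positive interior
offset (a few percent) from its strong regularization smearing the
peripheral surplus inward; since the vendor's penalty normalization is
proprietary, equivalence for that protocol is behavioural (noise and
recovery trends), not quantitative.

## Study conditions and problem sizes

`desk_profile()` fixes the default study conditions: a 64^3 grid at
4.92 mm (twice the intrinsic 2.46 mm pitch), 60 views over 360 degrees,
900 s acquisitions, one day between phantom preparation and acquisition,
and the protocol grid OSEM/BSREM-RDP (`beta = 0.005`, `gamma = 1`) at
{12, 48, 96, 192, 576} updates with one subset plus the factory protocol.
These sizes keep a full calibration + quantification study under ~10
minutes on one CPU; `full_profile()` provides the native 2.46 mm / 180-view
setting for offline use.  The 12i16s subset variant of the source protocol
cannot be formed on 60 or 180 views (16 does not divide them); subset
dependence is exercised with 12 subsets instead, and the factory protocol's
10 subsets divide 60 exactly.

## Numerical choices and degenerate inputs

Compartment boundaries are anti-aliased by 3x3x3 subsampling of boundary
voxels, making voxelized volumes accurate to well under 1 % and activity
fills mass-conserving to < 0.1 %.  Projection bins are floored at 1e-12
before ratios; subset sensitivities at 1e-10 of their maximum.  All-zero
projection data reconstruct to an all-zero volume with a warning; zero
iterations, non-dividing subsets, negative priors, empty VOIs and
out-of-grid geometry raise validation errors.  Every stochastic step
(Poisson draws, lesion placement) takes an explicit seed and restores the
caller's RNG state.

## What passing tests do and do not show

The synthetic generator emulates uniform phantoms, idealized sphere
geometry and Gaussian responses.  Passing the acceptance bounds shows the
pipeline is self-consistent and reproduces the reported error structure
under these conditions; it does not validate the simulator against real
CZT hardware (count-rate effects, realistic penetration streak shapes,
body-contour orbits, CT-derived attenuation) and RC/CV magnitudes at desk
resolution are not expected to match console values sphere by sphere.

## Hot-background recovery

The reported deterioration of small-sphere recovery by background activity
is reproduced here through the relative difference prior: a hot background
raises the `x_j + x_k` denominators of the penalty, weakening its edge
preservation and flattening small spheres, which lowers their recovery
coefficients by tens of points with the usual small-sphere emphasis.  For
an unregularized, converged OSEM reconstruction with geometric sphere VOIs
the effect largely cancels against background spill-in (hot and cold
recovery agree within a few points) — count-rate and spectral effects that
degrade real unregularized reconstructions are outside this simulator's
scope.  Recovery comparisons in the test-suite therefore use the
RDP-regularized protocol.
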