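---
title: "Quantitative Lu-177 SPECT/CT: calibration, recovery and calibrator metrology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative Lu-177 SPECT/CT: calibration, recovery and calibrator metrology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(luquant)
```

## What this package models

Quantitative Lu-177 SPECT/CT rests on a short metrology chain. A well-type
radionuclide calibrator (RNC), ideally traceable to a primary activity
standard, assays the activity used to fill calibration phantoms. A uniform
cylindrical phantom imaged on the SPECT/CT system yields the image
calibration factor (ICF), the number of reconstructed counts per second
and per MBq, which converts counts images into activity. A NEMA IQ body
phantom with hot spheres then characterizes the system's effective
resolution through recovery coefficients (RCs), and the radial profile of
the largest sphere exposes edge ringing ("Gibbs" artifacts) introduced by
resolution-recovery reconstruction. `luquant` implements this whole
analysis chain, together with a synthetic image generator so every stage
can be exercised and verified without scanner data.

## The quantities

**Image calibration factor.** For a counts image of the uniform cylinder
with acquisition duration $\Delta t$,

$$\mathrm{ICF} = \frac{[C]}{\Delta t\,[A_C]} \quad (\mathrm{cps/MBq}),$$

where $[C]$ is the counts concentration (counts/mL) in a cylindrical VOI
of 120 mm diameter and 150 mm length centered in the phantom, and $[A_C]$
is the reference activity concentration from gamma-counter samples. The
VOI is deliberately smaller than the phantom so it excludes edge
artifacts; it is placed on the intensity centroid of the image (voxels
above half the robust maximum), so off-center positioning is tracked
without CT. An alternative calibration sums *all* counts in a
phantom-plus-margin region and divides by the total activity
(`compute_icf_expanded()`); it is immune to edge artifacts but picks up
any background counts inside the margin, which is why the central VOI is
the default. Some reconstructions scale projections by a factor (4 on the
systems that motivated the `rr_scale` field) before reconstruction; this
is sidecar metadata, never inferred from voxel values, and the ICF divides
it out.

**Correction factor.** Systems that emit images already in Bq/mL can
still be off by a constant factor. The correction factor
$\mathrm{CF} = [A_{\mathrm{meas},C}]/[A_C]$, measured over the same
cylinder VOI, removes that bias. Because both paths calibrate against the
same cylinder acquisition, recovery coefficients computed through the
ICF (counts) or CF (Bq/mL) route are algebraically identical — a property
the test suite checks to $10^{-10}$.

**Recovery coefficients.** For sphere $i$ with true concentration
$[A_N]$,

$$\mathrm{RC}_i = \frac{[A_i]}{[A_N]}, \qquad
  [A_i] = \frac{[C_i]}{\mathrm{ICF}\,\Delta t}
  \ \text{or}\ \frac{[A_{\mathrm{meas},i}]}{\mathrm{CF}},$$

with $[C_i]$ the mean counts concentration over a voxel-center-in-sphere
mask at the theoretical sphere diameter. Spheres are localized from the
SPECT image itself: the nominal constellation is first rigidly translated
(voxel-step grid search maximizing summed in-sphere intensity, translation
only since phantoms are scanned axis-aligned), then each center is refined
to the local intensity center of mass. Spheres whose peak is not clearly
above background are flagged rather than silently placed. RC is defined
from the *mean* in-sphere concentration; no peak or max variants are
offered. The cold background is not subtracted, matching a cold-background
phantom fill.

**Gibbs artifact strength.** One point per voxel within a ball around the
largest sphere gives a radial scatter, normalized so the true in-sphere
signal is 1 and background 0. A smoothing spline (generalized
cross-validation by default; the smoothing parameter can be fixed for
exact cross-dataset reproducibility) is fitted to the scatter, and

$$\mathrm{GA} = \frac{M - m}{M + m}$$

with $M$ the spline maximum over $[0,\ 0.9R]$ and $m$ the minimum over
$[0, r_M]$. The 0.9 cap excludes the blur-dominated edge falloff so the
search sees the ringing overshoot, not the falling edge. If the profile
is monotone decreasing (maximum at the center), there is no interior
extremum pair and GA is 0 by definition. This extremum-identification rule
is this package's own operational definition; both the cap and the spline
smoothing are configurable.

**Calibrator metrology.** A session of at least nine repeated vial
readings is background-subtracted, decay-corrected to a common reference
time ($A_\mathrm{ref} = A(t)\,2^{(t - t_\mathrm{ref})/T_{1/2}}$,
$T_{1/2} = 6.6443$ d for Lu-177) and averaged; the session summary is the
mean fractional deviation from the traceable reference and the relative
SD. A corrected dial setting inverts the chamber's dial-response model:
proportional response for VIK-202-type chambers
($d' = d/(1+\mathrm{dev})$), inverse for CRC-type chambers
($d' = d(1+\mathrm{dev})$), and a user-supplied sensitivity for anything
else. These response models are local linearizations inferred from the
direction and size of published factory-to-corrected dial steps; vendor
manuals are not public, so the model is pluggable. Vial-geometry
correction factors are the relative response of the clinical versus the
reference vial geometry; by this package's convention a factor above 1
means the clinical geometry reads relatively high, and a clinical reading
is corrected by division. Uncertainty budgets follow GUM practice:
components declared as $k=1$ normal, $k=2$ normal, or rectangular
half-widths are converted to standard uncertainties (divide by 1, 2,
$\sqrt 3$), combined in quadrature and multiplied by the coverage factor.

## The synthetic data generator

The simulator produces "reconstructed" images directly in image space:

1. a phantom spec (uniform cylinder: 195 mm diameter, 211 mm length,
   6.3 L, 812 MBq; NEMA IQ: six spheres of 13, 17, 22, 28, 37, 60 mm at
   4 MBq/mL on the standard 57.2 mm hexagonal ring, cold background) is
   voxelized by voxel-center membership;
2. the truth map is convolved with an isotropic point-spread function —
   a Gaussian of the stated FWHM, or a difference-of-Gaussians
   $k = (1+\beta)G(\sigma) - \beta G(\alpha\sigma)$ when edge ringing is
   wanted;
3. expected counts per voxel are formed as
   truth $\times$ ICF$_\mathrm{true}$ $\times\ \Delta t\ \times$ voxel
   volume, with $\Delta t$ chosen to hit the standardized stop conditions
   (7 MCts for the cylinder, 3 MCts for the NEMA phantom) given the
   system sensitivity;
4. optional per-voxel Poisson noise is drawn, and the result is emitted
   as counts (optionally multiplied by a declared projection scale) or as
   Bq/mL with a configurable constant quantification bias, so the CF path
   is exercised non-trivially.

Design choices worth stating. The difference-of-Gaussians ringing
surrogate was chosen over frequency-domain apodization because the
blurred-sphere response then has a closed form (a difference of two
blurred-sphere profiles), giving an independent analytic oracle for both
RC and GA tests. Per-voxel Poisson noise is a deliberate simplification:
real reconstructed noise is spatially correlated and
algorithm-dependent, so passing noise-robustness tests here demonstrates
correct statistical behaviour of the estimators, not realism of the noise
texture. Sphere placement uses the standard hexagonal NEMA arrangement
since phantom documentation, not the analysis, fixes it; the diameter set
13–60 mm brackets the clinical range with the 28 and 37 mm intermediate
sizes that matter for lesion dosimetry. The default sphere set sums to
160.4 mL of fill; the conventional rounded total of 161 mL is used where
a total sphere volume is quoted.

RNC sessions are simulated as
$A(t)\,(1+\mathrm{bias})(1+\varepsilon) + \mathrm{background}$ with
$\varepsilon \sim N(0, \mathrm{jitter})$, hourly readings by default;
gamma-counter samples as normal draws at a stated CV around the true
concentration.

## Numerical choices

* Voxel membership is center-in, with a sub-nanometre inclusive slack on
  boundary comparisons so that voxel centers falling exactly on a
  compartment boundary (which happens with integer phantom geometry) are
  not flipped by float rounding of detected centers.
* Convolution is separable, sampled at the voxel pitch, kernels
  renormalized to unit sum, zero padding; grids are built with a 36 mm
  default margin (about 3 subtracted-Gaussian sigmas at FWHM 12 mm,
  $\alpha = 2$) so blur does not leak off the grid and total counts are
  conserved to better than 0.1%.
* The DoG undershoot can push expected counts marginally below zero in
  the cold background; Poisson draws clamp the expectation at zero.
* The constellation search is a voxel-step grid search within ±12 mm;
  subvoxel placement comes from the center-of-mass refinement.
* Smoothing-spline fits require at least 20 points and at least 8
  distinct radii; ties in radius are expected (many voxels share a
  radius) and handled by `stats::smooth.spline`.
* Default working resolution is 4 mm isotropic voxels, matching typical
  clinical Lu-177 SPECT; oracle-equivalence tests run at 2 mm against an
  analytic profile sampled at 1 mm. At these sizes a full four-system,
  two-scenario study runs in seconds.

## What the tests do and do not show

The test suite verifies the analysis chain against closed forms
(volumes, collimator sensitivity formulas, interaction probabilities,
quadrature), against independent analytic oracles (blurred-sphere
profiles for RC and GA), and against self-consistency requirements
(ICF/CF path equivalence, dial-correction closure, decay round trips).
Passing these demonstrates the estimators are implemented correctly and
behave as the physics dictates *under the generator's assumptions*:
isotropic stationary PSF, uncorrelated Poisson noise, perfectly uniform
fills, no scatter, attenuation, septal penetration or dead time. Real
multicenter variability — energy-window choices, reconstruction
implementations, CZT geometry effects — is outside what synthetic data
can certify; on real data this package quantifies those effects, it does
not predict them.

## Worked example

```{r example, eval = FALSE}
cyl <- cylinder_phantom()            # 812 MBq, 6.3 L
nema <- nema_iq_phantom()            # 4 MBq/mL spheres, cold background

cyl_img <- simulate_reconstruction(
  voxelize(cyl, default_grid(cyl, 4)),
  recon_model(psf_fwhm = 12, icf_true = 20, count_target = 7e6,
              noise = "poisson", seed = 1))
icf <- compute_icf(cyl_img, place_cylinder_voi(cyl_img, cyl),
                   cyl$cylinder_concentration)

nema_img <- simulate_reconstruction(
  voxelize(nema, default_grid(nema, 4)),
  recon_model(psf_fwhm = 12, icf_true = 20, count_target = 3e6,
              noise = "poisson", seed = 2))
loc <- locate_spheres(nema_img, nema, fwhm = 12)
diams <- vapply(nema$spheres, `[[`, 0, "diameter")
rc <- compute_recovery_curve(nema_img,
                             segment_spheres(loc, diams, nema_img),
                             icf, 4, diams)
rc
gibbs_analysis(nema_img, nema, icf, 4, fwhm = 12)
```

## Known limitations

* The noise model is per-voxel Poisson; correlated reconstruction noise
  is not emulated, so VOI standard deviations are not comparable to
  clinical values.
* Only rigid translation is used to register the sphere constellation;
  rotated phantom placements are out of scope.
* The chamber dial-response models are first-order local models; a real
  recalibration should verify the corrected dial with a follow-up
  measurement (the closure property the tests enforce).
* The Gibbs extremum rule is an operational definition; comparisons with
  other software should fix the spline smoothing parameter rather than
  rely on GCV agreement.
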