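# luquant

Quantitative Lu-177 SPECT/CT calibration and image-quality analysis in R.

Post-therapy imaging of Lu-177 treatments (PSMA, DOTATATE) needs
quantitatively accurate SPECT/CT: activity estimates feed directly into
patient dosimetry, and differences between scanners, reconstruction
settings and dose-calibrator practice translate into differences in
absorbed-dose estimates between hospitals. `luquant` implements the
standard phantom-based quality-control chain used to characterize and
harmonize such systems, for medical physicists running calibrations and
for multicenter studies pooling data across sites:

* **Image calibration factor** (ICF, cps/MBq) from a uniform cylindrical
  phantom: `ICF = [C] / (Δt [A_C])`, with `[C]` the counts concentration
  in a 120 mm × 150 mm cylindrical VOI and `[A_C]` the gamma-counter
  reference concentration. An expanded-VOI variant and a correction
  factor `CF = [A_meas,C] / [A_C]` for vendor-quantified Bq/mL images
  are included.
* **Recovery coefficients** (`RC_i = [A_i]/[A_N]`) of the six hot
  spheres of a NEMA IQ phantom, with SPECT-based sphere localization and
  theoretical-size segmentation, recovery bands and spread statistics
  across systems.
* **Gibbs-artifact strength** `GA = (M − m)/(M + m)` of the largest
  sphere, from a smoothing-spline fit to the voxelwise radial profile.
* **Radionuclide-calibrator metrology**: repeated-reading sessions with
  background and decay correction, corrected dial settings under
  chamber-specific response models, vial-geometry correction factors,
  and GUM-style expanded uncertainty budgets (quadrature, k = 2).
* **A synthetic data generator** producing reconstructed-image
  surrogates (parametric PSF with optional edge ringing, count-targeted
  Poisson noise, counts or Bq/mL output with a configurable
  quantification bias) and calibrator/gamma-counter sessions, so the
  whole chain is testable end-to-end without scanner data.

## Worked example

Calibrate on a simulated cylinder, then measure recovery on a simulated
NEMA phantom (4 mm voxels, FWHM 12 mm, standardized count targets):

```r
library(luquant)

cyl  <- cylinder_phantom()   # 195 mm x 211 mm, 6.3 L, 812 MBq
nema <- nema_iq_phantom()    # 6 spheres 13-60 mm at 4 MBq/mL, cold background

cyl_img <- simulate_reconstruction(
  voxelize(cyl, default_grid(cyl, 4)),
  recon_model(psf_fwhm = 12, icf_true = 20, count_target = 7e6,
              noise = "poisson", seed = 1))
icf <- compute_icf(cyl_img, place_cylinder_voi(cyl_img, cyl),
                   cyl$cylinder_concentration)
#> ICF = 20.00 cps/MBq (VOI SD 11.9%, 26011 voxels)

nema_img <- simulate_reconstruction(
  voxelize(nema, default_grid(nema, 4)),
  recon_model(psf_fwhm = 12, icf_true = 20, count_target = 3e6,
              noise = "poisson", seed = 2))
loc   <- locate_spheres(nema_img, nema, fwhm = 12)
diams <- vapply(nema$spheres, `[[`, 0, "diameter")
compute_recovery_curve(nema_img, segment_spheres(loc, diams, nema_img),
                       icf, 4, diams)
#> <recovery_curve> sim / synthetic  [A_N] = 4 MBq/mL
#>  diameter concentration        rc
#>        13     0.9915903 0.2478976
#>        17     1.4674834 0.3668709
#>        22     1.9596828 0.4899207
#>        28     2.3486986 0.5871747
#>        37     2.7123553 0.6780888
#>        60     3.1920418 0.7980104
```

The recovered ICF matches the simulator's true sensitivity of 20
cps/MBq, and the recovery coefficients rise with sphere diameter: small
spheres lose apparent concentration to partial-volume blur (the 13 mm
sphere recovers only ~25% of its true concentration at this resolution),
while the 60 mm sphere recovers ~80%. A Gaussian-PSF image shows no
ringing (`gibbs_analysis(...)` reports GA = 0.000 here); reconstructions
with resolution-recovery-style overshoot produce GA > 0.

`run_study()` drives the same chain over a manifest of synthetic systems
× scenarios and aggregates per-family recovery bands, RC spreads and a
GA table; `render_reports()` writes the CSV tables and plots. A thin
command-line wrapper with `simulate`, `icf`, `cf`, `rc`, `gibbs`, `rnc`
and `study` subcommands is installed at `inst/cli/luquant.R`.

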