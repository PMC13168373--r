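# Shared small fixtures, built in code at test time.

# standard phantoms on the default (4 mm) grid
fix_cylinder <- function() cylinder_phantom()
fix_nema <- function() nema_iq_phantom()

# noiseless matched cylinder + NEMA simulation pair and the cylinder ICF
fix_noiseless_pair <- function(fwhm = 12, beta = 0, icf_true = 20,
                               spacing = 4, seed = 1L) {
  cyl <- fix_cylinder()
  nema <- fix_nema()
  cyl_truth <- voxelize(cyl, default_grid(cyl, spacing))
  nema_truth <- voxelize(nema, default_grid(nema, spacing))
  m_cyl <- recon_model(psf_fwhm = fwhm, ringing_beta = beta,
                       icf_true = icf_true, count_target = 7e6,
                       noise = "none", seed = seed)
  m_nema <- recon_model(psf_fwhm = fwhm, ringing_beta = beta,
                        icf_true = icf_true, count_target = 3e6,
                        noise = "none", seed = seed + 1L)
  cyl_img <- simulate_reconstruction(cyl_truth, m_cyl)
  nema_img <- simulate_reconstruction(nema_truth, m_nema)
  icf <- compute_icf(cyl_img, place_cylinder_voi(cyl_img, cyl),
                     cyl$cylinder_concentration)
  list(cyl = cyl, nema = nema, cyl_truth = cyl_truth,
       nema_truth = nema_truth, cyl_img = cyl_img, nema_img = nema_img,
       icf = icf)
}

nema_diameters <- function(spec) vapply(spec$spheres, `[[`, 0, "diameter")

# full recovery curve from an image + calibration
fix_recovery <- function(img, spec, calib, ref_conc = 4, fwhm = 12) {
  loc <- locate_spheres(img, spec, fwhm = fwhm)
  diams <- nema_diameters(spec)
  masks <- segment_spheres(loc, diams, img)
  compute_recovery_curve(img, masks, calib, ref_conc, diams)
}
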