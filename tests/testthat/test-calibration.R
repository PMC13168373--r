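test_that("cylinder VOI geometry and centroid tracking are correct", {
  cyl <- cylinder_phantom()
  truth <- voxelize(cyl, default_grid(cyl, 2, margin = 8))
  voi <- place_cylinder_voi(truth, cyl)
  vol_L <- sum(voi) * voxel_volume_mL(truth) / 1000
  expect_equal(vol_L, pi * 6^2 * 15 / 1000, tolerance = 0.02) # 1.696 L

  # whole-voxel translation: centroid tracking must give the same mask
  shifted <- translate_phantom(cyl, c(8, -6, 4))
  g <- default_grid(cyl, 2, margin = 24)
  voi_a <- place_cylinder_voi(voxelize(cyl, g), cyl)
  voi_b <- place_cylinder_voi(voxelize(shifted, g), shifted)
  expect_identical(sum(voi_b), sum(voi_a))

  expect_error(place_cylinder_voi(truth, cyl, voi_diameter = 200),
               "inside the phantom")
})

test_that("ICF follows its closed form, linearity, and the projection-scale rule", {
  # uniform 1000 counts/mL, dt = 100 s, [A_C] = 0.5 MBq/mL -> 20 cps/MBq
  arr <- array(1000 * 0.064, c(30, 30, 30)) # 4 mm voxels: 0.064 mL
  img <- voxel_image(arr, 4, units = "counts", duration = 100)
  voi <- array(TRUE, dim(arr))
  res <- compute_icf(img, voi, 0.5)
  expect_equal(res$icf, 20, tolerance = 1e-12)
  expect_equal(res$counts_concentration, 1000, tolerance = 1e-12)

  img2 <- img; img2$values <- 3 * img$values
  expect_equal(compute_icf(img2, voi, 0.5)$icf, 3 * res$icf, tolerance = 1e-12)

  img4 <- img; img4$rr_scale <- 4
  expect_equal(compute_icf(img4, voi, 0.5)$icf, res$icf / 4, tolerance = 1e-15)
})

test_that("simulated cylinder recovers the true ICF within 0.5% at 7 MCts", {
  cyl <- cylinder_phantom()
  truth <- voxelize(cyl, default_grid(cyl, 4))
  m <- recon_model(psf_fwhm = 12, icf_true = 12, count_target = 7e6,
                   noise = "poisson", seed = 21L)
  img <- simulate_reconstruction(truth, m)
  icf <- compute_icf(img, place_cylinder_voi(img, cyl),
                     cyl$cylinder_concentration)
  expect_lt(abs(icf$icf - 12) / 12, 0.005)
})

test_that("ICF is insensitive to VOI size inside the uniform region", {
  fx <- fix_noiseless_pair()
  base <- compute_icf(fx$cyl_img, place_cylinder_voi(fx$cyl_img, fx$cyl),
                      fx$cyl$cylinder_concentration)$icf
  for (d in c(-20, 20)) {
    alt <- compute_icf(fx$cyl_img,
                       place_cylinder_voi(fx$cyl_img, fx$cyl,
                                          voi_diameter = 120 + d,
                                          voi_length = 150 + d),
                       fx$cyl$cylinder_concentration)$icf
    expect_lt(abs(alt - base) / base, 0.002)
  }
})

test_that("expanded-VOI ICF agrees with the central VOI when blur is contained", {
  fx <- fix_noiseless_pair()
  central <- fx$icf$icf
  # the simulated fill's activity is the integral of the truth map
  expanded <- compute_icf_expanded(fx$cyl_img, fx$cyl, margin = 24,
                                   ref_activity = total_activity(fx$cyl_truth))$icf
  expect_lt(abs(expanded - central) / central, 0.01)

  # a uniform count background inflates the expanded estimate only
  bgimg <- fx$cyl_img
  bgimg$values <- bgimg$values + 0.05 * mean(bgimg$values)
  exp_bg <- compute_icf_expanded(bgimg, fx$cyl, margin = 24,
                                 ref_activity = total_activity(fx$cyl_truth))$icf
  cen_bg <- compute_icf(bgimg, place_cylinder_voi(bgimg, fx$cyl),
                        fx$cyl$cylinder_concentration)$icf
  expect_gt((exp_bg - expanded) / expanded, (cen_bg - central) / central + 0.01)

  # zero margin on an unblurred image matches the central method closely
  m0 <- recon_model(psf_fwhm = 0, icf_true = 20, count_target = 7e6,
                    noise = "none")
  img0 <- simulate_reconstruction(fx$cyl_truth, m0)
  c0 <- compute_icf(img0, place_cylinder_voi(img0, fx$cyl),
                    fx$cyl$cylinder_concentration)$icf
  e0 <- compute_icf_expanded(img0, fx$cyl, margin = 0,
                             ref_activity = total_activity(fx$cyl_truth))$icf
  expect_lt(abs(e0 - c0) / c0, 1e-9) # same uniform value, exact reference
})

test_that("correction factor recovers the quantification bias and is linear", {
  cyl <- cylinder_phantom(concentration = 0.12)
  truth <- voxelize(cyl, default_grid(cyl, 8))
  mk <- function(qb) recon_model(psf_fwhm = 0, icf_true = 20, duration = 100,
                                 noise = "none", units_out = "Bq/mL",
                                 quant_bias = qb)
  img <- simulate_reconstruction(truth, mk(1.1))
  voi <- place_cylinder_voi(img, cyl)
  expect_equal(compute_cf(img, voi, 0.12)$cf, 1.1, tolerance = 1e-9)

  img1 <- simulate_reconstruction(truth, mk(1))
  expect_equal(compute_cf(img1, voi, 0.12)$cf, 1, tolerance = 1e-9)

  imgc <- img; imgc$values <- 2.5 * img$values
  expect_equal(compute_cf(imgc, voi, 0.12)$cf, 2.5 * 1.1, tolerance = 1e-9)
})

test_that("phantom activity from gamma samples is concentration times volume", {
  expect_equal(phantom_activity_from_samples(3.75, 161), 603.75)
  expect_equal(round(phantom_activity_from_samples(3.75, 161)), 604)
  expect_equal(phantom_activity_from_samples(2, 50), 100)
  expect_equal(phantom_activity_from_samples(c(1, 2, 3), 10), 20)
  expect_error(phantom_activity_from_samples(c(1, -1), 10), ">= 0")
})

test_that("image-based activity estimates behave like spill-out predicts", {
  fx <- fix_noiseless_pair()
  truth_act <- total_activity(fx$cyl_truth) # activity actually simulated
  est_exp <- estimate_total_activity(fx$cyl_img, fx$icf, fx$cyl,
                                     method = "expanded", margin = 24)
  expect_lt(abs(est_exp - truth_act) / truth_act, 0.01)

  # blurred NEMA spheres: plain sphere VOIs lose spill-out counts
  nema_act <- phantom_total_activity(fx$nema)
  est_voi <- estimate_total_activity(fx$nema_img, fx$icf, fx$nema, "voi")
  est_exp2 <- estimate_total_activity(fx$nema_img, fx$icf, fx$nema,
                                      "expanded", margin = 24)
  expect_lt(est_voi, nema_act)
  expect_gte(est_exp2, est_voi)

  zero <- fx$cyl_img; zero$values[] <- 0
  expect_equal(estimate_total_activity(zero, fx$icf, fx$cyl, "voi"), 0)
})

test_that("collimator geometry reproduces the printed sensitivities", {
  disc <- collimator_geometry(3, 1.05, 58, mu_lead = 1.13, K = 0.26)
  expect_equal(round(disc$sensitivity, 3), 0.011)
  symb <- collimator_geometry(2.94, 1.14, 40.64, mu_lead = 1.13, K = 0.26)
  expect_gte(symb$sensitivity, 0.0195)
  expect_lte(symb$sensitivity, 0.0215)
  # thicker septa only reduce sensitivity
  expect_lt(collimator_geometry(3, 50, 58)$sensitivity, disc$sensitivity)
  expect_error(collimator_geometry(3, 1.05, 1, mu_lead = 1.13), "non-positive")
})

test_that("crystal interaction ratio explains the thick-crystal sensitivity gain", {
  r <- crystal_interaction_ratio(9.525, 15.875, 0.111) # 3/8" vs 5/8"
  expect_equal(r, 1.27, tolerance = 0.01)
  expect_equal(crystal_interaction_ratio(10, 10, 0.111), 1)
  expect_equal(crystal_interaction_ratio(9.525, 15.875, 100), 1, tolerance = 1e-6)
})
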