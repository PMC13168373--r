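test_that("effective kernel is normalized and reduces to a Gaussian", {
  m0 <- recon_model(psf_fwhm = 10, ringing_beta = 0, duration = 100)
  k0 <- effective_kernel(m0)
  x <- seq(-40, 40, by = 0.01)
  expect_equal(k0(x), dnorm(x, sd = attr(k0, "sigma")), tolerance = 1e-12)

  m1 <- recon_model(psf_fwhm = 10, ringing_beta = 0.3, ringing_alpha = 2,
                    duration = 100)
  k1 <- effective_kernel(m1)
  expect_equal(sum(k1(x)) * 0.01, 1, tolerance = 1e-6)
  expect_error(recon_model(psf_fwhm = 10, ringing_alpha = 1, duration = 1),
               "> 1")
})

test_that("DoG kernel overshoots at a step edge", {
  m <- recon_model(psf_fwhm = 10, ringing_beta = 0.3, ringing_alpha = 2,
                   duration = 100)
  k <- effective_kernel(m)
  # 1D numerical convolution of a unit step with the kernel
  h <- 0.05
  x <- seq(-60, 60, by = h)
  step <- as.numeric(x < 0)
  resp <- vapply(seq(-20, 20, by = 0.5), function(x0)
    sum(step * k(x0 - x)) * h, 0)
  expect_gt(max(resp), 1.02) # overshoot above the plateau
  expect_lt(min(resp), -0.02) # matching undershoot on the far side
})

test_that("count-target duration follows the stop-condition arithmetic", {
  expect_equal(duration_for_count_target(812, 20, 7e6), 7e6 / (20 * 812))
  expect_equal(duration_for_count_target(812, 20, 7e6), 431.0, tolerance = 1e-3)
  expect_equal(duration_for_count_target(1, 1, 60), 60)
  expect_equal(duration_for_count_target(50, 10, 2e6),
               2 * duration_for_count_target(50, 10, 1e6))
  expect_error(duration_for_count_target(0, 20, 7e6), "positive")
})

test_that("noiseless simulation with a delta kernel reproduces the truth scaling", {
  cyl <- cylinder_phantom()
  truth <- voxelize(cyl, default_grid(cyl, 8))
  m <- recon_model(psf_fwhm = 0, icf_true = 15, duration = 120, noise = "none")
  img <- simulate_reconstruction(truth, m)
  expect_equal(img$values,
               truth$values * 15 * 120 * voxel_volume_mL(truth),
               tolerance = 1e-12)
})

test_that("kernel conserves mass and Poisson totals hit the count target", {
  cyl <- cylinder_phantom()
  truth <- voxelize(cyl, default_grid(cyl, 4))
  m <- recon_model(psf_fwhm = 12, icf_true = 20, count_target = 7e6,
                   noise = "none", rr_scale = 4)
  img <- simulate_reconstruction(truth, m)
  expected <- 20 * img$duration * total_activity(truth) * 4
  expect_equal(sum(img$values), expected, tolerance = 1e-3)

  mp <- recon_model(psf_fwhm = 12, icf_true = 20, count_target = 7e6,
                    noise = "poisson", seed = 11L)
  imgp <- simulate_reconstruction(truth, mp)
  expect_lt(abs(sum(imgp$values) - 7e6), 4 * sqrt(7e6))
})

test_that("Bq/mL output applies the quantification bias", {
  cyl <- cylinder_phantom(concentration = 0.12)
  truth <- voxelize(cyl, default_grid(cyl, 8))
  m <- recon_model(psf_fwhm = 0, icf_true = 20, duration = 100,
                   noise = "none", units_out = "Bq/mL", quant_bias = 1.1)
  img <- simulate_reconstruction(truth, m)
  voi <- place_cylinder_voi(img, cyl)
  expect_equal(mean(img$values[voi]), 1.1 * 0.12 * 1e6, tolerance = 1e-9)
})

test_that("simulation is reproducible by seed", {
  cyl <- cylinder_phantom()
  truth <- voxelize(cyl, default_grid(cyl, 8))
  mk <- function(seed) recon_model(psf_fwhm = 8, icf_true = 20,
                                   count_target = 1e6, noise = "poisson",
                                   seed = seed)
  a <- simulate_reconstruction(truth, mk(5L))
  b <- simulate_reconstruction(truth, mk(5L))
  c <- simulate_reconstruction(truth, mk(6L))
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
})

test_that("calibrator sessions reproduce bias and jitter by construction", {
  m0 <- rnc_model(300, bias = 0, jitter_sd = 0, background = 0,
                  reading_times = as.POSIXct("2026-01-01 08:00:00", tz = "UTC"),
                  ref_time = as.POSIXct("2026-01-01 08:00:00", tz = "UTC"))
  s0 <- simulate_rnc_session(m0)
  expect_equal(s0$readings$raw_MBq, 300, tolerance = 1e-12)

  mb <- rnc_model(300, bias = 0.05, jitter_sd = 0, n_readings = 9L)
  sb <- simulate_rnc_session(mb)
  res <- summarize_session(sb, 300)
  expect_equal(res$deviation_pct, 5, tolerance = 1e-9)

  mj <- rnc_model(300, bias = 0, jitter_sd = 0.004, n_readings = 500L, seed = 3L)
  sj <- simulate_rnc_session(mj)
  resj <- summarize_session(sj, 300)
  expect_equal(resj$sd_pct, 0.4, tolerance = 0.15)
})

test_that("gamma-counter samples behave like the stated sampling model", {
  expect_equal(simulate_gamma_samples(3.75, 3, cv = 0), rep(3.75, 3))
  expect_equal(simulate_gamma_samples(0, 5, cv = 0.05), rep(0, 5))
  x <- simulate_gamma_samples(3.75, 3, cv = 0.01, seed = 2L)
  expect_lt(abs(mean(x) - 3.75) / 3.75, 3 * 0.01 / sqrt(3))
})
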