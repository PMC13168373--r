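ts <- function(s) as.POSIXct(s, tz = "UTC")

test_that("decay correction has the right sign convention and round-trips", {
  t0 <- ts("2026-01-01 08:00:00")
  expect_equal(decay_correct(100, t0, t0), 100)
  one_hl <- t0 + 6.6443 * 86400
  expect_equal(decay_correct(100, one_hl, t0), 200, tolerance = 1e-9)
  # at t_ref the source is stronger; measuring later maps back up
  t1 <- t0 + 3600 * 30
  fwd <- decay_correct(100, t0, t1) # activity at t1 given 100 at t0
  expect_lt(fwd, 100)
  expect_equal(decay_correct(fwd, t1, t0), 100, tolerance = 1e-12)
})

test_that("session summaries recover constructed bias and background", {
  sb <- simulate_rnc_session(rnc_model(300, bias = 0.05, jitter_sd = 0))
  expect_equal(summarize_session(sb, 300)$deviation_pct, 5, tolerance = 1e-9)

  # background equal to the raw reading wipes out the signal entirely
  df <- data.frame(timestamp = ts("2026-01-01 09:00:00") + 0:8 * 3600,
                   raw_MBq = 50, background_MBq = 50)
  s <- rnc_session(df, ref_time = ts("2026-01-01 09:00:00"))
  expect_equal(summarize_session(s, 100)$deviation_pct, -100)

  one <- rnc_session(df[1, ], ref_time = ts("2026-01-01 09:00:00"))
  expect_true(is.na(summarize_session(one, 100)$sd_pct))
})

test_that("session summary is invariant to reading order and time origin", {
  m <- rnc_model(300, bias = 0.03, jitter_sd = 0.004, background = 0.4,
                 seed = 9L)
  s <- simulate_rnc_session(m)
  res <- summarize_session(s, 300)

  perm <- s
  perm$readings <- perm$readings[sample(nrow(perm$readings)), ]
  expect_equal(summarize_session(perm, 300)$deviation_pct, res$deviation_pct)
  expect_equal(summarize_session(perm, 300)$sd_pct, res$sd_pct)

  shifted <- s
  shifted$readings$timestamp <- shifted$readings$timestamp + 86400
  shifted$ref_time <- shifted$ref_time + 86400
  expect_equal(summarize_session(shifted, 300)$deviation_pct,
               res$deviation_pct, tolerance = 1e-12)
})

test_that("dial correction reproduces the chamber response models", {
  expect_equal(corrected_dial(751, 0.0093, "vik202"), 744L)
  expect_equal(corrected_dial(751, -0.0093, "vik202"), 758L)
  expect_equal(corrected_dial(456, 0.0155, "crc55tr"), 463L)
  expect_equal(corrected_dial(751, 0, "vik202"), 751L)
  expect_equal(corrected_dial(500, 0.02, "generic", sensitivity = 1e-3), 480L)
  expect_error(corrected_dial(500, 0.02, "generic"), "sensitivity")
  expect_error(corrected_dial(751, 0.6, "vik202"), "50")
})

test_that("one dial-correction step closes the loop under each model", {
  # local response models: vik reads proportionally to dial, crc inversely
  read_vik <- function(dial, dial0, dev) (1 + dev) * dial / dial0
  read_crc <- function(dial, dial0, dev) (1 + dev) * dial0 / dial
  for (dev in c(-0.1, -0.04, 0.03, 0.1)) {
    d1 <- corrected_dial(751, dev, "vik202")
    expect_lt(abs(read_vik(d1, 751, dev) - 1), 0.001)
    d2 <- corrected_dial(456, dev, "crc55tr")
    expect_lt(abs(read_crc(d2, 456, dev) - 1), 0.001)
  }
})

test_that("geometry correction factor isolates the relative vial response", {
  mk <- function(act, bias, seed) simulate_rnc_session(
    rnc_model(act, bias = bias, jitter_sd = 0, seed = seed),
    dial_setting = 751L)
  same <- geometry_correction_factor(mk(291, 0.02, 1), mk(158, 0.02, 2),
                                     291, 158)
  expect_equal(same, 1, tolerance = 1e-9)

  # clinical vial responding 0.6% low relative to the reference vial
  low <- geometry_correction_factor(mk(291, 0.02, 1),
                                    mk(158, 0.02 - 0.006 * 1.02, 2), 291, 158)
  expect_equal(low, 0.994, tolerance = 1e-3)

  # invariant to the absolute activity level (chamber linearity)
  low2 <- geometry_correction_factor(mk(66, 0.02, 1),
                                     mk(35, 0.02 - 0.006 * 1.02, 2), 66, 35)
  expect_equal(low2, low, tolerance = 1e-9)

  bad <- mk(158, 0.02, 2); bad$dial_setting <- 700L
  expect_error(geometry_correction_factor(mk(291, 0.02, 1), bad, 291, 158),
               "same chamber")
})

test_that("uncertainty combination follows GUM quadrature", {
  expect_equal(combine_uncertainty(
    uncertainty_budget("fidelis", 2.8, "normal_k2", k = 2)), 2.8)
  expect_equal(combine_uncertainty(
    uncertainty_budget(c("a", "b"), c(3, 4), "normal_k1", k = 1)), 5)
  expect_equal(combine_uncertainty(
    uncertainty_budget(c("cal", "dilution"), c(3.3, 2),
                       c("normal_k2", "rectangular_halfwidth"), k = 2)),
    4.03, tolerance = 0.01)
})

test_that("combined uncertainty is permutation-invariant and monotone", {
  mags <- c(1.2, 0.4, 2.8, 0.7)
  dists <- c("normal_k1", "rectangular_halfwidth", "normal_k2", "normal_k1")
  base <- combine_uncertainty(uncertainty_budget(letters[1:4], mags, dists))
  p <- c(3, 1, 4, 2)
  expect_equal(combine_uncertainty(
    uncertainty_budget(letters[p], mags[p], dists[p])), base)
  for (i in seq_along(mags)) {
    up <- mags; up[i] <- up[i] + 0.5
    expect_gt(combine_uncertainty(uncertainty_budget(letters[1:4], up, dists)),
              base)
  }
  expect_gte(base, 2 * 2.8 / 2) # >= k x largest standard component
})
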