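#' Reconstruction model for the synthetic SPECT simulator
#'
#' Parametrizes a synthetic "reconstructed" SPECT image: an isotropic
#' point-spread function (pure Gaussian, or difference-of-Gaussians when
#' `ringing_beta > 0`, which produces the edge overshoot/undershoot typical
#' of resolution-recovery reconstructions), a true image calibration factor
#' (cps/MBq), count-targeted acquisition duration, optional per-voxel
#' Poisson noise, and the output unit convention (raw counts, or Bq/mL with
#' an optional multiplicative quantification bias, emulating
#' vendor-quantified images whose scale is off by a constant factor).
#'
#' Exactly one of `count_target` and `duration` must be given.
#'
#' @param psf_fwhm PSF full width at half maximum, mm.
#' @param ringing_beta DoG overshoot amplitude (>= 0; 0 = pure Gaussian).
#' @param ringing_alpha DoG width ratio of the subtracted Gaussian (> 1).
#' @param icf_true true system sensitivity in cps/MBq.
#' @param quant_bias multiplicative bias applied when emitting Bq/mL.
#' @param count_target total-count stop condition (e.g. 7e6 for the
#'   cylinder, 3e6 for the NEMA phantom).
#' @param duration fixed acquisition duration in seconds.
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer RNG seed (recorded in the output metadata).
#' @param units_out `"counts"` or `"Bq/mL"`.
#' @param rr_scale projection scale convention recorded in the sidecar
#'   (counts images only); voxel values are multiplied by it.
#' @return A `recon_model` list.
#' @export
recon_model <- function(psf_fwhm = 12, ringing_beta = 0, ringing_alpha = 2,
                        icf_true = 20, quant_bias = 1,
                        count_target = NULL, duration = NULL,
                        noise = c("none", "poisson"), seed = 1L,
                        units_out = c("counts", "Bq/mL"), rr_scale = 1) {
  noise <- match.arg(noise)
  units_out <- match.arg(units_out)
  if (psf_fwhm < 0) stop("`psf_fwhm` must be >= 0")
  if (ringing_beta < 0) stop("`ringing_beta` must be >= 0")
  if (ringing_alpha <= 1) stop("`ringing_alpha` must be > 1")
  if (icf_true <= 0) stop("`icf_true` must be positive")
  if (is.null(count_target) == is.null(duration))
    stop("exactly one of `count_target` and `duration` must be set")
  structure(list(psf_fwhm = psf_fwhm, ringing_beta = ringing_beta,
                 ringing_alpha = ringing_alpha, icf_true = icf_true,
                 quant_bias = quant_bias, count_target = count_target,
                 duration = duration, noise = noise, seed = as.integer(seed),
                 units_out = units_out, rr_scale = rr_scale),
            class = "recon_model")
}

#' Effective 1D point-spread kernel
#'
#' Returns the radially symmetric 1D kernel profile implied by a
#' reconstruction model: `k(x) = (1+beta) G(x; sigma) - beta G(x; alpha
#' sigma)` with `sigma = fwhm / (2 sqrt(2 log 2))`. The kernel integrates
#' to one; `beta = 0` gives a pure Gaussian; `beta > 0` gives a
#' difference-of-Gaussians whose step response overshoots at edges.
#'
#' @param model a `recon_model` (or a list with `psf_fwhm`, `ringing_beta`,
#'   `ringing_alpha`).
#' @return A function of distance (mm) returning the kernel density, with
#'   attributes `sigma`, `beta`, `alpha`.
#' @export
effective_kernel <- function(model) {
  beta <- model$ringing_beta
  alpha <- model$ringing_alpha
  if (beta < 0) stop("`ringing_beta` must be >= 0")
  if (alpha <= 1) stop("`ringing_alpha` must be > 1")
  sigma <- model$psf_fwhm / (2 * sqrt(2 * log(2)))
  k <- function(x) (1 + beta) * stats::dnorm(x, sd = sigma) -
    beta * stats::dnorm(x, sd = alpha * sigma)
  attr(k, "sigma") <- sigma
  attr(k, "beta") <- beta
  attr(k, "alpha") <- alpha
  k
}

# separable 3D Gaussian blur; discrete 1D kernels are sampled at the voxel
# pitch and renormalized to unit sum, so mass is conserved away from edges
.blur_gaussian <- function(values, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(values)
  for (axis in 1:3) {
    h <- spacing[axis]
    half <- max(1L, ceiling(4 * sigma_mm / h))
    kx <- (-half:half) * h
    k1 <- exp(-kx^2 / (2 * sigma_mm^2))
    k1 <- k1 / sum(k1)
    values <- .conv_axis(values, k1, axis)
  }
  values
}

# convolve along one axis with a short symmetric kernel (zero padding),
# implemented as a banded-matrix multiply so BLAS does the work
.conv_axis <- function(values, k1, axis) {
  d <- dim(values)
  n <- d[axis]
  half <- (length(k1) - 1L) / 2L
  C <- matrix(0, n, n)
  for (j in seq_along(k1)) {
    off <- j - half - 1L
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    C[cbind(idx[ok], src[ok])] <- C[cbind(idx[ok], src[ok])] + k1[j]
  }
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(values, perm)
  dv <- dim(v)
  v <- C %*% matrix(v, nrow = n)
  dim(v) <- dv
  aperm(v, order(perm))
}

# apply the model PSF (Gaussian or DoG) to a 3D array
.apply_psf <- function(values, model, spacing) {
  sigma <- model$psf_fwhm / (2 * sqrt(2 * log(2)))
  if (sigma <= 0) return(values)
  g1 <- .blur_gaussian(values, sigma, spacing)
  if (model$ringing_beta == 0) return(g1)
  g2 <- .blur_gaussian(values, model$ringing_alpha * sigma, spacing)
  (1 + model$ringing_beta) * g1 - model$ringing_beta * g2
}

#' Acquisition duration for a total-count stop condition
#'
#' Standardized acquisition protocols stop at a fixed total count (7 MCts
#' for the cylinder, 3 MCts for the NEMA phantom) so that count statistics
#' are comparable across systems of different sensitivity.
#'
#' @param truth MBq/mL `voxel_image` truth map (or a total activity in MBq).
#' @param icf_true system sensitivity in cps/MBq.
#' @param target total counts.
#' @return Duration in seconds.
#' @export
#' @examples
#' duration_for_count_target(812, 20, 7e6) # 431 s
duration_for_count_target <- function(truth, icf_true, target) {
  act <- if (inherits(truth, "voxel_image")) total_activity(truth) else as.numeric(truth)
  if (!is.finite(act) || act <= 0) stop("total activity must be positive")
  if (icf_true <= 0 || target <= 0) stop("icf and count target must be positive")
  target / (icf_true * act)
}

#' Simulate a reconstructed SPECT image
#'
#' Applies the model PSF to an activity truth map, scales to expected
#' counts (`truth (*) k * icf_true * duration * voxel volume`), optionally
#' draws per-voxel Poisson noise, and emits either a counts image (voxel
#' values additionally multiplied by `rr_scale`, which is recorded in the
#' metadata) or a Bq/mL image (counts converted back through the true
#' calibration and multiplied by `quant_bias`).
#'
#' @param truth `voxel_image` in MBq/mL.
#' @param model a `recon_model`.
#' @param system_id,scenario provenance labels stored in the output.
#' @return A `voxel_image` in the model's output units.
#' @export
simulate_reconstruction <- function(truth, model, system_id = "sim",
                                    scenario = "synthetic") {
  stopifnot(inherits(truth, "voxel_image"), inherits(model, "recon_model"))
  if (truth$units != "MBq/mL") stop("truth map must be in MBq/mL")
  duration <- model$duration %||%
    duration_for_count_target(truth, model$icf_true, model$count_target)
  vox <- voxel_volume_mL(truth)
  blurred <- .apply_psf(truth$values, model, truth$spacing)
  expected <- blurred * model$icf_true * duration * vox
  counts <- if (model$noise == "poisson") {
    set.seed(model$seed)
    # DoG undershoot can leave tiny negative expectations; clamp at zero
    array(stats::rpois(length(expected), pmax(expected, 0)), dim(expected))
  } else expected
  if (model$units_out == "counts") {
    voxel_image(counts * model$rr_scale, truth$spacing, units = "counts",
                duration = duration, origin = truth$origin,
                system_id = system_id, scenario = scenario,
                rr_scale = model$rr_scale)
  } else {
    bq <- counts / (model$icf_true * duration * vox) * 1e6 * model$quant_bias
    voxel_image(bq, truth$spacing, units = "Bq/mL", duration = duration,
                origin = truth$origin, system_id = system_id,
                scenario = scenario)
  }
}

#' Radionuclide-calibrator session model
#'
#' Describes a simulated measurement session on a well-type radionuclide
#' calibrator: a vial of known activity at a reference time, decaying with
#' the Lu-177 half-life, read repeatedly with a constant relative bias
#' (dial miscalibration), multiplicative Gaussian jitter (repositioning and
#' electrometer noise), and an additive background.
#'
#' @param true_activity_at_ref vial activity at `ref_time`, MBq.
#' @param half_life radionuclide half-life in days (default Lu-177,
#'   6.6443 d).
#' @param bias constant fractional reading bias (0.05 = reads 5% high).
#' @param jitter_sd fractional standard deviation of reading noise.
#' @param background additive background reading, MBq.
#' @param n_readings number of readings (protocols use at least 9).
#' @param reading_times `POSIXct` times; default hourly from `ref_time`.
#' @param ref_time reference `POSIXct` time.
#' @param seed RNG seed.
#' @return An `rnc_model` list.
#' @export
rnc_model <- function(true_activity_at_ref, half_life = 6.6443, bias = 0,
                      jitter_sd = 0, background = 0, n_readings = 9L,
                      reading_times = NULL,
                      ref_time = as.POSIXct("2026-01-01 08:00:00", tz = "UTC"),
                      seed = 1L) {
  if (true_activity_at_ref <= 0) stop("true activity must be positive")
  if (half_life <= 0) stop("half-life must be positive")
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0")
  if (is.null(reading_times)) {
    reading_times <- ref_time + 3600 * seq_len(n_readings)
  }
  if (length(reading_times) < 1L) stop("at least one reading is required")
  structure(list(true_activity_at_ref = true_activity_at_ref,
                 half_life = half_life, bias = bias, jitter_sd = jitter_sd,
                 background = background,
                 reading_times = reading_times, ref_time = ref_time,
                 seed = as.integer(seed)),
            class = "rnc_model")
}

#' Simulate a calibrator reading session
#'
#' Each reading is `A(t) * (1 + bias) * (1 + eps) + background` with
#' `eps ~ N(0, jitter_sd)` and `A(t)` the decayed activity at the reading
#' time.
#'
#' @param model an `rnc_model`.
#' @param protocol,chamber_model,dial_setting,vial_geometry session
#'   metadata carried into the result.
#' @return An `rnc_session` (see [rnc_session()]).
#' @export
simulate_rnc_session <- function(model, protocol = "factory",
                                 chamber_model = "vik202",
                                 dial_setting = NA_integer_,
                                 vial_geometry = "reference") {
  stopifnot(inherits(model, "rnc_model"))
  set.seed(model$seed)
  t <- model$reading_times
  dt_days <- as.numeric(difftime(t, model$ref_time, units = "days"))
  a_t <- model$true_activity_at_ref * 2^(-dt_days / model$half_life)
  eps <- stats::rnorm(length(t), 0, model$jitter_sd)
  raw <- a_t * (1 + model$bias) * (1 + eps) + model$background
  rnc_session(data.frame(timestamp = t, raw_MBq = raw,
                         background_MBq = model$background),
              protocol = protocol, chamber_model = chamber_model,
              dial_setting = dial_setting, vial_geometry = vial_geometry,
              ref_time = model$ref_time)
}

#' Simulate gamma-counter sample measurements
#'
#' Emulates taking small (1 mL) samples from a phantom fill and measuring
#' their activity concentration on a cross-calibrated gamma counter.
#'
#' @param concentration true concentration, MBq/mL.
#' @param n number of samples (three in the standard procedure).
#' @param cv fractional coefficient of variation of a single measurement.
#' @param seed RNG seed.
#' @return Numeric vector of `n` measured concentrations (MBq/mL).
#' @export
simulate_gamma_samples <- function(concentration, n = 3L, cv = 0.01, seed = 1L) {
  if (n < 1L) stop("`n` must be >= 1")
  if (cv < 0) stop("`cv` must be >= 0")
  if (concentration < 0) stop("concentration must be >= 0")
  if (concentration == 0 || cv == 0) return(rep(concentration, n))
  set.seed(seed)
  concentration * stats::rnorm(n, 1, cv)
}
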