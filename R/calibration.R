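#' Place the standard cylindrical calibration VOI
#'
#' Builds the voxel mask of a coaxial cylindrical volume of interest
#' (default 120 mm diameter, 150 mm length) centered on the phantom. The
#' phantom center is located from the image itself by intensity-weighted
#' center of mass after thresholding at 50% of a robust maximum, so the
#' VOI tracks off-center phantom positioning without relying on CT or
#' header information. The VOI deliberately stays well inside the phantom,
#' away from edge (Gibbs) artifacts.
#'
#' @param image `voxel_image` of the uniform cylinder.
#' @param spec the `phantom_spec` of the cylinder (used only to check that
#'   the VOI fits strictly inside the phantom).
#' @param voi_diameter,voi_length VOI dimensions in mm.
#' @return A logical 3D mask (same dimensions as the image).
#' @export
place_cylinder_voi <- function(image, spec, voi_diameter = 120, voi_length = 150) {
  stopifnot(inherits(image, "voxel_image"))
  if (!is.null(spec)) {
    if (voi_diameter >= spec$cylinder_diameter || voi_length >= spec$cylinder_length)
      stop("VOI must be strictly inside the phantom")
  }
  ctr <- .image_centroid(image)
  .cylinder_mask(image, center = ctr, diameter = voi_diameter,
                 length = voi_length)
}

# intensity-weighted center of mass of voxels above half the robust max
.image_centroid <- function(image) {
  v <- image$values
  mx <- stats::quantile(v, 0.99, names = FALSE)
  if (mx <= 0) stop("image has no signal to locate the phantom")
  m <- v >= 0.5 * mx
  co <- voxel_coords(image)
  idx <- which(m, arr.ind = TRUE)
  w <- v[m]
  c(sum(co[[1]][idx[, 1]] * w), sum(co[[2]][idx[, 2]] * w),
    sum(co[[3]][idx[, 3]] * w)) / sum(w)
}

#' Image calibration factor from a uniform-cylinder counts image
#'
#' The image calibration factor (ICF, cps/MBq) converts reconstructed
#' counts to activity: `ICF = [C] / (dt * [A_C])`, with `[C]` the counts
#' concentration (counts/mL) in a VOI inside the cylinder, `dt` the
#' acquisition duration and `[A_C]` the reference activity concentration
#' from the gamma counter. If the image declares a projection scale
#' (`rr_scale` in the sidecar), the ICF is divided by it so that systems
#' using scaled projections are comparable with the rest.
#'
#' @param image counts `voxel_image` of the uniform cylinder.
#' @param voi logical VOI mask (see [place_cylinder_voi()]).
#' @param ref_concentration reference activity concentration, MBq/mL.
#' @return An `icf_result`: fields `icf` (cps/MBq), `counts_concentration`
#'   (counts/mL), `duration` (s), `ref_concentration` (MBq/mL),
#'   `voi_voxel_count`, `voi_sd` (fractional SD in the VOI), `rr_scale`.
#' @export
compute_icf <- function(image, voi, ref_concentration) {
  stopifnot(inherits(image, "voxel_image"))
  if (image$units != "counts") stop("ICF requires a counts image")
  if (!is.finite(image$duration) || image$duration <= 0)
    stop("counts image must carry a positive duration")
  if (ref_concentration <= 0) stop("reference concentration must be positive")
  vals <- image$values[voi]
  if (!length(vals)) stop("VOI is empty")
  cc <- mean(vals) / voxel_volume_mL(image)
  icf <- cc / (image$duration * ref_concentration) / image$rr_scale
  structure(list(icf = icf,
                 counts_concentration = cc,
                 duration = image$duration,
                 ref_concentration = ref_concentration,
                 voi_voxel_count = length(vals),
                 voi_sd = stats::sd(vals) / mean(vals),
                 rr_scale = image$rr_scale),
            class = "icf_result")
}

#' ICF from an expanded VOI capturing all phantom counts
#'
#' Alternative calibration that sums all counts in a phantom-plus-margin
#' region and divides by the total reference activity, instead of using a
#' central VOI. It is immune to edge artifacts but picks up any background
#' counts (scatter, septal penetration) inside the margin, which is why
#' the central-VOI method is the default.
#'
#' @param image counts `voxel_image` of the cylinder.
#' @param spec `phantom_spec` of the cylinder.
#' @param margin expansion margin in mm; a good default is twice the PSF
#'   FWHM so essentially all spilled counts are captured.
#' @param ref_activity total reference activity in MBq; defaults to the
#'   spec's analytic activity.
#' @return An `icf_result` (with `counts_concentration` the total-count
#'   concentration over the expanded VOI).
#' @export
compute_icf_expanded <- function(image, spec, margin = 24,
                                 ref_activity = phantom_total_activity(spec)) {
  stopifnot(inherits(image, "voxel_image"), inherits(spec, "phantom_spec"))
  if (image$units != "counts") stop("ICF requires a counts image")
  if (ref_activity <= 0) stop("reference activity must be positive")
  mask <- .expanded_phantom_mask(image, spec, margin)
  if (!all(dim(mask) == dim(image$values))) stop("mask/image mismatch")
  # expanded region must stay on the grid
  bb <- .phantom_bbox(spec)
  half_extent <- dim(image$values) * image$spacing / 2
  if (any(bb$lo - margin < image$origin - half_extent) ||
      any(bb$hi + margin > image$origin + half_extent))
    stop("expanded VOI exceeds the image grid")
  total <- sum(image$values[mask])
  icf <- total / (image$duration * ref_activity) / image$rr_scale
  structure(list(icf = icf,
                 counts_concentration = total / (sum(mask) * voxel_volume_mL(image)),
                 duration = image$duration,
                 ref_concentration = ref_activity,
                 voi_voxel_count = sum(mask),
                 voi_sd = NA_real_,
                 rr_scale = image$rr_scale),
            class = "icf_result")
}

# phantom compartments expanded by a margin (mm)
.expanded_phantom_mask <- function(image, spec, margin) {
  off <- spec$offset %||% c(0, 0, 0)
  if (spec$kind == "cylinder") {
    m <- .cylinder_mask(image, off,
                        diameter = spec$cylinder_diameter + 2 * margin,
                        length = spec$cylinder_length + 2 * margin)
  } else {
    m <- array(FALSE, dim(image$values))
    for (s in spec$spheres)
      m <- m | (.dist2_to_point(image, s$center) <=
                  (s$diameter / 2 + margin)^2 + .mask_eps)
  }
  m
}

#' Correction factor for images already expressed in Bq/mL
#'
#' Systems that emit quantified images can still be off by a constant
#' factor; the correction factor `CF = [A_meas,C] / [A_C]` (measured over
#' the same cylinder VOI as the ICF) removes that bias before recovery
#' coefficients are computed.
#'
#' @param image Bq/mL `voxel_image` of the uniform cylinder.
#' @param voi logical VOI mask.
#' @param ref_concentration reference concentration, MBq/mL.
#' @return A `cf_result`: `cf` (dimensionless MBq/MBq),
#'   `measured_concentration` (MBq/mL), `ref_concentration`, `voi_sd`.
#' @export
compute_cf <- function(image, voi, ref_concentration) {
  stopifnot(inherits(image, "voxel_image"))
  if (image$units != "Bq/mL") stop("CF requires a Bq/mL image")
  if (ref_concentration <= 0) stop("reference concentration must be positive")
  vals <- image$values[voi]
  if (!length(vals)) stop("VOI is empty")
  meas <- mean(vals) / 1e6 # Bq/mL -> MBq/mL
  structure(list(cf = meas / ref_concentration,
                 measured_concentration = meas,
                 ref_concentration = ref_concentration,
                 voi_voxel_count = length(vals),
                 voi_sd = stats::sd(vals) / mean(vals)),
            class = "cf_result")
}

#' Phantom activity from gamma-counter samples
#'
#' Reference phantom activity is the mean measured sample concentration
#' times the phantom volume.
#'
#' @param sample_concentrations measured concentrations, MBq/mL.
#' @param volume phantom (or total-sphere) volume, mL.
#' @return Activity in MBq.
#' @export
#' @examples
#' phantom_activity_from_samples(3.75, 161) # 603.75 MBq
phantom_activity_from_samples <- function(sample_concentrations, volume) {
  if (!length(sample_concentrations)) stop("at least one sample is required")
  if (any(sample_concentrations < 0)) stop("concentrations must be >= 0")
  if (volume <= 0) stop("volume must be positive")
  mean(sample_concentrations) * volume
}

#' Estimate total phantom activity from an image
#'
#' Counts images: total counts in the region divided by `ICF * rr_scale *
#' dt`. Bq/mL images: integrated concentration divided by CF. The region
#' is either the theoretical phantom compartments (`method = "voi"`,
#' which underestimates blurred objects through spill-out) or the
#' compartments expanded by a margin (`method = "expanded"`).
#'
#' @param image counts or Bq/mL `voxel_image`.
#' @param calib matching `icf_result` or `cf_result`.
#' @param spec `phantom_spec` defining the compartments.
#' @param method `"voi"` or `"expanded"`.
#' @param margin expansion margin (mm) for `method = "expanded"`.
#' @return Estimated activity in MBq.
#' @export
estimate_total_activity <- function(image, calib, spec,
                                    method = c("voi", "expanded"), margin = 24) {
  stopifnot(inherits(image, "voxel_image"), inherits(spec, "phantom_spec"))
  method <- match.arg(method)
  mask <- if (method == "expanded") .expanded_phantom_mask(image, spec, margin)
          else .expanded_phantom_mask(image, spec, 0)
  if (image$units == "counts") {
    if (!inherits(calib, "icf_result")) stop("counts images need an icf_result")
    sum(image$values[mask]) / (calib$icf * image$rr_scale * image$duration)
  } else if (image$units == "Bq/mL") {
    if (!inherits(calib, "cf_result")) stop("Bq/mL images need a cf_result")
    sum(image$values[mask]) / 1e6 * voxel_volume_mL(image) / calib$cf
  } else stop("image must be in counts or Bq/mL")
}

#' Parallel-hole collimator geometric sensitivity and resolution
#'
#' Anger-camera geometry formulas: with effective hole length
#' `L_eff = L - 2/mu` (septal penetration correction), geometric
#' sensitivity `g = (K d^2 / (L_eff (d + s)))^2` (reported as a
#' percentage) and geometric resolution `R = d (L_eff + b) / L_eff` at a
#' source distance `b` from the collimator face (an optional
#' collimator-to-detector gap can be added to `b`).
#'
#' @param hole_d hole diameter, mm.
#' @param septa septal thickness, mm.
#' @param length hole length, mm.
#' @param mu_lead linear attenuation of the septal material at the imaging
#'   energy, 1/mm (1.13 for lead at 208 keV).
#' @param distance source distance, mm (100 mm = standard 10 cm).
#' @param K hole-shape constant (0.26 for hexagonal holes).
#' @param gap additional collimator-to-detector gap added to the
#'   resolution distance, mm.
#' @return List with `sensitivity` (percent) and `resolution` (mm FWHM).
#' @export
#' @examples
#' collimator_geometry(3, 1.05, 58)      # Discovery MEGP: 0.011%
#' collimator_geometry(2.94, 1.14, 40.64) # Symbia MELP: 0.020%
collimator_geometry <- function(hole_d, septa, length, mu_lead = 1.13,
                                distance = 100, K = 0.26, gap = 0) {
  if (hole_d <= 0 || septa <= 0 || length <= 0 || mu_lead <= 0)
    stop("collimator parameters must be positive")
  l_eff <- length - 2 / mu_lead
  if (l_eff <= 0) stop("effective hole length is non-positive")
  g <- (K * hole_d^2 / (l_eff * (hole_d + septa)))^2
  r <- hole_d * (l_eff + distance + gap) / l_eff
  list(sensitivity = 100 * g, resolution = r, l_eff = l_eff)
}

#' Photopeak interaction-probability ratio of two crystal thicknesses
#'
#' Ratio of photoelectric-interaction probabilities
#' `(1 - exp(-mu b)) / (1 - exp(-mu a))` for crystals of thickness `a` and
#' `b`; explains the sensitivity gain of a 5/8" over a 3/8" NaI crystal at
#' 208 keV (about +27%).
#'
#' @param thickness_a,thickness_b crystal thicknesses, mm.
#' @param mu_crystal linear attenuation coefficient, 1/mm (0.111 for NaI
#'   at 208 keV).
#' @return Dimensionless ratio (b relative to a).
#' @export
crystal_interaction_ratio <- function(thickness_a, thickness_b, mu_crystal = 0.111) {
  if (thickness_a <= 0 || thickness_b <= 0 || mu_crystal <= 0)
    stop("thicknesses and attenuation must be positive")
  (1 - exp(-mu_crystal * thickness_b)) / (1 - exp(-mu_crystal * thickness_a))
}
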