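#' Locate the hot spheres in a NEMA image
#'
#' Two-stage SPECT-based localization: first the nominal sphere
#' constellation is rigidly translated over a grid of voxel-step shifts and
#' the shift maximizing the summed in-sphere intensity is kept; then each
#' sphere center is refined to the intensity center of mass inside a
#' search ball of radius (sphere radius + one PSF FWHM) around its shifted
#' nominal position. Spheres whose peak intensity is not clearly above
#' background (max < 2x background level) are flagged rather than silently
#' placed.
#'
#' @param image NEMA `voxel_image` (counts or Bq/mL).
#' @param spec `phantom_spec` with the nominal sphere geometry.
#' @param fwhm assumed PSF FWHM (mm), controls the refinement ball.
#' @param max_shift translation search range per axis, mm.
#' @return A data.frame with columns `diameter`, `x`, `y`, `z` (mm),
#'   `flagged`; the common translation is in `attr(, "shift")`.
#' @export
locate_spheres <- function(image, spec, fwhm = 10, max_shift = 12) {
  stopifnot(inherits(image, "voxel_image"), inherits(spec, "phantom_spec"))
  if (!length(spec$spheres)) stop("spec has no spheres")
  centers <- t(vapply(spec$spheres, function(s) s$center, numeric(3)))
  diam <- vapply(spec$spheres, function(s) s$diameter, 0)
  v <- image$values
  co <- voxel_coords(image)

  # nominal masks as linear-index vectors, shifted in voxel steps
  masks <- lapply(seq_len(nrow(centers)), function(i)
    which(.dist2_to_point(image, centers[i, ]) <= (diam[i] / 2)^2 + .mask_eps))
  dims <- dim(v)
  steps <- lapply(1:3, function(a) {
    s <- seq(-floor(max_shift / image$spacing[a]), floor(max_shift / image$spacing[a]))
    s
  })
  stride <- c(1, dims[1], dims[1] * dims[2])
  n_tot <- prod(dims)
  best <- c(0L, 0L, 0L); best_val <- -Inf
  for (sx in steps[[1]]) for (sy in steps[[2]]) for (sz in steps[[3]]) {
    off <- sx * stride[1] + sy * stride[2] + sz * stride[3]
    tot <- 0
    for (m in masks) {
      idx <- m + off
      idx <- idx[idx >= 1 & idx <= n_tot]
      tot <- tot + sum(v[idx])
    }
    if (tot > best_val) { best_val <- tot; best <- c(sx, sy, sz) }
  }
  shift <- best * image$spacing

  # background level: median over everything outside the (shifted) spheres
  out_mask <- array(TRUE, dims)
  for (i in seq_len(nrow(centers)))
    out_mask[.dist2_to_point(image, centers[i, ] + shift) <=
               (diam[i] / 2 + fwhm)^2] <- FALSE
  bg <- stats::median(v[out_mask])

  res <- lapply(seq_len(nrow(centers)), function(i) {
    c0 <- centers[i, ] + shift
    ball <- .dist2_to_point(image, c0) <= (diam[i] / 2 + fwhm)^2
    w <- v[ball]
    flagged <- max(w) < 2 * max(bg, .Machine$double.eps)
    if (flagged || sum(pmax(w, 0)) == 0) {
      cen <- c0
    } else {
      idx <- which(ball, arr.ind = TRUE)
      w <- pmax(w, 0)
      cen <- c(sum(co[[1]][idx[, 1]] * w), sum(co[[2]][idx[, 2]] * w),
               sum(co[[3]][idx[, 3]] * w)) / sum(w)
    }
    data.frame(diameter = diam[i], x = cen[1], y = cen[2], z = cen[3],
               flagged = flagged)
  })
  out <- do.call(rbind, res)
  attr(out, "shift") <- shift
  out
}

#' Segment spheres at their theoretical sizes
#'
#' Voxel-center-in-sphere masks at the theoretical diameters, centered on
#' the located centers. Masks must be pairwise disjoint.
#'
#' @param centers data.frame with `x`, `y`, `z` (mm) as returned by
#'   [locate_spheres()], or an n x 3 matrix.
#' @param diameters sphere diameters, mm.
#' @param image `voxel_image` providing the grid.
#' @return List of logical 3D masks, ordered like `diameters`.
#' @export
segment_spheres <- function(centers, diameters, image) {
  stopifnot(inherits(image, "voxel_image"))
  if (is.data.frame(centers)) centers <- as.matrix(centers[, c("x", "y", "z")])
  if (nrow(centers) != length(diameters))
    stop("one center per diameter is required")
  masks <- lapply(seq_along(diameters), function(i)
    .dist2_to_point(image, centers[i, ]) <= (diameters[i] / 2)^2 + .mask_eps)
  tot <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(tot > 1L)) stop("sphere masks overlap")
  masks
}

#' Compute a sphere recovery curve
#'
#' For each sphere, converts the mean in-sphere voxel value to an activity
#' concentration -- counts images via the ICF from the matching cylinder
#' acquisition (`[A_i] = [C_i] / (ICF dt)`, with any declared projection
#' scale folded back in), Bq/mL images via the correction factor
#' (`[A_i] = [A_meas,i] / CF`) -- and divides by the reference
#' concentration to get the recovery coefficient `RC_i = [A_i] / [A_N]`.
#'
#' @param image NEMA `voxel_image`.
#' @param masks list of sphere masks (see [segment_spheres()]).
#' @param calib `icf_result` (counts images) or `cf_result` (Bq/mL
#'   images) obtained with the same acquisition/reconstruction condition.
#' @param ref_concentration reference sphere concentration `[A_N]`,
#'   MBq/mL.
#' @param diameters sphere diameters (mm), one per mask.
#' @param system_id,scenario labels carried into the result.
#' @return A `recovery_curve`: `measurements` data.frame (`diameter`,
#'   `mean_value`, `concentration` in MBq/mL, `rc`) sorted by diameter,
#'   plus metadata.
#' @export
compute_recovery_curve <- function(image, masks, calib, ref_concentration,
                                   diameters, system_id = image$system_id,
                                   scenario = image$scenario) {
  stopifnot(inherits(image, "voxel_image"))
  if (length(masks) != length(diameters))
    stop("one mask per diameter is required")
  if (ref_concentration <= 0) stop("reference concentration must be positive")
  conc <- vapply(seq_along(masks), function(i) {
    vals <- image$values[masks[[i]]]
    if (!length(vals)) stop("empty sphere mask")
    .to_concentration(mean(vals), image, calib)
  }, 0)
  ord <- order(diameters)
  meas <- data.frame(diameter = diameters[ord],
                     concentration = conc[ord],
                     rc = conc[ord] / ref_concentration)
  structure(list(measurements = meas, ref_concentration = ref_concentration,
                 system_id = system_id, scenario = scenario),
            class = "recovery_curve")
}

# mean voxel value -> activity concentration (MBq/mL)
.to_concentration <- function(mean_value, image, calib) {
  if (image$units == "counts") {
    if (!inherits(calib, "icf_result"))
      stop("counts images require an icf_result calibration")
    cc <- mean_value / voxel_volume_mL(image) # counts/mL
    cc / (calib$icf * image$rr_scale * image$duration)
  } else if (image$units == "Bq/mL") {
    if (!inherits(calib, "cf_result"))
      stop("Bq/mL images require a cf_result calibration")
    mean_value / 1e6 / calib$cf
  } else stop("image must be in counts or Bq/mL")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve> %s / %s  [A_N] = %.3g MBq/mL\n",
              x$system_id, x$scenario, x$ref_concentration))
  print(x$measurements, row.names = FALSE)
  invisible(x)
}

#' Recovery band over several curves
#'
#' Elementwise mean / min / max of recovery coefficients across curves
#' sharing the same sphere diameters (the band plot of a multi-system
#' comparison: dashed mean, outer range lines).
#'
#' @param curves list of `recovery_curve` objects.
#' @return data.frame with `diameter_mm`, `mean`, `min`, `max`.
#' @export
recovery_band <- function(curves) {
  if (!length(curves)) stop("at least one curve is required")
  d0 <- curves[[1]]$measurements$diameter
  rcs <- vapply(curves, function(cu) {
    if (!isTRUE(all.equal(cu$measurements$diameter, d0)))
      stop("curves have mismatched sphere diameters")
    cu$measurements$rc
  }, numeric(length(d0)))
  rcs <- matrix(rcs, nrow = length(d0))
  data.frame(diameter_mm = d0,
             mean = rowMeans(rcs),
             min = apply(rcs, 1, min),
             max = apply(rcs, 1, max))
}

#' Recovery-coefficient spread at one sphere size
#'
#' Max-minus-min recovery coefficient across curves at a given diameter,
#' in absolute percentage points.
#'
#' @param curves list of `recovery_curve` objects (at least two).
#' @param diameter sphere diameter, mm.
#' @return Spread in percentage points.
#' @export
rc_spread <- function(curves, diameter) {
  if (length(curves) < 2L) stop("at least two curves are required")
  rcs <- vapply(curves, function(cu) {
    i <- which(abs(cu$measurements$diameter - diameter) < 1e-9)
    if (!length(i)) stop("diameter ", diameter, " mm not present in a curve")
    cu$measurements$rc[i[1]]
  }, 0)
  (max(rcs) - min(rcs)) * 100
}
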