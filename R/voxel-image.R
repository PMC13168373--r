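#' 3D voxel image with physical metadata
#'
#' Container for a reconstructed (or simulated) SPECT volume: a 3D numeric
#' array plus the physical metadata the quantification chain needs. Values
#' are either raw reconstructed counts, activity concentration in Bq/mL
#' (vendor-quantified images), or MBq/mL (ground-truth activity maps).
#' Counts images must carry the acquisition duration so count rates can be
#' formed.
#'
#' @param values 3D numeric array.
#' @param spacing voxel spacing in mm, length-3 (or scalar, recycled).
#' @param units one of `"counts"`, `"Bq/mL"`, `"MBq/mL"`.
#' @param duration acquisition duration in seconds; required when
#'   `units == "counts"`.
#' @param origin physical coordinate (mm) of the grid center, length-3.
#' @param system_id,scenario free-text provenance labels.
#' @param rr_scale projection scale factor declared for this reconstruction
#'   (some resolution-recovery reconstructions scale projections by 4; the
#'   calibration step divides it back out). Metadata only, never inferred
#'   from the values.
#'
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(values, spacing, units = c("counts", "Bq/mL", "MBq/mL"),
                        duration = NULL, origin = c(0, 0, 0),
                        system_id = "", scenario = "", rr_scale = 1) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("image values must be finite")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  if (identical(units, "counts")) {
    if (is.null(duration) || !is.finite(duration) || duration <= 0)
      stop("counts images require a positive acquisition `duration` (s)")
  }
  if (!is.null(duration) && (!is.finite(duration) || duration <= 0))
    stop("`duration` must be positive when given")
  if (!is.numeric(rr_scale) || length(rr_scale) != 1L || rr_scale <= 0)
    stop("`rr_scale` must be a positive scalar")
  structure(list(
    values = values,
    spacing = spacing,
    units = units,
    duration = if (is.null(duration)) NA_real_ else as.numeric(duration),
    origin = rep_len(as.numeric(origin), 3L),
    system_id = as.character(system_id),
    scenario = as.character(scenario),
    rr_scale = as.numeric(rr_scale)
  ), class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("<voxel_image> %s  [%s]\n",
              paste(dim(x$values), collapse = " x "), x$units))
  cat(sprintf("  spacing: %s mm, voxel volume %.4f mL\n",
              paste(signif(x$spacing, 4), collapse = " x "),
              voxel_volume_mL(x)))
  if (is.finite(x$duration)) cat(sprintf("  duration: %.1f s\n", x$duration))
  if (x$rr_scale != 1) cat(sprintf("  rr_scale: %g\n", x$rr_scale))
  if (nzchar(x$system_id) || nzchar(x$scenario))
    cat(sprintf("  system: %s  scenario: %s\n", x$system_id, x$scenario))
  invisible(x)
}

#' Voxel volume in millilitres
#'
#' @param image a `voxel_image` (or a length-3 spacing vector in mm).
#' @return Voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_mL <- function(image) {
  spacing <- if (inherits(image, "voxel_image")) image$spacing else rep_len(image, 3L)
  prod(spacing) / 1000
}

#' Physical coordinates of voxel centers
#'
#' Returns the voxel-center coordinates along each axis, in mm, using the
#' convention that the grid center sits at `origin` (phantom frame).
#'
#' @param image a `voxel_image`.
#' @return A list of three numeric vectors (x, y, z coordinates in mm).
#' @export
voxel_coords <- function(image) {
  stopifnot(inherits(image, "voxel_image"))
  dims <- dim(image$values)
  lapply(1:3, function(a) {
    (seq_len(dims[a]) - (dims[a] + 1) / 2) * image$spacing[a] + image$origin[a]
  })
}

# squared distance of every voxel center to a point (mm); returns 3D array
.dist2_to_point <- function(image, point) {
  co <- voxel_coords(image)
  dx2 <- (co[[1]] - point[1])^2
  dy2 <- (co[[2]] - point[2])^2
  dz2 <- (co[[3]] - point[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

#' Total activity of an activity-map image
#'
#' Integrates an MBq/mL truth map over the grid.
#'
#' @param image `voxel_image` with units MBq/mL.
#' @return Total activity in MBq.
#' @export
total_activity <- function(image) {
  stopifnot(inherits(image, "voxel_image"))
  if (image$units != "MBq/mL")
    stop("total_activity() expects an MBq/mL truth map")
  sum(image$values) * voxel_volume_mL(image)
}
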