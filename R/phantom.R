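#' Sphere volume from diameter
#'
#' @param diameter sphere diameter in mm.
#' @return Volume in mL.
#' @export
#' @examples
#' sphere_volume(60) # 113.1 mL
sphere_volume <- function(diameter) {
  if (!is.numeric(diameter) || any(diameter <= 0))
    stop("sphere diameter must be positive")
  pi * diameter^3 / 6 / 1000
}

#' Cylinder volume from internal dimensions
#'
#' @param diameter internal diameter in mm.
#' @param length internal length in mm.
#' @return Volume in litres.
#' @export
#' @examples
#' cylinder_volume(195, 211) # 6.30 L
cylinder_volume <- function(diameter, length) {
  if (!is.numeric(diameter) || any(diameter <= 0) ||
      !is.numeric(length) || any(length <= 0))
    stop("cylinder dimensions must be positive")
  pi * (diameter / 2)^2 * length / 1e6
}

#' Hot-sphere specification
#'
#' @param center length-3 center in mm (phantom frame, origin at phantom
#'   center).
#' @param diameter sphere diameter in mm.
#' @param activity_concentration activity concentration in MBq/mL.
#' @return A `sphere_spec` list.
#' @export
sphere_spec <- function(center, diameter, activity_concentration) {
  if (length(center) != 3L || !all(is.finite(center)))
    stop("`center` must be a finite length-3 vector (mm)")
  if (diameter <= 0) stop("sphere diameter must be positive")
  if (activity_concentration < 0) stop("activity concentration must be >= 0")
  structure(list(center = as.numeric(center),
                 diameter = as.numeric(diameter),
                 activity_concentration = as.numeric(activity_concentration)),
            class = "sphere_spec")
}

# standard NEMA IEC hexagonal arrangement: six centers on a 114.4 mm circle
# in one transaxial plane, largest sphere at 12 o'clock, diameters descending
# around the ring
.nema_default_centers <- function(ring_radius = 57.2) {
  ang <- (90 - 60 * (0:5)) * pi / 180
  cbind(ring_radius * cos(ang), ring_radius * sin(ang), 0)
}

#' Phantom specifications
#'
#' `cylinder_phantom()` describes the uniform cylindrical calibration
#' phantom (defaults: 195 mm internal diameter, 211 mm internal length,
#' 6.3 L). `nema_iq_phantom()` describes a NEMA IEC body phantom with six
#' hot spheres in the standard hexagonal arrangement and a (by default
#' cold) background compartment, modeled here as a cylindrical body.
#'
#' @param length,diameter internal cylinder dimensions in mm.
#' @param concentration activity concentration of the cylinder fill
#'   (MBq/mL).
#' @param sphere_diameters six sphere diameters in mm.
#' @param sphere_concentration hot-sphere activity concentration (MBq/mL).
#' @param background_concentration background compartment concentration
#'   (MBq/mL); 0 is the cold background used for recovery measurements.
#' @param centers optional 6x3 matrix of sphere centers (mm); defaults to
#'   the standard hexagonal arrangement on a 57.2 mm radius ring.
#' @param body_length,body_diameter extent of the background body cylinder
#'   (mm).
#' @return A `phantom_spec` list with `kind` `"cylinder"` or `"nema_iq"`.
#' @export
cylinder_phantom <- function(length = 211, diameter = 195, concentration = 812 / 6301.6) {
  if (length <= 0 || diameter <= 0) stop("cylinder dimensions must be positive")
  if (concentration < 0) stop("concentration must be >= 0")
  structure(list(kind = "cylinder",
                 cylinder_length = length, cylinder_diameter = diameter,
                 cylinder_concentration = concentration,
                 spheres = list(), background_concentration = 0),
            class = "phantom_spec")
}

#' @rdname cylinder_phantom
#' @export
nema_iq_phantom <- function(sphere_diameters = c(60, 37, 28, 22, 17, 13),
                            sphere_concentration = 4,
                            background_concentration = 0,
                            centers = NULL,
                            body_length = 180, body_diameter = 230) {
  if (length(sphere_diameters) < 1L || any(sphere_diameters <= 0))
    stop("sphere diameters must be positive")
  if (is.null(centers)) {
    centers <- .nema_default_centers()[seq_along(sphere_diameters), , drop = FALSE]
  }
  centers <- as.matrix(centers)
  if (nrow(centers) != length(sphere_diameters) || ncol(centers) != 3L)
    stop("`centers` must be one length-3 row per sphere")
  spheres <- lapply(seq_along(sphere_diameters), function(i)
    sphere_spec(centers[i, ], sphere_diameters[i], sphere_concentration))
  spec <- structure(list(kind = "nema_iq",
                         cylinder_length = body_length,
                         cylinder_diameter = body_diameter,
                         cylinder_concentration = background_concentration,
                         spheres = spheres,
                         background_concentration = background_concentration),
                    class = "phantom_spec")
  .check_sphere_overlap(spec)
  spec
}

.check_sphere_overlap <- function(spec) {
  sp <- spec$spheres
  if (length(sp) < 2L) return(invisible(TRUE))
  for (i in seq_len(length(sp) - 1L)) for (j in seq(i + 1L, length(sp))) {
    d <- sqrt(sum((sp[[i]]$center - sp[[j]]$center)^2))
    if (d < (sp[[i]]$diameter + sp[[j]]$diameter) / 2)
      stop(sprintf("spheres %d and %d overlap", i, j))
  }
  invisible(TRUE)
}

#' Translate a phantom specification
#'
#' Shifts every compartment by `shift` (mm) in the grid frame; used to
#' emulate off-center phantom positioning.
#'
#' @param spec a `phantom_spec`.
#' @param shift length-3 translation in mm.
#' @return The shifted spec, carrying the accumulated offset in `$offset`.
#' @export
translate_phantom <- function(spec, shift) {
  stopifnot(inherits(spec, "phantom_spec"), length(shift) == 3L)
  spec$offset <- (spec$offset %||% c(0, 0, 0)) + as.numeric(shift)
  spec$spheres <- lapply(spec$spheres, function(s) {
    s$center <- s$center + as.numeric(shift)
    s
  })
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic total activity of a phantom spec
#'
#' @param spec a `phantom_spec`.
#' @return Total activity in MBq (closed-form volumes times concentrations).
#' @export
phantom_total_activity <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  body_mL <- cylinder_volume(spec$cylinder_diameter, spec$cylinder_length) * 1000
  sph_mL <- vapply(spec$spheres, function(s) sphere_volume(s$diameter), 0)
  bg <- spec$background_concentration %||% 0
  body_conc <- if (spec$kind == "cylinder") spec$cylinder_concentration else bg
  body_conc * (body_mL - sum(sph_mL)) +
    sum(sph_mL * vapply(spec$spheres, function(s) s$activity_concentration, 0))
}

#' Grid specification
#'
#' @param shape three integers (voxels per axis).
#' @param spacing voxel spacing in mm (scalar or length-3).
#' @param origin mm coordinate of the grid center in the phantom frame.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(shape < 1L)) stop("grid shape must be positive")
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  structure(list(shape = shape, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "grid_spec")
}

#' Default grid enclosing a phantom
#'
#' Builds an isotropic grid that contains the phantom plus a margin (so
#' that simulated blur does not leak off the grid edge).
#'
#' @param spec a `phantom_spec`.
#' @param spacing isotropic voxel spacing in mm.
#' @param margin clearance around the phantom bounding box in mm.
#' @return A `grid_spec`.
#' @export
default_grid <- function(spec, spacing = 4, margin = 36) {
  bb <- .phantom_bbox(spec)
  extent <- bb$hi - bb$lo + 2 * margin
  center <- (bb$hi + bb$lo) / 2
  shape <- pmax(2L, as.integer(ceiling(extent / spacing)))
  grid_spec(shape, spacing, origin = center)
}

# axis-aligned bounding box of all compartments, mm
.phantom_bbox <- function(spec) {
  off <- spec$offset %||% c(0, 0, 0)
  r <- spec$cylinder_diameter / 2
  hl <- spec$cylinder_length / 2
  lo <- off + c(-r, -r, -hl)
  hi <- off + c(r, r, hl)
  for (s in spec$spheres) {
    lo <- pmin(lo, s$center - s$diameter / 2)
    hi <- pmax(hi, s$center + s$diameter / 2)
  }
  list(lo = lo, hi = hi)
}

#' Voxelize a phantom into an activity truth map
#'
#' Produces the ground-truth activity-concentration image (MBq/mL) of a
#' phantom on a grid. Each voxel takes the concentration of the compartment
#' containing its center (no partial-volume weighting; resolution blur is
#' applied later by the simulator). The grid must fully contain the
#' phantom.
#'
#' @param spec a `phantom_spec`.
#' @param grid a `grid_spec`.
#' @return A `voxel_image` with units MBq/mL.
#' @export
voxelize <- function(spec, grid) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "grid_spec"))
  img <- voxel_image(array(0, grid$shape), grid$spacing, units = "MBq/mL",
                     origin = grid$origin)
  bb <- .phantom_bbox(spec)
  lo_edge <- (0 - (grid$shape + 1) / 2) * grid$spacing + grid$origin + grid$spacing / 2
  hi_edge <- (grid$shape - (grid$shape + 1) / 2) * grid$spacing + grid$origin + grid$spacing / 2
  if (any(bb$lo < lo_edge) || any(bb$hi > hi_edge))
    stop("grid does not fully contain the phantom")
  vals <- array(0, grid$shape)
  off <- spec$offset %||% c(0, 0, 0)
  body_conc <- if (spec$kind == "cylinder") spec$cylinder_concentration
               else spec$background_concentration
  if (body_conc != 0 || spec$kind == "cylinder") {
    m <- .cylinder_mask(img, center = off,
                        diameter = spec$cylinder_diameter,
                        length = spec$cylinder_length)
    vals[m] <- body_conc
  }
  for (s in spec$spheres) {
    m <- .dist2_to_point(img, s$center) <= (s$diameter / 2)^2 + .mask_eps
    vals[m] <- s$activity_concentration
  }
  img$values <- vals
  img
}

# tiny inclusive slack on boundary comparisons (sub-nanometre scale) so
# that exact voxel-center-on-boundary ties are not flipped by float noise
# in detected centers; applied identically in voxelization and masking
.mask_eps <- 1e-7   # mm^2 slack on squared distances
.mask_eps_lin <- 1e-9 # mm slack on linear distances

# logical mask of voxel centers inside an axis-aligned (z-axis) cylinder
.cylinder_mask <- function(image, center, diameter, length) {
  co <- voxel_coords(image)
  r2 <- outer((co[[1]] - center[1])^2, (co[[2]] - center[2])^2, "+")
  in_xy <- r2 <= (diameter / 2)^2 + .mask_eps
  in_z <- abs(co[[3]] - center[3]) <= length / 2 + .mask_eps_lin
  outer(in_xy, in_z, "&")
}
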