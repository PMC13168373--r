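#' Normalized radial profile of a sphere
#'
#' One point per voxel whose center lies within `r_max` of the sphere
#' center: radius (mm) against the quantified, normalized voxel value.
#' Values are scaled so that the true in-sphere signal is 1 and the (cold)
#' background is 0 -- counts images are quantified through the ICF (and any
#' declared projection scale), Bq/mL images through the CF, then divided
#' by the reference concentration.
#'
#' @param image NEMA `voxel_image`.
#' @param center sphere center, mm (length-3).
#' @param r_max profile radius, mm (at least the sphere radius).
#' @param ref_concentration true sphere concentration, MBq/mL.
#' @param calib `icf_result` or `cf_result` matching the image units.
#' @return data.frame with `radius` (mm) and `value` (normalized).
#' @export
radial_profile <- function(image, center, r_max, ref_concentration, calib) {
  stopifnot(inherits(image, "voxel_image"))
  if (ref_concentration <= 0) stop("reference concentration must be positive")
  co <- voxel_coords(image)
  rng <- vapply(co, range, numeric(2))
  if (any(center < rng[1, ]) || any(center > rng[2, ]))
    stop("sphere center lies outside the image")
  d2 <- .dist2_to_point(image, center)
  sel <- d2 <= r_max^2
  vals <- .to_concentration(image$values[sel], image, calib) / ref_concentration
  data.frame(radius = sqrt(d2[sel]), value = vals)
}

#' Fit a smoothing spline to a radial profile
#'
#' Deterministic univariate smoothing spline through the (radius, value)
#' scatter; the smoothing parameter is chosen by generalized
#' cross-validation by default, or fixed explicitly (`spar`) for exact
#' reproducibility across datasets.
#'
#' @param points data.frame with `radius`, `value` (at least 20 points).
#' @param smoothing `"gcv"` or a numeric `spar` value in (0, 1].
#' @return A `smooth.spline` fit.
#' @export
fit_smoothing_spline <- function(points, smoothing = "gcv") {
  if (nrow(points) < 20L) stop("at least 20 profile points are required")
  if (length(unique(round(points$radius, 9))) < 8L)
    stop("degenerate radii: too few distinct radial positions")
  if (identical(smoothing, "gcv")) {
    stats::smooth.spline(points$radius, points$value, cv = FALSE)
  } else if (is.numeric(smoothing)) {
    stats::smooth.spline(points$radius, points$value, spar = smoothing)
  } else stop("`smoothing` must be \"gcv\" or a numeric spar")
}

#' Gibbs-artifact strength of a sphere profile
#'
#' From the fitted spline, `M` is the profile maximum over radii in
#' `[0, search_fraction * R]` (the cap excludes the blur-dominated edge
#' falloff) and `m` the minimum over `[0, r_M]` -- the dip inside the
#' ringing overshoot. The artifact strength is `GA = (M - m) / (M + m)`.
#' A monotone-decreasing profile (maximum at the center) has no interior
#' extremum pair and GA = 0 by definition.
#'
#' @param spline a fit from [fit_smoothing_spline()].
#' @param sphere_radius sphere radius R, mm.
#' @param search_fraction fraction of R bounding the search (default 0.9).
#' @param step evaluation step along the radius, mm.
#' @return A `gibbs_result`: `ga`, `M`, `m`, `r_M`, `r_m`.
#' @export
gibbs_strength <- function(spline, sphere_radius, search_fraction = 0.9,
                           step = 0.1) {
  if (sphere_radius <= 0) stop("sphere radius must be positive")
  r <- seq(0, search_fraction * sphere_radius, by = step)
  y <- stats::predict(spline, r)$y
  i_max <- which.max(y)
  if (i_max == 1L) {
    res <- list(ga = 0, M = y[1], m = y[1], r_M = 0, r_m = 0)
  } else {
    m_i <- which.min(y[seq_len(i_max)])
    M <- y[i_max]; m <- y[m_i]
    if (M + m <= 0) stop("profile levels are non-positive; GA undefined")
    res <- list(ga = (M - m) / (M + m), M = M, m = m,
                r_M = r[i_max], r_m = r[m_i])
  }
  structure(res, class = "gibbs_result")
}

#' @export
print.gibbs_result <- function(x, ...) {
  cat(sprintf("<gibbs_result> GA = %.3f (M = %.3f at %.1f mm, m = %.3f at %.1f mm)\n",
              x$ga, x$M, x$r_M, x$m, x$r_m))
  invisible(x)
}

#' End-to-end Gibbs analysis of the largest sphere
#'
#' Locates the spheres, extracts the radial profile of the largest (by
#' default) sphere out to `r_max`, fits the smoothing spline, and computes
#' the artifact strength.
#'
#' @param image NEMA `voxel_image`.
#' @param spec NEMA `phantom_spec`.
#' @param calib `icf_result` or `cf_result`.
#' @param ref_concentration true sphere concentration, MBq/mL.
#' @param diameter sphere to analyze, mm; default the largest in the spec.
#' @param fwhm assumed PSF FWHM for localization, mm.
#' @param r_max_factor profile radius as a multiple of the sphere radius.
#' @param smoothing passed to [fit_smoothing_spline()].
#' @param search_fraction passed to [gibbs_strength()].
#' @return A `gibbs_result` with the profile in `$profile` and the spline
#'   in `$spline`.
#' @export
gibbs_analysis <- function(image, spec, calib, ref_concentration,
                           diameter = NULL, fwhm = 10, r_max_factor = 1.5,
                           smoothing = "gcv", search_fraction = 0.9) {
  diams <- vapply(spec$spheres, function(s) s$diameter, 0)
  diameter <- diameter %||% max(diams)
  i <- which.min(abs(diams - diameter))
  loc <- locate_spheres(image, spec, fwhm = fwhm)
  center <- as.numeric(loc[i, c("x", "y", "z")])
  prof <- radial_profile(image, center, r_max_factor * diameter / 2,
                         ref_concentration, calib)
  sp <- fit_smoothing_spline(prof, smoothing)
  res <- gibbs_strength(sp, diameter / 2, search_fraction)
  res$profile <- prof
  res$spline <- sp
  res$diameter <- diameter
  res
}
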