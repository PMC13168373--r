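# Independent analytic oracles used to cross-check the image pipeline.
# These never call the package's convolution or segmentation code: the
# radial profile of a Gaussian-blurred uniform sphere has a closed form,
# and sphere means are taken by direct fine-grid sampling of that form.

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# value at radius r of a uniform unit sphere (radius R) convolved with an
# isotropic 3D Gaussian of width sigma (closed form)
blurred_sphere_profile <- function(r, R, sigma) {
  out <- 0.5 * (erf((R - r) / (sigma * sqrt(2))) + erf((R + r) / (sigma * sqrt(2)))) -
    sigma / (r * sqrt(2 * pi)) *
      (exp(-(R - r)^2 / (2 * sigma^2)) - exp(-(R + r)^2 / (2 * sigma^2)))
  r0 <- r == 0
  if (any(r0))
    out[r0] <- erf(R / (sigma * sqrt(2))) -
      R * sqrt(2 / pi) / sigma * exp(-R^2 / (2 * sigma^2))
  out
}

# same for a difference-of-Gaussians kernel
dog_sphere_profile <- function(r, R, sigma, beta, alpha) {
  (1 + beta) * blurred_sphere_profile(r, R, sigma) -
    beta * blurred_sphere_profile(r, R, alpha * sigma)
}

# brute-force recovery coefficients: sample each true sphere on a fine
# grid and average the summed analytic contributions of all spheres
rc_oracle <- function(spec, fwhm, beta = 0, alpha = 2, step = 1) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  cen <- t(vapply(spec$spheres, `[[`, numeric(3), "center"))
  dia <- vapply(spec$spheres, `[[`, 0, "diameter")
  conc <- vapply(spec$spheres, `[[`, 0, "activity_concentration")
  vapply(seq_along(dia), function(i) {
    R <- dia[i] / 2
    g <- seq(-R, R, by = step)
    pts <- as.matrix(expand.grid(x = g, y = g, z = g))
    pts <- pts[rowSums(pts^2) <= R^2, , drop = FALSE]
    pts <- sweep(pts, 2, cen[i, ], `+`)
    v <- 0
    for (j in seq_along(dia)) {
      d <- sqrt(rowSums(sweep(pts, 2, cen[j, ])^2))
      v <- v + conc[j] * dog_sphere_profile(d, dia[j] / 2, sigma, beta, alpha)
    }
    mean(v) / conc[i]
  }, 0)
}

# Gibbs strength of the analytic 1D profile of an isolated sphere, using
# the same extremum rule as the pipeline but on the exact curve
ga_oracle_1d <- function(R, fwhm, beta, alpha = 2, search_fraction = 0.9) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- seq(0, search_fraction * R, by = 0.05)
  y <- dog_sphere_profile(r, R, sigma, beta, alpha)
  i_max <- which.max(y)
  if (i_max == 1L) return(0)
  (y[i_max] - min(y[seq_len(i_max)])) / (y[i_max] + min(y[seq_len(i_max)]))
}
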