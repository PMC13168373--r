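#' Study manifest: synthetic systems crossed with scenarios
#'
#' Describes a multicenter-style synthetic study: a named list of systems
#' (each a list of [recon_model()] arguments plus an optional `family`
#' label), the scenarios to run, and the phantom/grid/seed configuration.
#'
#' @param systems named list; each element is a list of `recon_model`
#'   arguments (e.g. `psf_fwhm`, `ringing_beta`, `icf_true`, `units_out`)
#'   and optionally `family`.
#' @param scenarios character vector of scenario labels; each scenario
#'   re-runs every system with a scenario-specific seed offset.
#' @param cylinder_activity total cylinder activity, MBq.
#' @param sphere_concentration NEMA sphere concentration, MBq/mL.
#' @param spacing voxel spacing, mm.
#' @param cylinder_count_target,nema_count_target stop conditions, counts.
#' @param noise `"poisson"` or `"none"`.
#' @param seed base RNG seed; each (system, scenario) gets a distinct
#'   deterministic seed derived from it.
#' @return A `study_manifest`.
#' @export
study_manifest <- function(systems, scenarios = "standardized",
                           cylinder_activity = 812,
                           sphere_concentration = 4,
                           spacing = 4,
                           cylinder_count_target = 7e6,
                           nema_count_target = 3e6,
                           noise = "poisson", seed = 1L) {
  if (!length(systems)) stop("at least one system is required")
  if (is.null(names(systems)) || anyDuplicated(names(systems)))
    stop("systems must be uniquely named")
  if (anyDuplicated(scenarios)) stop("scenario labels must be unique")
  structure(list(systems = systems, scenarios = scenarios,
                 cylinder_activity = cylinder_activity,
                 sphere_concentration = sphere_concentration,
                 spacing = spacing,
                 cylinder_count_target = cylinder_count_target,
                 nema_count_target = nema_count_target,
                 noise = noise, seed = as.integer(seed)),
            class = "study_manifest")
}

#' Run a synthetic multicenter study
#'
#' For every (system, scenario) pair: simulates the uniform cylinder and
#' the NEMA phantom with the system's reconstruction model, computes the
#' calibration (ICF for counts systems, CF for Bq/mL systems), the sphere
#' recovery curve, and the Gibbs-artifact strength of the largest sphere.
#' Aggregates recovery bands per system family and the per-sphere RC
#' spread. Fully deterministic given the manifest seed; per-system
#' failures are reported in the `errors` element and do not stop the run.
#'
#' @param manifest a `study_manifest`.
#' @return A `study_result` list: `calibration` (data.frame), `rc`
#'   (long data.frame), `ga` (data.frame system x scenario), `curves`
#'   (list of `recovery_curve`), `bands` (per family x scenario),
#'   `spread` (per diameter x scenario), `errors`.
#' @export
run_study <- function(manifest) {
  stopifnot(inherits(manifest, "study_manifest"))
  cyl_spec <- cylinder_phantom(concentration =
    manifest$cylinder_activity / (cylinder_volume(195, 211) * 1000))
  nema_spec <- nema_iq_phantom(sphere_concentration = manifest$sphere_concentration)
  cyl_truth <- voxelize(cyl_spec, default_grid(cyl_spec, manifest$spacing))
  nema_truth <- voxelize(nema_spec, default_grid(nema_spec, manifest$spacing))
  cyl_conc <- manifest$cylinder_activity / (cylinder_volume(195, 211) * 1000)

  calib_rows <- list(); rc_rows <- list(); ga_rows <- list()
  curves <- list(); errors <- list()
  run_id <- 0L
  for (scen in manifest$scenarios) for (sys in names(manifest$systems)) {
    run_id <- run_id + 1L
    pars <- manifest$systems[[sys]]
    family <- pars$family %||% sys
    pars$family <- NULL
    key <- paste(sys, scen, sep = "/")
    res <- tryCatch({
      seed_base <- manifest$seed + 1000L * run_id
      m_cyl <- do.call(recon_model, c(pars, list(
        count_target = manifest$cylinder_count_target,
        noise = manifest$noise, seed = seed_base)))
      m_nema <- do.call(recon_model, c(pars, list(
        count_target = manifest$nema_count_target,
        noise = manifest$noise, seed = seed_base + 1L)))
      cyl_img <- simulate_reconstruction(cyl_truth, m_cyl, sys, scen)
      nema_img <- simulate_reconstruction(nema_truth, m_nema, sys, scen)
      voi <- place_cylinder_voi(cyl_img, cyl_spec)
      calib <- if (m_cyl$units_out == "counts")
        compute_icf(cyl_img, voi, cyl_conc)
      else compute_cf(cyl_img, voi, cyl_conc)
      loc <- locate_spheres(nema_img, nema_spec, fwhm = m_nema$psf_fwhm)
      diams <- vapply(nema_spec$spheres, function(s) s$diameter, 0)
      masks <- segment_spheres(loc, diams, nema_img)
      curve <- compute_recovery_curve(nema_img, masks, calib,
                                      manifest$sphere_concentration, diams,
                                      system_id = sys, scenario = scen)
      ga <- gibbs_analysis(nema_img, nema_spec, calib,
                           manifest$sphere_concentration,
                           fwhm = m_nema$psf_fwhm)
      list(calib = calib, curve = curve, ga = ga, family = family,
           units = m_nema$units_out)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
      next
    }
    calib_rows[[key]] <- data.frame(
      system = sys, scenario = scen, family = res$family, units = res$units,
      icf = if (inherits(res$calib, "icf_result")) res$calib$icf else NA_real_,
      cf = if (inherits(res$calib, "cf_result")) res$calib$cf else NA_real_,
      voi_sd = res$calib$voi_sd, n_voxels = res$calib$voi_voxel_count)
    rc_rows[[key]] <- cbind(system = sys, scenario = scen,
                            family = res$family, res$curve$measurements)
    ga_rows[[key]] <- data.frame(system = sys, scenario = scen,
                                 family = res$family, ga = res$ga$ga)
    curves[[key]] <- res$curve
    attr(curves[[key]], "family") <- res$family
  }

  bands <- list(); spread <- list()
  for (scen in manifest$scenarios) {
    keys <- names(curves)[vapply(curves, function(cu) cu$scenario == scen, TRUE)]
    fams <- unique(vapply(keys, function(k) attr(curves[[k]], "family"), ""))
    for (fam in fams) {
      sel <- keys[vapply(keys, function(k) attr(curves[[k]], "family") == fam, TRUE)]
      bands[[paste(fam, scen, sep = "/")]] <-
        cbind(family = fam, scenario = scen, recovery_band(curves[sel]))
    }
    if (length(keys) >= 2L) {
      d0 <- curves[[keys[1]]]$measurements$diameter
      spread[[scen]] <- data.frame(
        scenario = scen, diameter_mm = d0,
        spread_pp = vapply(d0, function(d) rc_spread(curves[keys], d), 0))
    }
  }
  structure(list(
    calibration = do.call(rbind, c(calib_rows, list(make.row.names = FALSE))),
    rc = do.call(rbind, c(rc_rows, list(make.row.names = FALSE))),
    ga = do.call(rbind, c(ga_rows, list(make.row.names = FALSE))),
    curves = curves,
    bands = if (length(bands)) do.call(rbind, c(bands, list(make.row.names = FALSE))),
    spread = if (length(spread)) do.call(rbind, c(spread, list(make.row.names = FALSE))),
    errors = errors,
    manifest = manifest
  ), class = "study_result")
}

#' Write study tables (and optional plots) to a directory
#'
#' Emits `calibration.csv`, `rc.csv`, `bands.csv` (columns `diameter_mm`,
#' `mean`, `min`, `max`), `ga.csv` (columns `system`, `scenario`, `ga`)
#' and an `index.json` manifest. If ggplot2 is installed, also writes a
#' recovery-band figure (dashed mean line, outer range lines).
#'
#' @param result a `study_result`.
#' @param dir output directory (created if missing).
#' @param plots emit figures when ggplot2 is available.
#' @return `dir`, invisibly.
#' @export
render_reports <- function(result, dir, plots = TRUE) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_table <- function(df, name, cols) {
    if (is.null(df)) df <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
    name
  }
  files <- c(
    .write_table(result$calibration, "calibration.csv",
                 c("system", "scenario", "family", "units", "icf", "cf",
                   "voi_sd", "n_voxels")),
    .write_table(result$rc, "rc.csv",
                 c("system", "scenario", "family", "diameter",
                   "concentration", "rc")),
    .write_table(result$bands, "bands.csv",
                 c("family", "scenario", "diameter_mm", "mean", "min", "max")),
    .write_table(result$ga[, c("system", "scenario", "ga")], "ga.csv",
                 c("system", "scenario", "ga")),
    .write_table(result$spread, "spread.csv",
                 c("scenario", "diameter_mm", "spread_pp")))
  if (plots && !is.null(result$bands) &&
      requireNamespace("ggplot2", quietly = TRUE)) {
    p <- plot_recovery_band(result$bands)
    ggplot2::ggsave(file.path(dir, "recovery_bands.pdf"), p,
                    width = 7, height = 5)
    files <- c(files, "recovery_bands.pdf")
  }
  jsonlite::write_json(list(files = files, seed = result$manifest$seed,
                            systems = names(result$manifest$systems),
                            scenarios = result$manifest$scenarios),
                       file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Recovery-band plot
#'
#' Mean recovery coefficient (dashed) with min/max range lines per system
#' family, versus sphere diameter.
#'
#' @param bands data.frame as produced in `study_result$bands`.
#' @return A ggplot object.
#' @export
plot_recovery_band <- function(bands) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(bands, ggplot2::aes(x = diameter_mm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = min, ymax = max,
                                      fill = family), alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = mean, colour = family),
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = min, colour = family)) +
    ggplot2::geom_line(ggplot2::aes(y = max, colour = family)) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "Sphere diameter (mm)", y = "Recovery coefficient") +
    ggplot2::theme_minimal()
}

#' Radial-profile plot with fitted spline
#'
#' One dot per voxel and the smoothing-spline fit, in normalized units
#' (true in-sphere signal 1, background 0).
#'
#' @param gibbs a result from [gibbs_analysis()].
#' @return A ggplot object.
#' @export
plot_radial_profile <- function(gibbs) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  prof <- gibbs$profile
  fit <- data.frame(radius = seq(0, max(prof$radius), length.out = 200))
  fit$value <- stats::predict(gibbs$spline, fit$radius)$y
  ggplot2::ggplot(prof, ggplot2::aes(x = radius, y = value)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = fit, colour = "red") +
    ggplot2::labs(x = "Radius (mm)", y = "Normalized signal") +
    ggplot2::theme_minimal()
}
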