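#' Write / read a voxel image as NIfTI plus JSON sidecar
#'
#' Values go into a NIfTI file with the voxel spacing in its header; all
#' other metadata (units, acquisition duration, origin, system, scenario,
#' declared projection scale) goes into a JSON sidecar. Units are explicit
#' strings in the sidecar and are never inferred from value magnitudes.
#'
#' @param image a `voxel_image`.
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param sidecar_path JSON sidecar path; defaults to `path` with a
#'   `.json` extension appended.
#' @return `write_image()` returns `path` invisibly; `read_image()` returns
#'   a `voxel_image`.
#' @export
write_image <- function(image, path, sidecar_path = paste0(path, ".json")) {
  stopifnot(inherits(image, "voxel_image"))
  nim <- RNifti::asNifti(image$values)
  RNifti::pixdim(nim) <- image$spacing
  RNifti::writeNifti(nim, path)
  meta <- list(units = image$units,
               duration = if (is.finite(image$duration)) image$duration else NULL,
               origin = image$origin,
               system_id = image$system_id,
               scenario = image$scenario,
               rr_scale = image$rr_scale)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)], sidecar_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, sidecar_path = paste0(path, ".json")) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (!file.exists(sidecar_path)) stop("sidecar not found: ", sidecar_path)
  nim <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  units <- meta$units %||% stop("sidecar missing `units`")
  if (!units %in% c("counts", "Bq/mL", "MBq/mL"))
    stop("unknown units string in sidecar: ", units)
  voxel_image(array(as.numeric(nim), dim = dim(nim)),
              spacing = RNifti::pixdim(nim),
              units = units,
              duration = meta$duration,
              origin = meta$origin %||% c(0, 0, 0),
              system_id = meta$system_id %||% "",
              scenario = meta$scenario %||% "",
              rr_scale = meta$rr_scale %||% 1)
}

# full default analysis configuration; VOI defaults follow the standard
# cylindrical calibration VOI (120 mm diameter x 150 mm length)
.default_config <- function() {
  list(
    phantom = list(
      cylinder_length = 211, cylinder_diameter = 195,
      cylinder_activity = 812,
      sphere_diameters = c(60, 37, 28, 22, 17, 13),
      sphere_concentration = 4,
      background_concentration = 0
    ),
    voi = list(diameter = 120, length = 150),
    grid = list(spacing = 4, margin = 36),
    recon = list(psf_fwhm = 12, ringing_beta = 0, ringing_alpha = 2,
                 icf_true = 20, quant_bias = 1,
                 cylinder_count_target = 7e6, nema_count_target = 3e6,
                 noise = "poisson", rr_scale = 1),
    gibbs = list(search_fraction = 0.9, smoothing = "gcv"),
    half_life_days = 6.6443,
    seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, applies defaults for every
#' missing key, and rejects unknown keys so that typos cannot silently
#' change an analysis.
#'
#' @param path YAML/JSON file path; `NULL` returns the full default set.
#' @return A validated configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
            else yaml::read_yaml(path)
    cfg <- .merge_config(cfg, user %||% list(), "")
  }
  .validate_config(cfg)
  cfg
}

.merge_config <- function(base, user, prefix) {
  if (!is.list(user)) stop("configuration section `", prefix, "` must be a mapping")
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && !is.null(names(base[[k]])))
      .merge_config(base[[k]], user[[k]], paste0(prefix, k, "."))
    else user[[k]]
  }
  base
}

.validate_config <- function(cfg) {
  p <- cfg$phantom
  if (p$cylinder_length <= 0 || p$cylinder_diameter <= 0)
    stop("cylinder dimensions must be positive")
  if (any(p$sphere_diameters <= 0)) stop("sphere diameters must be positive")
  if (p$sphere_concentration < 0 || p$background_concentration < 0)
    stop("concentrations must be >= 0")
  if (cfg$voi$diameter <= 0 || cfg$voi$length <= 0)
    stop("VOI dimensions must be positive")
  if (cfg$grid$spacing <= 0) stop("grid spacing must be positive")
  if (cfg$recon$psf_fwhm < 0) stop("`recon.psf_fwhm` must be >= 0")
  if (cfg$recon$ringing_beta < 0) stop("`recon.ringing_beta` must be >= 0")
  if (cfg$recon$ringing_alpha <= 1) stop("`recon.ringing_alpha` must be > 1")
  if (cfg$recon$icf_true <= 0) stop("`recon.icf_true` must be positive")
  if (cfg$half_life_days <= 0) stop("half-life must be positive")
  invisible(cfg)
}

#' Write / read a calibrator session as CSV
#'
#' Plain-text interchange format for calibrator sessions: columns
#' `timestamp` (ISO-8601, UTC), `raw_MBq`, `background_MBq`, plus constant
#' metadata columns `protocol`, `chamber`, `dial`, `vial_id`.
#'
#' @param session an `rnc_session`.
#' @param path CSV path.
#' @return `write_rnc_session()` returns `path` invisibly;
#'   `read_rnc_session()` returns an `rnc_session`.
#' @export
write_rnc_session <- function(session, path) {
  stopifnot(inherits(session, "rnc_session"))
  df <- session$readings
  out <- data.frame(
    timestamp = format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    raw_MBq = df$raw_MBq,
    background_MBq = df$background_MBq,
    protocol = session$protocol,
    chamber = session$chamber_model,
    dial = session$dial_setting,
    vial_id = session$vial_geometry,
    ref_time = format(session$ref_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rnc_session
#' @export
read_rnc_session <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "raw_MBq", "background_MBq")
  if (!all(need %in% names(df)))
    stop("session CSV must have columns: ", paste(need, collapse = ", "))
  rnc_session(
    data.frame(timestamp = as.POSIXct(df$timestamp, tz = "UTC",
                                      format = "%Y-%m-%dT%H:%M:%SZ"),
               raw_MBq = df$raw_MBq, background_MBq = df$background_MBq),
    protocol = df$protocol[1] %||% "clinical",
    chamber_model = df$chamber[1] %||% "generic",
    dial_setting = df$dial[1] %||% NA_integer_,
    vial_geometry = df$vial_id[1] %||% "",
    ref_time = if ("ref_time" %in% names(df))
      as.POSIXct(df$ref_time[1], tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
    else min(as.POSIXct(df$timestamp, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ"))
  )
}
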