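#' Radionuclide-calibrator session
#'
#' A set of repeated vial readings on one calibrator under one protocol:
#' timestamps, raw readings and the session background, plus chamber and
#' dial metadata.
#'
#' @param readings data.frame with columns `timestamp` (`POSIXct`),
#'   `raw_MBq`, `background_MBq`.
#' @param protocol `"factory"` or `"clinical"`.
#' @param chamber_model `"vik202"`, `"crc55tr"` or `"generic"`.
#' @param dial_setting integer dial setting used for the session.
#' @param vial_geometry free-text vial identifier.
#' @param ref_time common reference `POSIXct` time for decay correction.
#' @return An `rnc_session`.
#' @export
rnc_session <- function(readings, protocol = c("factory", "clinical"),
                        chamber_model = c("vik202", "crc55tr", "generic"),
                        dial_setting = NA_integer_, vial_geometry = "",
                        ref_time = min(readings$timestamp)) {
  protocol <- match.arg(protocol)
  chamber_model <- match.arg(chamber_model)
  need <- c("timestamp", "raw_MBq", "background_MBq")
  if (!is.data.frame(readings) || !all(need %in% names(readings)))
    stop("`readings` must have columns: ", paste(need, collapse = ", "))
  if (nrow(readings) < 1L) stop("at least one reading is required")
  if (any(readings$raw_MBq < 0)) stop("raw readings must be >= 0")
  structure(list(readings = readings, protocol = protocol,
                 chamber_model = chamber_model,
                 dial_setting = dial_setting,
                 vial_geometry = vial_geometry, ref_time = ref_time),
            class = "rnc_session")
}

#' Decay-correct an activity to a reference time
#'
#' Returns the activity at `t_ref` implied by a measurement at `t`:
#' `A_ref = A(t) * 2^((t - t_ref) / T_half)` (a later measurement of a
#' decaying source maps back to a larger activity).
#'
#' @param activity measured activity, MBq.
#' @param t measurement time (`POSIXct`).
#' @param t_ref reference time (`POSIXct`).
#' @param half_life half-life in days (default Lu-177).
#' @return Activity at `t_ref`, MBq.
#' @export
decay_correct <- function(activity, t, t_ref, half_life = 6.6443) {
  if (half_life <= 0) stop("half-life must be positive")
  dt_days <- as.numeric(difftime(t, t_ref, units = "days"))
  activity * 2^(dt_days / half_life)
}

#' Summarize a calibrator session against a reference activity
#'
#' Each reading is background-subtracted and decay-corrected to the
#' session reference time; the summary is the mean fractional deviation
#' from the reference activity, the relative standard deviation of the
#' corrected readings, and the number of readings.
#'
#' @param session an `rnc_session`.
#' @param ref_activity reference activity at `session$ref_time`, MBq.
#' @param half_life half-life in days.
#' @return List: `deviation_pct`, `sd_pct` (NA, flagged, for n < 2), `n`,
#'   `mean_corrected_MBq`.
#' @export
summarize_session <- function(session, ref_activity, half_life = 6.6443) {
  stopifnot(inherits(session, "rnc_session"))
  if (ref_activity <= 0) stop("reference activity must be positive")
  df <- session$readings
  corr <- decay_correct(df$raw_MBq - df$background_MBq, df$timestamp,
                        session$ref_time, half_life)
  m <- mean(corr)
  list(deviation_pct = 100 * (m / ref_activity - 1),
       sd_pct = if (nrow(df) >= 2L) 100 * stats::sd(corr) / m else NA_real_,
       n = nrow(df),
       mean_corrected_MBq = m)
}

#' Corrected dial setting from a measured deviation
#'
#' Re-tunes a calibrator dial so the chamber reads the traceable reference
#' correctly. Chamber response models: VIK-202-type chambers respond
#' locally proportionally to the dial (`dial_new = dial / (1 + dev)`),
#' CRC-type chambers inversely (`dial_new = dial * (1 + dev)`); a generic
#' chamber takes a user-supplied sensitivity (fractional response change
#' per dial unit, `dial_new = dial - dev / sensitivity`). Results are
#' rounded to the nearest integer dial.
#'
#' @param dial current integer dial setting.
#' @param deviation measured fractional deviation (reading/true - 1),
#'   |deviation| < 0.5.
#' @param chamber_model `"vik202"`, `"crc55tr"` or `"generic"`.
#' @param sensitivity fractional response change per dial unit (generic
#'   model only).
#' @return Integer corrected dial setting.
#' @export
corrected_dial <- function(dial, deviation,
                           chamber_model = c("vik202", "crc55tr", "generic"),
                           sensitivity = NULL) {
  chamber_model <- match.arg(chamber_model)
  if (abs(deviation) >= 0.5) stop("|deviation| must be below 50%")
  new <- switch(chamber_model,
    vik202 = dial / (1 + deviation),
    crc55tr = dial * (1 + deviation),
    generic = {
      if (is.null(sensitivity) || sensitivity == 0)
        stop("generic chamber model requires a nonzero `sensitivity`")
      dial - deviation / sensitivity
    })
  as.integer(round(new))
}

#' Vial-geometry correction factor
#'
#' Relative chamber response to a clinical vial geometry versus the
#' reference geometry: `(response_clin / true_clin) / (response_ref /
#' true_ref)` from two sessions on the same chamber and dial. A factor
#' above 1 means the clinical geometry reads relatively high; a clinical
#' reading is corrected by dividing by this factor.
#'
#' @param session_ref,session_clin `rnc_session`s for the reference and
#'   clinical vials.
#' @param true_ref,true_clin true activities at each session's reference
#'   time, MBq.
#' @param half_life half-life in days.
#' @return Dimensionless correction factor.
#' @export
geometry_correction_factor <- function(session_ref, session_clin,
                                       true_ref, true_clin,
                                       half_life = 6.6443) {
  if (true_ref <= 0 || true_clin <= 0) stop("true activities must be positive")
  if (!identical(session_ref$chamber_model, session_clin$chamber_model) ||
      !identical(session_ref$dial_setting, session_clin$dial_setting))
    stop("sessions must use the same chamber and dial setting")
  r_ref <- summarize_session(session_ref, true_ref, half_life)
  r_clin <- summarize_session(session_clin, true_clin, half_life)
  (r_clin$mean_corrected_MBq / true_clin) / (r_ref$mean_corrected_MBq / true_ref)
}

#' Uncertainty budget
#'
#' A set of uncertainty components with their distribution conventions:
#' `normal_k1` magnitudes are standard uncertainties, `normal_k2` are
#' expanded (k = 2) values, `rectangular_halfwidth` are half-widths of a
#' rectangular distribution.
#'
#' @param labels component names.
#' @param magnitudes component magnitudes, percent.
#' @param distributions one of `"normal_k1"`, `"normal_k2"`,
#'   `"rectangular_halfwidth"` per component.
#' @param k coverage factor of the combined result.
#' @return An `uncertainty_budget`.
#' @export
uncertainty_budget <- function(labels, magnitudes, distributions, k = 2) {
  n <- length(magnitudes)
  distributions <- rep_len(distributions, n)
  labels <- rep_len(labels, n)
  if (n < 1L) stop("at least one component is required")
  if (any(magnitudes < 0)) stop("magnitudes must be >= 0")
  ok <- c("normal_k1", "normal_k2", "rectangular_halfwidth")
  if (!all(distributions %in% ok))
    stop("distributions must be one of: ", paste(ok, collapse = ", "))
  if (k <= 0) stop("coverage factor must be positive")
  structure(list(components = data.frame(label = labels,
                                         magnitude = magnitudes,
                                         distribution = distributions),
                 k = k),
            class = "uncertainty_budget")
}

#' Expanded combined uncertainty of a budget
#'
#' Converts every component to a standard uncertainty (`normal_k1` as-is,
#' `normal_k2` divided by 2, rectangular half-widths divided by sqrt(3)),
#' combines in quadrature, and multiplies by the coverage factor.
#'
#' @param budget an `uncertainty_budget`.
#' @return Expanded uncertainty, percent.
#' @export
#' @examples
#' # 3-4-5 quadrature
#' combine_uncertainty(uncertainty_budget(c("a", "b"), c(3, 4), "normal_k1", k = 1))
combine_uncertainty <- function(budget) {
  stopifnot(inherits(budget, "uncertainty_budget"))
  div <- c(normal_k1 = 1, normal_k2 = 2, rectangular_halfwidth = sqrt(3))
  u <- budget$components$magnitude / div[budget$components$distribution]
  budget$k * sqrt(sum(u^2))
}
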