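#' Default ECG generating parameters by group and timepoint
#'
#' Returns the per-group beat-stream generating parameters used by the
#' synthetic cohort: mean RR and its beat-to-beat (AR(1)) standard deviation,
#' the linear QT--RR relation (slope ms/ms, intercept ms), the QT additive
#' noise SD, and Gaussian means for the PQ, QRS and TpTe intervals.
#'
#' At baseline (`"week0"`) both groups share the pooled QT--RR relation
#' (slope 0.045, intercept 187 ms).  At `"week16"` the intercepts differ by
#' group so that the generated QT mean at the group mean RR reproduces the
#' study-condition group means; the slope is unchanged.
#'
#' @param group `"SED"` or `"TRN"`.
#' @param timepoint `"week0"` or `"week16"`.
#' @return Named list of generating parameters (all times in ms).
#' @export
ecg_defaults <- function(group = c("SED", "TRN"),
                         timepoint = c("week16", "week0")) {
  group <- match.arg(group)
  timepoint <- match.arg(timepoint)
  tab <- list(
    week0 = list(
      SED = list(rr_mean_ms = 588.4, qt_intercept = 187,
                 pq_mean_ms = 103.2, qrs_mean_ms = 59.6, tpte_mean_ms = 27.3,
                 qt_noise_sd = 3.2),
      TRN = list(rr_mean_ms = 579.3, qt_intercept = 187,
                 pq_mean_ms = 98.3, qrs_mean_ms = 60.5, tpte_mean_ms = 27.9,
                 qt_noise_sd = 3.2)
    ),
    week16 = list(
      SED = list(rr_mean_ms = 644.2, qt_intercept = 194.011,
                 pq_mean_ms = 102.8, qrs_mean_ms = 56.3, tpte_mean_ms = 30.9,
                 qt_noise_sd = 3.2),
      TRN = list(rr_mean_ms = 841.8, qt_intercept = 213.419,
                 pq_mean_ms = 110.7, qrs_mean_ms = 70.8, tpte_mean_ms = 36.5,
                 qt_noise_sd = 4.4)
    )
  )
  p <- tab[[timepoint]][[group]]
  c(p, list(qt_slope = 0.045, rr_sd_ms = 40, rr_autocorr = 0.8,
            pq_sd_ms = 2, qrs_sd_ms = 2, tpte_sd_ms = 2))
}

#' Reference echocardiographic group means
#'
#' Group means and their standard errors (n = 12 animals per group) for the
#' raw echo measurements the generator draws from: interventricular septum
#' (IVS), left ventricular posterior wall (LVPW), end-systolic and
#' end-diastolic diameters (LVESD, LVEDD) in mm and left atrial volume (LAV)
#' in ml, at baseline and after 16 weeks.
#'
#' @return Data frame with columns `group`, `timepoint`, `variable`, `mean`,
#'   `sem`, `n`.
#' @export
echo_reference_means <- function() {
  ref <- rbind(
    c("SED", "week0",  "ivs_mm",   7.1,  0.3),
    c("TRN", "week0",  "ivs_mm",   6.8,  0.2),
    c("SED", "week0",  "lvpw_mm",  7.1,  0.2),
    c("TRN", "week0",  "lvpw_mm",  6.95, 0.2),
    c("SED", "week0",  "lvesd_mm", 14.2, 0.3),
    c("TRN", "week0",  "lvesd_mm", 17.6, 0.7),
    c("SED", "week0",  "lvedd_mm", 28.7, 0.7),
    c("TRN", "week0",  "lvedd_mm", 29.0, 0.96),
    c("SED", "week0",  "lav_ml",   9.0,  0.9),
    c("TRN", "week0",  "lav_ml",   8.9,  0.6),
    c("SED", "week16", "ivs_mm",   7.4,  0.2),
    c("TRN", "week16", "ivs_mm",   8.13, 0.2),
    c("SED", "week16", "lvpw_mm",  7.4,  0.3),
    c("TRN", "week16", "lvpw_mm",  7.64, 0.3),
    c("SED", "week16", "lvesd_mm", 18.7, 0.5),
    c("TRN", "week16", "lvesd_mm", 18.4, 0.1),
    c("SED", "week16", "lvedd_mm", 30.4, 0.7),
    c("TRN", "week16", "lvedd_mm", 32.0, 0.7),
    c("SED", "week16", "lav_ml",   10.4, 0.9),
    c("TRN", "week16", "lav_ml",   11.4, 1.4)
  )
  out <- data.frame(group = ref[, 1], timepoint = ref[, 2],
                    variable = ref[, 3],
                    mean = as.numeric(ref[, 4]), sem = as.numeric(ref[, 5]),
                    n = 12L, stringsAsFactors = FALSE)
  out
}

#' Build a validated cohort configuration
#'
#' Assembles every tunable of the synthetic two-group cohort.  Defaults are
#' the study conditions: group mean intervals and cellular readouts, reported
#' standard errors converted to between-unit SDs via `SD = SEM * sqrt(n)`,
#' an escape-beat rate of 29.7/hr in the trained group and 0/hr in the
#' sedentary group, and the AP jitter SD chosen so that the expected
#' short-term variability `sigma * sqrt(2/pi)` matches the group STV-APD
#' (29.5 ms trained, 17.5 ms sedentary).
#'
#' @param n_per_group Animals per group.
#' @param seed Master seed; per-animal streams use `seed + animal index`.
#' @param rr_autocorr Lag-1 autocorrelation of the RR AR(1) process, in
#'   `[0, 1)`.
#' @param escape_rate_per_hr,premature_rate_per_hr Named numeric vectors
#'   (`SED`, `TRN`) of Poisson ectopy rates.
#' @param pause_factor Escape pause as a multiple of the prevailing RR.
#' @param coupling_factor Premature coupling interval as a multiple of the
#'   prevailing RR.
#' @param apd90_mean_ms,apd90_between_cell_sd_ms,apd_jitter_sd_ms Named
#'   per-group APD90 generating parameters (ms).
#' @param ito_density_mean,ito_density_sd Named per-group transient-outward
#'   current densities at the +50 mV step (pA/pF).
#' @param capacitance_mean_pF,capacitance_sd_pF Cell capacitance draw
#'   (Gaussian truncated at 0).
#' @param iv_noise_sd_pA Additive measurement noise on each step current.
#' @param n_ap_cells,n_stv_cells,n_iv_cells Named per-group cell counts for
#'   AP trains, STV-APD analysis and voltage-clamp records.
#' @param bw_range_kg Body-weight range (uniform draw), kg.
#' @param recording_duration_min,n_recordings Resting ECG protocol: length
#'   and number of recordings per animal.
#' @param echo_means Data frame as returned by [echo_reference_means()].
#' @return Object of class `"cohort_config"` (a named list).
#' @export
cohort_config <- function(n_per_group = 12L,
                          seed = 1L,
                          rr_autocorr = 0.8,
                          escape_rate_per_hr = c(SED = 0, TRN = 29.7),
                          premature_rate_per_hr = c(SED = 1, TRN = 1),
                          pause_factor = 1.8,
                          coupling_factor = 0.6,
                          apd90_mean_ms = c(SED = 370.1, TRN = 472.8),
                          apd90_between_cell_sd_ms =
                            c(SED = 32.7 * sqrt(25), TRN = 29.6 * sqrt(29)),
                          apd_jitter_sd_ms =
                            c(SED = 17.5 / sqrt(2 / pi),
                              TRN = 29.5 / sqrt(2 / pi)),
                          ito_density_mean = c(SED = 8.8, TRN = 6.4),
                          ito_density_sd =
                            c(SED = 0.9 * sqrt(42), TRN = 0.5 * sqrt(54)),
                          capacitance_mean_pF = 125,
                          capacitance_sd_pF = 20,
                          iv_noise_sd_pA = 25,
                          n_ap_cells = c(SED = 25L, TRN = 29L),
                          n_stv_cells = c(SED = 18L, TRN = 27L),
                          n_iv_cells = c(SED = 42L, TRN = 54L),
                          bw_range_kg = c(9, 15),
                          recording_duration_min = 20,
                          n_recordings = 3L,
                          echo_means = echo_reference_means()) {
  cfg <- list(
    n_per_group = as.integer(n_per_group), seed = as.integer(seed),
    rr_autocorr = rr_autocorr,
    escape_rate_per_hr = escape_rate_per_hr,
    premature_rate_per_hr = premature_rate_per_hr,
    pause_factor = pause_factor, coupling_factor = coupling_factor,
    apd90_mean_ms = apd90_mean_ms,
    apd90_between_cell_sd_ms = apd90_between_cell_sd_ms,
    apd_jitter_sd_ms = apd_jitter_sd_ms,
    ito_density_mean = ito_density_mean, ito_density_sd = ito_density_sd,
    capacitance_mean_pF = capacitance_mean_pF,
    capacitance_sd_pF = capacitance_sd_pF,
    iv_noise_sd_pA = iv_noise_sd_pA,
    n_ap_cells = n_ap_cells, n_stv_cells = n_stv_cells,
    n_iv_cells = n_iv_cells,
    bw_range_kg = bw_range_kg,
    recording_duration_min = recording_duration_min,
    n_recordings = as.integer(n_recordings),
    echo_means = echo_means
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param config Object to validate.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c("SED", "TRN")
  need_groups <- function(x, nm) {
    if (!all(groups %in% names(x)))
      stop("config field '", nm, "' must be named for SED and TRN",
           call. = FALSE)
    if (any(!is.finite(x[groups])))
      stop("config field '", nm, "' has non-finite values", call. = FALSE)
  }
  for (nm in c("escape_rate_per_hr", "premature_rate_per_hr",
               "apd90_mean_ms", "apd90_between_cell_sd_ms",
               "apd_jitter_sd_ms", "ito_density_mean", "ito_density_sd",
               "n_ap_cells", "n_stv_cells", "n_iv_cells"))
    need_groups(config[[nm]], nm)
  if (config$n_per_group < 1L) stop("n_per_group must be >= 1")
  if (config$rr_autocorr < 0 || config$rr_autocorr >= 1)
    stop("rr_autocorr must lie in [0, 1)")
  if (any(config$escape_rate_per_hr < 0) ||
      any(config$premature_rate_per_hr < 0))
    stop("ectopy rates must be >= 0")
  if (any(c(config$apd90_between_cell_sd_ms, config$apd_jitter_sd_ms,
            config$ito_density_sd, config$capacitance_sd_pF,
            config$iv_noise_sd_pA) < 0))
    stop("standard deviations must be >= 0")
  if (!(config$coupling_factor < 1 && config$pause_factor > 1))
    stop("coupling_factor must be < 1 and pause_factor > 1")
  if (config$recording_duration_min <= 0) stop("recording duration must be > 0")
  if (config$bw_range_kg[1] <= 0 || diff(config$bw_range_kg) < 0)
    stop("bw_range_kg must be positive and ordered")
  invisible(config)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d animals/group, seed %d\n", x$n_per_group, x$seed))
  cat(sprintf("  resting ECG: %d x %.0f min recordings\n",
              x$n_recordings, x$recording_duration_min))
  cat(sprintf("  escape rate/hr: SED %.1f, TRN %.1f; premature: SED %.1f, TRN %.1f\n",
              x$escape_rate_per_hr["SED"], x$escape_rate_per_hr["TRN"],
              x$premature_rate_per_hr["SED"], x$premature_rate_per_hr["TRN"]))
  cat(sprintf("  APD90 means (ms): SED %.1f, TRN %.1f; Ito at +50 mV (pA/pF): SED %.1f, TRN %.1f\n",
              x$apd90_mean_ms["SED"], x$apd90_mean_ms["TRN"],
              x$ito_density_mean["SED"], x$ito_density_mean["TRN"]))
  invisible(x)
}
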