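#' Extract per-beat action-potential features
#'
#' For each stimulus, within the window up to the next stimulus: the
#' resting membrane potential (RMP) is the mean voltage over the
#' `rmp_window_ms` immediately preceding the stimulus; the peak is the
#' maximum voltage of the beat; amplitude = peak - RMP; APD at the chosen
#' repolarization fraction is measured from the maximum-upstroke-velocity
#' point (midpoint of the steepest sampled interval; or the stimulus time
#' with `onset = "stimulus"`) to the first downward crossing of
#' `peak - repol_fraction * amplitude`, linearly interpolated between
#' samples.  A beat is excluded when RMP is more positive than -70 mV or
#' the amplitude is below 90 mV; a beat that does not recross the level
#' before the next stimulus is marked unmeasurable.  Exclusions are applied
#' before any aggregation.
#'
#' @param trace An `"ap_trace"` (see [generate_ap_train()]) or a list with
#'   `t_ms`, `v_mV`, `stimulus_times_ms`.
#' @param repol_fraction Repolarization fraction (0.9 for APD90).
#' @param rmp_window_ms Pre-stimulus averaging window (ms).
#' @param onset `"upstroke"` (default) or `"stimulus"`.
#' @param rmp_max_mV,amplitude_min_mV Inclusion thresholds.
#' @return Data frame of class `"ap_features"`, one row per beat: `beat`,
#'   `rmp_mV`, `peak_mV`, `amplitude_mV`, `apd_ms`, `included`,
#'   `exclusion_reason`.
#' @export
extract_ap_features <- function(trace, repol_fraction = 0.9,
                                rmp_window_ms = 20,
                                onset = c("upstroke", "stimulus"),
                                rmp_max_mV = -70, amplitude_min_mV = 90) {
  onset <- match.arg(onset)
  stopifnot(!is.null(trace$t_ms), !is.null(trace$v_mV),
            length(trace$stimulus_times_ms) >= 1)
  if (repol_fraction <= 0 || repol_fraction >= 1)
    stop("repol_fraction must lie in (0, 1)")
  t <- trace$t_ms
  v <- trace$v_mV
  stim <- trace$stimulus_times_ms
  bounds <- c(stim, t[length(t)] + (t[2] - t[1]))
  n_beats <- length(stim)
  out <- data.frame(beat = seq_len(n_beats), rmp_mV = NA_real_,
                    peak_mV = NA_real_, amplitude_mV = NA_real_,
                    apd_ms = NA_real_, included = FALSE,
                    exclusion_reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_beats)) {
    pre <- t >= (stim[k] - rmp_window_ms) & t < stim[k]
    if (!any(pre)) {
      out$exclusion_reason[k] <- "no_prestimulus_window"
      next
    }
    rmp <- mean(v[pre])
    win <- which(t >= stim[k] & t < bounds[k + 1])
    if (length(win) < 3L) {
      out$exclusion_reason[k] <- "window_too_short"
      next
    }
    tv <- t[win]; vv <- v[win]
    ipk <- which.max(vv)
    peak <- vv[ipk]
    amp <- peak - rmp
    out$rmp_mV[k] <- rmp
    out$peak_mV[k] <- peak
    out$amplitude_mV[k] <- amp
    if (rmp > rmp_max_mV) {
      out$exclusion_reason[k] <- "RMP"
      next
    }
    if (amp < amplitude_min_mV) {
      out$exclusion_reason[k] <- "amplitude"
      next
    }
    t0 <- if (onset == "stimulus") stim[k] else {
      dv <- diff(vv[seq_len(ipk)])
      if (!length(dv)) tv[1] else {
        j <- which.max(dv)
        (tv[j] + tv[j + 1]) / 2  # midpoint of the steepest interval
      }
    }
    level <- peak - repol_fraction * amp
    below <- which(vv <= level)
    below <- below[below > ipk]
    if (!length(below)) {
      out$exclusion_reason[k] <- "no_crossing_before_next_stimulus"
      next
    }
    j <- below[1]
    # linear interpolation of the downward crossing
    tc <- if (j == 1L) tv[1] else {
      f <- (vv[j - 1] - level) / (vv[j - 1] - vv[j])
      tv[j - 1] + f * (tv[j] - tv[j - 1])
    }
    out$apd_ms[k] <- tc - t0
    out$included[k] <- TRUE
  }
  class(out) <- c("ap_features", "data.frame")
  out
}

#' Short-term variability of APD90 over 30 consecutive beats
#'
#' Applies the short-term variability statistic (see [stv()]) to exactly
#' `n_beats` consecutive included APD90 values, taken from the END of the
#' recorded run so an initial equilibration period is discarded: by default
#' the last 30 of at least 60 recorded beats.
#'
#' @param apd90_series Numeric APD90 series (ms), or an `"ap_features"`
#'   frame (included beats are used).
#' @param n_beats Analysis window in beats (default 30).
#' @param min_recorded Minimum recorded beats before analysis is allowed
#'   (default 60); set lower only for reduced designs.
#' @return STV-APD in ms.
#' @export
stv_apd <- function(apd90_series, n_beats = 30L, min_recorded = 60L) {
  if (inherits(apd90_series, "ap_features"))
    apd90_series <- apd90_series$apd_ms[apd90_series$included]
  apd90_series <- apd90_series[!is.na(apd90_series)]
  if (length(apd90_series) < max(n_beats, min_recorded))
    stop(sprintf("need >= %d recorded beats (have %d)",
                 max(n_beats, min_recorded), length(apd90_series)))
  stv(utils::tail(apd90_series, n_beats))
}

#' Capacitance-normalized current density
#'
#' `density = peak current / cell capacitance`, in pA/pF.
#'
#' @param peak_current_pA Peak current(s), pA.
#' @param capacitance_pF Cell capacitance, pF (> 0).
#' @return Density in pA/pF (vectorized over currents).
#' @export
current_density <- function(peak_current_pA, capacitance_pF) {
  if (any(capacitance_pF <= 0)) stop("capacitance must be > 0")
  peak_current_pA / capacitance_pF
}

#' Assemble a group current--voltage relationship
#'
#' Normalizes each cell's step currents by its capacitance and aggregates
#' densities across cells at each protocol voltage (mean and SEM, n).  With
#' `voltage` given, returns the summary at that named step only; a voltage
#' absent from the protocol grid is an error, as is a group of fewer than
#' two cells (SEM undefined).
#'
#' @param records List of `"iv_record"` objects (one group).
#' @param voltage Optional single voltage (mV) to extract.
#' @return Data frame `v_mV`, `mean_pApF`, `sem_pApF`, `n`; or a one-row
#'   subset when `voltage` is given.
#' @export
assemble_iv <- function(records, voltage = NULL) {
  if (inherits(records, "iv_record")) records <- list(records)
  if (length(records) < 2L) stop("need >= 2 cells per group (SEM undefined)")
  dens <- lapply(records, function(r) {
    stopifnot(inherits(r, "iv_record"))
    data.frame(v_mV = r$steps$v_mV,
               d = current_density(r$steps$i_pA, r$capacitance_pF))
  })
  all_v <- sort(unique(unlist(lapply(dens, function(d) d$v_mV))))
  agg <- do.call(rbind, lapply(all_v, function(vv) {
    x <- unlist(lapply(dens, function(d) d$d[d$v_mV == vv]))
    data.frame(v_mV = vv, mean_pApF = mean(x),
               sem_pApF = stats::sd(x) / sqrt(length(x)), n = length(x))
  }))
  if (!is.null(voltage)) {
    hit <- which(abs(agg$v_mV - voltage) < 1e-9)
    if (!length(hit))
      stop("voltage ", voltage, " mV is not in the protocol grid")
    agg <- agg[hit, , drop = FALSE]
    rownames(agg) <- NULL
  }
  agg
}
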