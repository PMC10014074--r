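#' Select the analysis window of consecutive sinus beats
#'
#' Returns the first run of `n_beats` CONSECUTIVE sinus-labelled beats
#' beginning at or after `start_min` minutes into the recording.  A
#' non-sinus beat resets the run (skip-and-restart rule).  Window
#' eligibility requires RR and QT to be present on every beat of the run.
#'
#' @param series A [beat_series()].
#' @param start_min Start of the eligible region, minutes (default 10).
#' @param n_beats Window length in beats (default 40).
#' @param require_qt Require `qt_ms` present on every window beat
#'   (default `TRUE`).
#' @return A [beat_series()] of exactly `n_beats` rows.
#' @export
select_analysis_window <- function(series, start_min = 10, n_beats = 40L,
                                   require_qt = TRUE) {
  stopifnot(inherits(series, "beat_series"))
  df <- as.data.frame(series)
  start_ms <- start_min * 60000
  eligible <- df$t_ms >= start_ms & df$label == "sinus" & !is.na(df$rr_ms)
  if (require_qt) eligible <- eligible & !is.na(df$qt_ms)
  # run lengths of consecutive eligible beats
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= n_beats)
  if (!length(ok)) {
    longest <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    stop(sprintf(
      "no run of %d consecutive sinus beats at/after minute %g (longest run: %d)",
      n_beats, start_min, longest), call. = FALSE)
  }
  i0 <- starts[ok[1]]
  win <- df[seq(i0, i0 + n_beats - 1L), ]
  win$beat_index <- seq_len(nrow(win))
  rownames(win) <- NULL
  beat_series(win, animal_id = attr(series, "animal_id"),
              group = attr(series, "group"),
              duration_min = attr(series, "duration_min"))
}

#' Windowed interval means and heart rate
#'
#' Arithmetic means of each interval column over the window; columns absent
#' from every beat yield `NA` means rather than errors.  Heart rate is
#' computed from the mean RR interval, `HR = 60000 / mean(RR)` bpm, not as
#' the mean of per-beat rates.
#'
#' @param window A non-empty [beat_series()] with RR on every beat.
#' @return Named list: `rr_ms`, `pq_ms`, `qrs_ms`, `qt_ms`, `tpte_ms`
#'   (means), `hr_bpm`, `n_beats`.
#' @export
mean_intervals <- function(window) {
  stopifnot(inherits(window, "beat_series"))
  if (nrow(window) == 0L) stop("empty window")
  if (anyNA(window$rr_ms)) stop("rr_ms must be present on all beats")
  m <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  out <- list(rr_ms = m(window$rr_ms), pq_ms = m(window$pq_ms),
              qrs_ms = m(window$qrs_ms), qt_ms = m(window$qt_ms),
              tpte_ms = m(window$tpte_ms))
  out$hr_bpm <- 60000 / out$rr_ms
  out$n_beats <- nrow(window)
  out
}

#' Root mean square of successive differences
#'
#' `sqrt(mean(diff(x)^2))` over the n-1 successive differences; the
#' standard time-domain RMSSD with no detrending.
#'
#' @param values Ordered numeric series (ms), length >= 2.
#' @return RMSSD in the units of `values`.
#' @export
rmssd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values))
    stop("rmssd needs >= 2 non-missing values")
  sqrt(mean(diff(values)^2))
}

#' Short-term variability of a beat series
#'
#' Mean absolute successive difference divided by sqrt(2):
#' `sum(|x[i+1] - x[i]|) / ((N - 1) * sqrt(2))`.  Geometrically, the mean
#' perpendicular distance of the Poincare points from the identity line.
#' The divisor counts differences (`N - 1`); set `divisor_n = TRUE` to
#' divide by `N` instead.
#'
#' @param values Ordered numeric series (ms), length >= 2.
#' @param divisor_n Use `N` instead of `N - 1` as the divisor.
#' @return STV in the units of `values`.
#' @export
stv <- function(values, divisor_n = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values))
    stop("stv needs >= 2 non-missing values")
  d <- abs(diff(values))
  denom <- if (divisor_n) length(values) else length(values) - 1L
  sum(d) / (denom * sqrt(2))
}

#' Poincare pairs of a series
#'
#' The n-1 ordered pairs `(x[n], x[n+1])`, no aggregation; the raw material
#' of a Poincare plot.
#'
#' @param values Ordered numeric series, length >= 2.
#' @return Data frame with columns `x` and `x_next`.
#' @export
poincare_pairs <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("poincare_pairs needs >= 2 values")
  n <- length(values)
  data.frame(x = values[-n], x_next = values[-1])
}

#' Beat-to-beat variability summary of a window
#'
#' Convenience wrapper computing, over an analysis window, the mean, RMSSD
#' and STV of one interval column.
#'
#' @param window A [beat_series()].
#' @param column Interval column name (e.g. `"rr_ms"`, `"qt_ms"`).
#' @return Named list: `mean_ms`, `rmssd_ms`, `stv_ms`, `n_beats_used`.
#' @export
variability_result <- function(window, column = "qt_ms") {
  stopifnot(inherits(window, "beat_series"), column %in% names(window))
  x <- window[[column]]
  x <- x[!is.na(x)]
  list(mean_ms = mean(x), rmssd_ms = rmssd(x), stv_ms = stv(x),
       n_beats_used = length(x))
}
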