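#' Classifier parameters for ventricular ectopy
#'
#' The class boundaries are dimensionless ratios of the prevailing RR (the
#' trailing median of recent sinus RRs), which makes classification
#' invariant to uniform time rescaling: a ventricular-morphology beat is
#' premature when its coupling RR is at most `premature_max_fraction` of
#' the prevailing RR and escape when its preceding pause is at least
#' `escape_min_fraction` of it.
#'
#' @param prevailing_window_beats Number of trailing sinus RRs in the
#'   prevailing-RR median (default 10).
#' @param premature_max_fraction Upper coupling bound for premature beats
#'   (default 0.80; must be < 1).
#' @param escape_min_fraction Lower pause bound for escape beats (default
#'   1.50; must be > 1).
#' @param require_wide_qrs,require_no_p Morphology flags a beat must carry
#'   to be considered ventricular (defaults `TRUE`).
#' @return List of class `"classifier_params"`.
#' @export
classifier_params <- function(prevailing_window_beats = 10L,
                              premature_max_fraction = 0.80,
                              escape_min_fraction = 1.50,
                              require_wide_qrs = TRUE,
                              require_no_p = TRUE) {
  if (!(premature_max_fraction > 0 && premature_max_fraction < 1 &&
        escape_min_fraction > 1))
    stop("need 0 < premature_max_fraction < 1 < escape_min_fraction")
  if (prevailing_window_beats < 1) stop("prevailing window must be >= 1 beat")
  structure(list(prevailing_window_beats = as.integer(prevailing_window_beats),
                 premature_max_fraction = premature_max_fraction,
                 escape_min_fraction = escape_min_fraction,
                 require_wide_qrs = require_wide_qrs,
                 require_no_p = require_no_p),
            class = "classifier_params")
}

#' Classify ventricular premature and escape beats
#'
#' Rewrites the `label` column of a beat series from interval geometry and
#' morphology flags alone (any existing labels are ignored).  Beats whose
#' morphology matches the ventricular criterion (wide QRS and/or no
#' associated P wave, per the params flags) are compared with the
#' prevailing RR -- the trailing median of the last
#' `prevailing_window_beats` sinus-morphology RRs: coupling at or below
#' `premature_max_fraction` times prevailing is premature, a pause at or
#' above `escape_min_fraction` times prevailing is escape, anything else is
#' `other`.  Narrow-QRS beats stay sinus.
#'
#' @param series A [beat_series()] with RR present on every beat.
#' @param params A [classifier_params()].
#' @return The series with the `label` column reassigned.
#' @export
classify_beats <- function(series, params = classifier_params()) {
  stopifnot(inherits(series, "beat_series"),
            inherits(params, "classifier_params"))
  df <- as.data.frame(series)
  if (anyNA(df$rr_ms)) stop("rr_ms must be present on all beats")
  if (nrow(df) < params$prevailing_window_beats)
    stop("series shorter than the prevailing-RR window (",
         params$prevailing_window_beats, " beats)")
  ventricular <- rep(TRUE, nrow(df))
  if (params$require_wide_qrs) ventricular <- ventricular & df$wide_qrs == 1L
  if (params$require_no_p) ventricular <- ventricular & df$p_associated == 0L
  label <- ifelse(ventricular, "other", "sinus")
  sinus_idx <- which(!ventricular)
  for (i in which(ventricular)) {
    prior <- sinus_idx[sinus_idx < i]
    if (!length(prior)) next  # no sinus history: leave as 'other'
    prev <- stats::median(
      df$rr_ms[utils::tail(prior, params$prevailing_window_beats)])
    ratio <- df$rr_ms[i] / prev
    if (ratio <= params$premature_max_fraction)
      label[i] <- "premature_ventricular"
    else if (ratio >= params$escape_min_fraction)
      label[i] <- "escape_ventricular"
  }
  df$label <- label
  beat_series(df, animal_id = attr(series, "animal_id"),
              group = attr(series, "group"),
              duration_min = attr(series, "duration_min"))
}

#' Count arrhythmic beats and convert to hourly rates
#'
#' Sums classified ventricular beats across one or more recordings of the
#' same animal; the total arrhythmic count is the sum of all ventricular
#' arrhythmic beats of any class, and rates use the pooled duration
#' (`count * 60 / duration_min`).
#'
#' @param recordings A classified [beat_series()] or a list of them.
#' @return List of class `"arrhythmia_counts"`: `n_premature`, `n_escape`,
#'   `n_other_ventricular`, `n_total_arrhythmic`, `duration_min`,
#'   `rate_premature_per_hr`, `rate_escape_per_hr`,
#'   `rate_total_per_hr`.
#' @export
count_and_rate <- function(recordings) {
  if (inherits(recordings, "beat_series")) recordings <- list(recordings)
  if (!length(recordings)) stop("need >= 1 recording")
  counts <- c(premature_ventricular = 0L, escape_ventricular = 0L,
              other = 0L)
  duration_min <- 0
  for (rec in recordings) {
    stopifnot(inherits(rec, "beat_series"))
    duration_min <- duration_min + attr(rec, "duration_min")
    tab <- table(factor(rec$label, levels = names(counts)))
    counts <- counts + as.integer(tab)
  }
  if (duration_min <= 0) stop("zero total duration")
  total <- sum(counts)
  structure(list(
    n_premature = unname(counts["premature_ventricular"]),
    n_escape = unname(counts["escape_ventricular"]),
    n_other_ventricular = unname(counts["other"]),
    n_total_arrhythmic = total,
    duration_min = duration_min,
    rate_premature_per_hr = unname(counts["premature_ventricular"]) * 60 /
      duration_min,
    rate_escape_per_hr = unname(counts["escape_ventricular"]) * 60 /
      duration_min,
    rate_total_per_hr = total * 60 / duration_min),
    class = "arrhythmia_counts")
}

#' @export
print.arrhythmia_counts <- function(x, ...) {
  cat(sprintf(
    "Arrhythmic beats over %.0f min: %d premature (%.1f/hr), %d escape (%.1f/hr), %d other; total %d (%.1f/hr)\n",
    x$duration_min, x$n_premature, x$rate_premature_per_hr, x$n_escape,
    x$rate_escape_per_hr, x$n_other_ventricular, x$n_total_arrhythmic,
    x$rate_total_per_hr))
  invisible(x)
}

#' Per-group incidence and 2x2 contingency table
#'
#' Converts per-animal event indicators (or counts, thresholded at > 0)
#' into group incidence proportions and the 2x2 table handed to the
#' chi-square test.
#'
#' @param events Named list (or two vectors via `sed`/`trn`) of per-animal
#'   logical indicators or non-negative counts.
#' @param sed,trn Alternative explicit per-group vectors.
#' @return List: `proportions` (named per group), `table` (2x2 matrix,
#'   rows = groups, cols = event yes/no), `n` per group.
#' @export
incidence <- function(events = NULL, sed = NULL, trn = NULL) {
  if (!is.null(events)) {
    sed <- events$SED
    trn <- events$TRN
  }
  if (!length(sed) || !length(trn)) stop("need >= 1 animal per group")
  to_flag <- function(x) {
    if (is.logical(x)) return(x)
    if (any(x < 0)) stop("counts must be >= 0")
    x > 0
  }
  sed <- to_flag(sed); trn <- to_flag(trn)
  tab <- matrix(c(sum(trn), sum(!trn), sum(sed), sum(!sed)),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("TRN", "SED"),
                                event = c("yes", "no")))
  list(proportions = c(TRN = mean(trn), SED = mean(sed)),
       table = tab, n = c(TRN = length(trn), SED = length(sed)))
}
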