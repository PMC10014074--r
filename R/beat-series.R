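#' Construct a beat series
#'
#' A beat series is one ECG recording reduced to one row per beat: the time
#' of the beat since the start of the recording, the interval measurements
#' (RR, PQ, QRS, QT, TpTe, all ms; any may be `NA`), two morphology flags
#' (wide QRS, P-wave association) and a rhythm label.  When produced by the
#' synthetic generator a `truth_label` column carries the injected ground
#' truth.
#'
#' @param beats Data frame with columns `t_ms`, `rr_ms` and optionally
#'   `pq_ms`, `qrs_ms`, `qt_ms`, `tpte_ms`, `wide_qrs`, `p_associated`,
#'   `label`, `truth_label`.
#' @param animal_id,group,duration_min Recording metadata.
#' @return Object of class `"beat_series"` (a data frame with attributes).
#' @export
beat_series <- function(beats, animal_id = NA_character_,
                        group = NA_character_, duration_min = NA_real_) {
  stopifnot(is.data.frame(beats), all(c("t_ms", "rr_ms") %in% names(beats)))
  n <- nrow(beats)
  defaults <- list(pq_ms = NA_real_, qrs_ms = NA_real_, qt_ms = NA_real_,
                   tpte_ms = NA_real_, wide_qrs = 0L, p_associated = 1L,
                   label = "sinus", truth_label = "sinus")
  for (nm in names(defaults))
    if (is.null(beats[[nm]])) beats[[nm]] <- rep(defaults[[nm]], n)
  beats$beat_index <- seq_len(n)
  cols <- c("beat_index", "t_ms", "rr_ms", "pq_ms", "qrs_ms", "qt_ms",
            "tpte_ms", "wide_qrs", "p_associated", "label", "truth_label")
  beats <- beats[, cols]
  validate_beat_frame(beats)
  structure(beats,
            animal_id = animal_id, group = group,
            duration_min = duration_min,
            class = c("beat_series", "data.frame"))
}

validate_beat_frame <- function(beats) {
  if (nrow(beats) == 0L) return(invisible(beats))
  if (is.unsorted(beats$t_ms, strictly = TRUE))
    stop("t_ms must be strictly increasing", call. = FALSE)
  for (nm in c("rr_ms", "pq_ms", "qrs_ms", "qt_ms", "tpte_ms")) {
    v <- beats[[nm]]
    if (any(!is.na(v) & v <= 0))
      stop("interval column '", nm, "' has non-positive values",
           call. = FALSE)
  }
  bad <- !beats$label %in%
    c("sinus", "premature_ventricular", "escape_ventricular", "other")
  if (any(bad)) stop("unknown beat label(s): ",
                     paste(unique(beats$label[bad]), collapse = ", "),
                     call. = FALSE)
  invisible(beats)
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("Beat series: %d beats, %.1f min (animal %s, group %s)\n",
              nrow(x), attr(x, "duration_min"), attr(x, "animal_id"),
              attr(x, "group")))
  tab <- table(x$label)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read and write beat-series CSV files
#'
#' The on-disk schema is one row per beat with columns `beat_index`, `t_ms`,
#' `rr_ms`, `pq_ms`, `qrs_ms`, `qt_ms`, `tpte_ms`, `wide_qrs`,
#' `p_associated`, `label`, `truth_label`; recording metadata travel in
#' `animal_id`, `group` and `duration_min` columns (constant per file).
#'
#' @param series A `beat_series`.
#' @param path File path.
#' @return `read_beat_table()` returns a `beat_series`;
#'   `write_beat_table()` returns `path` invisibly.
#' @export
write_beat_table <- function(series, path) {
  df <- as.data.frame(series)
  df$animal_id <- attr(series, "animal_id")
  df$group <- attr(series, "group")
  df$duration_min <- attr(series, "duration_min")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beat_table
#' @export
read_beat_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- list(animal_id = df$animal_id[1], group = df$group[1],
               duration_min = df$duration_min[1])
  df$animal_id <- df$group <- df$duration_min <- NULL
  beat_series(df, animal_id = meta$animal_id, group = meta$group,
              duration_min = meta$duration_min)
}

#' Validate a beat-table CSV against its schema
#'
#' Checks column presence, strictly increasing `t_ms` (reporting the first
#' offending line), positive intervals, and flags a missing `qt_ms` column
#' as a warning (it only removes window eligibility) rather than a failure.
#'
#' @param path CSV file path.
#' @return List with elements `ok` (logical), `errors`, `warnings`
#'   (character vectors; errors carry data line numbers where applicable).
#' @export
validate_beat_table <- function(path) {
  errors <- character()
  warnings <- character()
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) e)
  if (inherits(df, "error"))
    return(list(ok = FALSE, errors = paste("unreadable file:",
                                           conditionMessage(df)),
                warnings = character()))
  required <- c("t_ms", "rr_ms")
  miss <- setdiff(required, names(df))
  if (length(miss))
    errors <- c(errors, paste("missing column(s):",
                              paste(miss, collapse = ", ")))
  if (!"qt_ms" %in% names(df))
    warnings <- c(warnings,
                  "no qt_ms column: series ineligible for QT windows")
  if ("t_ms" %in% names(df) && nrow(df) > 1) {
    bad <- which(diff(df$t_ms) <= 0)
    if (length(bad))
      errors <- c(errors, sprintf("t_ms not strictly increasing at line %d",
                                  bad[1] + 2L))  # +1 diff offset, +1 header
  }
  for (nm in intersect(c("rr_ms", "pq_ms", "qrs_ms", "qt_ms", "tpte_ms"),
                       names(df))) {
    bad <- which(!is.na(df[[nm]]) & df[[nm]] <= 0)
    if (length(bad))
      errors <- c(errors, sprintf("non-positive %s at line %d", nm,
                                  bad[1] + 1L))
  }
  list(ok = length(errors) == 0L, errors = errors, warnings = warnings)
}
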