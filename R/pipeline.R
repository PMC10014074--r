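#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> extract -> compare: simulates the cohort,
#' fits the pooled QT--RR correction on the baseline (week-0) beat
#' streams, computes per-animal windowed ECG metrics (interval means,
#' heart rate, QTc, rmsSD-RR, STV-QT), classifies and counts ventricular
#' ectopy over the resting recordings, extracts cellular APD90 / STV-APD /
#' transient-outward current density, derives the echo indices, and runs
#' the normality-gated TRN-vs-SED comparisons on every variable.
#' Identical config and seed give identical output.
#'
#' @param config A [cohort_config()].
#' @param window_start_min,window_n_beats Analysis window settings
#'   (defaults: 40 consecutive sinus beats at the 10th minute).
#' @param rr_ref_ms Reference RR for the correction (default 528).
#' @param params Classifier parameters, see [classifier_params()].
#' @param stv_qt_beats,stv_apd_beats Variability window sizes (40 and 30).
#' @param output_dir Optional directory; when given, the tables and a run
#'   manifest (seed, config hash) are written as CSV/JSON.
#' @return Object of class `"pipeline_result"`: `model` (the fitted
#'   `qtrr`), `ecg` (per-animal metrics), `arrhythmia` (per-animal counts
#'   and rates), `cells` (per-cell features), `echo` (derived panels),
#'   `comparisons` (group-stats table), `incidence` (escape-beat
#'   incidence), and `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(),
                         window_start_min = 10, window_n_beats = 40L,
                         rr_ref_ms = 528,
                         params = classifier_params(),
                         stv_qt_beats = 40L, stv_apd_beats = 30L,
                         output_dir = NULL) {
  cohort <- simulate_cohort(config)

  # pooled baseline QT-RR fit
  base_pairs <- do.call(rbind, lapply(cohort$animals, function(an)
    qt_rr_pairs(an$baseline)))
  model <- qtrr(base_pairs, rr_ref_ms = rr_ref_ms)

  # per-animal windowed ECG metrics on the first resting recording
  ecg_rows <- lapply(cohort$animals, function(an) {
    rec <- classify_beats(an$recordings[[1]], params)
    win <- tryCatch(select_analysis_window(rec, window_start_min,
                                           window_n_beats),
                    error = function(e) NULL)
    if (is.null(win))
      return(data.frame(animal_id = an$animal_id, group = an$group,
                        window_ok = FALSE))
    mi <- mean_intervals(win)
    pairs <- qt_rr_pairs(win)
    qtc <- correct_qt(pairs$qt_ms, pairs$rr_prev_ms, model)
    vr_rr <- variability_result(win, "rr_ms")
    vr_qt <- variability_result(win, "qt_ms")
    data.frame(animal_id = an$animal_id, group = an$group,
               window_ok = TRUE,
               rr_ms = mi$rr_ms, hr_bpm = mi$hr_bpm, pq_ms = mi$pq_ms,
               qrs_ms = mi$qrs_ms, qt_ms = mi$qt_ms, tpte_ms = mi$tpte_ms,
               qtc_ms = mean(qtc),
               rmssd_rr_ms = vr_rr$rmssd_ms, stv_qt_ms = vr_qt$stv_ms,
               stringsAsFactors = FALSE)
  })
  ecg <- do.call(rbind, ecg_rows)

  # per-animal arrhythmia counts over all resting recordings
  arr_rows <- lapply(cohort$animals, function(an) {
    recs <- lapply(an$recordings, classify_beats, params = params)
    ct <- count_and_rate(recs)
    data.frame(animal_id = an$animal_id, group = an$group,
               n_premature = ct$n_premature, n_escape = ct$n_escape,
               n_total_arrhythmic = ct$n_total_arrhythmic,
               duration_min = ct$duration_min,
               rate_premature_per_hr = ct$rate_premature_per_hr,
               rate_escape_per_hr = ct$rate_escape_per_hr,
               stringsAsFactors = FALSE)
  })
  arrhythmia <- do.call(rbind, arr_rows)
  esc_inc <- incidence(sed = arrhythmia$n_escape[arrhythmia$group == "SED"],
                       trn = arrhythmia$n_escape[arrhythmia$group == "TRN"])

  # cellular features
  cell_rows <- list()
  for (g in c("SED", "TRN")) {
    aps <- cohort$cells$ap[[g]]
    n_stv <- config$n_stv_cells[[g]]
    for (j in seq_along(aps)) {
      feats <- extract_ap_features(aps[[j]])
      inc <- feats$apd_ms[feats$included]
      stv_val <- if (j <= n_stv && length(inc) >= max(stv_apd_beats, 60L))
        stv_apd(inc, n_beats = stv_apd_beats) else NA_real_
      cell_rows[[length(cell_rows) + 1L]] <-
        data.frame(group = g, cell = sprintf("%s_ap%02d", g, j),
                   kind = "ap", apd90_ms = mean(inc),
                   stv_apd_ms = stv_val, ito_50_pApF = NA_real_,
                   stringsAsFactors = FALSE)
    }
    ivs <- cohort$cells$iv[[g]]
    for (j in seq_along(ivs)) {
      d50 <- current_density(
        ivs[[j]]$steps$i_pA[ivs[[j]]$steps$v_mV == 50],
        ivs[[j]]$capacitance_pF)
      cell_rows[[length(cell_rows) + 1L]] <-
        data.frame(group = g, cell = ivs[[j]]$cell_id, kind = "iv",
                   apd90_ms = NA_real_, stv_apd_ms = NA_real_,
                   ito_50_pApF = d50, stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cell_rows)

  # echo indices at week 16
  echo <- do.call(rbind, lapply(cohort$animals, function(an)
    derive_echo_panel(an$echo$week16)))

  # group comparisons (unpaired, TRN vs SED at week 16)
  tidy <- rbind(
    stats::reshape(ecg[ecg$window_ok,
                       c("animal_id", "group", "rr_ms", "hr_bpm", "qt_ms",
                         "qtc_ms", "stv_qt_ms", "rmssd_rr_ms")],
                   direction = "long",
                   varying = c("rr_ms", "hr_bpm", "qt_ms", "qtc_ms",
                               "stv_qt_ms", "rmssd_rr_ms"),
                   v.names = "value", timevar = "variable",
                   times = c("rr_ms", "hr_bpm", "qt_ms", "qtc_ms",
                             "stv_qt_ms", "rmssd_rr_ms"))[,
                     c("animal_id", "group", "variable", "value")],
    data.frame(animal_id = echo$animal_id, group = echo$group,
               variable = "lvmi_g_m2", value = echo$lvmi_g_m2),
    data.frame(animal_id = echo$animal_id, group = echo$group,
               variable = "ef_pct", value = echo$ef_pct),
    data.frame(animal_id = cells$cell[cells$kind == "ap"],
               group = cells$group[cells$kind == "ap"],
               variable = "apd90_ms",
               value = cells$apd90_ms[cells$kind == "ap"]),
    data.frame(animal_id = cells$cell[cells$kind == "iv"],
               group = cells$group[cells$kind == "iv"],
               variable = "ito_50_pApF",
               value = cells$ito_50_pApF[cells$kind == "iv"])
  )
  stv_cells <- cells[cells$kind == "ap" & !is.na(cells$stv_apd_ms), ]
  if (nrow(stv_cells))
    tidy <- rbind(tidy, data.frame(animal_id = stv_cells$cell,
                                   group = stv_cells$group,
                                   variable = "stv_apd_ms",
                                   value = stv_cells$stv_apd_ms))
  comparisons <- compare_table(tidy[!is.na(tidy$value), ])

  manifest <- list(seed = config$seed,
                   n_per_group = config$n_per_group,
                   config_hash = config_hash(config),
                   created = "run_pipeline")
  result <- structure(list(model = model, ecg = ecg,
                           arrhythmia = arrhythmia, cells = cells,
                           echo = echo, comparisons = comparisons,
                           incidence = esc_inc, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_result(result, output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  print(x$model)
  cat(sprintf("  %d animals with ECG metrics; escape incidence TRN %.0f%%, SED %.0f%%\n",
              nrow(x$ecg), 100 * x$incidence$proportions["TRN"],
              100 * x$incidence$proportions["SED"]))
  cat("  group comparisons:\n")
  print(x$comparisons[, c("variable", "mean_sed", "mean_trn", "test_used",
                          "p_value", "significant")], digits = 4)
  invisible(x)
}

# stable hash of the configuration (content-based, no external deps)
config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(js, tmp)
  unname(tools::md5sum(tmp))
}

#' Write the pipeline result bundle
#'
#' Writes the per-animal metrics, arrhythmia, cell, echo and comparison
#' tables as CSV plus a JSON run manifest into `dir`.
#'
#' @param result A `"pipeline_result"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$ecg, file.path(dir, "ecg_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$arrhythmia, file.path(dir, "arrhythmia.csv"),
                   row.names = FALSE)
  utils::write.csv(result$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(result$echo, file.path(dir, "echo_derived.csv"),
                   row.names = FALSE)
  utils::write.csv(result$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Validate every beat-table CSV under a path
#'
#' Walks `path` (a directory or a single file) and checks each beat-table
#' CSV (files whose name contains `"beats"`, or any single CSV given
#' directly) against the schema via [validate_beat_table()].
#'
#' @param path Directory or CSV file.
#' @return Data frame: `file`, `ok`, `message` (first error or warning).
#' @export
validate_inputs <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  files <- if (dir.exists(path))
    list.files(path, pattern = "beats.*\\.csv$", full.names = TRUE)
  else path
  if (!length(files)) stop("no beat-table CSVs found under ", path)
  rows <- lapply(files, function(f) {
    rep <- validate_beat_table(f)
    msg <- if (length(rep$errors)) rep$errors[1]
    else if (length(rep$warnings)) rep$warnings[1] else ""
    data.frame(file = basename(f), ok = rep$ok, message = msg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
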