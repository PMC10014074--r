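#' Generate a sinus beat stream
#'
#' RR intervals follow a stationary first-order autoregressive Gaussian
#' process with configurable mean, stationary SD and lag-1 autocorrelation
#' (a coarse stand-in for respiratory sinus arrhythmia), floored at 200 ms.
#' QT of beat x is generated from the PRECEDING RR,
#' `QT_x = a * RR_(x-1) + b + eps_x` with i.i.d. Gaussian noise, so that the
#' rearranged rate correction has an exactly zero QTc-vs-RR slope when the
#' noise SD is zero.  (The first beat, which has no predecessor, uses its
#' own RR.)  PQ, QRS and TpTe are i.i.d. Gaussian around group means.  All
#' beats are labelled sinus.
#'
#' @param duration_min Recording length in minutes (> 0).
#' @param group `"SED"` or `"TRN"` (used for defaults and metadata).
#' @param timepoint `"week16"` or `"week0"` (selects default parameters).
#' @param params Generating parameters, see [ecg_defaults()]; individual
#'   entries may be overridden via `...`.
#' @param seed Optional integer seed for this stream; `NULL` uses the
#'   current RNG state.
#' @param animal_id Metadata carried on the returned series.
#' @param ... Named overrides of entries in `params` (e.g. `qt_noise_sd = 0`).
#' @return A [beat_series()].
#' @export
generate_beat_stream <- function(duration_min,
                                 group = c("SED", "TRN"),
                                 timepoint = c("week16", "week0"),
                                 params = NULL, seed = NULL,
                                 animal_id = NA_character_, ...) {
  group <- match.arg(group)
  timepoint <- match.arg(timepoint)
  if (!is.numeric(duration_min) || duration_min <= 0)
    stop("duration_min must be > 0")
  if (is.null(params)) params <- ecg_defaults(group, timepoint)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(params))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    params[names(over)] <- over
  }
  p <- params
  if (p$rr_mean_ms <= 0) stop("rr_mean_ms must be > 0")
  if (p$rr_sd_ms < 0 || p$qt_noise_sd < 0) stop("SDs must be >= 0")
  if (p$rr_autocorr < 0 || p$rr_autocorr >= 1)
    stop("rr_autocorr must lie in [0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))

  duration_ms <- duration_min * 60000
  n_max <- ceiling(1.3 * duration_ms / p$rr_mean_ms) + 50L
  rho <- p$rr_autocorr
  innov_sd <- p$rr_sd_ms * sqrt(1 - rho^2)
  e <- stats::rnorm(n_max, 0, innov_sd)
  rr <- numeric(n_max)
  rr[1] <- stats::rnorm(1, p$rr_mean_ms, p$rr_sd_ms)
  if (n_max > 1)
    rr[-1] <- p$rr_mean_ms +
      as.numeric(stats::filter(e[-1], rho, method = "recursive",
                               init = rr[1] - p$rr_mean_ms))
  rr <- pmax(rr, 200 + 1e-9)
  t_ms <- cumsum(rr)
  keep <- t_ms <= duration_ms
  if (!any(keep)) keep[1] <- TRUE
  rr <- rr[keep]; t_ms <- t_ms[keep]
  n <- length(rr)

  rr_prev <- c(rr[1], rr[-n])
  qt <- p$qt_slope * rr_prev + p$qt_intercept +
    stats::rnorm(n, 0, p$qt_noise_sd)
  beats <- data.frame(
    t_ms = t_ms, rr_ms = rr,
    pq_ms = stats::rnorm(n, p$pq_mean_ms, p$pq_sd_ms),
    qrs_ms = stats::rnorm(n, p$qrs_mean_ms, p$qrs_sd_ms),
    qt_ms = qt,
    tpte_ms = stats::rnorm(n, p$tpte_mean_ms, p$tpte_sd_ms)
  )
  beat_series(beats, animal_id = animal_id, group = group,
              duration_min = duration_min)
}

#' Inject ventricular ectopy into a sinus beat stream
#'
#' Escape and premature events are drawn from independent homogeneous
#' Poisson processes over the recording.  An escape event replaces the next
#' sinus beat with a pause of `pause_factor` times the prevailing RR
#' followed by a wide-QRS beat without an associated P wave.  A premature
#' event inserts a wide-QRS, non-P beat at `coupling_factor` times the
#' prevailing RR before the next sinus beat, whose own RR is stretched to
#' the compensatory value `(2 - coupling_factor)` times the prevailing RR.
#' The prevailing RR is the median of up to the last 10 sinus RRs.  Ground
#' truth is stored in `truth_label` (and mirrored into `label`).
#'
#' @param series A [beat_series()] of sinus beats.
#' @param escape_rate_per_hr,premature_rate_per_hr Poisson rates (>= 0).
#' @param pause_factor,coupling_factor Event geometry relative to the
#'   prevailing RR; defaults 1.8 and 0.6.
#' @param seed Optional integer seed.
#' @return A [beat_series()] with ectopic beats and refreshed time stamps.
#' @export
inject_ectopy <- function(series, escape_rate_per_hr, premature_rate_per_hr,
                          pause_factor = 1.8, coupling_factor = 0.6,
                          seed = NULL) {
  stopifnot(inherits(series, "beat_series"))
  if (escape_rate_per_hr < 0 || premature_rate_per_hr < 0)
    stop("ectopy rates must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (escape_rate_per_hr == 0 && premature_rate_per_hr == 0) return(series)

  duration_min <- attr(series, "duration_min")
  duration_ms <- duration_min * 60000
  hours <- duration_min / 60
  df <- as.data.frame(series)
  n0 <- nrow(df)

  draw_times <- function(rate) {
    k <- stats::rpois(1, rate * hours)
    sort(stats::runif(k, 0, duration_ms))
  }
  esc_t <- draw_times(escape_rate_per_hr)
  pre_t <- draw_times(premature_rate_per_hr)

  prevailing_before <- function(df, idx) {
    prior <- which(df$truth_label[seq_len(idx - 1L)] == "sinus")
    if (!length(prior)) return(df$rr_ms[idx])
    stats::median(df$rr_ms[utils::tail(prior, 10L)])
  }

  # escapes: modify the next sinus beat in place
  for (tt in esc_t) {
    idx <- which(df$t_ms > tt & df$truth_label == "sinus")
    idx <- idx[idx > 1L]
    if (!length(idx)) next
    i <- idx[1]
    prev_rr <- prevailing_before(df, i)
    df$rr_ms[i] <- pause_factor * prev_rr
    df$wide_qrs[i] <- 1L
    df$p_associated[i] <- 0L
    df$pq_ms[i] <- NA_real_
    df$qrs_ms[i] <- 1.6 * df$qrs_ms[i]
    df$qt_ms[i] <- NA_real_
    df$tpte_ms[i] <- NA_real_
    df$truth_label[i] <- "escape_ventricular"
  }

  # prematures: insert before the next sinus beat, stretch that beat's RR
  inserts <- list()
  for (tt in pre_t) {
    idx <- which(df$t_ms > tt & df$truth_label == "sinus")
    idx <- idx[idx > 1L & idx < nrow(df)]
    if (!length(idx)) next
    i <- idx[1]
    prev_rr <- prevailing_before(df, i)
    new <- df[i, ]
    new$rr_ms <- coupling_factor * prev_rr
    new$wide_qrs <- 1L
    new$p_associated <- 0L
    new$pq_ms <- NA_real_
    new$qrs_ms <- 1.6 * df$qrs_ms[i]
    new$qt_ms <- NA_real_
    new$tpte_ms <- NA_real_
    new$truth_label <- "premature_ventricular"
    df$rr_ms[i] <- (2 - coupling_factor) * prev_rr  # compensatory pause
    inserts[[length(inserts) + 1L]] <- list(before = i, row = new)
  }
  if (length(inserts)) {
    pos <- vapply(inserts, function(x) x$before, numeric(1))
    rows <- do.call(rbind, lapply(inserts, function(x) x$row))
    df$.ord <- seq_len(nrow(df))
    rows$.ord <- pos - 0.5
    df <- rbind(df, rows)
    df <- df[order(df$.ord), ]
    df$.ord <- NULL
  }

  df$t_ms <- cumsum(df$rr_ms)
  df$label <- df$truth_label
  df$beat_index <- seq_len(nrow(df))
  rownames(df) <- NULL
  out <- beat_series(df, animal_id = attr(series, "animal_id"),
                     group = attr(series, "group"),
                     duration_min = duration_min)
  stopifnot(nrow(out) == n0 + sum(out$truth_label == "premature_ventricular"))
  out
}

#' Generate a paced action-potential train
#'
#' Builds a parametric membrane-voltage waveform for `n_beats` beats paced
#' at a fixed cycle length: a 1 ms linear upstroke from the resting level to
#' the peak, then a logistic (plateau plus sigmoidal repolarization) decay
#' whose 90%-repolarization crossing falls exactly at the constructed APD90
#' for that beat.  Per-beat APD90 is `cell_mean + jitter`, where the cell
#' mean is drawn from the between-cell Gaussian (rejection-truncated to
#' [100, 820] ms so every beat repolarizes within the cycle) and jitter is
#' i.i.d. Gaussian.  The constructed APD90, measured from the upstroke, is
#' recorded per beat as ground truth.
#'
#' @param n_beats Number of paced beats (>= 1).
#' @param group `"SED"` or `"TRN"`; sets defaults from [cohort_config()]
#'   when `apd90_mean_ms` etc. are not given.
#' @param apd90_mean_ms,between_cell_sd_ms,jitter_sd_ms Generating
#'   parameters (ms); defaults follow the group.
#' @param cell_mean_ms Optional fixed cell mean (skips the between-cell
#'   draw).
#' @param cycle_length_ms Pacing cycle length (default 1000 ms, i.e. 1 Hz).
#' @param dt_ms Sampling interval (<= 1 ms).
#' @param rest_mV,peak_mV Resting and peak membrane potentials.
#' @param seed Optional integer seed.
#' @return Object of class `"ap_trace"`: `t_ms`, `v_mV`,
#'   `stimulus_times_ms`, `cycle_length_ms`, `dt_ms`, `source`, and a
#'   `truth` data frame (`beat`, `apd90_ms`, `cell_mean_ms`).
#' @export
generate_ap_train <- function(n_beats = 60L, group = c("TRN", "SED"),
                              apd90_mean_ms = NULL,
                              between_cell_sd_ms = NULL,
                              jitter_sd_ms = NULL,
                              cell_mean_ms = NULL,
                              cycle_length_ms = 1000, dt_ms = 1,
                              rest_mV = -85, peak_mV = 25,
                              seed = NULL, source = "isolated_myocyte") {
  group <- match.arg(group)
  if (n_beats < 1) stop("n_beats must be >= 1")
  if (dt_ms > 1) stop("sampling interval must be <= 1 ms")
  defaults <- cohort_config()
  if (is.null(apd90_mean_ms)) apd90_mean_ms <- defaults$apd90_mean_ms[[group]]
  if (is.null(between_cell_sd_ms))
    between_cell_sd_ms <- defaults$apd90_between_cell_sd_ms[[group]]
  if (is.null(jitter_sd_ms)) jitter_sd_ms <- defaults$apd_jitter_sd_ms[[group]]
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (is.null(cell_mean_ms)) {
    for (try in seq_len(100L)) {
      cell_mean_ms <- stats::rnorm(1, apd90_mean_ms, between_cell_sd_ms)
      if (cell_mean_ms >= 100 && cell_mean_ms <= 820) break
      if (try == 100L) stop("could not draw a feasible cell-mean APD90")
    }
  }
  apd <- cell_mean_ms + stats::rnorm(n_beats, 0, jitter_sd_ms)
  apd <- pmin(pmax(apd, 60), cycle_length_ms - 150)

  lead_in <- 50
  stim <- lead_in + (seq_len(n_beats) - 1) * cycle_length_ms
  total_ms <- lead_in + n_beats * cycle_length_ms
  t <- seq(0, total_ms - dt_ms, by = dt_ms)
  amp <- peak_mV - rest_mV

  beat_of <- pmin(pmax(floor((t - lead_in) / cycle_length_ms) + 1L, 0L),
                  n_beats)
  v <- rep(rest_mV, length(t))
  active <- beat_of >= 1L
  tloc <- t[active] - stim[beat_of[active]]
  tau <- apd[beat_of[active]] / 12
  ctr <- apd[beat_of[active]] - tau * log(9)
  upstroke <- pmin(pmax(tloc, 0), 1)
  sig <- 1 / (1 + exp((tloc - ctr) / tau))
  v[active] <- rest_mV + amp * pmin(upstroke, sig)

  structure(list(t_ms = t, v_mV = v, stimulus_times_ms = stim,
                 cycle_length_ms = cycle_length_ms, dt_ms = dt_ms,
                 source = source,
                 truth = data.frame(beat = seq_len(n_beats),
                                    apd90_ms = apd,
                                    cell_mean_ms = cell_mean_ms)),
            class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf(
    "AP trace: %d beats at CL %.0f ms, dt %.2g ms, source %s\n",
    length(x$stimulus_times_ms), x$cycle_length_ms, x$dt_ms, x$source))
  cat(sprintf("  constructed APD90: mean %.1f ms (cell mean %.1f ms)\n",
              mean(x$truth$apd90_ms), x$truth$cell_mean_ms[1]))
  invisible(x)
}

#' Generate a voltage-clamp step record for the transient outward current
#'
#' Capacitance is Gaussian truncated at zero.  The per-cell density at the
#' +50 mV step is Gaussian around the group mean; other steps scale by a
#' monotone activation curve that is zero at and below the activation
#' threshold and one at +50 mV.  Peak current at each step is
#' `density(V) * capacitance` plus Gaussian measurement noise.
#'
#' @param group `"SED"` or `"TRN"`; sets density defaults.
#' @param density_mean,density_sd Density at +50 mV (pA/pF); defaults follow
#'   the group.
#' @param density_50_pApF Optional fixed per-cell density (skips the draw).
#' @param capacitance_mean_pF,capacitance_sd_pF Capacitance draw.
#' @param capacitance_pF Optional fixed capacitance.
#' @param voltages Step-voltage grid (mV).
#' @param activation_threshold_mV Voltage at and below which density is 0.
#' @param noise_sd_pA Measurement noise SD (pA).
#' @param cell_id Identifier carried on the record.
#' @param seed Optional integer seed.
#' @return Object of class `"iv_record"`: `cell_id`, `capacitance_pF`,
#'   `steps` (data frame `v_mV`, `i_pA`), `protocol`, and the generating
#'   `density_50_pApF`.
#' @export
generate_iv_record <- function(group = c("TRN", "SED"),
                               density_mean = NULL, density_sd = NULL,
                               density_50_pApF = NULL,
                               capacitance_mean_pF = 125,
                               capacitance_sd_pF = 20,
                               capacitance_pF = NULL,
                               voltages = seq(-30, 50, by = 10),
                               activation_threshold_mV = -20,
                               noise_sd_pA = 25,
                               cell_id = NA_character_, seed = NULL) {
  group <- match.arg(group)
  defaults <- cohort_config()
  if (is.null(density_mean)) density_mean <- defaults$ito_density_mean[[group]]
  if (is.null(density_sd)) density_sd <- defaults$ito_density_sd[[group]]
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(capacitance_pF)) {
    for (try in seq_len(100L)) {
      capacitance_pF <- stats::rnorm(1, capacitance_mean_pF,
                                     capacitance_sd_pF)
      if (capacitance_pF > 0) break
      if (try == 100L) stop("could not draw a positive capacitance")
    }
  }
  if (is.null(density_50_pApF))
    density_50_pApF <- stats::rnorm(1, density_mean, density_sd)
  act <- ito_activation(voltages, activation_threshold_mV)
  i_pA <- density_50_pApF * act * capacitance_pF +
    stats::rnorm(length(voltages), 0, noise_sd_pA)
  structure(list(cell_id = cell_id, capacitance_pF = capacitance_pF,
                 steps = data.frame(v_mV = voltages, i_pA = i_pA),
                 protocol = "Ito", density_50_pApF = density_50_pApF),
            class = "iv_record")
}

# Normalized monotone activation: 0 at/below threshold, 1 at +50 mV.
ito_activation <- function(v, threshold_mV = -20, k = 15) {
  num <- 1 - exp(-(v - threshold_mV) / k)
  den <- 1 - exp(-(50 - threshold_mV) / k)
  pmax(num, 0) / den
}

#' Generate a raw echocardiographic panel
#'
#' Raw linear measurements are Gaussian around the group/timepoint means
#' with SD = SEM * sqrt(n) from the reference table; a draw with
#' LVEDD <= LVESD is rejected and redrawn (at most 100 tries).  Body weight
#' is uniform on the configured range.  Derived indices are left `NA` for
#' [derive_echo_panel()].
#'
#' @param group,timepoint Panel cell of the reference table.
#' @param echo_means Reference table, see [echo_reference_means()].
#' @param bw_range_kg Body-weight range (kg).
#' @param animal_id Identifier.
#' @param seed Optional integer seed.
#' @return One-row data frame of class `"echo_panel"` with raw fields
#'   `ivs_mm`, `lvpw_mm`, `lvesd_mm`, `lvedd_mm`, `lav_ml`, `bw_kg`.
#' @export
generate_echo_panel <- function(group = c("SED", "TRN"),
                                timepoint = c("week16", "week0"),
                                echo_means = echo_reference_means(),
                                bw_range_kg = c(9, 15),
                                animal_id = NA_character_, seed = NULL) {
  group <- match.arg(group)
  timepoint <- match.arg(timepoint)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ref <- echo_means[echo_means$group == group &
                      echo_means$timepoint == timepoint, ]
  if (!nrow(ref)) stop("no reference means for ", group, "/", timepoint)
  draw_one <- function(variable) {
    row <- ref[ref$variable == variable, ]
    stats::rnorm(1, row$mean, row$sem * sqrt(row$n))
  }
  for (try in seq_len(100L)) {
    vals <- vapply(c("ivs_mm", "lvpw_mm", "lvesd_mm", "lvedd_mm", "lav_ml"),
                   draw_one, numeric(1))
    ok <- all(vals > 0) && vals["lvedd_mm"] > vals["lvesd_mm"]
    if (ok) break
    if (try == 100L) stop("could not draw a valid echo panel in 100 tries")
  }
  panel <- data.frame(animal_id = animal_id, group = group,
                      timepoint = timepoint,
                      ivs_mm = vals[["ivs_mm"]], lvpw_mm = vals[["lvpw_mm"]],
                      lvesd_mm = vals[["lvesd_mm"]],
                      lvedd_mm = vals[["lvedd_mm"]],
                      lav_ml = vals[["lav_ml"]],
                      bw_kg = stats::runif(1, bw_range_kg[1], bw_range_kg[2]),
                      stringsAsFactors = FALSE)
  class(panel) <- c("echo_panel", "data.frame")
  panel
}

#' Simulate the full two-group virtual cohort
#'
#' Per animal (seed = master seed + animal index): a baseline (week-0) beat
#' stream, `n_recordings` week-16 resting recordings with ectopy injected at
#' the group rates, and echo panels at both timepoints.  Per group, pooled
#' cell-level records: AP trains (>= 60 beats each) and voltage-clamp
#' records, with their own derived seed blocks so the cohort is extensible
#' without reshuffling.
#'
#' @param config A [cohort_config()].
#' @param include Character subset of `c("ecg", "cells", "echo")` to
#'   generate.
#' @return Object of class `"virtual_cohort"`: `config`, `animals` (list:
#'   `animal_id`, `group`, `bw_kg`, `baseline`, `recordings`, `echo`), and
#'   `cells` (`ap` and `iv` lists by group).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            include = c("ecg", "cells", "echo")) {
  validate_cohort_config(config)
  include <- match.arg(include, several.ok = TRUE)
  groups <- rep(c("SED", "TRN"), each = config$n_per_group)
  animals <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    id <- sprintf("%s%02d", g, ((i - 1L) %% config$n_per_group) + 1L)
    set.seed(config$seed + i)
    an <- list(animal_id = id, group = g)
    if ("ecg" %in% include) {
      an$baseline <- generate_beat_stream(config$recording_duration_min,
                                          group = g, timepoint = "week0",
                                          animal_id = id)
      an$recordings <- lapply(seq_len(config$n_recordings), function(r) {
        s <- generate_beat_stream(config$recording_duration_min, group = g,
                                  timepoint = "week16", animal_id = id)
        inject_ectopy(s, config$escape_rate_per_hr[[g]],
                      config$premature_rate_per_hr[[g]],
                      pause_factor = config$pause_factor,
                      coupling_factor = config$coupling_factor)
      })
    }
    if ("echo" %in% include) {
      an$echo <- list(
        week0 = generate_echo_panel(g, "week0", config$echo_means,
                                    config$bw_range_kg, animal_id = id),
        week16 = generate_echo_panel(g, "week16", config$echo_means,
                                     config$bw_range_kg, animal_id = id))
      an$bw_kg <- an$echo$week16$bw_kg
    }
    animals[[i]] <- an
  }
  cells <- NULL
  if ("cells" %in% include) {
    make_cells <- function(gen, counts, seed_base) {
      offset <- 0L
      out <- list()
      for (g in c("SED", "TRN")) {
        n <- counts[[g]]
        out[[g]] <- lapply(seq_len(n), function(j)
          gen(g, config$seed + seed_base + offset + j))
        offset <- offset + n
      }
      out
    }
    cells <- list(
      ap = make_cells(function(g, s)
        generate_ap_train(60L, group = g,
                          apd90_mean_ms = config$apd90_mean_ms[[g]],
                          between_cell_sd_ms =
                            config$apd90_between_cell_sd_ms[[g]],
                          jitter_sd_ms = config$apd_jitter_sd_ms[[g]],
                          seed = s),
        config$n_ap_cells, 100000L),
      iv = make_cells(function(g, s)
        generate_iv_record(group = g,
                           density_mean = config$ito_density_mean[[g]],
                           density_sd = config$ito_density_sd[[g]],
                           capacitance_mean_pF = config$capacitance_mean_pF,
                           capacitance_sd_pF = config$capacitance_sd_pF,
                           noise_sd_pA = config$iv_noise_sd_pA,
                           cell_id = sprintf("%s_iv%03d", g, s), seed = s),
        config$n_iv_cells, 200000L)
    )
  }
  structure(list(config = config, animals = animals, cells = cells),
            class = "virtual_cohort")
}

#' @export
print.virtual_cohort <- function(x, ...) {
  cat(sprintf("Virtual cohort: %d animals (%d per group), seed %d\n",
              length(x$animals), x$config$n_per_group, x$config$seed))
  if (!is.null(x$cells))
    cat(sprintf("  cells: AP %d SED / %d TRN; IV %d SED / %d TRN\n",
                length(x$cells$ap$SED), length(x$cells$ap$TRN),
                length(x$cells$iv$SED), length(x$cells$iv$TRN)))
  invisible(x)
}
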