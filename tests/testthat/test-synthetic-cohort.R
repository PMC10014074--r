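test_that("noise-free beat streams lie exactly on the generating QT-RR line", {
  s <- generate_beat_stream(10, "TRN", "week0", seed = 1, qt_noise_sd = 0)
  p <- qt_rr_pairs(s)
  expect_equal(p$qt_ms, 0.045 * p$rr_prev_ms + 187, tolerance = 1e-12)
  expect_true(all(s$label == "sinus"))
  # time stamps consistent with RR
  expect_equal(diff(s$t_ms), s$rr_ms[-1], tolerance = 1e-9)
})

test_that("generated RR means and OLS-recovered QT-RR coefficients match the configuration", {
  s <- generate_beat_stream(20, "TRN", "week16", seed = 7)
  sem <- sd(s$rr_ms) / sqrt(nrow(s))
  # AR(1) inflates the SE of the mean by ~sqrt((1+rho)/(1-rho)) = 3
  expect_lt(abs(mean(s$rr_ms) - 841.8), 3 * 3 * sem)

  # slope/intercept recovery on 10,000 noisy beats, vs the independent oracle
  long <- generate_beat_stream(200, "SED", "week0", seed = 3,
                               qt_noise_sd = 5, rr_sd_ms = 40)
  p <- qt_rr_pairs(long)[1:10000, ]
  fit <- qtrr(p)
  orc <- ols_oracle(p$rr_prev_ms, p$qt_ms)
  expect_equal(unname(coef(fit)), unname(orc), tolerance = 1e-10)
  expect_lt(abs(fit$slope_a - 0.045), 3 * fit$se_slope)
  expect_lt(abs(fit$intercept_b - 187), 3 * fit$se_intercept)
})

test_that("ectopy injection is conservative, labelled, and Poisson-calibrated", {
  s <- generate_beat_stream(20, "TRN", "week16", seed = 2)
  expect_identical(inject_ectopy(s, 0, 0), s)

  # premature events insert beats; escapes replace them
  e <- inject_ectopy(s, 10, 6, seed = 5)
  n_pre <- sum(e$truth_label == "premature_ventricular")
  expect_equal(nrow(e), nrow(s) + n_pre)
  expect_true(all(e$wide_qrs[e$truth_label != "sinus"] == 1L))
  expect_true(all(e$p_associated[e$truth_label != "sinus"] == 0L))
  expect_equal(diff(e$t_ms), e$rr_ms[-1], tolerance = 1e-9)

  # mean injected premature count over many seeds ~ Poisson mean (6/hr x 1hr)
  counts <- vapply(1:40, function(sd) {
    s1 <- generate_beat_stream(60, "SED", "week16", seed = 100 + sd)
    e1 <- inject_ectopy(s1, 0, 6, seed = 200 + sd)
    sum(e1$truth_label == "premature_ventricular")
  }, numeric(1))
  expect_lt(abs(mean(counts) - 6), 3 * sd(counts) / sqrt(length(counts)))

  expect_error(inject_ectopy(s, -1, 0), "rates")
})

test_that("AP trains carry their constructed APD90 and honour pacing geometry", {
  tr <- generate_ap_train(10, cell_mean_ms = 300, jitter_sd_ms = 0, seed = 1)
  f <- extract_ap_features(tr)
  expect_true(all(f$included))
  expect_true(all(abs(f$apd_ms - 300) <= 1))  # within one sample
  expect_equal(length(tr$stimulus_times_ms), 10L)
  expect_equal(diff(tr$stimulus_times_ms), rep(1000, 9))
  expect_error(generate_ap_train(0), "n_beats")
})

test_that("IV records scale density by capacitance and vanish below threshold", {
  iv <- generate_iv_record(capacitance_pF = 125, density_50_pApF = 6.4,
                           noise_sd_pA = 0)
  expect_equal(iv$steps$i_pA[iv$steps$v_mV == 50], 800)
  expect_equal(iv$steps$i_pA[iv$steps$v_mV <= -20], c(0, 0))
  # monotone activation
  expect_true(all(diff(iv$steps$i_pA) >= 0))
})

test_that("echo panels follow the reference means and reject LVEDD <= LVESD", {
  panels <- do.call(rbind, lapply(1:12, function(j)
    generate_echo_panel("TRN", "week16", seed = j)))
  ref <- echo_reference_means()
  ivs_ref <- ref[ref$group == "TRN" & ref$timepoint == "week16" &
                   ref$variable == "ivs_mm", ]
  sem <- sd(panels$ivs_mm) / sqrt(nrow(panels))
  expect_lt(abs(mean(panels$ivs_mm) - ivs_ref$mean), 3 * sem + 3 * ivs_ref$sem)
  expect_true(all(panels$lvedd_mm > panels$lvesd_mm))

  # SD = 0 collapses every panel onto the group mean vector
  zero <- echo_reference_means()
  zero$sem <- 0
  p1 <- generate_echo_panel("SED", "week16", echo_means = zero, seed = 1)
  p2 <- generate_echo_panel("SED", "week16", echo_means = zero, seed = 2)
  expect_equal(p1[, c("ivs_mm", "lvpw_mm", "lvesd_mm", "lvedd_mm", "lav_ml")],
               p2[, c("ivs_mm", "lvpw_mm", "lvesd_mm", "lvedd_mm", "lav_ml")])
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- cohort_config(n_per_group = 2, seed = 9,
                       n_ap_cells = c(SED = 2L, TRN = 2L),
                       n_stv_cells = c(SED = 2L, TRN = 2L),
                       n_iv_cells = c(SED = 2L, TRN = 2L),
                       recording_duration_min = 5, n_recordings = 1L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$animals, b$animals)
  expect_identical(a$cells, b$cells)
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(rr_autocorr = 1), "rr_autocorr")
  expect_error(cohort_config(escape_rate_per_hr = c(SED = -1, TRN = 0)),
               "rates")
  expect_error(cohort_config(coupling_factor = 1.2), "coupling_factor")
  expect_error(generate_beat_stream(0), "duration_min")
})
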