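test_that("inclusion rules fire on depolarized RMP and low amplitude", {
  dep <- generate_ap_train(3, cell_mean_ms = 300, jitter_sd_ms = 0,
                           rest_mV = -65, seed = 1)
  f <- extract_ap_features(dep)
  expect_true(all(!f$included))
  expect_true(all(f$exclusion_reason == "RMP"))

  low <- generate_ap_train(3, cell_mean_ms = 300, jitter_sd_ms = 0,
                           rest_mV = -85, peak_mV = 0, seed = 1)
  f2 <- extract_ap_features(low)
  expect_true(all(f2$exclusion_reason == "amplitude"))
  expect_true(all(f2$amplitude_mV < 90))

  # excluded beats never enter STV or means
  expect_error(stv_apd(f, min_recorded = 3), "recorded beats")
})

test_that("APD is monotone in the repolarization fraction and tracks ground truth", {
  tr <- generate_ap_train(10, group = "TRN", seed = 6)
  f50 <- extract_ap_features(tr, repol_fraction = 0.5)
  f90 <- extract_ap_features(tr, repol_fraction = 0.9)
  expect_true(all(f50$apd_ms <= f90$apd_ms))
  # within one sampling interval of the constructed APD90
  expect_true(all(abs(f90$apd_ms - tr$truth$apd90_ms) <= tr$dt_ms))
})

test_that("a beat that never recrosses the level is unmeasurable, not wrong", {
  tr <- generate_ap_train(1, cell_mean_ms = 300, jitter_sd_ms = 0, seed = 1)
  # clamp the trace at plateau level after the upstroke: never recrosses
  tr$v_mV[tr$t_ms >= tr$stimulus_times_ms[1] + 5] <- 20
  f <- extract_ap_features(tr)
  expect_false(f$included[1])
  expect_equal(f$exclusion_reason[1], "no_crossing_before_next_stimulus")
})

test_that("STV-APD uses the last 30 of at least 60 recorded beats", {
  expect_equal(stv_apd(rep(300, 60)), 0)
  expect_error(stv_apd(rep(300, 40)), "need >= 60")
  expect_equal(stv_apd(c(rnorm(30, 500, 50), rep(300, 15), rep(310, 15))),
               stv(c(rep(300, 15), rep(310, 15))))

  # i.i.d. jitter sigma: E[STV] = sigma*sqrt(2/pi) (Monte-Carlo)
  set.seed(8)
  sims <- replicate(300, stv_apd(rnorm(60, 400, 36.97)))
  expect_lt(abs(mean(sims) - 36.97 * sqrt(2 / pi)),
            3 * sd(sims) / sqrt(length(sims)))
})

test_that("current density and I-V assembly are capacitance-exact", {
  expect_equal(current_density(800, 125), 6.4)
  expect_equal(current_density(1100, 125), 8.8)
  expect_equal(current_density(0, 125), 0)
  expect_error(current_density(100, 0), "> 0")

  recs <- lapply(1:6, function(j)
    generate_iv_record("TRN", capacitance_pF = 100 + 10 * j,
                       density_50_pApF = 5 + j, noise_sd_pA = 0))
  agg <- assemble_iv(recs, voltage = 50)
  # per-cell averaging oracle
  dens <- vapply(recs, function(r)
    r$steps$i_pA[r$steps$v_mV == 50] / r$capacitance_pF, numeric(1))
  expect_equal(agg$mean_pApF, mean(dens), tolerance = 1e-12)
  expect_equal(agg$sem_pApF, sd(dens) / sqrt(6), tolerance = 1e-12)
  expect_equal(agg$n, 6L)

  # mean density differs from pooled mean(current)/mean(capacitance)
  # unless capacitance is constant
  pooled <- mean(vapply(recs, function(r)
    r$steps$i_pA[r$steps$v_mV == 50], numeric(1))) /
    mean(vapply(recs, function(r) r$capacitance_pF, numeric(1)))
  expect_false(isTRUE(all.equal(agg$mean_pApF, pooled)))
  same_c <- lapply(1:4, function(j)
    generate_iv_record("TRN", capacitance_pF = 120,
                       density_50_pApF = 5 + j, noise_sd_pA = 0))
  agg_c <- assemble_iv(same_c, voltage = 50)
  pooled_c <- mean(vapply(same_c, function(r)
    r$steps$i_pA[r$steps$v_mV == 50], numeric(1))) / 120
  expect_equal(agg_c$mean_pApF, pooled_c, tolerance = 1e-12)

  expect_error(assemble_iv(recs[1]), "SEM undefined")
  expect_error(assemble_iv(recs, voltage = 55), "protocol grid")
})
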