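test_that("analysis window starts at the requested minute and restarts after ectopy", {
  s <- constant_series(3000, rr = 600)
  w <- select_analysis_window(s, 10, 40)
  expect_equal(nrow(w), 40L)
  expect_true(all(w$t_ms >= 600000))

  # an escape beat 20 beats into the eligible region restarts the run
  df <- as.data.frame(s)
  first_eligible <- which(df$t_ms >= 600000)[1]
  k <- first_eligible + 19L
  df$label[k] <- "escape_ventricular"
  s2 <- beat_series(df)
  w2 <- select_analysis_window(s2, 10, 40)
  expect_true(min(w2$t_ms) > df$t_ms[k])

  expect_error(select_analysis_window(constant_series(30), 0, 40),
               "longest run: 30")
})

test_that("window selection is deterministic and idempotent", {
  s <- generate_beat_stream(20, "TRN", "week16", seed = 4)
  w1 <- select_analysis_window(s, 10, 40)
  w2 <- select_analysis_window(s, 10, 40)
  expect_identical(as.data.frame(w1), as.data.frame(w2))
  # re-windowing a window returns it unchanged
  w3 <- select_analysis_window(w1, 0, 40)
  expect_equal(w3$rr_ms, w1$rr_ms)
})

test_that("interval means and heart rate follow the mean-RR definition", {
  w <- constant_series(40, rr = 841.8)
  mi <- mean_intervals(w)
  expect_equal(mi$hr_bpm, 60000 / 841.8, tolerance = 1e-12)
  expect_equal(round(mi$hr_bpm, 1), 71.3)
  expect_equal(mean_intervals(constant_series(10, rr = 500))$hr_bpm, 120)
  # missing interval columns yield NA means, not errors
  expect_true(is.na(mi$pq_ms))
  expect_error(mean_intervals(w[0, ]), "empty|beat_series")
})

test_that("rmssd and stv match hand arithmetic and analytic expectations", {
  expect_equal(rmssd(c(500, 500, 500)), 0)
  expect_equal(rmssd(c(500, 510, 500, 510)), 10)
  expect_equal(stv(c(200, 210, 200, 210, 200)), 10 / sqrt(2))
  expect_equal(stv(rep(7, 10)), 0)
  expect_error(rmssd(1), ">= 2")
  expect_error(stv(1), ">= 2")

  # i.i.d. Gaussian: E[rmssd] -> sigma*sqrt(2), E[stv] -> sigma*sqrt(2/pi)
  set.seed(42)
  x <- rnorm(1e5, 0, 10)
  expect_equal(rmssd(x), 10 * sqrt(2), tolerance = 0.01)
  y <- rnorm(1e5, 0, 5)
  expect_equal(stv(y), 5 * sqrt(2 / pi), tolerance = 0.01)
})

test_that("poincare pairs reproduce the series and carry the STV geometry", {
  p <- poincare_pairs(c(1, 2, 3))
  expect_equal(p$x, c(1, 2))
  expect_equal(p$x_next, c(2, 3))
  const <- poincare_pairs(rep(4, 6))
  expect_true(all(const$x == const$x_next))

  # stv equals the mean perpendicular distance of pairs from the identity line
  set.seed(1)
  x <- rnorm(200, 300, 12)
  pp <- poincare_pairs(x)
  perp <- abs(pp$x_next - pp$x) / sqrt(2)
  expect_equal(stv(x), mean(perp), tolerance = 1e-12)
})

test_that("variability statistics are scale-equivariant, translation-invariant, and Jensen-ordered", {
  set.seed(99)
  for (rep in 1:20) {
    x <- rnorm(50, 400, 20)
    c_ <- runif(1, 0.1, 5)
    expect_equal(stv(c_ * x), c_ * stv(x), tolerance = 1e-10)
    expect_equal(rmssd(c_ * x), c_ * rmssd(x), tolerance = 1e-10)
    expect_equal(stv(x + 100), stv(x), tolerance = 1e-10)
    expect_equal(rmssd(x + 100), rmssd(x), tolerance = 1e-10)
    expect_lte(stv(x), rmssd(x) / sqrt(2) + 1e-12)
  }
})
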