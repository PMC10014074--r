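make_wide <- function(df, idx) {
  df$wide_qrs[idx] <- 1L
  df$p_associated[idx] <- 0L
  df
}

test_that("classification rule traces: pause -> escape, short coupling -> premature", {
  df <- as.data.frame(constant_series(30, rr = 600))
  # wide-QRS beat after a 1200 ms pause: 1200/600 = 2.0 >= 1.5 -> escape
  df$rr_ms[20] <- 1200
  df <- make_wide(df, 20)
  df$t_ms <- cumsum(df$rr_ms)
  out <- classify_beats(beat_series(df))
  expect_equal(out$label[20], "escape_ventricular")

  # wide-QRS beat at 400 ms coupling: 400/600 = 0.67 <= 0.8 -> premature
  df2 <- as.data.frame(constant_series(30, rr = 600))
  df2$rr_ms[20] <- 400
  df2 <- make_wide(df2, 20)
  df2$t_ms <- cumsum(df2$rr_ms)
  out2 <- classify_beats(beat_series(df2))
  expect_equal(out2$label[20], "premature_ventricular")

  # wide beat meeting neither rule -> other; narrow beats stay sinus
  df3 <- as.data.frame(constant_series(30, rr = 600))
  df3 <- make_wide(df3, 20)
  df3$t_ms <- cumsum(df3$rr_ms)
  out3 <- classify_beats(beat_series(df3))
  expect_equal(out3$label[20], "other")
  expect_true(all(out3$label[-20] == "sinus"))

  # all-sinus stream: zero ectopic labels
  out4 <- classify_beats(constant_series(50))
  expect_true(all(out4$label == "sinus"))

  expect_error(classify_beats(constant_series(5)), "shorter")
})

test_that("classification is invariant to uniform time rescaling", {
  s <- generate_beat_stream(10, "TRN", "week16", seed = 31)
  e <- inject_ectopy(s, 30, 10, seed = 32)
  l1 <- classify_beats(e)$label
  df <- as.data.frame(e)
  df$rr_ms <- df$rr_ms * 2.5
  df$t_ms <- cumsum(df$rr_ms)
  l2 <- classify_beats(beat_series(df, duration_min =
                                     attr(e, "duration_min")))$label
  expect_identical(l1, l2)
})

test_that("classifier recovers ground truth perfectly at default injection geometry", {
  hits <- 0L; total <- 0L
  for (sd in 1:5) {
    s <- generate_beat_stream(20, "TRN", "week16", seed = 400 + sd)
    e <- inject_ectopy(s, 29.7, 6, seed = 500 + sd)
    cl <- classify_beats(e)
    expect_identical(cl$label, e$truth_label)
    # label conservation: counts partition the series
    expect_equal(sum(table(cl$label)), nrow(cl))
    hits <- hits + sum(cl$label != "sinus")
    total <- total + nrow(cl)
  }
  expect_gt(hits, 0L)
})

test_that("counts aggregate across recordings into hourly rates", {
  df <- as.data.frame(constant_series(100, rr = 600))
  df$label[c(10, 50)] <- "escape_ventricular"
  rec <- beat_series(df, duration_min = 20)
  ct <- count_and_rate(rec)
  expect_equal(ct$n_escape, 2L)
  expect_equal(ct$rate_escape_per_hr, 6.0)
  expect_equal(ct$n_total_arrhythmic, 2L)

  # three clean recordings: all rates zero
  clean <- beat_series(as.data.frame(constant_series(100)), duration_min = 20)
  ct0 <- count_and_rate(list(clean, clean, clean))
  expect_equal(ct0$rate_escape_per_hr, 0)
  expect_equal(ct0$duration_min, 60)
  expect_equal(ct0$n_total_arrhythmic,
               ct0$n_premature + ct0$n_escape + ct0$n_other_ventricular)
})

test_that("incidence builds the 2x2 table with conserved marginals", {
  inc <- incidence(sed = c(rep(TRUE, 3), rep(FALSE, 7)),
                   trn = c(rep(TRUE, 6), rep(FALSE, 4)))
  expect_equal(unname(inc$proportions["TRN"]), 0.6)
  expect_equal(unname(inc$proportions["SED"]), 0.3)
  expect_equal(unname(inc$table), matrix(c(6, 4, 3, 7), 2, byrow = TRUE))
  expect_equal(rowSums(inc$table), c(TRN = 10, SED = 10))

  zero <- incidence(sed = rep(0L, 10), trn = rep(0L, 10))
  expect_equal(unname(zero$proportions), c(0, 0))
  expect_error(incidence(sed = logical(0), trn = TRUE), ">= 1 animal")
})
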