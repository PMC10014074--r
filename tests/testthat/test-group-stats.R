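test_that("summaries report mean, sd (n-1) and sem = sd/sqrt(n)", {
  s <- summarize_values(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$sem, 1 / sqrt(3))
  const <- summarize_values(rep(5, 8))
  expect_equal(const$sd, 0)
  expect_equal(const$sem, 0)
  set.seed(2)
  for (rep in 1:10) {
    x <- rnorm(sample(3:50, 1))
    sm <- summarize_values(x)
    expect_equal(sm$sem * sqrt(sm$n), sm$sd, tolerance = 1e-12)
  }
  expect_error(summarize_values(numeric(0)), "empty")
})

test_that("chi-square closed form matches the expected-counts oracle and stats::chisq.test", {
  res <- chi_square_2x2(matrix(c(6, 4, 3, 7), 2, byrow = TRUE))
  expect_equal(res$statistic, 20 * (6 * 7 - 4 * 3)^2 / (10 * 10 * 9 * 11),
               tolerance = 1e-12)
  expect_equal(round(res$statistic, 3), 1.818)
  expect_equal(res$p_value, 0.178, tolerance = 1e-2)
  expect_false(res$significant)

  # identical rows: statistic 0, p 1
  flat <- chi_square_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  set.seed(3)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 8) + 1L, 2)
    mine <- chi_square_2x2(tab)
    expect_equal(mine$statistic, chisq_oracle(tab), tolerance = 1e-12)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    yates <- chi_square_2x2(tab, correction = TRUE)
    refy <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(yates$statistic, unname(refy$statistic), tolerance = 1e-10)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 7), 2, byrow = TRUE)),
               "marginal")
})

test_that("the gate routes Gaussian data to t and skewed data to Mann-Whitney", {
  set.seed(4)
  a <- rnorm(40, 10, 2); b <- rnorm(40, 12, 2)
  res <- choose_and_run(a, b)
  expect_match(res$test_used, "unpaired t")
  expect_true(res$significant)

  skew_a <- rexp(60)^3; skew_b <- rexp(60)^3
  res2 <- choose_and_run(skew_a, skew_b)
  expect_match(res2$test_used, "Mann-Whitney")
  expect_true(all(res2$normality <= 0.05))

  paired <- choose_and_run(a, a + rnorm(40, 1, 0.5), design = "paired")
  expect_match(paired$test_used, "paired t")
  expect_error(choose_and_run(a, a, design = "paired"), "degenerate")
  expect_error(choose_and_run(a[1:3], b), "n >= 5")
  expect_error(choose_and_run(a[1:10], b, design = "paired"),
               "equal sample lengths")
})

test_that("Mann-Whitney branch is invariant to monotone transforms", {
  set.seed(5)
  a <- rexp(30)^2; b <- rexp(30)^2 * 1.5
  p1 <- choose_and_run(a, b)$p_value
  p2 <- choose_and_run(log(a), log(b))$p_value
  # both route to Mann-Whitney; identical ranks give identical p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the gated procedure holds its nominal type-I error", {
  set.seed(6)
  n_rep <- 600
  rej_gauss <- mean(replicate(n_rep,
    choose_and_run(rnorm(20), rnorm(20))$p_value <= 0.05))
  rej_heavy <- mean(replicate(n_rep,
    choose_and_run(rt(20, df = 2), rt(20, df = 2))$p_value <= 0.05))
  # 3-sigma Monte-Carlo band around 5% at 600 reps is ~ +/- 2.7%
  expect_gt(rej_gauss, 0.023); expect_lt(rej_gauss, 0.077)
  expect_gt(rej_heavy, 0.023); expect_lt(rej_heavy, 0.077)
})

test_that("compare_table mirrors the per-variable procedure", {
  set.seed(7)
  tidy <- data.frame(
    animal_id = rep(sprintf("a%02d", 1:24), 2),
    group = rep(rep(c("SED", "TRN"), each = 12), 2),
    variable = rep(c("v1", "v2"), each = 24),
    value = c(rnorm(12, 10), rnorm(12, 14), rnorm(24, 5)))
  out <- compare_table(tidy)
  expect_equal(nrow(out), 2L)
  expect_true(out$significant[out$variable == "v1"])
  expect_equal(out$n_sed, c(12L, 12L))
  direct <- choose_and_run(tidy$value[13:24], tidy$value[1:12])
  expect_equal(out$p_value[1], direct$p_value, tolerance = 1e-12)
})
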