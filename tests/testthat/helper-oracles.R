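# Independent oracles used across the suite.

# OLS through the raw normal-equation sums (independent of stats::lm).
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- sy / n - slope * sx / n
  c(slope = slope, intercept = intercept)
}

# Chi-square statistic via explicit expected counts.
chisq_oracle <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

# A small all-sinus series with constant RR, for rule traces.
constant_series <- function(n, rr = 600, qt = 220) {
  beat_series(data.frame(t_ms = cumsum(rep(rr, n)), rr_ms = rr, qt_ms = qt))
}
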