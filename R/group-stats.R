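#' Mean, SD, SEM summary
#'
#' Sample mean, standard deviation (n-1 denominator) and standard error of
#' the mean `sd/sqrt(n)`, the form in which continuous variables are
#' reported.
#'
#' @param values Numeric vector (missing values dropped), n >= 1.
#' @return Named list: `mean`, `sd`, `sem`, `n`.
#' @export
summarize_values <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("empty input")
  s <- if (n > 1L) stats::sd(values) else 0
  list(mean = mean(values), sd = s, sem = s / sqrt(n), n = n)
}

#' Normality-gated two-sample comparison
#'
#' Implements the decision procedure of the statistical layer: each sample
#' is first checked for normality with a Kolmogorov--Smirnov test using
#' estimated mean/SD (Lilliefors critical values, alpha = 0.05).  If both
#' samples pass, a Student's t-test is run (paired or unpaired per the
#' design, equal variances); otherwise a two-sided Mann--Whitney U test.
#' Significance is declared at p <= 0.05.  The full provenance of the
#' choice (per-sample normality p-values and the test used) is returned.
#'
#' For the paired design the normality gate is applied to the two samples
#' as reported; zero-variance paired differences raise a degenerate-test
#' error rather than returning NaN.
#'
#' @param sample_a,sample_b Numeric samples (n >= 5 each; equal lengths for
#'   the paired design).
#' @param design `"unpaired"` (default) or `"paired"`.
#' @param variable Label carried into the result.
#' @param alpha_normality Gate level for the normality test.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `"comparison_result"`: `variable`, `design`,
#'   `test_used`, `statistic`, `p_value`, `significant`, `normality`
#'   (per-sample p-values), and `summary_a`/`summary_b` from
#'   [summarize_values()].
#' @export
choose_and_run <- function(sample_a, sample_b,
                           design = c("unpaired", "paired"),
                           variable = NA_character_,
                           alpha_normality = 0.05, alpha = 0.05) {
  design <- match.arg(design)
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 5L || length(sample_b) < 5L)
    stop("need n >= 5 per sample for the normality-gated procedure")
  if (design == "paired" && length(sample_a) != length(sample_b))
    stop("paired design requires equal sample lengths")
  if (design == "paired" && stats::sd(sample_a - sample_b) < 1e-12)
    stop("degenerate paired test: zero-variance differences")
  norm_p <- c(a = nortest::lillie.test(sample_a)$p.value,
              b = nortest::lillie.test(sample_b)$p.value)
  both_normal <- all(norm_p > alpha_normality)
  if (both_normal) {
    ht <- stats::t.test(sample_a, sample_b, paired = design == "paired",
                        var.equal = TRUE)
    test_used <- if (design == "paired") "paired t" else "unpaired t"
  } else {
    ht <- stats::wilcox.test(sample_a, sample_b,
                             paired = design == "paired", exact = NULL)
    test_used <- "Mann-Whitney U"
  }
  structure(list(variable = variable, design = design,
                 test_used = test_used,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 significant = ht$p.value <= alpha,
                 normality = norm_p,
                 summary_a = summarize_values(sample_a),
                 summary_b = summarize_values(sample_b)),
            class = "comparison_result")
}

#' Chi-square test for a 2x2 contingency table
#'
#' Closed form without continuity correction (the default):
#' `chi^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on one degree of
#' freedom; the Yates-corrected variant is available behind the flag.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param correction Apply the Yates continuity correction.
#' @param variable Label carried into the result.
#' @param alpha Significance level (default 0.05).
#' @return A `"comparison_result"` with `test_used = "chi-square"`.
#' @export
chi_square_2x2 <- function(table, correction = FALSE,
                           variable = NA_character_, alpha = 0.05) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  n <- sum(table)
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) stop("zero marginal total")
  num <- abs(a * d - b * c_)
  if (correction) num <- max(num - n / 2, 0)
  stat <- n * num^2 / prod(margins)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(variable = variable, design = "categorical",
                 test_used = if (correction) "chi-square (Yates)"
                             else "chi-square",
                 statistic = stat, p_value = p,
                 significant = p <= alpha,
                 table = table),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  mark <- if (isTRUE(x$significant)) " *" else ""
  cat(sprintf("%s [%s]: %s, statistic = %.4g, p = %.4g%s\n",
              if (is.na(x$variable)) "comparison" else x$variable,
              x$design, x$test_used, x$statistic, x$p_value, mark))
  if (!is.null(x$summary_a))
    cat(sprintf("  A: %.4g +/- %.4g (n=%d)   B: %.4g +/- %.4g (n=%d)  (mean +/- SEM)\n",
                x$summary_a$mean, x$summary_a$sem, x$summary_a$n,
                x$summary_b$mean, x$summary_b$sem, x$summary_b$n))
  invisible(x)
}

#' Compare every variable of a tidy per-animal table between groups
#'
#' Runs [choose_and_run()] for each variable of a long-format table
#' (`animal_id`, `group`, `variable`, `value`), TRN vs SED, and returns a
#' result table with mean +/- SEM per group and significance markers.
#'
#' @param tidy Data frame with columns `animal_id`, `group`, `variable`,
#'   `value`.
#' @param design Passed to [choose_and_run()].
#' @return Data frame: one row per variable with `mean_sed`, `sem_sed`,
#'   `n_sed`, `mean_trn`, `sem_trn`, `n_trn`, `test_used`, `p_value`,
#'   `significant`.
#' @export
compare_table <- function(tidy, design = "unpaired") {
  stopifnot(all(c("group", "variable", "value") %in% names(tidy)))
  vars <- unique(tidy$variable)
  rows <- lapply(vars, function(v) {
    sub <- tidy[tidy$variable == v, ]
    trn <- sub$value[sub$group == "TRN"]
    sed <- sub$value[sub$group == "SED"]
    res <- tryCatch(choose_and_run(trn, sed, design = design, variable = v),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(variable = v,
                        mean_sed = mean(sed), sem_sed = NA_real_,
                        n_sed = length(sed),
                        mean_trn = mean(trn), sem_trn = NA_real_,
                        n_trn = length(trn),
                        test_used = "none (insufficient n)",
                        p_value = NA_real_, significant = NA,
                        stringsAsFactors = FALSE))
    data.frame(variable = v,
               mean_sed = res$summary_b$mean, sem_sed = res$summary_b$sem,
               n_sed = res$summary_b$n,
               mean_trn = res$summary_a$mean, sem_trn = res$summary_a$sem,
               n_trn = res$summary_a$n,
               test_used = res$test_used, p_value = res$p_value,
               significant = res$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
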