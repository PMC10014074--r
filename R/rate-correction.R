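#' Extract (preceding RR, QT) pairs from a beat series
#'
#' QT of beat x is paired with the RR that ended at beat x-1 (the preceding
#' cycle), the pairing used for both fitting and correction.  The first
#' beat, having no predecessor, is dropped.  A same-beat pairing mode is
#' available for sensitivity analysis.
#'
#' @param series A [beat_series()] (or data frame with `rr_ms`, `qt_ms`).
#' @param pairing `"preceding"` (default) or `"same"`.
#' @return Data frame with columns `rr_prev_ms`, `qt_ms` (complete cases).
#' @export
qt_rr_pairs <- function(series, pairing = c("preceding", "same")) {
  pairing <- match.arg(pairing)
  df <- as.data.frame(series)
  stopifnot(all(c("rr_ms", "qt_ms") %in% names(df)))
  n <- nrow(df)
  if (pairing == "preceding") {
    out <- data.frame(rr_prev_ms = df$rr_ms[-n], qt_ms = df$qt_ms[-1])
  } else {
    out <- data.frame(rr_prev_ms = df$rr_ms, qt_ms = df$qt_ms)
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Fit the QT--RR rate-correction model
#'
#' Ordinary least squares of QT on the preceding RR interval,
#' `QT = a * RR_prev + b`, stored together with the reference RR at which
#' corrected QT values are reported (default 528 ms, a ventricular rate of
#' about 118 bpm).  The rearranged correction is
#' `QTc_x = QT_x - a * (RR_(x-1) - rr_ref)`, applied by
#' [correct_qt()] / `predict()`.
#'
#' @param data A [beat_series()], a data frame with `rr_ms` and `qt_ms`
#'   columns, or a data frame with `rr_prev_ms` and `qt_ms` columns
#'   (already-paired observations).
#' @param rr_ref_ms Reference RR interval (ms) for the correction.
#' @param pairing Passed to [qt_rr_pairs()] when `data` still needs pairing.
#' @return Object of class `"qtrr"`: `slope_a` (ms/ms), `intercept_b` (ms),
#'   `rr_ref_ms`, `n_fit`, `r` (Pearson correlation of the fit), `se_slope`,
#'   `se_intercept`, and the fitted pairs.
#' @export
qtrr <- function(data, rr_ref_ms = 528, pairing = c("preceding", "same")) {
  if (rr_ref_ms <= 0) stop("rr_ref_ms must be > 0")
  pairs <- if (is.data.frame(data) && "rr_prev_ms" %in% names(data) &&
               !inherits(data, "beat_series"))
    data[stats::complete.cases(data[, c("rr_prev_ms", "qt_ms")]), ]
  else qt_rr_pairs(data, pairing)
  if (nrow(pairs) < 3L) stop("need >= 3 (rr_prev, qt) pairs to fit")
  if (stats::sd(pairs$rr_prev_ms) < 1e-9)
    stop("degenerate RR spread: cannot fit QT-RR regression")
  fit <- stats::lm(qt_ms ~ rr_prev_ms, data = pairs)
  cf <- stats::coef(fit)
  # a noise-free input is a legitimate perfect fit; silence summary.lm
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  structure(list(slope_a = unname(cf["rr_prev_ms"]),
                 intercept_b = unname(cf["(Intercept)"]),
                 rr_ref_ms = rr_ref_ms,
                 n_fit = nrow(pairs),
                 r = stats::cor(pairs$rr_prev_ms, pairs$qt_ms),
                 se_slope = unname(se["rr_prev_ms"]),
                 se_intercept = unname(se["(Intercept)"]),
                 pairs = pairs),
            class = "qtrr")
}

#' The reported rate-correction model
#'
#' Builds a `qtrr` model directly from stated coefficients rather than a
#' fit; by default the pooled baseline relation `QT = 0.045 * RR + 187`
#' referenced to RR = 528 ms.
#'
#' @param slope_a Slope (ms QT per ms RR).
#' @param intercept_b Intercept (ms).
#' @param rr_ref_ms Reference RR (ms).
#' @return A `"qtrr"` object with `n_fit = NA`.
#' @export
qtrr_reference <- function(slope_a = 0.045, intercept_b = 187,
                           rr_ref_ms = 528) {
  if (rr_ref_ms <= 0) stop("rr_ref_ms must be > 0")
  structure(list(slope_a = slope_a, intercept_b = intercept_b,
                 rr_ref_ms = rr_ref_ms, n_fit = NA_integer_, r = NA_real_,
                 se_slope = NA_real_, se_intercept = NA_real_, pairs = NULL),
            class = "qtrr")
}

#' Rate-correct QT intervals
#'
#' Pure linear correction `qtc = qt - slope_a * (rr_prev - rr_ref)`: QT is
#' shifted along the fitted rate dependence to the reference RR, with no
#' clamping.  At `rr_prev = rr_ref` the QT is returned unchanged.
#'
#' @param qt_ms QT interval(s), ms (> 0).
#' @param rr_prev_ms Preceding RR interval(s), ms (> 0).
#' @param model A `"qtrr"` object.
#' @return QTc in ms (vectorized).
#' @export
correct_qt <- function(qt_ms, rr_prev_ms, model) {
  stopifnot(inherits(model, "qtrr"))
  if (any(qt_ms <= 0, na.rm = TRUE) || any(rr_prev_ms <= 0, na.rm = TRUE))
    stop("qt_ms and rr_prev_ms must be > 0")
  qt_ms - model$slope_a * (rr_prev_ms - model$rr_ref_ms)
}

#' Verify the zero-slope property of the correction
#'
#' Regresses corrected QTc on the preceding RR.  When the model was fitted
#' by OLS on the same data, residual orthogonality makes this slope zero to
#' machine precision; on new data it estimates residual rate dependence.
#'
#' @param series A [beat_series()] (or paired data frame, see [qtrr()]).
#' @param model A `"qtrr"` object.
#' @return List: `slope` and `se` of QTc on RR_prev.
#' @export
verify_zero_slope <- function(series, model) {
  stopifnot(inherits(model, "qtrr"))
  pairs <- if (is.data.frame(series) && "rr_prev_ms" %in% names(series) &&
               !inherits(series, "beat_series")) series
  else qt_rr_pairs(series)
  if (nrow(pairs) < 3L) stop("need >= 3 pairs")
  qtc <- correct_qt(pairs$qt_ms, pairs$rr_prev_ms, model)
  # direct OLS: avoids summary.lm's perfect-fit warning on noise-free data
  x <- pairs$rr_prev_ms
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (qtc - mean(qtc))) / sxx
  intercept <- mean(qtc) - slope * mean(x)
  rss <- sum((qtc - intercept - slope * x)^2)
  list(slope = slope, se = sqrt(rss / (n - 2) / sxx))
}

#' @export
coef.qtrr <- function(object, ...) {
  c(slope_a = object$slope_a, intercept_b = object$intercept_b)
}

#' @export
print.qtrr <- function(x, ...) {
  cat("QT-RR rate-correction model\n")
  cat(sprintf("  QT = %.4g * RR_prev + %.4g  (ms)\n",
              x$slope_a, x$intercept_b))
  cat(sprintf("  reference RR: %.0f ms;  QTc_x = QT_x - %.4g * (RR_(x-1) - %.0f)\n",
              x$rr_ref_ms, x$slope_a, x$rr_ref_ms))
  if (!is.na(x$n_fit))
    cat(sprintf("  fitted on %d pairs, r = %.3f\n", x$n_fit, x$r))
  else cat("  coefficients stated, not fitted\n")
  invisible(x)
}

#' @export
summary.qtrr <- function(object, ...) {
  out <- object[c("slope_a", "intercept_b", "rr_ref_ms", "n_fit", "r",
                  "se_slope", "se_intercept")]
  class(out) <- "summary.qtrr"
  out
}

#' @export
print.summary.qtrr <- function(x, ...) {
  cat("QT-RR model summary\n")
  cat(sprintf("  slope    %.5f ms/ms (se %.5f)\n", x$slope_a, x$se_slope))
  cat(sprintf("  intercept %.3f ms (se %.3f)\n", x$intercept_b,
              x$se_intercept))
  cat(sprintf("  rr_ref   %.0f ms; n = %s; r = %.3f\n", x$rr_ref_ms,
              format(x$n_fit), x$r))
  invisible(x)
}

#' Predict from a QT--RR model
#'
#' `type = "qt"` returns the fitted QT at the supplied preceding RR;
#' `type = "qtc"` applies the rate correction to supplied `qt_ms` values.
#'
#' @param object A `"qtrr"` object.
#' @param rr_prev_ms Preceding RR values (ms).
#' @param qt_ms QT values (ms), required for `type = "qtc"`.
#' @param type `"qt"` or `"qtc"`.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.qtrr <- function(object, rr_prev_ms, qt_ms = NULL,
                         type = c("qt", "qtc"), ...) {
  type <- match.arg(type)
  if (type == "qt")
    return(object$slope_a * rr_prev_ms + object$intercept_b)
  if (is.null(qt_ms)) stop("qt_ms required for type = 'qtc'")
  correct_qt(qt_ms, rr_prev_ms, object)
}

#' @export
residuals.qtrr <- function(object, ...) {
  if (is.null(object$pairs)) stop("model was stated, not fitted: no residuals")
  object$pairs$qt_ms -
    (object$slope_a * object$pairs$rr_prev_ms + object$intercept_b)
}

#' Diagnostic plot of a fitted QT--RR model
#'
#' Scatter of QT against preceding RR with the fitted line, and (when
#' `show_qtc = TRUE`) the corrected QTc against the same RR values, whose
#' regression slope is zero by construction on the fitting data.
#'
#' @param x A fitted `"qtrr"` object.
#' @param show_qtc Overlay corrected QTc points.
#' @param ... Passed to [plot()].
#' @export
plot.qtrr <- function(x, show_qtc = TRUE, ...) {
  if (is.null(x$pairs)) stop("model was stated, not fitted: nothing to plot")
  p <- x$pairs
  plot(p$rr_prev_ms, p$qt_ms, xlab = "preceding RR (ms)", ylab = "QT (ms)",
       pch = 16, col = "grey40", ...)
  graphics::abline(x$intercept_b, x$slope_a, col = "firebrick", lwd = 2)
  if (show_qtc) {
    qtc <- correct_qt(p$qt_ms, p$rr_prev_ms, x)
    graphics::points(p$rr_prev_ms, qtc, pch = 1, col = "steelblue")
    graphics::abline(h = mean(qtc), col = "steelblue", lty = 2)
    graphics::legend("topleft", legend = c("QT (fit)", "QTc (slope 0)"),
                     col = c("firebrick", "steelblue"), lty = c(1, 2),
                     bty = "n")
  }
  invisible(x)
}
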