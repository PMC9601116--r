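# Secular-trend and seasonal-harmonic removal for monthly series.

#' Fit and remove a secular trend
#'
#' Least-squares fit of either a linear trend `c0 + c1 t` or an exponential
#' trend `c0 + c1 exp(c2 t)` (nonlinear least squares, initialized from a
#' log-linear fit) over the month index `t = 0, 1, ...`; the fitted trend is
#' subtracted from the series.
#'
#' @param series a [monthly_series()] (missing months are ignored in the fit
#'   and stay missing in the residual).
#' @param kind `"linear"` or `"exponential"`.
#' @return A list with elements `report` (a `detrend_report`: trend kind,
#'   fitted coefficients, residual summary) and `series` (the detrended
#'   [monthly_series()]).
#' @examples
#' s <- monthly_series(rep(2000:2003, each = 12), rep(1:12, 4),
#'                     5 + 0.1 * (0:47), precision = 0.01)
#' out <- fit_remove_trend(s, "linear")
#' out$report$coefficients
#' @export
fit_remove_trend <- function(series, kind = c("linear", "exponential")) {
  stopifnot(inherits(series, "monthly_series"))
  kind <- match.arg(kind)
  y <- series$value
  if (sum(!is.na(y)) < 24) stop("need at least 24 non-missing months")
  t <- seq_along(y) - 1
  if (kind == "linear") {
    fit <- stats::lm(y ~ t, na.action = stats::na.exclude)
    coefs <- c(c0 = unname(stats::coef(fit)[1]), c1 = unname(stats::coef(fit)[2]))
    trend <- stats::coef(fit)[1] + stats::coef(fit)[2] * t
  } else {
    ok <- !is.na(y)
    # initialize: c0 slightly below the minimum, then log-linear regression
    c0_0 <- min(y[ok]) - 0.05 * diff(range(y[ok])) - 1e-8
    lf <- stats::lm(log(y[ok] - c0_0) ~ t[ok])
    start <- list(c0 = c0_0, c1 = exp(unname(stats::coef(lf)[1])),
                  c2 = unname(stats::coef(lf)[2]))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ c0 + c1 * exp(c2 * t), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200),
                        na.action = stats::na.exclude),
      error = function(e)
        stop("exponential trend fit failed to converge (", conditionMessage(e),
             "); consider kind = \"linear\""))
    coefs <- stats::coef(fit)
    trend <- coefs["c0"] + coefs["c1"] * exp(coefs["c2"] * t)
  }
  resid <- y - trend
  report <- structure(list(kind = kind, coefficients = coefs,
                           harmonics = NULL,
                           residual_sd = stats::sd(resid, na.rm = TRUE)),
                      class = "detrend_report")
  out <- series
  out$value <- resid
  out$name <- paste0(series$name, " (detrended)")
  list(report = report, series = out)
}

#' Remove the highest-power seasonal harmonics
#'
#' Identifies the `k` non-DC periodogram frequencies with the largest power
#' and removes the corresponding sinusoids, fitting amplitude and phase of
#' all selected frequencies jointly by least squares.
#'
#' @param series a [monthly_series()], ideally already detrended.
#' @param k number of harmonics to remove, `>= 0`.
#' @return A list with `report` (a `detrend_report` whose `harmonics` data
#'   frame lists frequency in cycles/month, power, amplitude and phase) and
#'   `series` (the filtered [monthly_series()]).
#' @export
remove_top_harmonics <- function(series, k) {
  stopifnot(inherits(series, "monthly_series"), k >= 0, k == round(k))
  y <- series$value
  n <- length(y)
  if (k == 0) {
    report <- structure(list(kind = "harmonics", coefficients = NULL,
                             harmonics = data.frame(freq = numeric(0),
                                                    power = numeric(0)),
                             residual_sd = stats::sd(y, na.rm = TRUE)),
                        class = "detrend_report")
    return(list(report = report, series = series))
  }
  ok <- !is.na(y)
  yc <- y - mean(y, na.rm = TRUE)
  yc[!ok] <- 0                      # zero-fill gaps for the periodogram only
  spec <- Mod(stats::fft(yc))^2 / n
  nf <- floor(n / 2)
  if (k > nf - 1) stop("k exceeds the number of available frequency bins")
  freqs <- (1:nf) / n               # cycles per month, DC excluded
  pw <- spec[2:(nf + 1)]
  sel <- order(pw, decreasing = TRUE)[seq_len(k)]
  fsel <- freqs[sel]
  t <- seq_len(n) - 1
  X <- do.call(cbind, lapply(fsel, function(f)
    cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))))
  fit <- stats::lm(y ~ X, na.action = stats::na.exclude)
  beta <- stats::coef(fit)[-1]
  amp <- sqrt(beta[seq(1, 2 * k, by = 2)]^2 + beta[seq(2, 2 * k, by = 2)]^2)
  phase <- atan2(-beta[seq(2, 2 * k, by = 2)], beta[seq(1, 2 * k, by = 2)])
  seasonal <- as.vector(X %*% beta) + stats::coef(fit)[1]
  resid <- y - seasonal
  report <- structure(list(kind = "harmonics", coefficients = NULL,
                           harmonics = data.frame(freq = fsel, power = pw[sel],
                                                  amplitude = unname(amp),
                                                  phase = unname(phase)),
                           residual_sd = stats::sd(resid, na.rm = TRUE)),
                      class = "detrend_report")
  out <- series
  out$value <- resid
  out$name <- paste0(series$name, " (harmonics removed)")
  list(report = report, series = out)
}

#' @export
print.detrend_report <- function(x, ...) {
  cat(sprintf("Detrend report (%s): residual sd = %.4g\n", x$kind, x$residual_sd))
  if (!is.null(x$coefficients)) {
    cat("  coefficients: ")
    cat(sprintf("%s = %.6g", names(x$coefficients), x$coefficients), sep = ", ")
    cat("\n")
  }
  if (!is.null(x$harmonics) && nrow(x$harmonics) > 0) {
    cat(sprintf("  removed %d harmonic(s) at %s cycles/month\n",
                nrow(x$harmonics),
                paste(signif(x$harmonics$freq, 4), collapse = ", ")))
  }
  invisible(x)
}
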