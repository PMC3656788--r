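## Sigmoidal substrate-degradation kinetics: least-squares fit of the
## 3-parameter logistic D(t) = K / (1 + exp(-r (t - t0))) with the peak
## degradation rate (r K / 4, attained at the inflection) and the lag time
## (t0, the day the peak rate is reached) derived analytically.

#' Fit a logistic degradation curve and extract peak rate and lag time
#'
#' @param timepoints Days (at least 5 points).
#' @param degraded Degraded substrate (g/L), non-negative.
#' @param init Optional named starting values `c(K=, r=, t0=)`; defaults are
#'   `K = max(degraded)`, `t0` at the half-maximum crossing and
#'   `r = 4 * max slope / K`.
#' @param baseline4p Fit a 4-parameter variant with a floating baseline
#'   (default FALSE; degraded mass starts at 0).
#' @return Object of class `SigmoidFit`: `K` (g/L), `r` (1/day), `t0`
#'   (day), `peak_rate = r K / 4` (g/L/day), `lag_time = t0` (day), `rss`,
#'   `converged`. Non-convergence is flagged, not raised.
#' @export
fit_sigmoid_extract <- function(timepoints, degraded, init = NULL,
                                baseline4p = FALSE) {
  if (length(timepoints) < 5L) .stopf("need at least 5 timepoints")
  if (length(degraded) != length(timepoints))
    .stopf("timepoints and degraded must have equal length")
  if (any(degraded < -1e-9)) .stopf("degraded values must be non-negative")
  bad_fit <- structure(list(K = NA_real_, r = NA_real_, t0 = NA_real_,
                            peak_rate = NA_real_, lag_time = NA_real_,
                            rss = NA_real_, converged = FALSE),
                       class = "SigmoidFit")
  if (max(degraded) - min(degraded) < 1e-9) return(bad_fit)

  if (is.null(init)) {
    K0 <- max(degraded)
    half <- which(degraded >= K0 / 2)[1L]
    t00 <- if (is.na(half)) stats::median(timepoints) else timepoints[half]
    slopes <- diff(degraded) / diff(timepoints)
    r0 <- max(4 * max(slopes, na.rm = TRUE) / K0, 0.1)
    init <- c(K = K0, r = r0, t0 = t00)
  }
  df <- data.frame(t = timepoints, D = degraded)
  fit <- tryCatch({
    if (baseline4p)
      minpack.lm::nlsLM(D ~ b + K / (1 + exp(-r * (t - t0))), data = df,
                        start = c(as.list(init), b = 0),
                        lower = c(K = 1e-9, r = 1e-9, t0 = -Inf, b = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(D ~ K / (1 + exp(-r * (t - t0))), data = df,
                        start = as.list(init),
                        lower = c(K = 1e-9, r = 1e-9, t0 = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) return(bad_fit)
  cf <- coef(fit)
  if (!all(is.finite(cf)) || cf[["K"]] <= 0 || cf[["r"]] <= 0)
    return(bad_fit)
  structure(list(K = cf[["K"]], r = cf[["r"]], t0 = cf[["t0"]],
                 peak_rate = cf[["r"]] * cf[["K"]] / 4,
                 lag_time = cf[["t0"]],
                 rss = sum(stats::residuals(fit)^2), converged = TRUE),
            class = "SigmoidFit")
}

#' @export
print.SigmoidFit <- function(x, ...) {
  if (!x$converged) cat("SigmoidFit: not converged\n")
  else cat(sprintf(
    "SigmoidFit: K = %.3f g/L, r = %.3f /day, t0 = %.2f day (peak rate %.3f g/L/day, lag %.2f day)\n",
    x$K, x$r, x$t0, x$peak_rate, x$lag_time))
  invisible(x)
}
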