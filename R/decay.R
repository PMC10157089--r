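# Mono-exponential luminescence decay fitting. Observed 5D0 lifetimes
# (tau_obs) for Eu(III) complexes are obtained by least-squares fitting of
# A*exp(-t/tau) + b to gated decay traces.

#' Construct a luminescence decay trace
#'
#' @param times Strictly increasing time axis in microseconds, length >= 4.
#' @param signal Non-negative signal values (detector counts or a.u.), same
#'   length as `times`.
#' @param label Free-text sample label.
#' @return A `"decay_trace"` object.
#' @export
decay_trace <- function(times, signal, label = "") {
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) < 4L) {
    stop("decay trace needs at least 4 points", call. = FALSE)
  }
  if (length(times) != length(signal)) {
    stop("times and signal must have the same length", call. = FALSE)
  }
  if (anyNA(times) || any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("times must be finite and strictly increasing", call. = FALSE)
  }
  if (anyNA(signal) || any(!is.finite(signal)) || any(signal < 0)) {
    stop("signal must be finite and non-negative", call. = FALSE)
  }
  structure(list(times = times, signal = signal, label = as.character(label)),
            class = "decay_trace")
}

#' Read a two-column decay trace file
#'
#' Delimited text (comma or whitespace), column 1 time in microseconds,
#' column 2 signal; `#` comments allowed.
#'
#' @param source Path, connection, or character vector of lines.
#' @inheritParams decay_trace
#' @return A [decay_trace()].
#' @export
read_decay_trace <- function(source, label = "") {
  m <- read_two_column(source, what = "decay")
  ord <- order(m[, 1L])
  decay_trace(m[ord, 1L], m[ord, 2L], label = label)
}

#' Fit a mono-exponential decay
#'
#' Least-squares fit of `A * exp(-t / tau) + b` to a decay trace, the model
#' used for all reported 5D0 lifetimes. Starting values come from a
#' log-linear regression on the baseline-subtracted tail; the nonlinear
#' refinement uses Levenberg-Marquardt. By default the fit starts at the
#' signal maximum (skipping the excitation/gate region) and the baseline `b`
#' is a free parameter.
#'
#' @param trace A [decay_trace()].
#' @param fit_start Time (microseconds) at which the fit window begins.
#'   `NULL` (default) uses the time of the signal maximum.
#' @param fit_baseline Fit a constant baseline `b`? If `FALSE`, `b` is fixed
#'   at 0.
#' @param weighting `"none"` (default, unweighted least squares) or
#'   `"poisson"` (weights `1/max(signal, 1)`, appropriate for photon-counting
#'   traces).
#' @return A `"decay_fit"` object: list with `tau_obs` (microseconds),
#'   `amplitude`, `baseline`, `rms_residual`, `n_points_used`, `fit_start`.
#' @export
#' @examples
#' tr <- gen_decay_trace(tau = 700, amplitude = 1000, window = c(0, 3000),
#'                       step = 5)
#' fit_monoexponential(tr)$tau_obs
fit_monoexponential <- function(trace, fit_start = NULL, fit_baseline = TRUE,
                                weighting = c("none", "poisson")) {
  stopifnot(inherits(trace, "decay_trace"))
  weighting <- match.arg(weighting)
  if (is.null(fit_start)) {
    fit_start <- trace$times[which.max(trace$signal)]
  }
  keep <- trace$times >= fit_start
  t <- trace$times[keep]
  y <- trace$signal[keep]
  n <- length(t)
  if (n < 4L) {
    stop("fewer than 4 points after fit_start", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("signal is constant; cannot fit a decay", call. = FALSE)
  }

  # starting values: baseline from the last decade of the trace, then
  # log-linear regression on the positive baseline-subtracted signal
  b0 <- if (fit_baseline) {
    mean(y[t >= t[1L] + 0.9 * (t[n] - t[1L])])
  } else 0
  ypos <- y - b0
  sel <- ypos > 0
  if (sum(sel) < 3L) {  # baseline guess too high; fall back to raw signal
    b0 <- 0
    ypos <- y
    sel <- ypos > 0
  }
  if (sum(sel) < 3L) {
    stop("too few positive signal values for initialization", call. = FALSE)
  }
  ll <- stats::lm(log(ypos[sel]) ~ t[sel], weights = ypos[sel])
  slope <- stats::coef(ll)[[2L]]
  tau0 <- if (is.finite(slope) && slope < 0) -1 / slope else (t[n] - t[1L]) / 3
  A0 <- exp(stats::coef(ll)[[1L]])
  if (!is.finite(A0) || A0 <= 0) A0 <- max(y)

  w <- if (weighting == "poisson") 1 / pmax(y, 1) else rep(1, n)
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    if (fit_baseline) {
      minpack.lm::nlsLM(y ~ A * exp(-t / tau) + b, data = dat,
                        start = list(A = A0, tau = tau0, b = b0),
                        weights = w,
                        lower = c(A = 1e-12, tau = 1e-12, b = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = dat,
                        start = list(A = A0, tau = tau0),
                        weights = w,
                        lower = c(A = 1e-12, tau = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) {
      stop(sprintf(paste0("mono-exponential fit failed: %s ",
                          "(last start: A=%.4g, tau=%.4g, b=%.4g)"),
                   conditionMessage(e), A0, tau0, b0), call. = FALSE)
    }
  )
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  structure(
    list(tau_obs = cf[["tau"]],
         amplitude = cf[["A"]],
         baseline = if (fit_baseline) cf[["b"]] else 0,
         rms_residual = sqrt(mean(res^2)),
         n_points_used = n,
         fit_start = fit_start,
         label = trace$label),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  tau_obs   = %.2f us\n", x$tau_obs))
  cat(sprintf("  amplitude = %.4g, baseline = %.4g\n", x$amplitude,
              x$baseline))
  cat(sprintf("  rms residual %.4g over %d points (fit from %g us)\n",
              x$rms_residual, x$n_points_used, x$fit_start))
  invisible(x)
}
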