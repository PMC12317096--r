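#' Time-correlation series container
#'
#' Holds a correlation function (or MSD) sampled on lags starting at 0.
#' `normalization` records whether values were divided by the zero-lag value.
#'
#' @param lags numeric lags, starting at 0, strictly increasing.
#' @param values correlation values at each lag.
#' @param normalization `"raw"` or `"zero-lag"`.
#' @param lag_unit `"fs"` or `"ps"` (bookkeeping for printing/IO).
#' @param ... extra metadata fields stored on the object.
#' @return object of class `correlation_series`.
#' @export
correlation_series <- function(lags, values, normalization = "raw",
                               lag_unit = "fs", ...) {
  if (length(lags) != length(values)) .stopf("lags/values length mismatch")
  if (lags[1] != 0 || any(diff(lags) <= 0))
    .stopf("lags must start at 0 and increase strictly")
  if (normalization == "zero-lag" && is.finite(values[1]) && values[1] != 0 &&
      abs(values[1] - 1) > 1e-8)
    .stopf("normalized series must start at 1 (got %g)", values[1])
  structure(c(list(lags = as.numeric(lags), values = as.numeric(values),
                   normalization = normalization, lag_unit = lag_unit),
              list(...)),
            class = "correlation_series")
}

#' @export
print.correlation_series <- function(x, ...) {
  cat(sprintf("correlation_series: %d lags in [0, %g] %s (%s)\n",
              length(x$lags), max(x$lags), x$lag_unit, x$normalization))
  invisible(x)
}

#' @export
as.data.frame.correlation_series <- function(x, ...) {
  data.frame(lag = x$lags, value = x$values)
}

# convert the lag axis between fs and ps
.series_in_unit <- function(series, unit) {
  if (series$lag_unit == unit) return(series)
  f <- if (unit == "ps") 1e-3 else 1e3
  series$lags <- series$lags * f
  series$lag_unit <- unit
  series
}

#' Interpolated 1/e decay time of a normalized correlation series
#'
#' Finds the first lag where the series crosses `exp(-1)` by linear
#' interpolation between bracketing samples.  Used as a model-free timescale
#' estimate for exponential-like decays.
#'
#' @param series a [correlation_series()] (normalized to 1 at lag 0).
#' @return decay time in the series' lag unit; `NA` if no crossing occurs.
#' @export
efolding_time <- function(series) {
  v <- series$values; l <- series$lags
  thr <- exp(-1)
  below <- which(v < thr)
  if (!length(below)) return(NA_real_)
  j <- below[1]
  if (j == 1) return(l[1])
  # linear interpolation between j-1 and j
  l[j - 1] + (l[j] - l[j - 1]) * (v[j - 1] - thr) / (v[j - 1] - v[j])
}

# FFT-based autocorrelation of the columns of a matrix, averaged over
# columns, with the unbiased all-origins normalization:
#   acf(k) = (1/(n-k)) sum_s x[s] x[s+k],  k = 0..max_lag_steps
.acf_columns <- function(x, max_lag_steps) {
  x <- as.matrix(x)
  n <- nrow(x)
  nfft <- stats::nextn(2L * n, 2)
  acc <- numeric(max_lag_steps + 1L)
  for (j in seq_len(ncol(x))) {
    f <- stats::fft(c(x[, j], numeric(nfft - n)))
    s <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / nfft
    acc <- acc + s[seq_len(max_lag_steps + 1L)]
  }
  acc / (ncol(x) * (n - 0:max_lag_steps))
}

#' Two-timescale exponential fit
#'
#' Fits `a0 exp(-t/tau0) + (1 - a0) exp(-t/tau1)` to a normalized
#' correlation series on a lag window by bounded least squares.  The fit is
#' deterministic: a fixed multi-start grid (`tau0` in 0.02/0.05/0.1/0.3 ps,
#' `tau1` in 0.5/1/2/5 ps, `a0` in 0.2/0.5/0.8) seeds L-BFGS-B, the best
#' residual wins and ties go to the smallest `tau1`.  Time constants are
#' returned ordered (`tau0 <= tau1`, swapping `a0` for `1 - a0` if needed).
#' A series that does not decay pins both constants at the upper bound and
#' is flagged in `degenerate`.
#'
#' With `offset = TRUE` the model becomes
#' `c + (1 - c) (a0 exp(-t/tau0) + (1 - a0) exp(-t/tau1))`, for
#' correlations that relax to a persistent-order plateau instead of zero
#' (orientational correlations of strongly confined molecules); the
#' plateau `c` is reported in the `offset` field.
#'
#' @param series a [correlation_series()] normalized at lag 0 (any lag unit;
#'   fitting is done in ps).
#' @param window `(t_min, t_max)` in ps, inside the available lag range.
#' @param offset also fit a constant plateau (default `FALSE`).
#' @return object of class `biexp_fit` with fields `a0`, `tau0`, `tau1`
#'   (ps), `fit_window`, `residual_norm`, `degenerate`, `offset`.
#' @export
fit_biexponential <- function(series, window = NULL, offset = FALSE) {
  s <- .series_in_unit(series, "ps")
  if (is.null(window)) window <- c(0, max(s$lags))
  sel <- s$lags >= window[1] & s$lags <= window[2]
  if (sum(sel) < 5) .stopf("fewer than 5 points in fit window")
  t <- s$lags[sel]; y <- s$values[sel]
  if (any(!is.finite(y))) .stopf("non-finite values in fit window")

  lower <- c(0, 1e-4, 1e-4)
  tau_hi <- max(100, 10 * max(t))
  upper <- c(1, tau_hi, tau_hi)
  model <- function(p) {
    core <- p[1] * exp(-t / p[2]) + (1 - p[1]) * exp(-t / p[3])
    if (offset) p[4] + (1 - p[4]) * core else core
  }
  obj <- function(p) sum((model(p) - y)^2)
  starts <- expand.grid(a0 = c(0.2, 0.5, 0.8),
                        tau0 = c(0.02, 0.05, 0.1, 0.3),
                        tau1 = c(0.5, 1, 2, 5),
                        c0 = if (offset) c(0, 0.3) else 0)
  if (offset) {
    lower <- c(lower, 0); upper <- c(upper, 0.95)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$a0[i], starts$tau0[i], starts$tau1[i],
            if (offset) starts$c0[i])
    fit <- tryCatch(stats::optim(p0, obj, method = "L-BFGS-B",
                                 lower = lower, upper = upper,
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    tau_slow <- max(fit$par[2], fit$par[3])
    if (is.null(best) || fit$value < best$value - 1e-14 ||
        (abs(fit$value - best$value) <= 1e-14 && tau_slow < best$tau_slow)) {
      best <- list(par = fit$par, value = fit$value, tau_slow = tau_slow)
    }
  }
  if (is.null(best)) .stopf("bi-exponential fit failed from every start")
  p <- best$par
  if (p[2] > p[3]) p[1:3] <- c(1 - p[1], p[3], p[2])
  degenerate <- p[3] >= 0.99 * tau_hi
  structure(list(a0 = p[1], tau0 = p[2], tau1 = p[3],
                 offset = if (offset) p[4] else 0,
                 fit_window = window,
                 residual_norm = sqrt(best$value / length(t)),
                 degenerate = degenerate),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("biexp_fit: %.3f exp(-t/%.4g ps) + %.3f exp(-t/%.4g ps)%s\n",
              x$a0, x$tau0, 1 - x$a0, x$tau1,
              if (isTRUE(x$degenerate)) "  [degenerate: no decay resolved]" else ""))
  invisible(x)
}

# two-column text output used by every correlation/spectrum writer
write_series_txt <- function(x, path, xname = "lag", yname = "value",
                             xunit = "", yunit = "") {
  hdr <- sprintf("# %s%s  %s%s", xname,
                 if (nzchar(xunit)) paste0(" [", xunit, "]") else "",
                 yname,
                 if (nzchar(yunit)) paste0(" [", yunit, "]") else "")
  df <- as.data.frame(x)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(df, digits = 10, scientific = TRUE, trim = TRUE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
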