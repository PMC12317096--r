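#' Joint frequency probability distribution
#'
#' Two-dimensional histogram of frequency pairs `(omega(s), omega(s + t2))`
#' over all oscillators and all admissible time origins, normalised to
#' total mass 1: the probability that a mode at `omega1` evolves to
#' `omega3` within the waiting time `t2`.  `t2` must be a multiple of the
#' sampling interval (no interpolation).
#'
#' @param freqs a [frequency_set()].
#' @param t2 waiting time, fs.
#' @param bin_width bin width, cm^-1 (default 10, matching the marginal
#'   distribution).
#' @param breaks optional explicit common breaks for both axes.
#' @return object of class `joint_distribution`: `omega1_bins`,
#'   `omega3_bins`, matrix `P` (omega1 rows, omega3 columns), `t2`,
#'   `bin_width`.
#' @export
joint_probability <- function(freqs, t2, bin_width = 10, breaks = NULL) {
  k <- t2 / freqs$dt
  if (abs(k - round(k)) > 1e-9)
    .stopf("t2 = %g fs is not a multiple of dt = %g fs (no interpolation)", t2, freqs$dt)
  k <- as.integer(round(k))
  om <- .valid_omega(freqs)
  n <- nrow(om)
  if (k >= n) .stopf("t2 exceeds the valid series span")
  w1 <- as.vector(om[seq_len(n - k), , drop = FALSE])
  w3 <- as.vector(om[seq_len(n - k) + k, , drop = FALSE])
  ok <- is.finite(w1) & is.finite(w3)
  w1 <- w1[ok]; w3 <- w3[ok]
  if (is.null(breaks)) breaks <- .freq_breaks(c(w1, w3), bin_width)
  nb <- length(breaks) - 1L
  i1 <- pmin(nb, pmax(1L, findInterval(w1, breaks, rightmost.closed = TRUE)))
  i3 <- pmin(nb, pmax(1L, findInterval(w3, breaks, rightmost.closed = TRUE)))
  P <- matrix(0, nb, nb)
  tab <- table(factor(i1, levels = seq_len(nb)), factor(i3, levels = seq_len(nb)))
  P[] <- as.numeric(tab) / length(w1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  structure(list(omega1_bins = mids, omega3_bins = mids, t2 = t2, P = P,
                 bin_width = diff(breaks)[1], breaks = breaks,
                 pair_correlation = if (stats::sd(w1) > 0 && stats::sd(w3) > 0)
                   stats::cor(w1, w3) else NA_real_),
            class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat(sprintf("joint_distribution: t2 = %g fs, %d x %d bins of %g cm^-1, pair correlation %.3f\n",
              x$t2, length(x$omega1_bins), length(x$omega3_bins),
              x$bin_width, x$pair_correlation))
  invisible(x)
}

#' Frequency-frequency time-correlation function
#'
#' `C(t) = < d_omega(s) d_omega(s+t) >` over oscillators and all time
#' origins, with fluctuations `d_omega` taken about each oscillator's own
#' time mean so static inter-oscillator inhomogeneity does not masquerade
#' as a frozen component.  With `normalized = TRUE` the series is divided
#' by its zero-lag value (the variance); a zero-variance input then
#' returns an all-zero series flagged `degenerate`.
#'
#' @param freqs a [frequency_set()].
#' @param max_lag largest lag in fs (default half the valid span).
#' @param normalized divide by `C(0)`.
#' @return a [correlation_series()] (lags fs, values cm^-2 if raw) with
#'   field `degenerate`.
#' @export
ftcf <- function(freqs, max_lag = NULL, normalized = TRUE) {
  om <- .valid_omega(freqs)
  n <- nrow(om)
  if (is.null(max_lag)) max_lag <- (n - 1) %/% 2 * freqs$dt
  lag_steps <- min(floor(max_lag / freqs$dt), n - 1L)
  dom <- sweep(om, 2, colMeans(om))
  cw <- .acf_columns(dom, lag_steps)
  degenerate <- cw[1] <= .Machine$double.eps * mean(om)^2
  if (normalized) {
    vals <- if (degenerate) rep(0, lag_steps + 1L) else cw / cw[1]
  } else vals <- cw
  out <- correlation_series(lags = (0:lag_steps) * freqs$dt, values = vals,
                            normalization = if (normalized && !degenerate)
                              "zero-lag" else "raw",
                            lag_unit = "fs")
  out$degenerate <- degenerate
  out$variance <- cw[1]
  out
}

#' Spectral-diffusion timescale from an FTCF
#'
#' Bi-exponential fit ([fit_biexponential()]) of a normalized FTCF on a
#' default window `[0, min(5 ps, max lag)]`; the slow constant `tau1` is
#' reported as the spectral-diffusion timescale (the fast one reflects the
#' initial librational-like decay).  When the slow component carries less
#' than 5% of the amplitude the decay is effectively single-exponential --
#' the nominal slow constant then only chases tail noise -- and `tau1` is
#' collapsed onto the dominant timescale (flagged `collapsed`).
#'
#' @param series a normalized [correlation_series()] (e.g. from [ftcf()]).
#' @param window optional `(t_min, t_max)` in ps.
#' @return a `biexp_fit`; `$tau1` is the spectral-diffusion time in ps.
#' @export
spectral_diffusion_time <- function(series, window = NULL) {
  s <- .series_in_unit(series, "ps")
  if (is.null(window)) window <- c(0, min(5, max(s$lags)))
  fit <- fit_biexponential(s, window)
  fit$collapsed <- FALSE
  if (1 - fit$a0 < 0.05) {
    fit$tau1 <- fit$tau0
    fit$collapsed <- TRUE
  }
  fit
}
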