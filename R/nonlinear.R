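# trapezoidal cumulative integral of the columns of x sampled at spacing dt
.cumtrapz <- function(x, dt) {
  x <- as.matrix(x)
  out <- apply(x, 2, function(v) c(0, cumsum((v[-1] + v[-length(v)]) / 2 * dt)))
  out
}

#' Third-order response functions of a two-level OH oscillator
#'
#' Rephasing and non-rephasing response functions of a fluctuating
#' two-level system in the Condon approximation with unit transition
#' dipole.  Per oscillator and time origin the frequency-fluctuation phase
#' is accumulated by trapezoidal integration over the coherence intervals
#' `[0, t1]` and `[t1+t2, t1+t2+t3]`; the phase factors
#' `exp(+- i phi1 - i phi3)` are ensemble-averaged and multiplied by the
#' mean-frequency carriers `exp(-i <w> t3 +- i <w> t1)`.  Fluctuations are
#' taken about the ensemble-mean frequency, so static inter-oscillator
#' inhomogeneity contributes to the (re)phasing dynamics as it must.
#'
#' @param freqs a [frequency_set()].
#' @param t2 waiting time, fs (multiple of the sampling interval).
#' @param t_max extent of the t1 and t3 grids, fs.
#' @param dt_r grid spacing, fs (multiple of the sampling interval).
#' @param t1_max,t3_max individual grid extents, both defaulting to
#'   `t_max` (a zero `t1_max` gives the linear-response slice alone).
#' @param origin_stride spacing of ensemble time origins, fs.
#' @param max_origins cap on the number of origins per oscillator.
#' @return object of class `response_grid`: complex matrices `R_rp`,
#'   `R_nr` and raw phase averages `phi_rp`, `phi_nr` over
#'   `(t1_grid, t3_grid)`, plus `t2`, `omega_mean` (cm^-1), `n_samples`.
#' @export
compute_response <- function(freqs, t2, t_max = 1000, dt_r = 2,
                             t1_max = t_max, t3_max = t_max,
                             origin_stride = 50, max_origins = 2000) {
  dts <- freqs$dt
  for (nm in c(t2 = t2, dt_r = dt_r)) if (abs(nm / dts - round(nm / dts)) > 1e-9)
    .stopf("t2 and dt_r must be multiples of the series dt (%g fs)", dts)
  om <- .valid_omega(freqs)
  if (any(!is.finite(om))) .stopf("non-finite frequencies in valid window")
  n <- nrow(om)
  omega_mean <- mean(om)
  dom_rad <- cm1_to_radfs(om - omega_mean)
  Iphase <- .cumtrapz(dom_rad, dts)

  i1 <- as.integer(round(seq(0, t1_max, by = dt_r) / dts))
  i3 <- as.integer(round(seq(0, t3_max, by = dt_r) / dts))
  i2 <- as.integer(round(t2 / dts))
  span <- max(i1) + i2 + max(i3)
  if (span >= n) .stopf("series too short: need %d frames, have %d", span + 1L, n)
  ostep <- max(1L, as.integer(round(origin_stride / dts)))
  origins <- seq(0L, n - 1L - span, by = ostep)
  if (length(origins) > max_origins)
    origins <- origins[round(seq(1, length(origins), length.out = max_origins))]
  av <- .phase_average_cpp(Iphase, as.integer(origins), i1, i2, i3)

  t1g <- i1 * dts; t3g <- i3 * dts
  wbar <- cm1_to_radfs(omega_mean)
  carrier_rp <- outer(exp(1i * wbar * t1g), exp(-1i * wbar * t3g))
  carrier_nr <- outer(exp(-1i * wbar * t1g), exp(-1i * wbar * t3g))
  structure(list(t1_grid = t1g, t3_grid = t3g, t2 = t2,
                 phi_rp = av$phi_rp, phi_nr = av$phi_nr,
                 R_rp = carrier_rp * av$phi_rp,
                 R_nr = carrier_nr * av$phi_nr,
                 mu10 = 1, omega_mean = omega_mean,
                 n_samples = length(origins) * ncol(om)),
            class = "response_grid")
}

#' @export
print.response_grid <- function(x, ...) {
  cat(sprintf("response_grid: t2 = %g fs, %d x %d (t1 x t3) points to %g fs, %d samples\n",
              x$t2, length(x$t1_grid), length(x$t3_grid), max(x$t1_grid), x$n_samples))
  invisible(x)
}

#' 2D-IR correlation spectrum
#'
#' Double Fourier transform of the rephasing and non-rephasing response
#' functions with opposite `t1` sign conventions, so both pathways map
#' onto positive `omega1`, and their sum taken real:
#' `S(omega1, t2, omega3) = Re[S_rp + S_nr]`.  The finite-grid integrals
#' are evaluated as trapezoid-weighted discrete transforms directly onto a
#' wavenumber grid centred on the carrier; `zero_pad` refines the output
#' grid below the bare `1/t_max` resolution exactly as zero padding would.
#'
#' @param resp a [compute_response()] result.
#' @param zero_pad grid-refinement factor.
#' @param omega_span half-width of the output axes about the mean
#'   frequency, cm^-1.
#' @return object of class `spectrum_2d`: `omega1_grid`, `omega3_grid`
#'   (cm^-1), real matrix `S` (omega1 rows), components `S_rp`, `S_nr`,
#'   `t2`.
#' @export
spectrum_2d <- function(resp, zero_pad = 4, omega_span = 400) {
  res_cm <- .freqfs_to_cm1(1 / max(resp$t1_grid)) / zero_pad
  w1 <- seq(resp$omega_mean - omega_span, resp$omega_mean + omega_span, by = res_cm)
  w3 <- w1
  t1 <- resp$t1_grid; t3 <- resp$t3_grid
  wt1 <- rep(diff(t1)[1], length(t1)); wt1[c(1, length(t1))] <- wt1[1] / 2
  wt3 <- rep(diff(t3)[1], length(t3)); wt3[c(1, length(t3))] <- wt3[1] / 2
  w1r <- cm1_to_radfs(w1); w3r <- cm1_to_radfs(w3)
  E1m <- exp(outer(-1i * w1r, t1)) * rep(wt1, each = length(w1))   # rephasing
  E1p <- exp(outer(+1i * w1r, t1)) * rep(wt1, each = length(w1))   # non-rephasing
  E3 <- exp(outer(+1i * w3r, t3)) * rep(wt3, each = length(w3))
  S_rp <- E1m %*% resp$R_rp %*% t(E3)
  S_nr <- E1p %*% resp$R_nr %*% t(E3)
  structure(list(omega1_grid = w1, omega3_grid = w3, t2 = resp$t2,
                 S = Re(S_rp + S_nr), S_rp = S_rp, S_nr = S_nr),
            class = "spectrum_2d")
}

#' @export
print.spectrum_2d <- function(x, ...) {
  cat(sprintf("spectrum_2d: t2 = %g fs, %d x %d grid, omega in [%.0f, %.0f] cm^-1\n",
              x$t2, length(x$omega1_grid), length(x$omega3_grid),
              min(x$omega1_grid), max(x$omega1_grid)))
  invisible(x)
}

#' Center-line slope of a 2D-IR peak
#'
#' For every `omega1` column whose maximum lies within the full width at
#' half maximum of the dominant positive peak, locates the `omega3` of
#' maximum signal and fits a least-squares line through those maxima; the
#' slope decays from ~1 (diagonally elongated, frequency memory intact)
#' towards 0 (round peak, memory lost) with waiting time, in proportion to
#' the normalized frequency correlation.
#'
#' @param spec a [spectrum_2d()].
#' @return the dimensionless slope.
#' @export
center_line_slope <- function(spec) {
  S <- spec$S
  peak <- max(S)
  if (peak <= 0) .stopf("no positive peak in spectrum")
  colmax <- apply(S, 1, max)
  sel <- which(colmax >= peak / 2)
  if (length(sel) < 3) .stopf("peak too narrow for a center-line fit")
  if (any(diff(sel) > 1))
    .warnf("multi-modal spectrum: FWHM region not contiguous, slope may be meaningless")
  d3 <- diff(spec$omega3_grid)[1]
  w3max <- vapply(sel, function(i) {
    row <- S[i, ]
    j <- which.max(row)
    if (j == 1 || j == length(row)) return(spec$omega3_grid[j])
    # sub-grid refinement: vertex of the parabola through the 3 top points
    num <- row[j - 1] - row[j + 1]
    den <- row[j - 1] - 2 * row[j] + row[j + 1]
    spec$omega3_grid[j] + if (abs(den) > 0) 0.5 * num / den * d3 else 0
  }, numeric(1))
  fit <- stats::lm.wfit(cbind(1, spec$omega1_grid[sel]), w3max, w = colmax[sel])
  unname(fit$coefficients[2])
}

#' Integrated photon-echo intensity and its short-time slope (S3PE)
#'
#' For each waiting time, integrates the squared modulus of the rephasing
#' response over the detection delay, `I(t1, t2) = int dt3 |R_rp|^2`
#' (trapezoid), and takes the two-point forward difference of `I` in `t1`
#' at `t1 = 0` as the echo peak-shift surrogate S3PE.  With
#' `normalize = TRUE` the S3PE series is scaled to 1 at the smallest
#' waiting time; a static oscillator (no fluctuation) gives an identically
#' zero slope, returned unnormalised and flagged.
#'
#' @param freqs a [frequency_set()].
#' @param t2_values waiting times, fs.
#' @param t1_max,t3_max grid extents, fs.
#' @param dt_r grid spacing, fs.
#' @param origin_stride,max_origins ensemble-averaging controls as in
#'   [compute_response()].
#' @param normalize scale S3PE to its value at the smallest t2.
#' @return object of class `echo_signal`: `t1_grid`, `t2_values`, matrix
#'   `I` (t1 rows, t2 columns), `s3pe`, `s3pe_raw`, `degenerate`.
#' @export
echo_intensity <- function(freqs, t2_values, t1_max = 200, t3_max = 400,
                           dt_r = 2, origin_stride = 50, max_origins = 2000,
                           normalize = TRUE) {
  t2_values <- sort(t2_values)
  t1g <- seq(0, t1_max, by = dt_r)
  Imat <- matrix(NA_real_, length(t1g), length(t2_values))
  for (j in seq_along(t2_values)) {
    resp <- compute_response(freqs, t2 = t2_values[j], dt_r = dt_r,
                             t1_max = t1_max, t3_max = t3_max,
                             origin_stride = origin_stride,
                             max_origins = max_origins)
    A2 <- Mod(resp$phi_rp)^2                  # carrier is unimodular
    t3 <- resp$t3_grid
    wt3 <- rep(diff(t3)[1], length(t3)); wt3[c(1, length(t3))] <- wt3[1] / 2
    Imat[, j] <- as.vector(A2 %*% wt3)
  }
  s3pe_raw <- (Imat[2, ] - Imat[1, ]) / dt_r
  degenerate <- abs(s3pe_raw[1]) < .Machine$double.eps * max(abs(Imat))
  s3pe <- if (normalize && !degenerate) s3pe_raw / s3pe_raw[1] else s3pe_raw
  structure(list(t1_grid = t1g, t2_values = t2_values, I = Imat,
                 s3pe = s3pe, s3pe_raw = s3pe_raw, degenerate = degenerate,
                 normalized = normalize && !degenerate),
            class = "echo_signal")
}

#' @export
print.echo_signal <- function(x, ...) {
  cat(sprintf("echo_signal: %d waiting times in [%g, %g] fs, S3PE %s\n",
              length(x$t2_values), min(x$t2_values), max(x$t2_values),
              if (x$degenerate) "identically zero (static input)"
              else if (x$normalized) "normalized to 1 at smallest t2" else "raw"))
  invisible(x)
}

#' Linear absorption lineshape from the response module
#'
#' Cosine transform of the `t1 = 0` slice of the rephasing response at
#' zero waiting time -- the linear-response (free-induction-decay) limit of
#' the third-order machinery.  For an Ornstein-Uhlenbeck frequency process
#' this must reproduce the analytic Kubo lineshape
#' `g(t) = Delta^2 tau_c^2 (exp(-t/tau_c) - 1 + t/tau_c)`.
#'
#' @param freqs a [frequency_set()].
#' @param t_max FID length, fs.
#' @param dt_r sampling, fs.
#' @param omega_span,d_omega output grid half-width and spacing, cm^-1.
#' @param origin_stride,max_origins averaging controls.
#' @return object of class `spectral_density` (grid in cm^-1).
#' @export
linear_lineshape <- function(freqs, t_max = 2000, dt_r = NULL,
                             omega_span = 400, d_omega = 1,
                             origin_stride = 50, max_origins = 4000) {
  if (is.null(dt_r)) dt_r <- freqs$dt
  resp <- compute_response(freqs, t2 = 0, dt_r = dt_r,
                           t1_max = 0, t3_max = t_max,
                           origin_stride = origin_stride,
                           max_origins = max_origins)
  J <- resp$R_rp[1, ]                       # t1 = 0 slice: exp(-i w t3) <phi>
  t3 <- resp$t3_grid
  wgrid <- seq(resp$omega_mean - omega_span, resp$omega_mean + omega_span,
               by = d_omega)
  wr <- cm1_to_radfs(wgrid)
  wt <- rep(diff(t3)[1], length(t3)); wt[c(1, length(t3))] <- wt[1] / 2
  spec <- Re(exp(outer(1i * wr, t3)) %*% (J * wt))[, 1]
  structure(list(omega = wgrid, intensity = spec, resolution = d_omega,
                 omega_mean = resp$omega_mean),
            class = "spectral_density")
}

#' Analytic Kubo absorption lineshape
#'
#' Closed-form reference for a Gaussian-Markov (Ornstein-Uhlenbeck)
#' frequency process: `I(omega) = Re int_0^inf exp(i (omega - w0) t - g(t)) dt`
#' with `g(t) = Delta^2 tau_c^2 (exp(-t/tau_c) - 1 + t/tau_c)`.
#'
#' @param omega_grid output grid, cm^-1.
#' @param omega_mean process mean, cm^-1.
#' @param delta stationary standard deviation, cm^-1.
#' @param tau_c correlation time, fs.
#' @param t_max,dt integration extent and step, fs.
#' @return object of class `spectral_density`.
#' @export
kubo_lineshape <- function(omega_grid, omega_mean, delta, tau_c,
                           t_max = 20 * tau_c, dt = NULL) {
  if (is.null(dt)) dt <- min(tau_c / 20, t_max / 2000)
  t <- seq(0, t_max, by = dt)
  D <- cm1_to_radfs(delta)
  g <- D^2 * tau_c^2 * (exp(-t / tau_c) - 1 + t / tau_c)
  wr <- cm1_to_radfs(omega_grid - omega_mean)
  wt <- rep(dt, length(t)); wt[c(1, length(t))] <- dt / 2
  spec <- Re(exp(outer(1i * wr, t)) %*% (exp(-g) * wt))[, 1]
  structure(list(omega = omega_grid, intensity = spec,
                 resolution = diff(omega_grid)[1]),
            class = "spectral_density")
}
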