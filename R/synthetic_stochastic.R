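#' Ornstein-Uhlenbeck frequency-process configuration
#'
#' Stochastic stand-in for instantaneous OH-stretch frequency trajectories:
#' a stationary Gaussian process with mean `omega_mean`, standard deviation
#' `delta` and exponential memory `tau_c`.  Because its frequency
#' correlation function is exactly `delta^2 exp(-t/tau_c)` (the Kubo
#' model), it is the analytic oracle for every spectroscopy stage.
#'
#' @param omega_mean mean frequency, cm^-1.
#' @param delta stationary standard deviation, cm^-1.
#' @param tau_c correlation time, fs.
#' @param dt sampling interval, fs.
#' @param n_steps number of steps (series has `n_steps + 1` samples).
#' @param n_oscillators number of independent oscillators.
#' @param seed integer seed.
#' @return object of class `ou_config`.
#' @export
ou_config <- function(omega_mean = 3500, delta = 50, tau_c = 500,
                      dt = 2, n_steps = 25000, n_oscillators = 200,
                      seed = 1L) {
  if (delta < 0) .stopf("delta must be >= 0")
  if (tau_c <= 0) .stopf("tau_c must be positive")
  if (dt <= 0 || n_steps < 1 || n_oscillators < 1) .stopf("invalid OU config")
  structure(as.list(environment()), class = "ou_config")
}

#' A set of per-oscillator frequency trajectories
#'
#' Common container for instantaneous frequencies, either generated
#' ([generate_ou_frequencies()]) or extracted from dynamics
#' ([wavelet_frequencies()] via [frequency_set()]).  `omega` is a
#' `(time x oscillator)` matrix in cm^-1; `valid_range` marks the
#' edge-trimmed index window within which every column is reliable.
#'
#' @param omega numeric matrix, time by oscillator, cm^-1.
#' @param dt sampling interval, fs.
#' @param bond_ids optional oscillator labels.
#' @param valid_range index pair; defaults to the full range.
#' @return object of class `frequency_set`.
#' @export
frequency_set <- function(omega, dt, bond_ids = NULL, valid_range = NULL) {
  omega <- as.matrix(omega)
  if (is.null(valid_range)) valid_range <- c(1L, nrow(omega))
  if (is.null(bond_ids)) bond_ids <- paste0("osc", seq_len(ncol(omega)))
  structure(list(omega = omega, dt = dt, bond_ids = bond_ids,
                 valid_range = as.integer(valid_range)),
            class = "frequency_set")
}

#' @export
print.frequency_set <- function(x, ...) {
  v <- x$valid_range
  cat(sprintf("frequency_set: %d oscillators x %d samples (dt = %g fs), valid [%d, %d], mean %.1f cm^-1\n",
              ncol(x$omega), nrow(x$omega), x$dt, v[1], v[2],
              mean(x$omega[v[1]:v[2], ])))
  invisible(x)
}

# valid-window slice of the frequency matrix
.valid_omega <- function(fs) fs$omega[fs$valid_range[1]:fs$valid_range[2], , drop = FALSE]

#' Generate exact Ornstein-Uhlenbeck frequency trajectories
#'
#' Uses the exact discrete update
#' `omega(t+dt) = mean + (omega(t) - mean) rho + delta sqrt(1 - rho^2) xi`
#' with `rho = exp(-dt/tau_c)` and standard-normal `xi`, initialised from
#' the stationary distribution, so samples are exact at any `dt`.
#'
#' @param config an [ou_config()].
#' @return a [frequency_set()].
#' @export
generate_ou_frequencies <- function(config = ou_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_steps + 1L
  m <- cfg$n_oscillators
  rho <- exp(-cfg$dt / cfg$tau_c)
  sig <- cfg$delta * sqrt(1 - rho^2)
  omega <- matrix(NA_real_, n, m)
  omega[1, ] <- cfg$omega_mean + cfg$delta * stats::rnorm(m)
  if (n > 1) {
    xi <- matrix(stats::rnorm((n - 1L) * m), n - 1L, m)
    for (k in 2:n)
      omega[k, ] <- cfg$omega_mean + (omega[k - 1, ] - cfg$omega_mean) * rho +
        sig * xi[k - 1L, ]
  }
  frequency_set(omega, dt = cfg$dt)
}

#' Generate 1-D Brownian motion along z
#'
#' Independent Gaussian increments of variance `2 D dt` per particle along
#' z (x and y fixed); the analytic oracle for the MSD/diffusion stage.
#'
#' @param D diffusion coefficient, 1e-10 m^2/s.
#' @param dt timestep, fs.
#' @param n_steps number of steps.
#' @param n_particles number of independent particles.
#' @param seed integer seed.
#' @return a [wire_trajectory()] of non-bonded "O" atoms with z already
#'   continuous (`unwrapped = "z"`).
#' @export
generate_brownian_z <- function(D, dt = 0.5, n_steps = 40000,
                                n_particles = 125, seed = 1L) {
  if (D < 0) .stopf("D must be >= 0")
  set.seed(seed)
  D_int <- diffusion_SI_to_A2fs(D)
  sd_step <- sqrt(2 * D_int * dt)
  n <- n_particles
  nf <- n_steps + 1L
  pos <- array(0, c(n, 3, nf))
  pos[, 1, ] <- rep(seq(5, by = 5, length.out = n), nf)
  pos[, 2, ] <- 5
  z0 <- rep(0, n)
  incr <- matrix(stats::rnorm(n * n_steps, sd = sd_step), n, n_steps)
  pos[, 3, ] <- cbind(z0, t(apply(incr, 1, cumsum)) + z0)
  top <- wire_topology(rep("O", n), seq_len(n), matrix(integer(), ncol = 2))
  wire_trajectory(top, pos, NULL, dt = dt,
                  box = c(5 * n + 5, 10, 1000), periodic_axes = "z",
                  unwrapped = "z")
}

#' Generate isotropic rotational diffusion of unit vectors
#'
#' Each unit vector is rotated every step about a random axis perpendicular
#' to it by a Gaussian angle of variance `4 D_r dt`.  The tangential
#' displacement spreads over the two perpendicular directions on the
#' sphere, giving `2 D_r dt` per direction -- exactly isotropic rotational
#' diffusion with constant `D_r`, whose second-rank orientational
#' correlation is `exp(-6 D_r t)`, the oracle for [compute_c2()].
#'
#' @param D_r rotational diffusion constant, 1/ps.
#' @param dt timestep, fs; `D_r * dt` must stay below 0.1 ps/ps.
#' @param n_steps number of steps.
#' @param n_vectors ensemble size.
#' @param seed integer seed.
#' @return object of class `vector_series`: unit vectors
#'   `(n_vectors x 3 x n_steps + 1)` plus `dt`.
#' @export
generate_rotational_diffusion <- function(D_r, dt = 2, n_steps = 2500,
                                          n_vectors = 500, seed = 1L) {
  if (D_r < 0) .stopf("D_r must be >= 0")
  Ddt <- D_r * dt / 1000
  if (Ddt > 0.1) .stopf("dt * D_r = %.3g exceeds 0.1; reduce dt", Ddt)
  set.seed(seed)
  n <- n_vectors
  e <- matrix(stats::rnorm(3 * n), n, 3)
  e <- e / sqrt(rowSums(e^2))
  out <- array(NA_real_, c(n, 3, n_steps + 1L))
  out[, , 1] <- e
  sd_ang <- sqrt(4 * Ddt)
  for (k in seq_len(n_steps)) {
    u <- matrix(stats::rnorm(3 * n), n, 3)
    a <- u - rowSums(u * e) * e                 # perpendicular component
    a <- a / sqrt(rowSums(a^2))
    phi <- stats::rnorm(n, sd = sd_ang)
    axe <- cbind(a[, 2] * e[, 3] - a[, 3] * e[, 2],
                 a[, 3] * e[, 1] - a[, 1] * e[, 3],
                 a[, 1] * e[, 2] - a[, 2] * e[, 1])
    e <- cos(phi) * e + sin(phi) * axe
    e <- e / sqrt(rowSums(e^2))
    out[, , k + 1L] <- e
  }
  structure(list(vectors = out, dt = dt), class = "vector_series")
}
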