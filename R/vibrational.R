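#' Vibrational density of states
#'
#' Fourier transform of the per-atom velocity autocorrelation function,
#' averaged over atoms and all time origins and cosine-transformed over
#' `[-max_lag, max_lag]` with no apodization window.  Velocities enter
#' unweighted (no mass weighting).  The output grid runs from 0 to the
#' Nyquist limit of the trajectory timestep with one point per resolution
#' element `1/(2 max_lag)`.
#'
#' @param traj a [wire_trajectory()] with velocities.
#' @param max_lag correlation length, fs (default 2000).
#' @param atoms index vector (default all atoms).
#' @return object of class `spectral_density`: `omega` (cm^-1),
#'   `intensity` (arbitrary units, modulus convention), `resolution`
#'   (cm^-1).
#' @export
compute_vdos <- function(traj, max_lag = 2000, atoms = NULL) {
  if (is.null(traj$velocities)) .stopf("velocity-free trajectory: VDOS unavailable")
  if (is.null(atoms)) atoms <- seq_len(n_atoms(traj$topology))
  nf <- n_frames(traj)
  lag_steps <- min(floor(max_lag / traj$dt), nf - 1L)
  vacf <- numeric(lag_steps + 1L)
  for (ax in 1:3) {
    v <- matrix(traj$velocities[atoms, ax, , drop = FALSE],
                nrow = length(atoms))
    vacf <- vacf + .acf_columns(t(v), lag_steps)
  }
  tlag <- (0:lag_steps) * traj$dt
  res_cm <- .freqfs_to_cm1(1 / (2 * max(tlag)))
  nyq_cm <- .freqfs_to_cm1(1 / (2 * traj$dt))
  omega <- seq(0, nyq_cm, by = res_cm)
  w_rad <- cm1_to_radfs(omega)
  # 2 * int_0^tau C(t) cos(wt) dt, trapezoid, no window
  wts <- rep(traj$dt, lag_steps + 1L); wts[c(1, lag_steps + 1L)] <- traj$dt / 2
  intensity <- abs(2 * (cos(outer(w_rad, tlag)) %*% (vacf * wts))[, 1])
  structure(list(omega = omega, intensity = intensity, resolution = res_cm),
            class = "spectral_density")
}

#' @export
as.data.frame.spectral_density <- function(x, ...)
  data.frame(omega = x$omega, intensity = x$intensity)

#' Complex OH-bond fluctuation signal
#'
#' For one O-H bond builds the time series entering the wavelet transform:
#' `dr`, the fluctuation of the minimum-image O-H distance about its time
#' mean; `dp`, the fluctuation of the reduced-mass-weighted relative
#' velocity projected on the O->H unit vector; and the complex signal
#' `f(t) = dr + i dp / (mu_OH * omega_ref)`.  The momentum scaling (default
#' reference 3500 cm^-1) gives both parts length units, so harmonic motion
#' traces a circle in the complex plane and the wavelet ridge is sharpest.
#'
#' @param traj a [wire_trajectory()] with velocities.
#' @param bond_id row index into `topology$oh_bonds`, or an `(O, H)` pair.
#' @param omega_ref momentum-scaling reference frequency, cm^-1.
#' @return object of class `bond_series` with fields `dr` (A), `dp`
#'   (amu A/fs), `f` (complex, A), `dt`, `bond_id`.
#' @export
build_bond_series <- function(traj, bond_id, omega_ref = 3500) {
  if (is.null(traj$velocities)) .stopf("velocity-free trajectory: bond series unavailable")
  bonds <- traj$topology$oh_bonds
  if (length(bond_id) == 1) {
    if (bond_id < 1 || bond_id > nrow(bonds)) .stopf("bond_id out of range")
    oh <- bonds[bond_id, ]
  } else {
    row <- which(bonds[, 1] == bond_id[1] & bonds[, 2] == bond_id[2])
    if (!length(row)) .stopf("bond (%d, %d) not in topology", bond_id[1], bond_id[2])
    oh <- bonds[row, ]
  }
  o <- oh[1]; h <- oh[2]
  d <- traj$positions[h, , ] - traj$positions[o, , ]          # 3 x nf
  for (ax in .axis_index(traj$periodic_axes)) {
    L <- traj$box[ax]
    d[ax, ] <- d[ax, ] - L * round(d[ax, ] / L)
  }
  r <- sqrt(colSums(d^2))
  u <- d / rep(r, each = 3)
  vrel <- traj$velocities[h, , ] - traj$velocities[o, , ]
  mu <- prod(traj$topology$masses[c(o, h)]) / sum(traj$topology$masses[c(o, h)])
  p <- mu * colSums(vrel * u)
  dr <- r - mean(r)
  dp <- p - mean(p)
  f <- complex(real = dr, imaginary = dp / (mu * cm1_to_radfs(omega_ref)))
  structure(list(bond_id = unname(oh), dr = dr, dp = dp, f = f, dt = traj$dt,
                 omega_ref = omega_ref),
            class = "bond_series")
}

# Morlet CWT modulus with scales mapped by omega = omega0 / s, so a
# monochromatic signal peaks exactly at its own frequency.  Handles both
# rotation senses by analysing f and Conj(f) and keeping the larger
# modulus.  Returns the ridge (argmax scale) per time point.
.morlet_ridge <- function(f, dt, omega_grid_cm, omega0) {
  n <- length(f)
  scales <- omega0 / cm1_to_radfs(omega_grid_cm)
  nfft <- stats::nextn(n, 2)
  wk <- 2 * pi * c(0:(nfft %/% 2), -((nfft - nfft %/% 2 - 1):1)) / (nfft * dt)
  pos <- wk > 0
  fh1 <- stats::fft(c(f, numeric(nfft - n)))
  fh2 <- stats::fft(c(Conj(f), numeric(nfft - n)))
  best_mod <- rep(-Inf, n)
  ridge <- integer(n)
  for (j in seq_along(scales)) {
    win <- numeric(nfft)
    win[pos] <- exp(-0.5 * (scales[j] * wk[pos] - omega0)^2)
    w1 <- stats::fft(fh1 * win, inverse = TRUE)[seq_len(n)]
    w2 <- stats::fft(fh2 * win, inverse = TRUE)[seq_len(n)]
    m <- pmax(Mod(w1), Mod(w2))
    sel <- m > best_mod
    ridge[sel] <- j
    best_mod[sel] <- m[sel]
  }
  list(ridge = ridge, scales = scales)
}

#' Instantaneous OH frequency by continuous wavelet transform
#'
#' Morlet continuous wavelet transform of the complex bond signal on a
#' log-spaced frequency (scale) grid; at each time point the ridge -- the
#' scale of maximum modulus -- gives the instantaneous frequency.  Edges
#' are trimmed by one wavelet support (4 Gaussian widths of the largest
#' scale) on each side; only the `valid_range` window should be consumed
#' downstream.
#'
#' @param series a [build_bond_series()] result, or any complex vector with
#'   attributes lost (then `dt` must be given).
#' @param omega_range frequency search window `c(min, max)`, cm^-1; must
#'   lie below the Nyquist limit.
#' @param n_scales number of log-spaced grid points.
#' @param wavelet_width Morlet dimensionless width parameter (default 6).
#' @param dt sampling interval, fs (taken from `series` when available).
#' @return object of class `frequency_trajectory`: `omega` (cm^-1 per
#'   frame; `NA` outside `valid_range`), `dt`, `valid_range`, `bond_id`,
#'   `support_fs`.
#' @export
wavelet_frequencies <- function(series, omega_range = c(2800, 4300),
                                n_scales = 128, wavelet_width = 6,
                                dt = NULL) {
  if (inherits(series, "bond_series")) {
    f <- series$f; dt <- series$dt; bond_id <- series$bond_id
  } else {
    f <- as.complex(series); bond_id <- NA
    if (is.null(dt)) .stopf("dt required for a bare signal")
  }
  nyq_cm <- .freqfs_to_cm1(1 / (2 * dt))
  if (omega_range[2] > nyq_cm)
    .stopf("omega_range exceeds the Nyquist limit (%.0f cm^-1)", nyq_cm)
  grid <- exp(seq(log(omega_range[1]), log(omega_range[2]), length.out = n_scales))
  # need at least 4 periods of the slowest frequency
  min_period_fs <- 1 / (.c_cm_fs * omega_range[1])
  if (length(f) * dt < 4 * min_period_fs) .stopf("series too short for omega_range")
  cw <- .morlet_ridge(f, dt, grid, wavelet_width)
  omega <- grid[cw$ridge]
  s_max <- max(cw$scales)
  trim <- ceiling(4 * s_max / dt)
  n <- length(f)
  if (2 * trim + 4 > n) .stopf("series too short after edge trimming")
  valid <- as.integer(c(trim + 1L, n - trim))
  omega[seq_len(trim)] <- NA
  omega[(n - trim + 1L):n] <- NA
  structure(list(bond_id = bond_id, omega = omega, dt = dt,
                 valid_range = valid, grid = grid,
                 support_fs = 4 * s_max),
            class = "frequency_trajectory")
}

#' Stack frequency trajectories into a frequency_set
#'
#' Combines per-bond [wavelet_frequencies()] results into the common
#' container used by the distribution, correlation and response stages,
#' trimming all series to the intersection of their valid ranges.
#'
#' @param trajs list of `frequency_trajectory` objects with equal `dt` and
#'   length.
#' @param bond_ids optional labels.
#' @return a [frequency_set()].
#' @export
stack_frequencies <- function(trajs, bond_ids = NULL) {
  stopifnot(length(trajs) >= 1)
  dt <- trajs[[1]]$dt
  lo <- max(vapply(trajs, function(x) x$valid_range[1], integer(1)))
  hi <- min(vapply(trajs, function(x) x$valid_range[2], integer(1)))
  if (hi <= lo) .stopf("no common valid window across bonds")
  omega <- vapply(trajs, function(x) x$omega[lo:hi], numeric(hi - lo + 1L))
  if (is.null(bond_ids))
    bond_ids <- vapply(seq_along(trajs), function(i) {
      b <- trajs[[i]]$bond_id
      if (all(is.na(b))) paste0("osc", i) else paste0("O", b[1], "-H", b[2])
    }, character(1))
  frequency_set(omega, dt = dt, bond_ids = bond_ids)
}

# shared binning so joint distributions and marginals use identical breaks
.freq_breaks <- function(x, bin_width) {
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  seq(lo, hi, by = bin_width)
}

#' Time-averaged OH frequency distribution
#'
#' Normalised histogram of instantaneous frequencies over all selected
#' oscillators and valid times (frames weighted equally), default bin
#' width 10 cm^-1.
#'
#' @param freqs a [frequency_set()].
#' @param bin_width bin width, cm^-1.
#' @param subset `"all"` or a logical/integer column selector (e.g. the
#'   OH1 members of a [classify_oh_modes()] labelling).
#' @param breaks optional explicit bin breaks (overrides `bin_width`
#'   placement; used for cross-consistency with [joint_probability()]).
#' @return object of class `frequency_distribution`: `bin_centers`,
#'   `probability`, `bin_width`, `subset`, `mean_omega`, `sd_omega`.
#' @export
frequency_distribution <- function(freqs, bin_width = 10, subset = "all",
                                   breaks = NULL) {
  om <- .valid_omega(freqs)
  if (!identical(subset, "all")) om <- om[, subset, drop = FALSE]
  x <- om[is.finite(om)]
  if (!length(x)) .stopf("empty subset selection")
  if (is.null(breaks)) breaks <- .freq_breaks(x, bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(list(bin_centers = h$mids, probability = h$counts / length(x),
                 bin_width = diff(breaks)[1],
                 subset = if (identical(subset, "all")) "all" else "subset",
                 mean_omega = mean(x), sd_omega = stats::sd(x)),
            class = "frequency_distribution")
}

#' @export
as.data.frame.frequency_distribution <- function(x, ...)
  data.frame(omega = x$bin_centers, probability = x$probability)

#' @export
print.frequency_distribution <- function(x, ...) {
  cat(sprintf("frequency_distribution (%s): mean %.1f cm^-1, sd %.1f, %d bins of %g cm^-1\n",
              x$subset, x$mean_omega, x$sd_omega, length(x$bin_centers), x$bin_width))
  invisible(x)
}

#' Label OH bonds as donating (OH1) or free (OH2)
#'
#' For every hydrogen-bonded O...O pair in every frame, the donating
#' hydrogen is the H of either oxygen that is nearest to the partner
#' oxygen with an H...O distance at or below `cutoff_HO` (default
#' 2.45 A) -- a donor-identification layer on top of the distance-only
#' O...O bond rule, which alone cannot name which H donates.  Each OH
#' bond's donation fraction is its share of frames with such an event; in
#' each molecule the bond with the larger fraction is labelled OH1
#' (hydrogen-bond donating) and its sibling OH2, and molecules whose
#' bonds never donate have both labelled OH2.
#'
#' @param traj a [wire_trajectory()].
#' @param hb an `hb_stats` from [detect_hbonds()] on the same trajectory.
#' @param cutoff_HO donor H...O criterion, A.
#' @return object of class `oh_labels`: factor `label` (`"OH1"`/`"OH2"`)
#'   per topology OH bond, numeric `donation_fraction`, and the molecule
#'   index of each bond.
#' @export
classify_oh_modes <- function(traj, hb, cutoff_HO = 2.45) {
  top <- traj$topology
  bonds <- top$oh_bonds
  nb <- nrow(bonds)
  nf <- n_frames(traj)
  don <- numeric(nb)
  per_ax <- .axis_index(traj$periodic_axes)
  mi_dist <- function(i, j, frames) {
    d <- traj$positions[i, , frames, drop = FALSE] -
      traj$positions[j, , frames, drop = FALSE]
    d <- array(d, c(3, length(frames)))
    for (ax in per_ax) {
      L <- traj$box[ax]
      d[ax, ] <- d[ax, ] - L * round(d[ax, ] / L)
    }
    sqrt(colSums(d^2))
  }
  for (p in seq_len(ncol(hb$bond_matrix))) {
    frames <- which(hb$bond_matrix[, p])
    if (!length(frames)) next
    oa <- hb$pair_table[p, 1]; ob <- hb$pair_table[p, 2]
    for (dir in list(c(oa, ob), c(ob, oa))) {
      donor <- dir[1]; acceptor <- dir[2]
      brows <- which(bonds[, 1] == donor)
      if (length(brows) != 2) next
      d1 <- mi_dist(bonds[brows[1], 2], acceptor, frames)
      d2 <- mi_dist(bonds[brows[2], 2], acceptor, frames)
      first_nearer <- d1 <= d2
      don[brows[1]] <- don[brows[1]] + sum(first_nearer & d1 <= cutoff_HO)
      don[brows[2]] <- don[brows[2]] + sum(!first_nearer & d2 <= cutoff_HO)
    }
  }
  frac <- don / nf
  mol <- top$molecule_index[bonds[, 1]]
  label <- rep("OH2", nb)
  for (m in unique(mol)) {
    rows <- which(mol == m)
    if (max(frac[rows]) > 0) {
      oh1 <- rows[which.max(frac[rows])]
      label[oh1] <- "OH1"
    }
  }
  structure(list(label = factor(label, levels = c("OH1", "OH2")),
                 donation_fraction = frac, molecule = mol,
                 cutoff_HO = cutoff_HO),
            class = "oh_labels")
}

#' @export
print.oh_labels <- function(x, ...) {
  cat(sprintf("oh_labels: %d OH1 (donating), %d OH2 (free) of %d bonds\n",
              sum(x$label == "OH1"), sum(x$label == "OH2"), length(x$label)))
  invisible(x)
}

#' Intramolecular OH frequency asymmetry
#'
#' Mean instantaneous frequency of the hydrogen-bond-donating (OH1) and
#' free (OH2) subsets and their signed difference
#' `gamma = mean(OH1) - mean(OH2)`; a red-shifted donating OH gives a
#' negative `gamma`, and magnitudes are what is usually quoted.
#'
#' @param freqs a [frequency_set()] whose columns follow the topology bond
#'   order.
#' @param labels an `oh_labels` from [classify_oh_modes()].
#' @return object of class `asymmetry_result` with `mean_omega_OH1`,
#'   `mean_omega_OH2`, `gamma` (cm^-1).
#' @export
asymmetry <- function(freqs, labels) {
  om <- .valid_omega(freqs)
  if (ncol(om) != length(labels$label))
    .stopf("frequency set has %d columns but %d labels", ncol(om), length(labels$label))
  m1 <- om[, labels$label == "OH1", drop = FALSE]
  m2 <- om[, labels$label == "OH2", drop = FALSE]
  if (!ncol(m1)) .stopf("no OH1-labelled bonds")
  if (!ncol(m2)) .stopf("no OH2-labelled bonds")
  mu1 <- mean(m1[is.finite(m1)]); mu2 <- mean(m2[is.finite(m2)])
  structure(list(mean_omega_OH1 = mu1, mean_omega_OH2 = mu2,
                 gamma = mu1 - mu2),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf("asymmetry: OH1 %.1f, OH2 %.1f, gamma = %.1f cm^-1 (|gamma| = %.1f)\n",
              x$mean_omega_OH1, x$mean_omega_OH2, x$gamma, abs(x$gamma)))
  invisible(x)
}
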