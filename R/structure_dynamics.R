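#' Pair distribution function
#'
#' Distance histogram over all frames and unordered A-B pairs (minimum
#' image on periodic axes), normalised per frame by the ideal-gas shell
#' count `4 pi r^2 dr * N_B / V` per A site, so a uniform gas gives
#' `g(r) = 1`.  For the quasi-1D systems this full-box normalisation only
#' scales the curve; peak positions, the interpreted feature, are
#' normalisation-independent (see the methods vignette).
#'
#' @param traj a [wire_trajectory()].
#' @param pair_spec length-2 character: element symbols of species A and B,
#'   e.g. `c("O", "O")`; selections may also be index vectors in a list.
#' @param r_max histogram range, A; must not exceed half the smallest box
#'   edge over the periodic axes.
#' @param dr bin width, A.
#' @param frame_stride analyse every `frame_stride`-th frame.
#' @return object of class `pair_distribution` with bin centers `r` and
#'   values `g`.
#' @export
compute_rdf <- function(traj, pair_spec = c("O", "O"), r_max = NULL, dr = 0.05,
                        frame_stride = 1L) {
  sel <- function(sp) {
    if (is.character(sp)) which(traj$topology$atom_labels == sp) else as.integer(sp)
  }
  ia <- sel(pair_spec[[1]]); ib <- sel(pair_spec[[2]])
  if (!length(ia) || !length(ib)) .stopf("empty species selection")
  per_ax <- .axis_index(traj$periodic_axes)
  if (is.null(r_max)) {
    r_max <- if (length(per_ax)) min(traj$box[per_ax]) / 2 else min(traj$box) / 2
  }
  if (length(per_ax) && r_max > min(traj$box[per_ax]) / 2 + 1e-9)
    .stopf("r_max exceeds half the smallest periodic box edge")
  same <- identical(sort(ia), sort(ib))
  frames <- seq(1, n_frames(traj), by = frame_stride)
  nbin <- ceiling(r_max / dr)
  counts <- numeric(nbin)
  for (k in frames) {
    p <- traj$positions[, , k]
    pa <- p[ia, , drop = FALSE]; pb <- p[ib, , drop = FALSE]
    d <- .cross_dist(pa, pb, traj$box, per_ax)
    if (same) d[lower.tri(d, diag = TRUE)] <- NA
    else d[outer(ia, ib, "==")] <- NA
    dd <- d[!is.na(d) & d < r_max]
    if (length(dd)) {
      h <- tabulate(pmin(nbin, floor(dd / dr) + 1L), nbins = nbin)
      counts <- counts + h
    }
  }
  r <- (seq_len(nbin) - 0.5) * dr
  V <- prod(traj$box)
  n_pairs_ideal <- if (same) length(ia) * (length(ia) - 1) / 2 else length(ia) * length(ib)
  shell <- 4 * pi * r^2 * dr / V
  g <- counts / (length(frames) * n_pairs_ideal * shell)
  structure(list(r = r, g = g, pair_spec = pair_spec, dr = dr,
                 normalization = "full-box ideal density"),
            class = "pair_distribution")
}

#' @export
as.data.frame.pair_distribution <- function(x, ...) data.frame(r = x$r, g = x$g)

# all-pairs minimum-image distance matrix between two coordinate sets
.cross_dist <- function(a, b, box, per_ax) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (ax in 1:3) {
    dd <- outer(a[, ax], b[, ax], "-")
    if (ax %in% per_ax) {
      L <- box[ax]
      dd <- dd - L * round(dd / L)
    }
    d2 <- d2 + dd^2
  }
  sqrt(d2)
}

#' Axial mean-square displacement
#'
#' `MSD(t) = < (z_i(s+t) - z_i(s))^2 >` averaged over the selected atoms
#' and over all time origins `s` (FFT algorithm), with lags limited to
#' half the run.  The trajectory must already be continuous along z
#' ([unwrap_axis()]); a jump heuristic warns otherwise.
#'
#' @param traj a [wire_trajectory()].
#' @param subject `"water_oxygens"` (molecular-translation proxy),
#'   `"all"` (the formula's sum over all wire atoms), an integer index
#'   vector, or `"auto"` (default): water oxygens when the topology has
#'   them, otherwise all atoms.
#' @return a [correlation_series()] of MSD values in A^2 against lag (fs).
#' @export
compute_msd_z <- function(traj, subject = "auto") {
  if (identical(subject, "auto"))
    subject <- if (length(traj$topology$water_oxygens)) "water_oxygens" else "all"
  idx <- switch(as.character(subject[1]),
                water_oxygens = traj$topology$water_oxygens,
                all = seq_len(n_atoms(traj$topology)),
                as.integer(subject))
  if (!length(idx)) .stopf("empty atom selection")
  z <- traj$positions[idx, 3, , drop = TRUE]
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (!"z" %in% traj$unwrapped && "z" %in% traj$periodic_axes) {
    jump <- max(abs(z[, -1, drop = FALSE] - z[, -ncol(z), drop = FALSE]))
    if (jump > traj$box[3] / 2)
      .warnf("z looks wrapped (max frame-to-frame jump %.1f A); unwrap_axis() first", jump)
  }
  nf <- ncol(z)
  max_lag <- nf %/% 2
  msd <- .msd_fft(t(z), max_lag)
  correlation_series(lags = (0:max_lag) * traj$dt, values = msd,
                     normalization = "raw", lag_unit = "fs")
}

# standard FFT MSD over all origins; x is time x particles
.msd_fft <- function(x, max_lag) {
  n <- nrow(x)
  lags <- 0:max_lag
  acc <- numeric(max_lag + 1L)
  nfft <- stats::nextn(2L * n, 2)
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    sq <- xj^2
    f <- stats::fft(c(xj, numeric(nfft - n)))
    s2 <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(max_lag + 1L)] / nfft
    s1 <- numeric(max_lag + 1L)
    s1[1] <- 2 * sum(sq)
    for (k in seq_len(max_lag))
      s1[k + 1L] <- s1[k] - sq[k] - sq[n - k + 1L]
    acc <- acc + (s1 - 2 * s2) / (n - lags)
  }
  pmax(acc / ncol(x), 0)
}

#' Axial diffusion coefficient from an MSD fit
#'
#' Ordinary least squares on `MSD(t)` over a lag window (default the
#' diffusive interval 1-6 ps); `D_z = slope / 2` for 1-D diffusion,
#' reported in 1e-10 m^2/s.  A fit with `r^2 < 0.99` triggers a
#' non-linearity warning (ballistic or plateau contamination).
#'
#' @param msd a [correlation_series()] from [compute_msd_z()] (A^2 vs fs
#'   or ps).
#' @param window `(t_min, t_max)` in ps.
#' @return object of class `diffusion_result` with `D_z` (1e-10 m^2/s),
#'   `fit_window`, `r2_of_fit` and the input `msd`.
#' @export
estimate_diffusion <- function(msd, window = c(1, 6)) {
  s <- .series_in_unit(msd, "ps")
  sel <- s$lags >= window[1] & s$lags <= window[2]
  if (sum(sel) < 5) .stopf("fewer than 5 points in fit window")
  t <- s$lags[sel]; y <- s$values[sel]
  fit <- stats::lm.fit(cbind(1, t), y)
  slope <- fit$coefficients[2]                      # A^2 / ps
  r2 <- 1 - sum(fit$residuals^2) / max(sum((y - mean(y))^2), .Machine$double.eps)
  if (is.finite(r2) && r2 < 0.99 && stats::sd(y) > 0)
    .warnf("MSD window poorly linear (r^2 = %.3f); window may not be diffusive", r2)
  D_A2ps <- max(slope, 0) / 2
  structure(list(D_z = diffusion_A2fs_to_SI(D_A2ps / 1000),
                 fit_window = window, msd = msd,
                 r2_of_fit = unname(r2)),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("diffusion_result: D_z = %.4g x 1e-10 m^2/s (window %g-%g ps, r^2 = %.4f)\n",
              x$D_z, x$fit_window[1], x$fit_window[2], x$r2_of_fit))
  invisible(x)
}

#' Second-rank orientational correlation function
#'
#' `C2(t) = < P2( e(s+t) . e(s) ) >` over molecules and all time origins,
#' normalised by its zero-lag value; `P2(x) = (3x^2 - 1)/2`.  For a
#' trajectory the unit vector is the geometric HOH-bisector dipole of each
#' water; a `vector_series` (e.g. [generate_rotational_diffusion()]) is
#' used as given.
#'
#' @param x a [wire_trajectory()] or a `vector_series`.
#' @param max_lag_frac largest lag as a fraction of the run (default half).
#' @param normalized divide by the zero-lag value (default `TRUE`).
#' @return a [correlation_series()] with lags in fs.
#' @export
compute_c2 <- function(x, max_lag_frac = 0.5, normalized = TRUE) {
  if (inherits(x, "wire_trajectory")) {
    e <- .dipole_vectors(x)
    dt <- x$dt
  } else if (inherits(x, "vector_series")) {
    e <- x$vectors
    dt <- x$dt
  } else .stopf("x must be a wire_trajectory or vector_series")
  nf <- dim(e)[3]
  max_lag <- floor((nf - 1) * max_lag_frac)
  # <(e(s).e(s+t))^2> from autocorrelations of the 6 unique tensor products
  acc <- numeric(max_lag + 1L)
  for (i in 1:3) for (j in i:3) {
    w <- if (i == j) 1 else 2
    q <- t(e[, i, ] * e[, j, ])                    # time x vectors
    acc <- acc + w * .acf_columns(q, max_lag)
  }
  c2 <- 1.5 * acc - 0.5
  if (normalized) c2 <- c2 / c2[1]
  correlation_series(lags = (0:max_lag) * dt, values = c2,
                     normalization = if (normalized) "zero-lag" else "raw",
                     lag_unit = "fs")
}

# geometric HOH-bisector unit vectors, n_water x 3 x n_frames
.dipole_vectors <- function(traj) {
  top <- traj$topology
  ox <- top$water_oxygens
  if (!length(ox)) .stopf("no water molecules in trajectory")
  nf <- n_frames(traj)
  e <- array(NA_real_, c(length(ox), 3, nf))
  for (m in seq_along(ox)) {
    o <- ox[m]
    hs <- top$oh_bonds[top$oh_bonds[, 1] == o, 2]
    d1 <- traj$positions[hs[1], , ] - traj$positions[o, , ]   # 3 x nf
    d2 <- traj$positions[hs[2], , ] - traj$positions[o, , ]
    for (ax in .axis_index(traj$periodic_axes)) {
      L <- traj$box[ax]
      d1[ax, ] <- d1[ax, ] - L * round(d1[ax, ] / L)
      d2[ax, ] <- d2[ax, ] - L * round(d2[ax, ] / L)
    }
    b <- d1 / rep(sqrt(colSums(d1^2)), each = 3) + d2 / rep(sqrt(colSums(d2^2)), each = 3)
    nb <- sqrt(colSums(b^2))
    if (any(nb < 1e-10)) .stopf("degenerate (zero-length) dipole vector")
    e[m, , ] <- b / rep(nb, each = 3)
  }
  e
}

#' Hydrogen-bond detection by O...O distance
#'
#' Two waters are hydrogen-bonded in a frame when their minimum-image
#' O...O distance is at or below the cutoff (default 3.3 A, boundary
#' inclusive); the definition is distance-only.  The mean number of
#' hydrogen bonds per water counts each bond for both partners:
#' `2 x bonds / n_water`, frame-averaged.
#'
#' @param traj a [wire_trajectory()] with at least 2 waters.
#' @param cutoff_OO distance cutoff, A.
#' @return object of class `hb_stats`: `per_frame_bonds` (list of 2-column
#'   matrices of bonded water-oxygen index pairs), `mean_hb_per_water`,
#'   `bond_matrix` (frames x pairs logical), `pair_table`, `cutoff_OO`,
#'   `dt`.
#' @export
detect_hbonds <- function(traj, cutoff_OO = 3.3) {
  ox <- traj$topology$water_oxygens
  if (length(ox) < 2) .stopf("need at least 2 water molecules")
  nf <- n_frames(traj)
  pairs <- utils::combn(ox, 2)
  np <- ncol(pairs)
  per_ax <- .axis_index(traj$periodic_axes)
  bonded <- matrix(FALSE, nf, np)
  for (p in seq_len(np)) {
    d <- traj$positions[pairs[1, p], , ] - traj$positions[pairs[2, p], , ]
    for (ax in per_ax) {
      L <- traj$box[ax]
      d[ax, ] <- d[ax, ] - L * round(d[ax, ] / L)
    }
    bonded[, p] <- sqrt(colSums(d^2)) <= cutoff_OO
  }
  nbonds <- rowSums(bonded)
  per_frame <- lapply(seq_len(nf), function(k)
    matrix(pairs[, bonded[k, ], drop = FALSE], nrow = 2))
  structure(list(cutoff_OO = cutoff_OO,
                 per_frame_bonds = per_frame,
                 bond_matrix = bonded,
                 pair_table = t(pairs),
                 mean_hb_per_water = mean(2 * nbonds / length(ox)),
                 dt = traj$dt),
            class = "hb_stats")
}

#' @export
print.hb_stats <- function(x, ...) {
  cat(sprintf("hb_stats: cutoff %.2f A, %.3f HBs per water (%d frames, %d candidate pairs)\n",
              x$cutoff_OO, x$mean_hb_per_water, nrow(x$bond_matrix),
              ncol(x$bond_matrix)))
  invisible(x)
}

#' Continuous hydrogen-bond lifetime correlation
#'
#' Survival correlation `S_HB(t) = < h(0) H(t) > / < h >` where `h` is the
#' bonded indicator of a pair and `H(t) = 1` only if the pair stayed bonded
#' at every intermediate frame (continuous definition, no reformation
#' credit).  The lifetime is the trapezoidal time integral of `S_HB` up to
#' its first drop below 0.01 (or the maximum lag, then flagged censored).
#'
#' @param stats an `hb_stats` from [detect_hbonds()].
#' @param dt frame spacing in fs (defaults to the value recorded in
#'   `stats`).
#' @param max_lag_frac largest lag as a fraction of the run.
#' @return a [correlation_series()] (lags in fs) with extra fields
#'   `lifetime` (ps) and `censored`.
#' @export
hb_lifetime <- function(stats, dt = stats$dt, max_lag_frac = 0.5) {
  b <- stats$bond_matrix
  if (!any(b)) .stopf("no hydrogen bonds in any frame")
  nf <- nrow(b)
  max_lag <- floor((nf - 1) * max_lag_frac)
  k <- 0:max_lag
  num <- numeric(max_lag + 1L)
  den <- numeric(max_lag + 1L)
  for (p in seq_len(ncol(b))) {
    r <- rle(b[, p])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      a <- starts[i]; z <- ends[i]
      # origins surviving k further frames inside this bonded run
      num <- num + pmax(0L, z - k - a + 1L)
      # bonded origins whose k-frame window fits in the series at all
      den <- den + pmax(0L, pmin(z, nf - k) - a + 1L)
    }
  }
  s <- ifelse(den > 0, num / den, 0)
  below <- which(s < 0.01)
  cut <- if (length(below)) below[1] else length(s)
  lags_fs <- (0:max_lag) * dt
  lifetime_fs <- sum(diff(lags_fs[1:cut]) * (s[1:cut][-1] + s[1:cut][-cut]) / 2)
  out <- correlation_series(lags = lags_fs, values = s,
                            normalization = "zero-lag", lag_unit = "fs")
  out$lifetime <- lifetime_fs / 1000
  out$censored <- !length(below)
  out
}
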