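#' Construct a trajectory object
#'
#' A `wire_trajectory` bundles a fixed [wire_topology()] with a uniformly
#' sampled time series of positions (and, when available, velocities), an
#' orthorhombic box and the set of periodic axes.  Positions are stored
#' wrapped into `[0, L)` on periodic axes; displacement-based analyses
#' ([compute_msd_z()]) operate on copies unwrapped with [unwrap_axis()].
#'
#' @param topology a [wire_topology()].
#' @param positions numeric array `n_atoms x 3 x n_frames`, Angstrom.
#' @param velocities matching array in A/fs, or `NULL` for a velocity-free
#'   trajectory (velocity-based analyses then refuse to run).
#' @param dt frame spacing in fs.
#' @param box orthorhombic edge lengths in Angstrom, length 3.
#' @param periodic_axes subset of `c("x","y","z")`.
#' @param time0 time of the first frame, fs.
#' @param unwrapped axes already continuous (bookkeeping, set by [unwrap_axis()]).
#' @return an object of class `wire_trajectory`.
#' @export
wire_trajectory <- function(topology, positions, velocities = NULL, dt,
                            box, periodic_axes = "z", time0 = 0,
                            unwrapped = character()) {
  stopifnot(inherits(topology, "wire_topology"))
  dp <- dim(positions)
  if (length(dp) != 3 || dp[1] != n_atoms(topology) || dp[2] != 3)
    .stopf("positions must be an n_atoms x 3 x n_frames array")
  if (dp[3] < 2) .stopf("a trajectory needs at least 2 frames")
  if (!is.null(velocities) && !identical(dim(velocities), dp))
    .stopf("velocities dimensions must match positions")
  if (!is.numeric(dt) || dt <= 0) .stopf("dt must be positive")
  if (length(box) != 3 || any(box <= 0)) .stopf("box must be 3 positive lengths")
  structure(list(topology = topology, positions = positions,
                 velocities = velocities, dt = as.numeric(dt),
                 box = as.numeric(box),
                 periodic_axes = as.character(periodic_axes),
                 time0 = as.numeric(time0),
                 unwrapped = as.character(unwrapped)),
            class = "wire_trajectory")
}

#' @export
print.wire_trajectory <- function(x, ...) {
  cat(sprintf(paste0("wire_trajectory: %d atoms, %d frames, dt = %g fs (%.3g ps), ",
                     "%s, box %.2f x %.2f x %.2f A, periodic: %s\n"),
              n_atoms(x$topology), n_frames(x), x$dt,
              (n_frames(x) - 1) * x$dt / 1000,
              if (is.null(x$velocities)) "velocity-free" else "with velocities",
              x$box[1], x$box[2], x$box[3],
              paste(x$periodic_axes, collapse = "")))
  invisible(x)
}

#' @rdname wire_trajectory
#' @param traj a `wire_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$positions)[3]

#' @rdname wire_trajectory
#' @export
frame_times <- function(traj) traj$time0 + (seq_len(n_frames(traj)) - 1) * traj$dt

#' Read an extended-XYZ trajectory
#'
#' Parses the extended-XYZ dialect: line 1 the atom count, line 2 a
#' `key=value` comment that may carry `Lattice="ax ay az bx by bz cx cy cz"`,
#' `Time=<fs>` and a `Properties=species:S:1:pos:R:3[:vel:R:3]` column
#' declaration, then one atom per line.  All frames must have the same atoms
#' in the same order and uniform time spacing.  The topology is inferred
#' from frame 1: each H is bonded to its nearest O within 1.2 A.
#'
#' @param path file path.
#' @param dt frame spacing in fs; if `NULL`, read from `Time=` comments.
#' @param box orthorhombic box lengths (A); if `NULL`, read from `Lattice=`.
#' @param periodic_axes axes treated as periodic, default `"z"`.
#' @return a [wire_trajectory()]; velocity-free if the file has no velocity
#'   columns.
#' @export
read_xyz_trajectory <- function(path, dt = NULL, box = NULL,
                                periodic_axes = "z") {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) .stopf("empty trajectory file: %s", path)
  i <- 1L
  frames <- list(); comments <- character()
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0) .stopf("bad atom count at line %d", i)
    if (i + 1L + nat > length(lines)) .stopf("truncated frame at line %d", i)
    frames[[length(frames) + 1L]] <- lines[(i + 2L):(i + 1L + nat)]
    comments[length(comments) + 1L] <- lines[i + 1L]
    if (length(frames) > 1L && length(frames[[length(frames)]]) != length(frames[[1L]]))
      .stopf("inconsistent atom count")
    # also verify the declared count matches frame 1
    if (nat != length(frames[[1L]])) .stopf("inconsistent atom count")
    i <- i + 2L + nat
  }
  nf <- length(frames)
  if (nf < 2) .stopf("a trajectory needs at least 2 frames")
  nat <- length(frames[[1]])

  parse_frame <- function(fr) {
    toks <- strsplit(trimws(fr), "\\s+")
    ncol1 <- length(toks[[1]])
    if (any(lengths(toks) != ncol1)) .stopf("ragged atom lines in frame")
    m <- matrix(unlist(toks), nrow = nat, byrow = TRUE)
    m
  }
  m1 <- parse_frame(frames[[1]])
  has_vel <- ncol(m1) >= 7
  labels <- m1[, 1]
  pos <- array(NA_real_, c(nat, 3, nf))
  vel <- if (has_vel) array(NA_real_, c(nat, 3, nf)) else NULL
  for (k in seq_len(nf)) {
    m <- parse_frame(frames[[k]])
    if (!identical(m[, 1], labels)) .stopf("atom order changed at frame %d", k)
    if ((ncol(m) >= 7) != has_vel) .stopf("velocity columns not uniform across frames")
    pos[, , k] <- suppressWarnings(matrix(as.numeric(m[, 2:4]), nat))
    if (has_vel) vel[, , k] <- suppressWarnings(matrix(as.numeric(m[, 5:7]), nat))
  }
  if (anyNA(pos)) .stopf("non-numeric coordinates")

  kv <- .parse_comment(comments[1])
  if (is.null(box)) {
    if (is.null(kv$Lattice)) .stopf("no box given and no Lattice= in file")
    lat <- as.numeric(strsplit(trimws(kv$Lattice), "\\s+")[[1]])
    if (length(lat) != 9) .stopf("Lattice must have 9 numbers")
    box <- lat[c(1, 5, 9)]
  }
  times <- vapply(comments, function(cm) {
    v <- .parse_comment(cm)$Time
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
  if (is.null(dt)) {
    if (anyNA(times)) .stopf("no dt given and Time= missing from some frames")
    dts <- diff(times)
    if (any(abs(dts - dts[1]) > 1e-6 * max(abs(dts[1]), 1)))
      .stopf("non-uniform frame spacing")
    dt <- dts[1]
  }
  top <- .infer_topology(labels, pos[, , 1], box, periodic_axes)
  wire_trajectory(top, pos, vel, dt = dt, box = box,
                  periodic_axes = periodic_axes,
                  time0 = if (is.na(times[1])) 0 else times[1])
}

.parse_comment <- function(cm) {
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("([^"]*)"|[^ ]+)'
  m <- gregexpr(pat, cm, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (s in regmatches(cm, gregexpr(pat, cm, perl = TRUE))[[1]]) {
    eq <- regexpr("=", s, fixed = TRUE)
    key <- substr(s, 1, eq - 1)
    val <- substr(s, eq + 1, nchar(s))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

#' Write a trajectory in extended-XYZ format
#'
#' Inverse of [read_xyz_trajectory()]; coordinates are printed with 8
#' decimals so a write/read round trip reproduces them to 1e-6 A.
#'
#' @param traj a [wire_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  nat <- n_atoms(traj$topology)
  nf <- n_frames(traj)
  has_vel <- !is.null(traj$velocities)
  lat <- sprintf("%.8f 0 0 0 %.8f 0 0 0 %.8f", traj$box[1], traj$box[2], traj$box[3])
  props <- if (has_vel) "species:S:1:pos:R:3:vel:R:3" else "species:S:1:pos:R:3"
  times <- frame_times(traj)
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_len(nf)) {
    writeLines(as.character(nat), con)
    writeLines(sprintf('Lattice="%s" Properties=%s Time=%.6f', lat, props, times[k]), con)
    p <- traj$positions[, , k]
    if (has_vel) {
      v <- traj$velocities[, , k]
      writeLines(sprintf("%-2s %.8f %.8f %.8f %.8f %.8f %.8f",
                         traj$topology$atom_labels,
                         p[, 1], p[, 2], p[, 3], v[, 1], v[, 2], v[, 3]), con)
    } else {
      writeLines(sprintf("%-2s %.8f %.8f %.8f", traj$topology$atom_labels,
                         p[, 1], p[, 2], p[, 3]), con)
    }
  }
  invisible(path)
}

#' Unwrap periodic-boundary jumps along one axis
#'
#' Makes per-atom coordinates continuous along a periodic axis: any
#' successive-frame jump larger than half the box length is folded back by a
#' whole box length, so displacements accumulated across the boundary are
#' physical.  Required before [compute_msd_z()].
#'
#' @param traj a [wire_trajectory()].
#' @param axis axis name (`"x"`, `"y"` or `"z"`); must be periodic.
#' @return the trajectory with that axis continuous and recorded in
#'   `$unwrapped`.
#' @export
unwrap_axis <- function(traj, axis = "z") {
  if (!axis %in% traj$periodic_axes) .stopf("axis '%s' is not periodic", axis)
  ax <- .axis_index(axis)
  L <- traj$box[ax]
  z <- traj$positions[, ax, , drop = TRUE]           # n_atoms x n_frames
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  dz <- z[, -1, drop = FALSE] - z[, -ncol(z), drop = FALSE]
  dz <- dz - L * round(dz / L)
  zu <- cbind(z[, 1], dz)
  zu <- t(apply(zu, 1, cumsum))
  traj$positions[, ax, ] <- zu
  traj$unwrapped <- union(traj$unwrapped, axis)
  traj
}

# wrap one axis back into [0, L) (used by tests and the generator)
wrap_axis <- function(traj, axis = "z") {
  ax <- .axis_index(axis)
  L <- traj$box[ax]
  traj$positions[, ax, ] <- traj$positions[, ax, ] %% L
  traj$unwrapped <- setdiff(traj$unwrapped, axis)
  traj
}
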