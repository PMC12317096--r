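#' Configuration for the toy confined water-wire generator
#'
#' Parameters of a deliberately minimal flexible 3-site water model used to
#' emulate a single-file water chain in a narrow cylindrical pore: a Morse
#' O-H stretch (so the stretching frequency red-shifts when the bond
#' elongates under hydrogen bonding), a harmonic H-O-H bend, SPC/Fw-style
#' site charges and O-O Lennard-Jones between molecules (minimum image
#' along the pore axis only, no Ewald), and a flat-bottom harmonic radial
#' wall standing in for the pore.  The defaults describe the reference
#' system used throughout the package: 12 waters on a 33 A periodic axis
#' (2.75 A spacing), a 1 A free-radius wall, 300 K, 0.5 fs timestep, 10 ps
#' of thermostatted equilibration and 20 ps of NVE production.  Morse
#' parameters place the isolated-molecule OH stretch near 3700 cm^-1 so the
#' free/bonded frequency split falls in the 3400-3800 cm^-1 window.
#'
#' @param n_water number of water molecules.
#' @param box_z periodic box length along the pore axis, A.
#' @param box_xy lateral (non-periodic) box lengths, A.
#' @param wall_radius flat-bottom radius of the confining wall, A.
#' @param wall_strength harmonic wall constant, kcal/mol/A^2 (0 disables).
#' @param morse_De,morse_a,morse_r0 Morse well depth (kcal/mol), range
#'   (1/A) and equilibrium length (A) of the O-H stretch.
#' @param angle_k,angle_theta0 bend constant (kcal/mol/rad^2) and
#'   equilibrium angle (rad).
#' @param lj_epsilon_OO,lj_sigma_OO O-O Lennard-Jones parameters.
#' @param charge_H hydrogen site charge, e (oxygen carries `-2 charge_H`).
#' @param temperature target temperature, K.
#' @param dt integration timestep, fs.
#' @param n_steps_equil,n_steps_prod equilibration / production step counts.
#' @param thermostat_tau CSVR time constant, fs (equilibration only).
#' @param r_cut shifted-force cutoff for the intermolecular terms, A;
#'   `NULL` (default) picks `min(12, 0.49 x smallest periodic box edge)`.
#' @param record_stride store every `record_stride`-th production frame.
#' @param periodic_axes periodic axes; the default wire is periodic in z
#'   only, a fully periodic cube gives an unconfined bulk-like reference.
#' @param arrangement `"wire"` (chain along z) or `"lattice"` (grid fill,
#'   for unconfined reference boxes).
#' @param seed integer seed; every stochastic stage derives from it.
#' @return object of class `wire_config`.
#' @export
wire_config <- function(n_water = 12, box_z = 33, box_xy = 20,
                        wall_radius = 1.0, wall_strength = 20,
                        morse_De = 120, morse_a = 2.17, morse_r0 = 1.012,
                        angle_k = 75.9, angle_theta0 = 113.24 * pi / 180,
                        lj_epsilon_OO = 0.1554253, lj_sigma_OO = 3.165492,
                        charge_H = 0.41, temperature = 300, dt = 0.5,
                        n_steps_equil = 20000, n_steps_prod = 40000,
                        thermostat_tau = 100, r_cut = NULL,
                        record_stride = 1L,
                        periodic_axes = "z", arrangement = "wire",
                        seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_water < 1) .stopf("n_water must be >= 1")
  if (cfg$dt <= 0) .stopf("dt must be positive")
  if (cfg$wall_strength > 0 && cfg$wall_radius <= 0)
    .stopf("wall_radius must be positive")
  if (cfg$morse_De <= 0 || cfg$morse_a <= 0 || cfg$morse_r0 <= 0)
    .stopf("Morse parameters must give a bound OH near r0")
  structure(cfg, class = "wire_config")
}

# wire or lattice starting structure; returns list(pos, topology)
.initial_structure <- function(cfg) {
  n <- cfg$n_water
  box <- c(cfg$box_xy, cfg$box_xy, cfg$box_z)
  if (cfg$arrangement == "lattice") box <- rep(cfg$box_z, 3)
  cx <- box[1] / 2; cy <- box[2] / 2
  r0 <- cfg$morse_r0; th <- cfg$angle_theta0
  pos <- matrix(0, 3 * n, 3)
  labels <- rep(c("O", "H", "H"), n)
  mol <- rep(seq_len(n), each = 3)
  bonds <- cbind(rep(seq(1, 3 * n, 3), each = 2),
                 c(rbind(seq(2, 3 * n, 3), seq(3, 3 * n, 3))))
  if (cfg$arrangement == "wire") {
    spacing <- cfg$box_z / n
    for (k in seq_len(n)) {
      o <- c(cx, cy, (k - 0.5) * spacing)
      phi <- k * 2.399963                      # golden-angle spiral of free OH
      # donating OH along +z toward the next molecule; the sibling points
      # outward at the equilibrium angle
      h1 <- o + r0 * c(0, 0, 1)
      h2 <- o + r0 * c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
      pos[3 * k - 2, ] <- o; pos[3 * k - 1, ] <- h1; pos[3 * k, ] <- h2
    }
  } else {
    m <- ceiling(n^(1 / 3))
    grid <- expand.grid(i = seq_len(m), j = seq_len(m), k = seq_len(m))
    grid <- grid[seq_len(n), ]
    sp <- box / m
    for (k in seq_len(n)) {
      o <- (unlist(grid[k, ]) - 0.5) * sp
      phi <- k * 2.399963
      h1 <- o + r0 * c(sin(th / 2) * cos(phi), sin(th / 2) * sin(phi), cos(th / 2))
      h2 <- o + r0 * c(sin(-th / 2) * cos(phi), sin(-th / 2) * sin(phi), cos(th / 2))
      pos[3 * k - 2, ] <- o; pos[3 * k - 1, ] <- h1; pos[3 * k, ] <- h2
    }
  }
  top <- wire_topology(labels, mol, bonds)
  list(pos = pos, topology = top, box = box)
}

#' Generate a toy confined water-wire trajectory
#'
#' Runs velocity-Verlet dynamics of the minimal flexible water model in
#' [wire_config()]: a thermostatted (stochastic velocity rescaling)
#' equilibration phase at the target temperature followed by strictly
#' microcanonical production.  Initial velocities are Maxwell-Boltzmann
#' with the centre-of-mass drift removed.  After production the wire is
#' checked for continuity: in every recorded frame each water oxygen must
#' have a neighbouring oxygen within 4 A, else an error names the frame.
#'
#' @param config a [wire_config()].
#' @param check_continuity assert the nearest-neighbour O-O gap stays
#'   below 4 A in every production frame.
#' @return a [wire_trajectory()] of the production phase (positions and
#'   velocities every `record_stride` frames), with the per-frame kinetic
#'   and potential energies attached as attribute `"energies"`.
#' @export
generate_water_wire <- function(config = wire_config(), check_continuity = TRUE) {
  cfg <- config
  init <- .initial_structure(cfg)
  r_cut <- cfg$r_cut
  if (is.null(r_cut)) {
    per <- .axis_index(cfg$periodic_axes)
    r_cut <- if (length(per)) min(12, 0.49 * min(init$box[per])) else 12
  }
  top <- init$topology
  n <- n_atoms(top)
  set.seed(cfg$seed)

  # Maxwell-Boltzmann velocities, COM momentum removed
  sd_v <- sqrt(.kB_kcal * .kcal_to_internal * cfg$temperature / top$masses)
  vel <- matrix(stats::rnorm(3 * n), n, 3) * sd_v
  vel <- sweep(vel, 2, colSums(vel * top$masses) / sum(top$masses))

  params <- list(morse_De = cfg$morse_De, morse_a = cfg$morse_a,
                 morse_r0 = cfg$morse_r0, angle_k = cfg$angle_k,
                 angle_theta0 = cfg$angle_theta0,
                 lj_epsilon_OO = cfg$lj_epsilon_OO,
                 lj_sigma_OO = cfg$lj_sigma_OO,
                 wall_strength = cfg$wall_strength,
                 wall_radius = cfg$wall_radius,
                 r_cut = r_cut,
                 box = init$box,
                 periodic = as.integer(c("x", "y", "z") %in% cfg$periodic_axes))
  charges <- ifelse(top$atom_labels == "O", -2 * cfg$charge_H, cfg$charge_H)
  angles <- matrix(top$oh_bonds[, 2], ncol = 2, byrow = TRUE)
  angles <- cbind(angles[, 1], top$oh_bonds[seq(1, nrow(top$oh_bonds), 2), 1],
                  angles[, 2])

  mol0 <- top$molecule_index - 1L
  oh0 <- top$oh_bonds - 1L
  ang0 <- angles - 1L

  if (cfg$n_steps_equil > 0) {
    eq <- .run_md_cpp(init$pos, vel, top$masses, charges, mol0, oh0, ang0,
                      params, cfg$dt, cfg$n_steps_equil,
                      max(1L, cfg$n_steps_equil), TRUE,
                      cfg$temperature, cfg$thermostat_tau, 1.0)
    pos <- eq$final_pos; vel <- eq$final_vel
  } else {
    pos <- init$pos
  }
  pr <- .run_md_cpp(pos, vel, top$masses, charges, mol0, oh0, ang0,
                    params, cfg$dt, cfg$n_steps_prod, cfg$record_stride,
                    FALSE, cfg$temperature, cfg$thermostat_tau, 1.0)

  rpos <- pr$positions; rvel <- pr$velocities
  # wrap into [0, L) on periodic axes for storage
  for (ax in .axis_index(cfg$periodic_axes))
    rpos[, ax, ] <- rpos[, ax, ] %% init$box[ax]
  traj <- wire_trajectory(top, rpos, rvel, dt = cfg$dt * cfg$record_stride,
                          box = init$box, periodic_axes = cfg$periodic_axes)
  attr(traj, "energies") <- data.frame(time = pr$time, ekin = pr$ekin,
                                       epot = pr$epot)
  attr(traj, "config") <- cfg
  if (check_continuity && cfg$n_water > 1) .check_continuity(traj)
  traj
}

.check_continuity <- function(traj, gap_max = 4.0) {
  ox <- traj$topology$water_oxygens
  nf <- n_frames(traj)
  pairs <- utils::combn(length(ox), 2)
  np <- ncol(pairs)
  # nearest-neighbour O-O gap per frame
  dmat <- matrix(NA_real_, np, nf)
  for (p in seq_len(np)) {
    a <- ox[pairs[1, p]]; b <- ox[pairs[2, p]]
    d <- traj$positions[a, , ] - traj$positions[b, , ]      # 3 x nf
    for (ax in .axis_index(traj$periodic_axes)) {
      L <- traj$box[ax]
      d[ax, ] <- d[ax, ] - L * round(d[ax, ] / L)
    }
    dmat[p, ] <- sqrt(colSums(d^2))
  }
  for (k in seq_len(nf)) {
    dmin <- rep(Inf, length(ox))
    for (p in seq_len(np)) {
      i <- pairs[1, p]; j <- pairs[2, p]
      dmin[i] <- min(dmin[i], dmat[p, k])
      dmin[j] <- min(dmin[j], dmat[p, k])
    }
    if (max(dmin) >= gap_max)
      .stopf("wire continuity violated at frame %d (nearest-neighbour O-O gap %.2f A)",
             k, max(dmin))
  }
  invisible(TRUE)
}

#' Unconfined bulk-like reference configuration
#'
#' Returns a copy of a wire configuration with the wall switched off and
#' the same molecules placed in a fully periodic cube at roughly liquid
#' density, used as the 3-D reference against which the axial diffusion of
#' the confined wire is compared.
#'
#' @param config a [wire_config()].
#' @param volume_per_water cube volume per molecule, A^3 (default near the
#'   300 K liquid value).
#' @return a modified `wire_config`.
#' @export
bulk_reference_config <- function(config = wire_config(), volume_per_water = 29.9) {
  cfg <- config
  cfg$wall_strength <- 0
  cfg$arrangement <- "lattice"
  cfg$box_z <- (cfg$n_water * volume_per_water)^(1 / 3)
  cfg$periodic_axes <- c("x", "y", "z")
  cfg$r_cut <- NULL          # re-derive for the smaller periodic box
  cfg
}
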