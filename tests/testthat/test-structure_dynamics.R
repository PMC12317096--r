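test_that("RDF reproduces a delta peak and ideal-gas flatness", {
  # two fixed atoms 3.0 A apart: a single occupied bin at 3.0 A
  pos <- rbind(c(5, 5, 5), c(5, 5, 8))
  traj <- static_trajectory(pos, c("O", "O"), nf = 3, box = c(10, 10, 10),
                            periodic_axes = c("x", "y", "z"))
  g <- compute_rdf(traj, c("O", "O"), r_max = 4.9, dr = 0.1)
  expect_equal(sum(g$g > 0), 1)
  expect_equal(g$r[which(g$g > 0)], 3.05, tolerance = 0.06)

  # uniform gas: g(r) = 1 +- 0.1 beyond short range
  set.seed(11)
  n <- 800; L <- 20
  upos <- matrix(runif(3 * n, 0, L), n, 3)
  utraj <- static_trajectory(upos, rep("O", n), nf = 6, box = rep(L, 3),
                             periodic_axes = c("x", "y", "z"))
  gu <- compute_rdf(utraj, c("O", "O"), r_max = 9.5, dr = 0.25)
  sel <- gu$r >= 2
  expect_true(all(abs(gu$g[sel] - 1) <= 0.1))
  # frame order does not matter
  utraj2 <- utraj
  utraj2$positions <- utraj$positions[, , rev(seq_len(6))]
  expect_equal(compute_rdf(utraj2, c("O", "O"), r_max = 9.5, dr = 0.25)$g, gu$g)
  expect_error(compute_rdf(utraj, c("N", "O"), r_max = 5), "empty species")
})

test_that("cross-molecule O-H RDF of the wire peaks at the H-bond distance", {
  tr <- cached_wire()
  top <- tr$topology
  g <- compute_rdf(tr, list(top$water_oxygens,
                            which(top$atom_labels == "H")),
                   r_max = 6, dr = 0.05, frame_stride = 25)
  # mask intramolecular distances: first peak beyond 1.2 A
  sel <- g$r > 1.3 & g$r < 2.6
  peak_r <- g$r[sel][which.max(g$g[sel])]
  expect_gte(peak_r, 1.6)
  expect_lte(peak_r, 2.2)
})

test_that("MSD: static, ballistic and Brownian closed forms", {
  # static input
  pos <- array(rep(c(1, 2, 3), 10), c(1, 3, 10))
  top <- wire_topology("O", 1L, matrix(integer(), ncol = 2))
  tr <- wire_trajectory(top, pos, NULL, dt = 1, box = c(10, 10, 10),
                        periodic_axes = character(), unwrapped = "z")
  m0 <- compute_msd_z(tr, "all")
  expect_lt(max(abs(m0$values)), 1e-10)
  expect_equal(m0$values[1], 0)

  # constant velocity: MSD(t) = (v t)^2 exactly
  v <- 0.3; nf <- 60
  pos2 <- array(0, c(1, 3, nf)); pos2[1, 3, ] <- v * (0:(nf - 1))
  tr2 <- wire_trajectory(top, pos2, NULL, dt = 1, box = c(10, 10, 1e4),
                         periodic_axes = "z", unwrapped = "z")
  m2 <- compute_msd_z(tr2, "all")
  expect_equal(m2$values, (v * m2$lags)^2, tolerance = 1e-10)

  # Brownian: MSD/t -> 2 D
  tb <- generate_brownian_z(D = 10, dt = 1, n_steps = 30000,
                            n_particles = 100, seed = 13)
  mb <- compute_msd_z(tb, "all")
  Db <- estimate_diffusion(mb, c(1, 6))
  expect_close(Db$D_z, 10, 1)
})

test_that("diffusion estimate converts units correctly and flags curvature", {
  # MSD(t) = 2 t A^2/ps: slope 2, D = 1 A^2/ps = 100 x 1e-10 m^2/s
  t_fs <- seq(0, 8000, by = 20)
  ser <- correlation_series(t_fs, 2 * t_fs / 1000, "raw", "fs")
  D <- estimate_diffusion(ser, c(1, 6))
  expect_equal(D$D_z, 100, tolerance = 1e-9)
  expect_equal(estimate_diffusion(
    correlation_series(t_fs, rep(0, length(t_fs)), "raw", "fs"), c(1, 6))$D_z, 0)
  # ballistic curve in the window: poor linearity warning
  expect_warning(estimate_diffusion(
    correlation_series(t_fs, (0.05 * t_fs)^2, "raw", "fs"), c(1, 6)),
    "poorly linear")
})

test_that("C2 is 1 for static dipoles and follows rotational diffusion", {
  pos <- water_chain_pos(3)
  tr <- static_trajectory(pos, rep(c("O", "H", "H"), 3), nf = 8)
  c2 <- compute_c2(tr)
  expect_true(all(abs(c2$values - 1) < 1e-12))

  vs <- generate_rotational_diffusion(D_r = 0.5, dt = 2, n_steps = 2500,
                                      n_vectors = 500, seed = 5)
  c2r <- compute_c2(vs)
  lag_ps <- c2r$lags / 1000
  sel <- lag_ps <= 2
  expect_lt(max(abs(c2r$values[sel] - exp(-6 * 0.5 * lag_ps[sel]))), 0.05)
  expect_equal(c2r$values[1], 1)
  expect_true(all(abs(c2r$values) <= 1 + 1e-12))
})

test_that("hydrogen-bond detection matches brute force and the cutoff is inclusive", {
  # two waters at O-O 3.2: bonded; at 3.4: not
  for (case in list(c(3.2, 1), c(3.4, 0))) {
    pos <- rbind(make_water_pos(c(10, 10, 5)),
                 make_water_pos(c(10, 10, 5 + case[1])))
    tr <- static_trajectory(pos, rep(c("O", "H", "H"), 2), nf = 2)
    hb <- detect_hbonds(tr)
    expect_equal(ncol(hb$per_frame_bonds[[1]]), case[2])
  }
  # static open 10-chain at 2.8 A: 9 bonds, 1.8 per water
  pos <- water_chain_pos(10, 2.8)
  tr <- static_trajectory(pos, rep(c("O", "H", "H"), 10), nf = 2,
                          box = c(20, 20, 60))
  hb <- detect_hbonds(tr)
  expect_equal(ncol(hb$per_frame_bonds[[1]]), 9)
  expect_equal(hb$mean_hb_per_water, 1.8)

  # brute-force cross-check on wire frames
  tr2 <- cached_wire()
  keep <- seq(1, n_frames(tr2), length.out = 5)
  ox <- tr2$topology$water_oxygens
  hb2 <- detect_hbonds(tr2)
  for (k in round(keep)) {
    p <- tr2$positions[ox, , k]
    ref <- NULL
    for (i in seq_along(ox)[-length(ox)]) for (j in (i + 1):length(ox)) {
      d <- p[i, ] - p[j, ]
      d[3] <- d[3] - tr2$box[3] * round(d[3] / tr2$box[3])
      if (sqrt(sum(d^2)) <= 3.3) ref <- cbind(ref, c(ox[i], ox[j]))
    }
    got <- hb2$per_frame_bonds[[k]]
    expect_equal(ncol(got), if (is.null(ref)) 0 else ncol(ref))
    if (!is.null(ref)) expect_equal(got, ref)
  }
})

test_that("continuous HB lifetime has the survival semantics", {
  # always-bonded pair: survival 1 everywhere, censored
  mk_stats <- function(bondvec, dt = 100) {
    structure(list(bond_matrix = matrix(bondvec, ncol = 1),
                   pair_table = matrix(c(1, 4), 1), cutoff_OO = 3.3, dt = dt),
              class = "hb_stats")
  }
  life <- hb_lifetime(mk_stats(rep(TRUE, 101)))
  expect_true(all(life$values == 1))
  expect_true(life$censored)
  # alternating frames: no continuous survival past one step
  alt <- hb_lifetime(mk_stats(rep(c(TRUE, FALSE), 50)))
  expect_equal(alt$values[2], 0)
  expect_lte(alt$lifetime, 0.1 * 100 / 1000 + 0.06)

  # telegraph process with break rate 2/ps: lifetime ~ 0.5 ps
  set.seed(17)
  dt <- 20                          # fs
  k_break <- 2 / 1000               # per fs
  n <- 200000
  state <- logical(n); s <- TRUE
  for (i in seq_len(n)) {
    state[i] <- s
    if (s && runif(1) < k_break * dt) s <- FALSE
    else if (!s && runif(1) < k_break * dt) s <- TRUE
  }
  lt <- hb_lifetime(mk_stats(state, dt))
  expect_close(lt$lifetime, 0.5, 0.075)
})
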