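test_that("VDOS locates harmonic frequencies", {
  dt <- 0.5; nf <- 40000
  t <- (0:(nf - 1)) * dt
  top <- wire_topology(c("O", "O"), 1:2, matrix(integer(), ncol = 2))
  pos <- array(0, c(2, 3, nf))
  vel <- array(0, c(2, 3, nf))
  w1 <- cm1_to_radfs(3400); w2 <- cm1_to_radfs(1650)
  vel[1, 1, ] <- cos(w1 * t)
  vel[2, 1, ] <- cos(w2 * t) + cos(cm1_to_radfs(3700) * t)
  tr <- wire_trajectory(top, pos, vel, dt = dt, box = c(10, 10, 10),
                        periodic_axes = character())
  # single oscillator at 3400: peak within one resolution element
  d1 <- compute_vdos(tr, max_lag = 2000, atoms = 1)
  expect_close(d1$omega[which.max(d1$intensity)], 3400, d1$resolution)
  # superposed 1650 + 3700: two resolved peaks
  d2 <- compute_vdos(tr, max_lag = 2000, atoms = 2)
  pk_lo <- d2$omega[d2$omega < 2500][which.max(d2$intensity[d2$omega < 2500])]
  pk_hi <- d2$omega[d2$omega > 2500][which.max(d2$intensity[d2$omega > 2500])]
  expect_close(pk_lo, 1650, d2$resolution)
  expect_close(pk_hi, 3700, d2$resolution)
  # constant velocities: all weight at zero frequency
  vel0 <- array(0.1, c(2, 3, 200))
  tr0 <- wire_trajectory(top, pos[, , 1:200], vel0, dt = dt,
                         box = c(10, 10, 10), periodic_axes = character())
  d0 <- compute_vdos(tr0, max_lag = 50)
  expect_equal(which.max(d0$intensity), 1)
  tr_nv <- tr; tr_nv$velocities <- NULL
  expect_error(compute_vdos(tr_nv), "velocity-free")
})

test_that("bond series: projection kills rigid rotation, harmonic motion is a circle", {
  dt <- 0.5; nf <- 2000
  t <- (0:(nf - 1)) * dt
  top <- wire_topology(c("O", "H", "H"), c(1L, 1L, 1L),
                       matrix(c(1L, 1L, 2L, 3L), 2))
  # rigid rotation of the OH bond in the xy plane about the O
  r0 <- 0.96; wrot <- 0.02
  pos <- array(0, c(3, 3, nf)); vel <- array(0, c(3, 3, nf))
  pos[1, , ] <- c(5, 5, 5)
  pos[2, 1, ] <- 5 + r0 * cos(wrot * t); pos[2, 2, ] <- 5 + r0 * sin(wrot * t)
  vel[2, 1, ] <- -r0 * wrot * sin(wrot * t); vel[2, 2, ] <- r0 * wrot * cos(wrot * t)
  pos[3, , ] <- c(5, 5, 5.96)
  tr <- wire_trajectory(top, pos, vel, dt = dt, box = c(10, 10, 10),
                        periodic_axes = character())
  bs <- build_bond_series(tr, 1)
  expect_lt(max(abs(bs$dr)), 1e-9)
  expect_lt(max(abs(bs$dp)), 1e-9)
  expect_lt(abs(mean(bs$dr)), 1e-12)

  # harmonic stretch at omega_ref: f(t) traces a circle of the mode amplitude
  A <- 0.05; w0 <- cm1_to_radfs(3500)
  mu <- 15.999 * 1.008 / (15.999 + 1.008)
  pos2 <- pos; vel2 <- array(0, c(3, 3, nf))
  pos2[2, , ] <- 0; pos2[2, 1, ] <- 5 + r0 + A * cos(w0 * t); pos2[2, 2, ] <- 5
  pos2[2, 3, ] <- 5
  vel2[2, 1, ] <- -A * w0 * sin(w0 * t)
  tr2 <- wire_trajectory(top, pos2, vel2, dt = dt, box = c(10, 10, 10),
                         periodic_axes = character())
  bs2 <- build_bond_series(tr2, 1, omega_ref = 3500)
  radius <- Mod(bs2$f)
  expect_lt(max(abs(radius - A)) / A, 0.01)
  expect_error(build_bond_series(tr2, 99), "out of range")
})

test_that("wavelet ridge is exact for monochromatic signals of either sense", {
  dt <- 1; n <- 4000; t <- (0:(n - 1)) * dt
  grid_step <- 3600 * (log(4300 / 2800) / 127)   # log-grid spacing near 3600
  for (sgn in c(-1, 1)) for (A in c(0.03, 2)) {
    f <- A * exp(sgn * 1i * (cm1_to_radfs(3600) * t + 0.7))
    ft <- wavelet_frequencies(f, dt = dt)
    v <- ft$valid_range
    expect_lt(max(abs(ft$omega[v[1]:v[2]] - 3600)), grid_step)
  }
  expect_error(wavelet_frequencies(exp(-1i * t), dt = 1,
                                   omega_range = c(2800, 40000)),
               "Nyquist")
  expect_error(wavelet_frequencies(exp(-1i * t[1:10]), dt = 1), "too short")
})

test_that("wavelet localizes a changepoint and tracks a wandering frequency", {
  dt <- 1; half <- 2000; t <- (0:(half - 1)) * dt
  f <- c(exp(-1i * cm1_to_radfs(3300) * t), exp(-1i * cm1_to_radfs(3700) * t))
  ft <- wavelet_frequencies(f, dt = dt)
  sw <- which(abs(ft$omega - 3700) < abs(ft$omega - 3300))[1]
  expect_lt(abs(sw - (half + 1)), ft$support_fs / dt)

  # OU-driven oscillator: ridge tracks the generating frequency
  ou <- generate_ou_frequencies(ou_config(omega_mean = 3500, delta = 80,
                                          tau_c = 300, dt = 1, n_steps = 20000,
                                          n_oscillators = 1, seed = 9))
  phi <- cumsum(cm1_to_radfs(ou$omega[, 1])) * dt
  fw <- wavelet_frequencies(exp(-1i * phi), dt = dt)
  idx <- fw$valid_range[1]:fw$valid_range[2]
  rmse <- sqrt(mean((fw$omega[idx] - ou$omega[idx, 1])^2))
  expect_lt(rmse, 80 / 3)
})

test_that("frequency distributions recover sample statistics", {
  # all mass in one bin
  fs1 <- frequency_set(matrix(3620, 100, 2), dt = 1)
  d1 <- frequency_distribution(fs1)
  expect_equal(sum(d1$probability > 0), 1)
  expect_equal(d1$mean_omega, 3620)
  expect_equal(sum(d1$probability), 1)
  # OU samples: mean and spread of the stationary law
  fs2 <- generate_ou_frequencies(ou_config(omega_mean = 3600, delta = 80,
                                           tau_c = 200, dt = 10, n_steps = 3000,
                                           n_oscillators = 100, seed = 23))
  d2 <- frequency_distribution(fs2)
  expect_close(d2$mean_omega, 3600, 2)
  expect_close(d2$sd_omega, 80, 4)
  # uniform samples: flat within multinomial error
  set.seed(5)
  fs3 <- frequency_set(matrix(runif(2e5, 3000, 3900), ncol = 4), dt = 1)
  d3 <- frequency_distribution(fs3, bin_width = 100)
  inner <- d3$probability[d3$bin_centers > 3050 & d3$bin_centers < 3850]
  expect_true(all(abs(inner - 1 / 9) < 0.01))
  expect_error(frequency_distribution(fs1, subset = integer()), "empty subset")
})

test_that("OH classification finds the donor in a dimer and isolated waters are free", {
  # linear dimer: donor H of molecule 1 points at the acceptor O (H..O 1.9)
  o1 <- c(10, 10, 5)
  h1d <- o1 + c(0, 0, 0.96)                  # donating, toward O2 at z = 7.86
  h1f <- o1 + 0.96 * c(sin(1.9), 0, cos(1.9))
  acc <- make_water_pos(c(10, 10, 5 + 0.96 + 1.9), axis_phi = pi / 3)
  pos <- rbind(o1, h1d, h1f, acc)
  tr <- static_trajectory(pos, rep(c("O", "H", "H"), 2), nf = 3)
  hb <- detect_hbonds(tr)
  expect_equal(ncol(hb$per_frame_bonds[[1]]), 1)
  lab <- classify_oh_modes(tr, hb)
  expect_equal(as.character(lab$label[1]), "OH1")   # the donating bond
  expect_equal(as.character(lab$label[2]), "OH2")   # its sibling

  # isolated molecule: both OH2
  tr1 <- static_trajectory(make_water_pos(c(5, 5, 5)), c("O", "H", "H"), nf = 2)
  hb1 <- detect_hbonds(static_trajectory(water_chain_pos(2, 6), rep(c("O", "H", "H"), 2), nf = 2))
  lab1 <- classify_oh_modes(static_trajectory(water_chain_pos(2, 6),
                                              rep(c("O", "H", "H"), 2), nf = 2), hb1)
  expect_true(all(lab1$label == "OH2"))
})

test_that("asymmetry is the signed difference of subset means", {
  om <- cbind(matrix(3500, 50, 2), matrix(3750, 50, 2))
  fs <- frequency_set(om, dt = 1)
  lab <- structure(list(label = factor(c("OH1", "OH1", "OH2", "OH2"),
                                       levels = c("OH1", "OH2"))),
                   class = "oh_labels")
  g <- asymmetry(fs, lab)
  expect_equal(g$gamma, -250)
  expect_equal(abs(g$gamma), 250)
  # identical distributions: gamma ~ 0
  fs2 <- frequency_set(matrix(rnorm(400, 3600, 10), ncol = 4), dt = 1)
  expect_lt(abs(asymmetry(fs2, lab)$gamma), 5)
  lab_bad <- structure(list(label = factor(rep("OH2", 4),
                                           levels = c("OH1", "OH2"))),
                       class = "oh_labels")
  expect_error(asymmetry(fs, lab_bad), "no OH1")
})
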