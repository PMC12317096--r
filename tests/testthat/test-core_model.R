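test_that("extended-XYZ reading infers water topology and round-trips", {
  # water dimer, O-O 2.8 A along z
  pos <- rbind(make_water_pos(c(10, 10, 5)), make_water_pos(c(10, 10, 7.8)))
  labels <- rep(c("O", "H", "H"), 2)
  traj <- static_trajectory(pos, labels, nf = 3, velocities = TRUE)
  expect_equal(length(unique(traj$topology$molecule_index)), 2)
  expect_equal(nrow(traj$topology$oh_bonds), 4)
  # every H bonded to the O of its own molecule (no cross-molecule OH)
  expect_true(all(traj$topology$molecule_index[traj$topology$oh_bonds[, 1]] ==
                  traj$topology$molecule_index[traj$topology$oh_bonds[, 2]]))

  f <- tempfile(fileext = ".xyz")
  write_xyz_trajectory(traj, f)
  rt <- read_xyz_trajectory(f)
  expect_equal(rt$positions, traj$positions, tolerance = 1e-6)
  expect_equal(rt$velocities, traj$velocities, tolerance = 1e-6)
  expect_equal(rt$dt, traj$dt)
  expect_equal(nrow(rt$topology$oh_bonds), 4)
  unlink(f)
})

test_that("single-water file parses and malformed frames are rejected", {
  pos <- make_water_pos(c(5, 5, 5))
  traj <- static_trajectory(pos, c("O", "H", "H"), nf = 2)
  f <- tempfile(fileext = ".xyz")
  write_xyz_trajectory(traj, f)
  rt <- read_xyz_trajectory(f)
  expect_equal(length(unique(rt$topology$molecule_index)), 1)
  expect_equal(nrow(rt$topology$oh_bonds), 2)
  expect_null(rt$velocities)

  # drop one atom from the second frame
  lines <- readLines(f)
  writeLines(lines[-length(lines)], f)
  expect_error(read_xyz_trajectory(f), "inconsistent atom count|truncated")
  unlink(f)

  # H with no nearby O
  f2 <- tempfile(fileext = ".xyz")
  lonely <- rbind(c(5, 5, 5), c(9, 9, 9), c(5.96, 5, 5))
  tr2 <- tryCatch(static_trajectory(lonely, c("O", "H", "H"), nf = 2),
                  error = identity)
  expect_s3_class(tr2, "error")
  expect_match(conditionMessage(tr2), "no O within")
  unlink(f2)
})

test_that("unwrap_axis folds boundary crossings and is invertible", {
  # constant-velocity atom crossing the z boundary 3 times
  L <- 10; dt <- 1; v <- 0.7
  nf <- 50
  z_true <- 1 + v * (0:(nf - 1))          # crosses at z = 10, 20, 30
  pos <- array(0, c(1, 3, nf))
  pos[1, 1, ] <- 5; pos[1, 2, ] <- 5
  pos[1, 3, ] <- z_true %% L
  top <- wire_topology("O", 1L, matrix(integer(), ncol = 2))
  traj <- wire_trajectory(top, pos, NULL, dt = dt, box = c(10, 10, L),
                          periodic_axes = "z")
  un <- unwrap_axis(traj, "z")
  expect_equal(un$positions[1, 3, ], z_true, tolerance = 1e-12)
  # re-wrapping restores the original coordinates exactly
  rw <- wirespec:::wrap_axis(un, "z")
  expect_equal(rw$positions, traj$positions, tolerance = 1e-12)
  # a static atom is untouched
  traj$positions[1, 3, ] <- 4.2
  expect_equal(unwrap_axis(traj, "z")$positions[1, 3, ], rep(4.2, nf))
  expect_error(unwrap_axis(traj, "x"), "not periodic")
})

test_that("bi-exponential fit recovers generating parameters", {
  t <- seq(0, 10, by = 0.02)
  cases <- expand.grid(a0 = c(0.2, 0.3, 0.6), tau0 = c(0.05, 0.1, 0.3),
                       tau1 = c(1.5, 2, 5))
  cases <- cases[cases$tau1 / cases$tau0 >= 5, ]
  for (i in seq_len(nrow(cases))) {
    p <- cases[i, ]
    y <- p$a0 * exp(-t / p$tau0) + (1 - p$a0) * exp(-t / p$tau1)
    fit <- fit_biexponential(
      correlation_series(t, y, "zero-lag", "ps"), c(0, 10))
    expect_close(fit$a0, p$a0, 0.01 * max(p$a0, 0.1))
    expect_close(fit$tau0, p$tau0, 0.01 * p$tau0)
    expect_close(fit$tau1, p$tau1, 0.01 * p$tau1)
    expect_true(fit$tau0 <= fit$tau1)
  }
})

test_that("bi-exponential fit handles degenerate inputs", {
  t <- seq(0, 10, by = 0.05)
  # single exponential: slow constant still recovered
  y <- exp(-t / 2)
  fit <- fit_biexponential(correlation_series(t, y, "zero-lag", "ps"))
  expect_close(fit$a0 * exp(-5 / fit$tau0) + (1 - fit$a0) * exp(-5 / fit$tau1),
               exp(-5 / 2), 1e-3)
  # non-decaying series pins the time constants at the bound, flagged
  flat <- fit_biexponential(correlation_series(t, rep(1, length(t)),
                                               "zero-lag", "ps"))
  expect_true(flat$degenerate)
  expect_error(fit_biexponential(
    correlation_series(t[1:4], y[1:4], "zero-lag", "ps"), c(0, 0.15)),
    "fewer than 5")
})

test_that("unit conversions match hand calculations", {
  # 1 A^2/ps = 1e-20 m^2 / 1e-12 s = 1e-8 m^2/s = 100 x 1e-10 m^2/s
  expect_equal(diffusion_A2fs_to_SI(1e-3), 100)
  expect_equal(diffusion_SI_to_A2fs(diffusion_A2fs_to_SI(0.37)), 0.37)
  # 3500 cm^-1 has period 1/(c * 3500) = 9.53 fs
  expect_equal(2 * pi / cm1_to_radfs(3500), 9.5304, tolerance = 1e-4)
  expect_equal(radfs_to_cm1(cm1_to_radfs(1234.5)), 1234.5)
})
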