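test_that("static two-level system: unimodular phases, carrier-only response", {
  fs <- frequency_set(matrix(3500, 400, 2), dt = 2)
  resp <- compute_response(fs, t2 = 20, t_max = 100, dt_r = 4,
                           origin_stride = 20)
  expect_lt(max(abs(Mod(resp$phi_rp) - 1)), 1e-12)
  expect_lt(max(abs(Mod(resp$phi_nr) - 1)), 1e-12)
  w <- cm1_to_radfs(3500)
  carrier <- outer(exp(1i * w * resp$t1_grid), exp(-1i * w * resp$t3_grid))
  expect_lt(max(Mod(resp$R_rp - carrier)), 1e-10)
  # spectrum: single Fourier-limited peak at the carrier
  sp <- spectrum_2d(resp, zero_pad = 4, omega_span = 300)
  i <- which(sp$S == max(sp$S), arr.ind = TRUE)
  expect_close(sp$omega1_grid[i[1]], 3500, 40)
  expect_close(sp$omega3_grid[i[2]], 3500, 40)
  # echo intensity independent of t1, S3PE identically zero
  echo <- echo_intensity(fs, t2_values = c(20, 60), t1_max = 40, t3_max = 100,
                         dt_r = 4, origin_stride = 20)
  expect_true(echo$degenerate)
  expect_lt(max(abs(echo$s3pe_raw)), 1e-12)
  expect_lt(diff(range(echo$I[, 1])) / mean(echo$I[, 1]), 1e-12)
})

test_that("time-reversal symmetry of the non-rephasing phase average", {
  fs <- generate_ou_frequencies(ou_config(omega_mean = 3500, delta = 60,
                                          tau_c = 300, dt = 4, n_steps = 10000,
                                          n_oscillators = 80, seed = 61))
  resp <- compute_response(fs, t2 = 100, t_max = 160, dt_r = 8,
                           origin_stride = 100, max_origins = 800)
  expect_lt(max(Mod(resp$phi_nr - t(resp$phi_nr))), 0.05)
})

test_that("linear-response slice matches the analytic Kubo lineshape", {
  area_err <- function(a, b) sum(abs(a / sum(a) - b / sum(b)))
  # fast modulation, Delta * tau_c = 0.1 rad
  D_cm <- radfs_to_cm1(0.005)
  fs <- generate_ou_frequencies(ou_config(omega_mean = 3500, delta = D_cm,
                                          tau_c = 20, dt = 2, n_steps = 10000,
                                          n_oscillators = 600, seed = 11))
  ls <- linear_lineshape(fs, t_max = 6000, dt_r = 10, omega_span = 60,
                         d_omega = 0.25, origin_stride = 200,
                         max_origins = 100000)
  kb <- kubo_lineshape(ls$omega, 3500, D_cm, 20, t_max = 6000, dt = 10)
  expect_lt(area_err(ls$intensity, kb$intensity), 0.03)
  # slow modulation, Delta * tau_c = 10 rad
  D2 <- radfs_to_cm1(0.01)
  fs2 <- generate_ou_frequencies(ou_config(omega_mean = 3500, delta = D2,
                                           tau_c = 1000, dt = 5, n_steps = 6000,
                                           n_oscillators = 400, seed = 12))
  ls2 <- linear_lineshape(fs2, t_max = 600, dt_r = 5, omega_span = 300,
                          d_omega = 2, origin_stride = 250, max_origins = 10000)
  kb2 <- kubo_lineshape(ls2$omega, 3500, D2, 1000, t_max = 600, dt = 5)
  expect_lt(area_err(ls2$intensity, kb2$intensity), 0.03)
})

test_that("2D peak shape follows frequency memory", {
  # inhomogeneous limit, short waiting time: diagonally elongated
  fs <- generate_ou_frequencies(ou_config(omega_mean = 3500, delta = 120,
                                          tau_c = 50000, dt = 4, n_steps = 3000,
                                          n_oscillators = 200, seed = 71))
  resp <- compute_response(fs, t2 = 8, t_max = 160, dt_r = 8,
                           origin_stride = 800, max_origins = 300)
  cls_early <- center_line_slope(spectrum_2d(resp, zero_pad = 8, omega_span = 450))
  expect_gte(cls_early, 0.8)
  # after many correlation times the peak is near-round
  fs2 <- generate_ou_frequencies(ou_config(omega_mean = 3500, delta = 120,
                                           tau_c = 200, dt = 4, n_steps = 10000,
                                           n_oscillators = 200, seed = 72))
  resp2 <- compute_response(fs2, t2 = 1000, t_max = 160, dt_r = 8,
                            origin_stride = 100, max_origins = 800)
  cls_late <- center_line_slope(spectrum_2d(resp2, zero_pad = 8, omega_span = 450))
  expect_lte(abs(cls_late), 0.1)
  # perfect diagonal / round synthetic landscapes
  w <- seq(3100, 3900, by = 10)
  G <- outer(w, w, function(a, b) exp(-((a - b)^2) / (2 * 60^2)) *
               exp(-((a + b - 7000)^2) / (2 * 300^2)))
  sdiag <- center_line_slope(structure(list(S = G, omega1_grid = w,
                                            omega3_grid = w, t2 = 0),
                                       class = "spectrum_2d"))
  # analytic center line of this tilted Gaussian: maximizing over omega3 at
  # fixed omega1 gives slope (1/60^2 ... ) = 24/26, not exactly 1
  expect_close(sdiag, 24 / 26, 0.03)
  R <- outer(w, w, function(a, b) exp(-((a - 3500)^2 + (b - 3500)^2) / (2 * 100^2)))
  sround <- center_line_slope(structure(list(S = R, omega1_grid = w,
                                             omega3_grid = w, t2 = 0),
                                        class = "spectrum_2d"))
  expect_lt(abs(sround), 0.02)
})

test_that("spectrum total intensity is conserved across waiting times", {
  fs <- generate_ou_frequencies(ou_config(omega_mean = 3500, delta = 100,
                                          tau_c = 400, dt = 4, n_steps = 12000,
                                          n_oscillators = 150, seed = 81))
  totals <- sapply(c(8, 200, 800), function(t2) {
    resp <- compute_response(fs, t2 = t2, t_max = 160, dt_r = 8,
                             origin_stride = 100, max_origins = 800)
    sum(spectrum_2d(resp, zero_pad = 4, omega_span = 450)$S)
  })
  expect_lt(max(abs(totals / totals[1] - 1)), 0.02)
})
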