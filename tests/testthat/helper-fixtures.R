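# Shared fixtures, built in code.

# a hand-placed water: O at origin, H's at r0 along x and in the xy plane
make_water_pos <- function(origin = c(0, 0, 0), r0 = 0.96, theta = 104.5 * pi / 180,
                           axis_phi = 0) {
  h1 <- origin + r0 * c(cos(axis_phi), sin(axis_phi), 0)
  h2 <- origin + r0 * c(cos(axis_phi + theta), sin(axis_phi + theta), 0)
  rbind(origin, h1, h2)
}

# static trajectory from a single frame replicated nf times
static_trajectory <- function(pos, labels, nf = 4, dt = 1, box = c(20, 20, 20),
                              periodic_axes = "z", velocities = FALSE) {
  n <- nrow(pos)
  parr <- array(rep(pos, nf), c(n, 3, nf))
  varr <- if (velocities) array(0, c(n, 3, nf)) else NULL
  top <- wirespec:::.infer_topology(labels, pos, box, periodic_axes)
  wire_trajectory(top, parr, varr, dt = dt, box = box,
                  periodic_axes = periodic_axes)
}

# open chain of n waters spaced `spacing` along z, bisectors along +x
water_chain_pos <- function(n, spacing = 2.8, box = c(20, 20, 40)) {
  pos <- NULL
  for (k in seq_len(n)) {
    o <- c(box[1] / 2, box[2] / 2, 2 + (k - 1) * spacing)
    pos <- rbind(pos, make_water_pos(o))
  }
  pos
}

# short default wire run cached across test files (generated once per session)
cached_wire <- local({
  env <- new.env()
  function() {
    if (is.null(env$traj)) {
      cfg <- wire_config(n_water = 12, n_steps_equil = 6000,
                        n_steps_prod = 16000, seed = 42)
      env$traj <- generate_water_wire(cfg)
    }
    env$traj
  }
})

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%g within %g of %g", object, tol, expected))
}
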