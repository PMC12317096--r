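#' Instantaneous frequencies for every OH bond of a trajectory
#'
#' Convenience wrapper chaining [build_bond_series()], [wavelet_frequencies()]
#' and [stack_frequencies()] over all topology OH bonds, optionally
#' subsampling frames first (the OH-stretch period of ~9 fs is still
#' oversampled 4-5x at a 2 fs sampling).
#'
#' @param traj a [wire_trajectory()] with velocities.
#' @param frame_stride analyse every `frame_stride`-th frame.
#' @param omega_range,n_scales,wavelet_width passed to
#'   [wavelet_frequencies()].
#' @param omega_ref momentum scaling reference, cm^-1.
#' @return a [frequency_set()] with one column per OH bond, in topology
#'   bond order.
#' @export
wire_frequencies <- function(traj, frame_stride = 2L,
                             omega_range = c(2800, 4300), n_scales = 128,
                             wavelet_width = 6, omega_ref = 3500) {
  if (frame_stride > 1L) {
    keep <- seq(1, n_frames(traj), by = frame_stride)
    traj$positions <- traj$positions[, , keep, drop = FALSE]
    traj$velocities <- traj$velocities[, , keep, drop = FALSE]
    traj$dt <- traj$dt * frame_stride
  }
  nb <- nrow(traj$topology$oh_bonds)
  trajs <- vector("list", nb)
  for (b in seq_len(nb)) {
    bs <- build_bond_series(traj, b, omega_ref = omega_ref)
    trajs[[b]] <- wavelet_frequencies(bs, omega_range = omega_range,
                                      n_scales = n_scales,
                                      wavelet_width = wavelet_width)
  }
  stack_frequencies(trajs)
}

# gridded text writer: omega1 rows, omega3 columns
.write_grid_txt <- function(M, rows, cols, path, what = "P",
                            row_name = "omega1", col_name = "omega3") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# %s grid: rows %s [cm^-1], columns %s [cm^-1]",
                     what, row_name, col_name), con)
  writeLines(paste("#", col_name, ":", paste(format(cols, digits = 8), collapse = " ")), con)
  utils::write.table(cbind(rows, M), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.write_freqs_txt <- function(freqs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("# time [fs]", paste(freqs$bond_ids, collapse = " ")), con)
  v <- freqs$valid_range
  t <- (seq(v[1], v[2]) - 1) * freqs$dt
  utils::write.table(cbind(t, .valid_omega(freqs)), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.pl_default <- function(params, stage, key, default) {
  v <- params[[stage]][[key]]
  if (is.null(v)) default else v
}

#' Run the full generate-analyze-report pipeline
#'
#' Executes the requested stages in dependency order -- trajectory
#' (generated or read) feeds the structural stages (`rdf`, `msd`, `c2`,
#' `hbonds`, `vdos`), the wavelet stage turns bond signals into
#' instantaneous frequencies, and those feed the spectroscopy stages
#' (`pdist`, `jointdist`, `ftcf`, `twodir`, `s3pe`).  Every output is
#' written as delimited text under `outdir` and listed, with its MD5
#' digest, in the returned manifest (also written as YAML), so a re-run
#' with the same config and seed reproduces every digest.
#'
#' @param config a YAML file path or an equivalent nested list.  Top-level
#'   keys: `seed`, `outdir`, `stages` (character vector), `generate`
#'   (`kind: wire` plus [wire_config()] overrides) or `trajectory` (an
#'   extended-XYZ path, with `dt`, `box`, `periodic_axes`), and `params`
#'   (per-stage named parameter lists).
#' @param seed overrides the config seed.
#' @param outdir overrides the config output directory.
#' @return the manifest, invisibly: config snapshot, seed, package
#'   version, per-stage wall-clock seconds and output digests.
#' @export
run_pipeline <- function(config, seed = NULL, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) .stopf("config must be a YAML file or list")
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (is.null(cfg$outdir)) .stopf("config field 'outdir' is required")
  known <- c("rdf", "msd", "c2", "hbonds", "vdos", "wavelet", "pdist",
             "jointdist", "ftcf", "twodir", "s3pe")
  stages <- cfg$stages
  if (is.null(stages)) .stopf("config field 'stages' is required")
  bad <- setdiff(stages, known)
  if (length(bad)) .stopf("config field 'stages': unknown stage(s) %s",
                          paste(bad, collapse = ", "))
  params <- if (is.null(cfg$params)) list() else cfg$params
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  outputs <- character()
  timings <- numeric()
  log_stage <- function(name, expr) {
    t0 <- proc.time()[3]
    message(sprintf("[wirespec] stage %s ...", name))
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[3] - t0, 2)
    res
  }
  emit <- function(name, writer) {
    path <- file.path(cfg$outdir, name)
    writer(path)
    outputs[[name]] <<- path
    path
  }

  # trajectory stage
  traj <- if (!is.null(cfg$trajectory)) {
    log_stage("read", read_xyz_trajectory(
      cfg$trajectory, dt = cfg$dt, box = cfg$box,
      periodic_axes = if (is.null(cfg$periodic_axes)) "z" else cfg$periodic_axes))
  } else {
    gen <- cfg$generate
    if (is.null(gen) || is.null(gen$kind))
      .stopf("config needs either 'trajectory' or 'generate: {kind: wire}'")
    if (gen$kind != "wire")
      .stopf("config field 'generate.kind': only 'wire' feeds the full pipeline")
    wc_args <- gen[setdiff(names(gen), "kind")]
    wc_args$seed <- cfg$seed
    log_stage("generate", generate_water_wire(do.call(wire_config, wc_args)))
  }

  needs_freqs <- any(c("wavelet", "pdist", "jointdist", "ftcf", "twodir", "s3pe")
                     %in% stages)
  freqs <- NULL
  labels <- NULL
  hb <- NULL

  if (any(c("hbonds", "pdist") %in% stages)) {
    hb <- log_stage("hbonds", detect_hbonds(
      traj, cutoff_OO = .pl_default(params, "hbonds", "cutoff_OO", 3.3)))
    if ("hbonds" %in% stages) {
      life <- hb_lifetime(hb)
      emit("hb_lifetime.txt", function(p)
        write_series_txt(life, p, "lag", "S_HB", "fs", ""))
      emit("hb_summary.txt", function(p)
        writeLines(c(sprintf("# mean_hb_per_water %f", hb$mean_hb_per_water),
                     sprintf("# lifetime_ps %f%s", life$lifetime,
                             if (life$censored) " (censored)" else "")), p))
    }
  }
  if ("rdf" %in% stages) {
    r <- log_stage("rdf", compute_rdf(
      traj, pair_spec = .pl_default(params, "rdf", "pair_spec", c("O", "O")),
      dr = .pl_default(params, "rdf", "dr", 0.05),
      frame_stride = .pl_default(params, "rdf", "frame_stride", 10)))
    emit("rdf.txt", function(p) write_series_txt(r, p, "r", "g", "A", ""))
  }
  if ("msd" %in% stages) {
    m <- log_stage("msd", compute_msd_z(unwrap_axis(traj, "z")))
    emit("msd.txt", function(p) write_series_txt(m, p, "lag", "MSD", "fs", "A^2"))
    win <- unlist(.pl_default(params, "msd", "window", c(1, 6)))
    max_ps <- max(m$lags) / 1000
    if (win[2] > max_ps) win <- c(0.2, 0.9) * max_ps
    D <- estimate_diffusion(m, window = win)
    emit("diffusion.txt", function(p)
      writeLines(sprintf("# D_z %f 1e-10 m^2/s (window %g-%g ps, r2 %f)",
                         D$D_z, D$fit_window[1], D$fit_window[2], D$r2_of_fit), p))
  }
  if ("c2" %in% stages) {
    c2 <- log_stage("c2", compute_c2(traj))
    emit("c2.txt", function(p) write_series_txt(c2, p, "lag", "C2", "fs", ""))
  }
  if ("vdos" %in% stages) {
    v <- log_stage("vdos", compute_vdos(
      traj, max_lag = .pl_default(params, "vdos", "max_lag", 2000)))
    emit("vdos.txt", function(p)
      write_series_txt(v, p, "omega", "DoS", "cm^-1", "arb"))
  }
  if (needs_freqs) {
    freqs <- log_stage("wavelet", wire_frequencies(
      traj,
      frame_stride = .pl_default(params, "wavelet", "frame_stride", 2),
      omega_range = unlist(.pl_default(params, "wavelet", "omega_range",
                                       c(2800, 4300))),
      n_scales = .pl_default(params, "wavelet", "n_scales", 128)))
    if ("wavelet" %in% stages)
      emit("frequencies.txt", function(p) .write_freqs_txt(freqs, p))
  }
  if ("pdist" %in% stages) {
    d <- log_stage("pdist", frequency_distribution(
      freqs, bin_width = .pl_default(params, "pdist", "bin_width", 10)))
    emit("pdist.txt", function(p)
      write_series_txt(d, p, "omega", "P", "cm^-1", ""))
    if (!is.null(hb)) {
      lab <- classify_oh_modes(traj, hb)
      g <- asymmetry(freqs, lab)
      emit("asymmetry.txt", function(p)
        writeLines(sprintf("# mean_OH1 %f mean_OH2 %f gamma %f cm^-1",
                           g$mean_omega_OH1, g$mean_omega_OH2, g$gamma), p))
    }
  }
  if ("jointdist" %in% stages) {
    for (t2 in unlist(.pl_default(params, "jointdist", "t2", 100))) {
      jp <- log_stage(paste0("jointdist_t2_", t2), joint_probability(
        freqs, t2 = t2,
        bin_width = .pl_default(params, "jointdist", "bin_width", 10)))
      emit(sprintf("jointdist_t2_%g.txt", t2), function(p)
        .write_grid_txt(jp$P, jp$omega1_bins, jp$omega3_bins, p, "P"))
    }
  }
  if ("ftcf" %in% stages) {
    cf <- log_stage("ftcf", ftcf(
      freqs, max_lag = .pl_default(params, "ftcf", "max_lag", NULL),
      normalized = .pl_default(params, "ftcf", "normalized", TRUE)))
    emit("ftcf.txt", function(p) write_series_txt(cf, p, "lag", "Cww", "fs", ""))
  }
  if ("twodir" %in% stages) {
    for (t2 in unlist(.pl_default(params, "twodir", "t2", 100))) {
      resp <- log_stage(paste0("twodir_t2_", t2), compute_response(
        freqs, t2 = t2,
        t_max = .pl_default(params, "twodir", "t_max", 400),
        dt_r = .pl_default(params, "twodir", "dt_r", 4),
        origin_stride = .pl_default(params, "twodir", "origin_stride", 50)))
      sp <- spectrum_2d(resp,
                        zero_pad = .pl_default(params, "twodir", "zero_pad", 4))
      emit(sprintf("twodir_t2_%g.txt", t2), function(p)
        .write_grid_txt(sp$S, sp$omega1_grid, sp$omega3_grid, p, "S"))
    }
  }
  if ("s3pe" %in% stages) {
    t2l <- unlist(.pl_default(params, "s3pe", "t2_list",
                              c(10, 100, 200, 500, 1000, 2000)))
    echo <- log_stage("s3pe", echo_intensity(
      freqs, t2_values = t2l,
      t1_max = .pl_default(params, "s3pe", "t1_max", 100),
      t3_max = .pl_default(params, "s3pe", "t3_max", 400),
      dt_r = .pl_default(params, "s3pe", "dt_r", 4),
      origin_stride = .pl_default(params, "s3pe", "origin_stride", 50)))
    emit("s3pe.txt", function(p) {
      df <- data.frame(t2 = echo$t2_values, s3pe = echo$s3pe)
      write_series_txt(df, p, "t2", "S3PE", "fs", "")
    })
  }

  manifest <- list(
    package = "wirespec",
    version = as.character(utils::packageVersion("wirespec")),
    seed = cfg$seed,
    config = cfg,
    stage_seconds = as.list(timings),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))
  invisible(manifest)
}
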