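#' Write a numeric grid as delimited text
#'
#' Plain whitespace-delimited numeric text, row = axial index, with a
#' one-line comment header `# rows cols dx dy` giving the shape and grid
#' spacing. Diff-able and language-neutral.
#'
#' @param grid numeric matrix.
#' @param path output file.
#' @param dx,dy grid spacings (mm) recorded in the header.
#' @return invisibly, `path`.
#' @export
write_grid <- function(grid, path, dx = NA, dy = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d %d %g %g", nrow(grid), ncol(grid), dx, dy), con)
  utils::write.table(grid, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a grid written by [write_grid()]
#'
#' @param path file path.
#' @return numeric matrix with attributes `dx`, `dy`.
#' @export
read_grid <- function(path) {
  hdr <- readLines(path, n = 1L)
  info <- as.numeric(strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1L]])
  g <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(g) <- NULL
  if (nrow(g) != info[1L] || ncol(g) != info[2L])
    stop(sprintf("grid shape %dx%d does not match header %dx%d",
                 nrow(g), ncol(g), info[1L], info[2L]))
  attr(g, "dx") <- info[3L]; attr(g, "dy") <- info[4L]
  g
}

#' Write an RF frame as 16-bit binary with a text sidecar header
#'
#' Samples are scaled to the int16 range, written column-major
#' (little-endian), with `<path>.hdr` recording `rows`, `cols`, `f0`,
#' `fs`, `line_pitch`, `c` and the scale factor as `key value` lines.
#'
#' @param frame an [rf_frame()].
#' @param path output binary path.
#' @return invisibly, `path`.
#' @export
write_rf_binary <- function(frame, path) {
  x <- frame$samples
  scale <- max(abs(x), 1e-300) / 32000
  q <- as.integer(round(x / scale))
  con <- file(path, "wb")
  writeBin(q, con, size = 2L, endian = "little")
  close(con)
  hdr <- c(rows = nrow(x), cols = ncol(x), f0 = frame$probe$f0,
           fs = frame$probe$fs, line_pitch = frame$probe$line_pitch,
           c = frame$probe$c, scale = scale)
  writeLines(paste(names(hdr), format(hdr, digits = 17, trim = TRUE)),
             paste0(path, ".hdr"))
  invisible(path)
}

#' Read an RF frame written by [write_rf_binary()]
#'
#' @param path binary path (expects `<path>.hdr` alongside).
#' @return an [rf_frame()].
#' @export
read_rf_binary <- function(path) {
  hl <- strsplit(readLines(paste0(path, ".hdr")), "\\s+")
  hdr <- stats::setNames(as.numeric(vapply(hl, `[`, "", 2L)),
                         vapply(hl, `[`, "", 1L))
  n <- hdr[["rows"]] * hdr[["cols"]]
  con <- file(path, "rb")
  on.exit(close(con))
  q <- readBin(con, "integer", n = n, size = 2L, endian = "little")
  if (length(q) != n)
    stop(sprintf("format error: expected %d int16 samples, found %d (%s)",
                 n, length(q), "truncated RF file?"))
  probe <- probe_spec(f0 = hdr[["f0"]], fs = hdr[["fs"]], c = hdr[["c"]],
                      line_pitch = hdr[["line_pitch"]])
  rf_frame(matrix(q * hdr[["scale"]], hdr[["rows"]], hdr[["cols"]]), probe)
}

#' Write an RF frame as delimited text (equivalent reader exists)
#'
#' @param frame an [rf_frame()].
#' @param path output path.
#' @export
write_rf_text <- function(frame, path) {
  write_grid(frame$samples, path, dx = frame$probe$line_pitch,
             dy = frame$probe$sample_depth_mm)
}

#' Read a text RF frame written by [write_rf_text()]
#'
#' @param path input path.
#' @param probe a [probe_spec()].
#' @export
read_rf_text <- function(path, probe = probe_spec()) {
  rf_frame(read_grid(path), probe)
}

#' Load a run configuration from structured text (YAML)
#'
#' Recognized top-level blocks: `phantom` (fields of [phantom_config()]),
#' `filter` (fields of [hinf_config()]), `probe` ([probe_spec()]),
#' `tiam` ([tiam_config()]), `seed`. Missing blocks fall back to package
#' defaults.
#'
#' @param path YAML file path.
#' @return list with `phantom`, `filter`, `probe`, `tiam`, `seed`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build <- function(fn, block) {
    args <- raw[[block]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad) > 0)
      stop(sprintf("usage error: unknown %s config field(s): %s",
                   block, paste(bad, collapse = ", ")))
    do.call(fn, args)
  }
  list(phantom = build(phantom_config, "phantom"),
       filter = build(hinf_config, "filter"),
       probe = build(probe_spec, "probe"),
       tiam = build(tiam_config, "tiam"),
       seed = as.integer(raw$seed %||% 1L))
}

write_manifest <- function(path, entries) {
  entries$package_version <- as.character(utils::packageVersion("elastofilt"))
  entries$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Simulate stage: phantom ground truth and noisy measurements to disk
#'
#' Runs build -> solve -> noise -> sample and writes: ground-truth and
#' noisy displacement grids (one delimited file per component), the mesh,
#' the measurement table, and a manifest recording the resolved
#' configuration, seed and realized SNRs.
#'
#' @param config a [phantom_config()] (or path to a YAML run config).
#' @param out_dir output directory (created).
#' @param seed root seed.
#' @param snr_axial,snr_lateral per-component SNR (dB); `NA` omits noise
#'   on that component from the measurement set.
#' @param kind noise kind.
#' @return invisibly, the manifest path.
#' @export
cli_simulate <- function(config = phantom_config(), out_dir, seed = 1L,
                         snr_axial = 30, snr_lateral = 10,
                         kind = "gaussian") {
  if (is.character(config)) config <- read_run_config(config)$phantom
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_phantom(config, seed = seed, snr_axial = snr_axial,
                          snr_lateral = snr_lateral, kind = kind)
  grid_of <- function(u) {
    nodes <- attr(sim$meas, "nodes")
    matrix(u[nodes], nrow = config$measurement_grid[1L])
  }
  dx <- config$width / (config$measurement_grid[2L] - 1L)
  dy <- config$height / (config$measurement_grid[1L] - 1L)
  write_grid(grid_of(sim$truth$u_axial),
             file.path(out_dir, "truth_axial.txt"), dx, dy)
  write_grid(grid_of(sim$truth$u_lateral),
             file.path(out_dir, "truth_lateral.txt"), dx, dy)
  write_grid(grid_of(sim$noisy[[1L]]$u_axial),
             file.path(out_dir, "noisy_axial.txt"), dx, dy)
  write_grid(grid_of(sim$noisy[[1L]]$u_lateral),
             file.path(out_dir, "noisy_lateral.txt"), dx, dy)
  write_mesh(sim$phantom$mesh, file.path(out_dir, "mesh"))
  utils::write.table(
    data.frame(dof = sim$meas$indices, value = sim$meas$values[, 1L],
               kappa = sim$meas$confidence),
    file.path(out_dir, "measurements.txt"), row.names = FALSE, quote = FALSE)
  write_manifest(file.path(out_dir, "manifest.yaml"), list(
    stage = "simulate", seed = seed, noise_kind = kind,
    snr_target_db = list(axial = snr_axial, lateral = snr_lateral),
    snr_realized_db = as.list(stats::setNames(
      as.numeric(sim$realized_snr_db[1L, ]),
      colnames(sim$realized_snr_db))),
    phantom = unclass(config)))
}

#' Track stage: phase-shift displacement estimation on an RF pair
#'
#' @param rf_pre,rf_post paths to RF binaries (see [write_rf_binary()])
#'   or [rf_frame()] objects.
#' @param out_dir output directory.
#' @param window_mm,overlap segment geometry ([segment_grid()]).
#' @return invisibly, the [estimate_axial_disp()] result; displacement
#'   and correlation-quality grids plus a manifest are written.
#' @export
cli_track <- function(rf_pre, rf_post, out_dir, window_mm = 1.5,
                      overlap = 0.75) {
  if (is.character(rf_pre)) rf_pre <- read_rf_binary(rf_pre)
  if (is.character(rf_post)) rf_post <- read_rf_binary(rf_post)
  if (!identical(dim(rf_pre$samples), dim(rf_post$samples)))
    stop("format error: pre and post RF frames differ in shape")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- segment_grid(rf_pre, window_mm = window_mm, overlap = overlap)
  dm <- estimate_axial_disp(rf_pre, rf_post, grid)
  write_grid(dm$d, file.path(out_dir, "axial_disp.txt"),
             dx = rf_pre$probe$line_pitch,
             dy = diff(dm$centers_mm[1:2]))
  write_grid(dm$corr_mag, file.path(out_dir, "corr_quality.txt"))
  write_manifest(file.path(out_dir, "manifest.yaml"), list(
    stage = "track", window_mm = window_mm, overlap = overlap,
    probe = unclass(rf_pre$probe)))
  invisible(dm)
}

#' Filter stage: model-constrained recovery, strains and metrics
#'
#' Assembles the uniform biomechanical model, runs the H-infinity filter
#' on the simulated measurements, derives all five strain images, and —
#' when the truth is available — writes a metric report (EDR, positional
#' error, optionally the incompressibility baseline comparison).
#'
#' @param sim a [simulate_phantom()] result (the in-memory product of
#'   the simulate stage).
#' @param out_dir output directory.
#' @param cfg an [hinf_config()].
#' @param baseline also run the TIAM baseline and report its EDR.
#' @return invisibly, a list with the filter fit, strain field and the
#'   metric report.
#' @export
cli_filter <- function(sim, out_dir, cfg = hinf_config(),
                       baseline = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- filter_phantom(sim, cfg)
  est <- fit$fields[[1L]]
  strain <- strain_from_displacement(est)
  for (comp in c("eps_axial", "eps_lateral", "eps_axial_shear",
                 "eps_lateral_shear", "eps_shear")) {
    r <- strain_raster(strain, comp, rows = 64L, cols = 64L)
    write_grid(r, file.path(out_dir, paste0(comp, ".txt")))
  }
  report <- list(edr = edr(est, sim$truth),
                 pos_err = positional_error(est, sim$truth)$pos_err_mean)
  if (baseline) report$edr_tiam <- tiam_phantom(sim)$edr
  writeLines(paste(names(report), vapply(report, format, "")),
             file.path(out_dir, "metrics.txt"))
  log <- data.frame(iteration = seq_len(nrow(fit$innovation)),
                    innovation_norm = fit$innovation[, 1L])
  utils::write.table(log, file.path(out_dir, "filter_log.txt"),
                     row.names = FALSE, quote = FALSE)
  write_manifest(file.path(out_dir, "manifest.yaml"), list(
    stage = "filter", gamma = cfg$gamma, n_iter = cfg$n_iter,
    q = cfg$q, v_axial = cfg$v_axial, v_lateral = cfg$v_lateral))
  invisible(list(fit = fit, strain = strain, report = report))
}
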