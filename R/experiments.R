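#' Simulate one set of noisy phantom measurements
#'
#' Runs the full synthetic-data chain for the compressed inclusion
#' phantom: forward solve for ground truth, typed noise per displacement
#' component at the requested SNRs, and grid sampling. The defaults are
#' the first study design: both components measured, 30 dB axial / 10 dB
#' lateral Gaussian noise on a 21 x 21 grid.
#'
#' @param config a [phantom_config()].
#' @param seed root seed for the noise substreams.
#' @param snr_axial,snr_lateral per-component SNR targets (dB); `NA`
#'   drops the component from the measurement set.
#' @param kind noise kind (see [noise_spec()]).
#' @param n_rep number of independent noise realisations (the sampled
#'   measurement values become a matrix with one column per repeat).
#' @param phantom optionally a prebuilt [build_phantom()] result.
#' @param truth optionally a precomputed [ground_truth()] field.
#' @return list with `phantom`, `truth`, `meas` (grid
#'   [measurement_set()], possibly matrix-valued), `noisy` (list of
#'   noisy fields), `realized_snr_db`, `config`.
#' @export
simulate_phantom <- function(config = phantom_config(), seed = 1L,
                             snr_axial = 30, snr_lateral = 10,
                             kind = "gaussian", n_rep = 1L,
                             phantom = NULL, truth = NULL) {
  if (is.null(phantom)) phantom <- build_phantom(config)
  if (is.null(truth)) truth <- ground_truth(config, phantom)
  components <- c(if (!is.na(snr_axial)) "axial",
                  if (!is.na(snr_lateral)) "lateral")
  if (length(components) == 0L) stop("at least one component must be noisy")
  noisy <- vector("list", n_rep)
  vals <- NULL
  snrs <- NULL
  for (r in seq_len(n_rep)) {
    ax <- truth$u_axial; lat <- truth$u_lateral
    rs <- c()
    if (!is.na(snr_axial)) {
      ax <- add_noise(truth$u_axial,
                      noise_spec(kind, snr_axial, seed + 1000L * r))
      rs <- c(rs, axial = attr(ax, "realized_snr_db"))
    }
    if (!is.na(snr_lateral)) {
      lat <- add_noise(truth$u_lateral,
                       noise_spec(kind, snr_lateral, seed + 1000L * r + 500L))
      rs <- c(rs, lateral = attr(lat, "realized_snr_db"))
    }
    noisy[[r]] <- displacement_field(phantom$mesh, as.numeric(ax),
                                     as.numeric(lat))
    ms <- sample_measurements(noisy[[r]], config$measurement_grid,
                              components = components)
    vals <- cbind(vals, ms$values)
    snrs <- rbind(snrs, rs)
    if (r == 1L) meas_template <- ms
  }
  meas <- measurement_set(meas_template$indices, vals,
                          meas_template$confidence)
  attr(meas, "nodes") <- attr(meas_template, "nodes")
  attr(meas, "components") <- components
  list(phantom = phantom, truth = truth, meas = meas, noisy = noisy,
       realized_snr_db = snrs, config = config)
}

#' Assemble the filter's biomechanical model for a phantom experiment
#'
#' The filter does not know the inclusion: its model is spatially
#' uniform (`filter_E`, `filter_nu`), as in the study design where the
#' modulus is initialized from known healthy-background properties.
#' Trusted boundary information enters by penalty: zero axial
#' displacement on the (supported) bottom edge, a lateral pin at the
#' bottom-center node, and the measured axial values at the sampled
#' top-edge nodes (one column per measurement realisation).
#'
#' @param sim a [simulate_phantom()] result.
#' @param filter_E uniform Young's modulus used by the filter (kPa);
#'   defaults to the phantom background.
#' @param filter_nu Poisson's ratio used by the filter; defaults to the
#'   phantom's.
#' @param kappa penalty confidence for the trusted boundary values.
#' @return penalty-augmented `fem_system`.
#' @export
filter_model_system <- function(sim, filter_E = NULL, filter_nu = NULL,
                                kappa = 1e6) {
  config <- sim$config
  mesh <- sim$phantom$mesh
  if (is.null(filter_E)) filter_E <- config$E_background
  if (is.null(filter_nu)) filter_nu <- config$nu
  material <- material_field(mesh, E = filter_E, nu = filter_nu,
                             rho = config$rho, alpha_R = config$alpha_R,
                             beta_R = config$beta_R)
  system <- assemble_system(mesh, material)
  bottom <- which(mesh$boundary_tags == "fixed")
  pin <- bottom[which.min(abs(mesh$nodes[bottom, 1L] - config$width / 2))]
  nr <- ncol(sim$meas$values)
  # measured axial values at sampled top-edge nodes, per realisation
  mnodes <- attr(sim$meas, "nodes")
  top_meas <- mnodes[mesh$nodes[mnodes, 2L] < 1e-9]
  has_axial <- "axial" %in% attr(sim$meas, "components")
  idx <- c(2L * bottom, 2L * pin - 1L)
  val <- matrix(0, length(idx), nr)
  if (has_axial && length(top_meas) > 0L) {
    rows <- match(2L * top_meas, sim$meas$indices)
    idx <- c(idx, 2L * top_meas)
    val <- rbind(val, sim$meas$values[rows, , drop = FALSE])
  }
  bc <- measurement_set(idx, val, kappa)
  apply_measurement_penalty(system, bc)
}

#' Recover the full displacement field of a simulated phantom
#'
#' Convenience wrapper: builds the uniform filter model, runs the
#' H-infinity filter against the sampled noisy measurements, and returns
#' the result.
#'
#' @inheritParams filter_model_system
#' @param cfg an [hinf_config()].
#' @return an `hinf_result` (see [run_filter()]).
#' @export
filter_phantom <- function(sim, cfg = hinf_config(), filter_E = NULL,
                           filter_nu = NULL) {
  system <- filter_model_system(sim, filter_E, filter_nu)
  run_filter(system, sim$meas, cfg)
}

# noisy axial displacement as a rows x cols grid matrix (row = axial)
grid_axial_matrix <- function(sim, rep = 1L) {
  rows <- sim$config$measurement_grid[1L]
  cols <- sim$config$measurement_grid[2L]
  nodes <- attr(sim$meas, "nodes")
  if (length(nodes) != rows * cols)
    stop("measurement grid nodes are not a full lattice")
  rows_idx <- match(2L * nodes, sim$meas$indices)
  u <- sim$meas$values[rows_idx, rep]
  matrix(u, nrow = rows)   # sampling order: y fastest within each x column
}

# true lateral displacement at the grid nodes, same layout
grid_truth_lateral <- function(sim) {
  nodes <- attr(sim$meas, "nodes")
  matrix(sim$truth$u_lateral[nodes],
         nrow = sim$config$measurement_grid[1L])
}

#' TIAM lateral recovery from the sampled noisy axial data
#'
#' Differentiates the gridded noisy axial displacement axially (central
#' differences), negates it as the incompressibility estimate of the
#' lateral strain, and integrates laterally (see [tiam_lateral()]).
#'
#' @param sim a [simulate_phantom()] result.
#' @param cfg a [tiam_config()].
#' @param rep which noise realisation to use.
#' @return list with `lateral` (grid matrix, mm), `edr` against the true
#'   lateral displacement at the grid nodes.
#' @export
tiam_phantom <- function(sim, cfg = tiam_config(origin = "center"),
                         rep = 1L) {
  u <- grid_axial_matrix(sim, rep)
  rows <- nrow(u); cols <- ncol(u)
  dy <- sim$config$height / (rows - 1L)
  dx <- sim$config$width / (cols - 1L)
  eps <- u * NA_real_
  eps[2:(rows - 1L), ] <- (u[3:rows, ] - u[1:(rows - 2L), ]) / (2 * dy)
  eps[1L, ] <- (u[2L, ] - u[1L, ]) / dy
  eps[rows, ] <- (u[rows, ] - u[rows - 1L, ]) / dy
  v <- tiam_lateral(eps, dx, cfg)
  truth_lat <- grid_truth_lateral(sim)
  list(lateral = v, edr = edr(as.vector(v), as.vector(truth_lat)))
}

#' Poisson's-ratio sweep: model-constrained filter vs incompressibility baseline
#'
#' For each Poisson's ratio, simulates the compressed phantom (both
#' displacement components measured, 30 dB axial / 10 dB lateral noise),
#' recovers the lateral displacement with the H-infinity filter (which
#' uses the true nu but a uniform background modulus) and with the
#' incompressibility baseline, and reports both error-to-displacement
#' ratios.
#'
#' @param nus Poisson's ratios to sweep.
#' @param config phantom configuration (its `nu` is overridden per point).
#' @param cfg filter configuration.
#' @param seed root seed.
#' @param snr_axial,snr_lateral measurement SNRs (dB).
#' @param n_rep noise realisations per sweep point; the reported EDRs are
#'   means over realisations (all realisations of one point share a
#'   single Riccati recursion).
#' @return data.frame with columns `nu`, `edr_hinf`, `edr_tiam`.
#' @export
edr_sweep <- function(nus = c(0.25, 0.30, 0.35, 0.40, 0.45, 0.49),
                      config = phantom_config(), cfg = hinf_config(),
                      seed = 1L, snr_axial = 30, snr_lateral = 10,
                      n_rep = 1L) {
  out <- data.frame(nu = nus, edr_hinf = NA_real_, edr_tiam = NA_real_)
  for (i in seq_along(nus)) {
    cfg_i <- config
    cfg_i$nu <- nus[i]
    sim <- simulate_phantom(cfg_i, seed = seed + i,
                            snr_axial = snr_axial,
                            snr_lateral = snr_lateral, n_rep = n_rep)
    fit <- filter_phantom(sim, cfg)
    out$edr_hinf[i] <- mean(vapply(fit$fields, edr, numeric(1),
                                   truth_lateral = sim$truth))
    out$edr_tiam[i] <- mean(vapply(seq_len(n_rep), function(r)
      tiam_phantom(sim, rep = r)$edr, numeric(1)))
  }
  out
}

#' Model-mismatch robustness study
#'
#' Axial-only measurements (30 dB); the filter's uniform material is
#' perturbed away from the phantom's true parameters either in
#' Poisson's ratio (`used nu = true nu + dnu`) or in Young's modulus
#' (`used E = background E + dE`, in kPa). Reports the mean nodal
#' positional error and the lateral EDR for every case.
#'
#' @param dnu,dE mismatch offsets (each evaluated with the other
#'   parameter held at truth/background).
#' @param config phantom configuration.
#' @param cfg filter configuration.
#' @param seed root seed.
#' @return data.frame with `param`, `offset`, `pos_err`, `edr`.
#' @export
mismatch_study <- function(dnu = c(0, -0.02, -0.04, -0.08),
                           dE = c(-20, 0, 20, 60),
                           config = phantom_config(), cfg = hinf_config(),
                           seed = 1L) {
  sim <- simulate_phantom(config, seed = seed, snr_axial = 30,
                          snr_lateral = NA)
  run_case <- function(E, nu) {
    fit <- filter_phantom(sim, cfg, filter_E = E, filter_nu = nu)
    c(pos = positional_error(fit$fields[[1L]], sim$truth)$pos_err_mean,
      edr = edr(fit$fields[[1L]], sim$truth))
  }
  rows <- list()
  for (d in dnu) {
    r <- run_case(config$E_background, config$nu + d)
    rows[[length(rows) + 1L]] <-
      data.frame(param = "nu", offset = d, pos_err = r[["pos"]],
                 edr = r[["edr"]])
  }
  for (d in dE) {
    if (d == 0) next  # identical to the dnu = 0 baseline
    r <- run_case(config$E_background + d, config$nu)
    rows[[length(rows) + 1L]] <-
      data.frame(param = "E", offset = d, pos_err = r[["pos"]],
                 edr = r[["edr"]])
  }
  do.call(rbind, rows)
}

#' Noise-type robustness study
#'
#' Axial-only measurements. For each SNR level and noise kind, runs
#' `n_rep` independent realisations through the filter and reports the
#' mean and standard deviation of the nodal positional error. All
#' realisations of one SNR level share a single Riccati recursion
#' (matrix-valued measurements), since the filter gain sequence does not
#' depend on the measured values.
#'
#' By default the filter runs with the phantom's true material field
#' (`filter_material = "matched"`), so the reported errors isolate
#' sensitivity to measurement noise; the uniform-initialization bias is
#' quantified separately by [mismatch_study()]. Set
#' `filter_material = "background"` for the uniform model instead.
#'
#' @param kinds noise kinds to compare.
#' @param snr_dbs SNR levels (dB).
#' @param n_rep repeats per (kind, SNR) cell.
#' @param config phantom configuration.
#' @param cfg filter configuration.
#' @param seed root seed.
#' @param filter_material `"matched"` or `"background"` (see Details).
#' @return data.frame with `kind`, `snr_db`, `pos_err_mean`, `pos_err_std`.
#' @export
noise_type_study <- function(kinds = c("gaussian", "uniform", "poisson",
                                       "rayleigh", "exponential"),
                             snr_dbs = c(20, 15), n_rep = 5L,
                             config = phantom_config(),
                             cfg = hinf_config(), seed = 1L,
                             filter_material = c("matched", "background")) {
  filter_material <- match.arg(filter_material)
  phantom <- build_phantom(config)
  truth <- ground_truth(config, phantom)
  fE <- if (filter_material == "matched") phantom$material$E else NULL
  out <- list()
  for (snr in snr_dbs) {
    sims <- list(); vals <- NULL
    for (ki in seq_along(kinds)) {
      s <- simulate_phantom(config, seed = seed + 7919L * ki +
                              round(100 * snr),
                            snr_axial = snr, snr_lateral = NA,
                            kind = kinds[ki], n_rep = n_rep,
                            phantom = phantom, truth = truth)
      sims[[ki]] <- s
      vals <- cbind(vals, s$meas$values)
    }
    meas_all <- measurement_set(sims[[1L]]$meas$indices, vals,
                                sims[[1L]]$meas$confidence)
    attr(meas_all, "nodes") <- attr(sims[[1L]]$meas, "nodes")
    attr(meas_all, "components") <- attr(sims[[1L]]$meas, "components")
    sim_all <- sims[[1L]]
    sim_all$meas <- meas_all
    fit <- filter_phantom(sim_all, cfg, filter_E = fE)
    for (ki in seq_along(kinds)) {
      cols <- (ki - 1L) * n_rep + seq_len(n_rep)
      pe <- positional_error(fit$fields[cols], truth)
      out[[length(out) + 1L]] <-
        data.frame(kind = kinds[ki], snr_db = snr,
                   pos_err_mean = pe$pos_err_mean,
                   pos_err_std = pe$pos_err_std)
    }
  }
  do.call(rbind, out)
}

#' Inclusion/background masks on phantom elements
#'
#' @param phantom a [build_phantom()] result.
#' @param config the phantom configuration.
#' @param shrink target mask keeps centroids within `shrink * radius`;
#'   background mask beyond `grow * radius`.
#' @param grow see `shrink`.
#' @return list of logical element masks `target` and `background`.
#' @export
phantom_masks <- function(phantom, config, shrink = 0.8, grow = 1.5) {
  cen <- t(vapply(seq_len(nrow(phantom$mesh$triangles)), function(e) {
    colMeans(phantom$mesh$nodes[phantom$mesh$triangles[e, ], , drop = FALSE])
  }, numeric(2)))
  d <- sqrt((cen[, 1L] - config$inclusion_center[1L])^2 +
            (cen[, 2L] - config$inclusion_center[2L])^2)
  list(target = d < shrink * config$inclusion_radius,
       background = d > grow * config$inclusion_radius)
}
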