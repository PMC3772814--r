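#' Configuration of the synthetic inclusion phantom
#'
#' Describes a rectangular soft body with a stiff circular inclusion under
#' uniaxial compression: the canonical numerical phantom for quasi-static
#' elastography. Defaults: 40 x 40 mm domain, 5 mm-radius inclusion at the
#' center, 80 kPa inclusion in a 25 kPa background, 2 % compression, 1 mm
#' node spacing and a 21 x 21 measurement grid (an every-other-node subset
#' of the default mesh).
#'
#' @param width,height domain size (mm).
#' @param inclusion_center length-2 vector `(x, y)` (mm).
#' @param inclusion_radius inclusion radius (mm); must fit inside the domain.
#' @param E_inclusion,E_background Young's moduli (kPa).
#' @param nu Poisson's ratio (shared by inclusion and background).
#' @param compression_ratio applied axial deformation fraction, in (0, 0.1).
#' @param mesh_density target node spacing (mm).
#' @param measurement_grid integer `(rows, cols)` of sampled nodes; both
#'   at least 2.
#' @param rho,alpha_R,beta_R material density and Rayleigh damping weights,
#'   passed to [material_field()].
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(width = 40, height = 40,
                           inclusion_center = c(width / 2, height / 2),
                           inclusion_radius = 5,
                           E_inclusion = 80, E_background = 25,
                           nu = 0.49, compression_ratio = 0.02,
                           mesh_density = 1,
                           measurement_grid = c(21L, 21L),
                           rho = 1000, alpha_R = 0.05, beta_R = 0.05) {
  stopifnot(width > 0, height > 0, inclusion_radius > 0,
            E_inclusion > 0, E_background > 0)
  if (compression_ratio <= 0 || compression_ratio >= 0.1)
    stop("compression_ratio must lie in (0, 0.1)")
  if (any(measurement_grid < 2L))
    stop("measurement_grid dimensions must be >= 2")
  cx <- inclusion_center[1L]; cy <- inclusion_center[2L]
  if (cx - inclusion_radius < 0 || cx + inclusion_radius > width ||
      cy - inclusion_radius < 0 || cy + inclusion_radius > height)
    stop("inclusion must lie fully inside the domain")
  structure(list(width = width, height = height,
                 inclusion_center = c(cx, cy),
                 inclusion_radius = inclusion_radius,
                 E_inclusion = E_inclusion, E_background = E_background,
                 nu = nu, compression_ratio = compression_ratio,
                 mesh_density = mesh_density,
                 measurement_grid = as.integer(measurement_grid),
                 rho = rho, alpha_R = alpha_R, beta_R = beta_R),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("phantom_config: %g x %g mm, inclusion r=%g mm @ (%g, %g)\n",
              x$width, x$height, x$inclusion_radius,
              x$inclusion_center[1L], x$inclusion_center[2L]))
  cat(sprintf("  E = %g / %g kPa (inclusion / background), nu = %g\n",
              x$E_inclusion, x$E_background, x$nu))
  cat(sprintf("  compression %g%%, mesh density %g mm, grid %d x %d\n",
              100 * x$compression_ratio, x$mesh_density,
              x$measurement_grid[1L], x$measurement_grid[2L]))
  invisible(x)
}

#' Build the phantom mesh and material field
#'
#' Meshes the rectangular domain at the requested density and labels each
#' element inclusion or background by whether its centroid falls inside
#' the inclusion circle. Bottom-edge nodes are tagged fixed, top-edge
#' nodes loaded.
#'
#' @param config a [phantom_config()].
#' @return list with `mesh` (a [tri_mesh()]) and `material`
#'   (a [material_field()]); element inclusion flags are attached to the
#'   material as `inclusion` (logical per element).
#' @export
build_phantom <- function(config) {
  nx <- max(2L, round(config$width / config$mesh_density) + 1L)
  ny <- max(2L, round(config$height / config$mesh_density) + 1L)
  mesh <- rect_grid_mesh(config$width, config$height, nx, ny)
  tri <- mesh$triangles
  cx <- (mesh$nodes[tri[, 1L], 1L] + mesh$nodes[tri[, 2L], 1L] +
         mesh$nodes[tri[, 3L], 1L]) / 3
  cy <- (mesh$nodes[tri[, 1L], 2L] + mesh$nodes[tri[, 2L], 2L] +
         mesh$nodes[tri[, 3L], 2L]) / 3
  inside <- (cx - config$inclusion_center[1L])^2 +
            (cy - config$inclusion_center[2L])^2 <=
            config$inclusion_radius^2
  if (sum(inside) < 8L)
    stop("mesh density too coarse to resolve the inclusion ",
         sprintf("(%d elements inside; need >= 8)", sum(inside)))
  E <- ifelse(inside, config$E_inclusion, config$E_background)
  material <- material_field(mesh, E = E, nu = config$nu, rho = config$rho,
                             alpha_R = config$alpha_R, beta_R = config$beta_R)
  material$inclusion <- inside
  list(mesh = mesh, material = material)
}

#' Boundary dofs and prescribed values for uniaxial phantom compression
#'
#' The bottom edge rests on rollers (axial displacement zero, free to
#' slide laterally) with the bottom-center node pinned laterally to remove
#' the rigid lateral translation; the top edge is displaced axially by
#' `compression_ratio * height` (downward, away from the probe) and is
#' laterally free.
#'
#' @param mesh phantom mesh.
#' @param config phantom config.
#' @return list with `dofs` and `values`.
#' @keywords internal
phantom_bc <- function(mesh, config) {
  delta <- config$compression_ratio * config$height
  top <- which(mesh$boundary_tags == "loaded")
  bottom <- which(mesh$boundary_tags == "fixed")
  pin <- bottom[which.min(abs(mesh$nodes[bottom, 1L] - config$width / 2))]
  dofs <- c(2L * top, 2L * bottom, 2L * pin - 1L)
  values <- c(rep(delta, length(top)), rep(0, length(bottom)), 0)
  list(dofs = dofs, values = values)
}

#' Ground-truth displacement field of the compressed phantom
#'
#' Solves the plane-strain equilibrium of the phantom under uniaxial
#' compression by exact Dirichlet elimination; deterministic for a given
#' configuration. This replaces the external finite-element ground truth
#' of the original experimental design with an in-package solve.
#'
#' @param config a [phantom_config()].
#' @param phantom optionally, a prebuilt [build_phantom()] result.
#' @return a [displacement_field()].
#' @export
ground_truth <- function(config, phantom = build_phantom(config)) {
  system <- assemble_system(phantom$mesh, phantom$material)
  bc <- phantom_bc(phantom$mesh, config)
  static_solve(system, bc$dofs, bc$values)
}

#' Specification of one additive measurement-noise draw
#'
#' @param kind one of `"gaussian"`, `"uniform"`, `"poisson"`, `"rayleigh"`,
#'   `"exponential"`.
#' @param snr_db target signal-to-noise ratio in dB
#'   (`10*log10(rms_signal^2 / rms_noise^2)`).
#' @param seed integer seed making the draw reproducible.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian", "uniform", "poisson",
                                "rayleigh", "exponential"),
                       snr_db, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.finite(snr_db)) stop("snr_db must be finite")
  structure(list(kind = kind, snr_db = snr_db, seed = as.integer(seed)),
            class = "noise_spec")
}

# draw n samples of the requested kind, centered by subtracting the
# distribution mean (not the sample mean)
draw_centered_noise <- function(kind, n) {
  switch(kind,
         gaussian = stats::rnorm(n),
         uniform = stats::runif(n, -1, 1),
         poisson = stats::rpois(n, lambda = 1) - 1,
         rayleigh = {
           # Rayleigh(sigma = 1) via inverse transform; mean sigma*sqrt(pi/2)
           sqrt(-2 * log(stats::runif(n))) - sqrt(pi / 2)
         },
         exponential = stats::rexp(n, rate = 1) - 1,
         stop("unknown noise kind: ", kind))
}

rms <- function(x) sqrt(mean(x^2))

# run expr with the RNG seeded locally, restoring global RNG state after
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Add typed noise at a target signal-to-noise ratio
#'
#' Draws noise of the requested kind, centers it to zero mean (the
#' distribution mean is subtracted for the asymmetric kinds) and scales it
#' so the realized SNR `10*log10(rms(x)^2 / rms(noise)^2)` equals
#' `spec$snr_db` exactly. Reproducible for a fixed seed.
#'
#' @param x numeric vector (a displacement component), or a
#'   [displacement_field()] (both components receive independent noise at
#'   the same SNR).
#' @param spec a [noise_spec()].
#' @return noisy copy of `x`; for vectors, the realized noise vector is
#'   attached as attribute `"noise"`.
#' @export
add_noise <- function(x, spec) UseMethod("add_noise")

#' @export
add_noise.numeric <- function(x, spec) {
  sig <- rms(x)
  if (sig == 0) stop("cannot scale noise: signal is identically zero")
  noise <- with_seed(spec$seed, draw_centered_noise(spec$kind, length(x)))
  target_rms <- sig * 10^(-spec$snr_db / 20)
  noise <- noise * (target_rms / rms(noise))
  out <- x + noise
  attr(out, "noise") <- noise
  attr(out, "realized_snr_db") <- 20 * log10(sig / rms(noise))
  out
}

#' @export
add_noise.displacement_field <- function(x, spec) {
  ax <- add_noise(x$u_axial, spec)
  spec_lat <- spec; spec_lat$seed <- spec$seed + 1L
  lat <- add_noise(x$u_lateral, spec_lat)
  out <- displacement_field(x$mesh, as.numeric(ax), as.numeric(lat))
  attr(out, "realized_snr_db") <- c(axial = attr(ax, "realized_snr_db"),
                                    lateral = attr(lat, "realized_snr_db"))
  out
}

#' Sample a displacement field on a regular measurement grid
#'
#' Lays a `rows x cols` grid over the mesh bounding box, snaps each grid
#' point to its nearest mesh node (deduplicated), and collects the
#' requested displacement components into a [measurement_set()] on system
#' dofs.
#'
#' @param field a [displacement_field()] (typically the noisy truth).
#' @param grid integer `(rows, cols)`; rows index the axial direction.
#' @param components subset of `c("axial", "lateral")`.
#' @param confidence named penalty/confidence weights per component
#'   (recycled), e.g. `c(axial = 1e6, lateral = 1e4)`.
#' @return a [measurement_set()]; the snapped node indices are attached as
#'   attribute `"nodes"`.
#' @export
sample_measurements <- function(field, grid,
                                components = c("axial", "lateral"),
                                confidence = c(axial = 1e6, lateral = 1e6)) {
  if (length(components) == 0L) stop("empty component set")
  components <- match.arg(components, several.ok = TRUE)
  mesh <- field$mesh
  bb <- apply(mesh$nodes, 2L, range)
  gy <- seq(bb[1L, 2L], bb[2L, 2L], length.out = grid[1L])
  gx <- seq(bb[1L, 1L], bb[2L, 1L], length.out = grid[2L])
  pts <- cbind(rep(gx, each = length(gy)), rep(gy, times = length(gx)))
  nearest <- vapply(seq_len(nrow(pts)), function(i) {
    which.min((mesh$nodes[, 1L] - pts[i, 1L])^2 +
              (mesh$nodes[, 2L] - pts[i, 2L])^2)
  }, integer(1))
  nodes <- unique(nearest)
  idx <- integer(0); val <- numeric(0); conf <- numeric(0)
  if ("axial" %in% components) {
    idx <- c(idx, 2L * nodes)
    val <- c(val, field$u_axial[nodes])
    ka <- if (!is.null(names(confidence))) confidence[["axial"]]
          else confidence[1L]
    conf <- c(conf, rep(ka, length(nodes)))
  }
  if ("lateral" %in% components) {
    idx <- c(idx, 2L * nodes - 1L)
    val <- c(val, field$u_lateral[nodes])
    kl <- if (!is.null(names(confidence))) confidence[["lateral"]]
          else confidence[length(confidence)]
    conf <- c(conf, rep(kl, length(nodes)))
  }
  out <- measurement_set(idx, val, conf)
  attr(out, "nodes") <- nodes
  attr(out, "components") <- components
  out
}
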