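#' Shape-function gradients and strain-displacement matrix of one element
#'
#' For a constant-strain (linear) triangle, returns the 2x3 matrix of
#' Cartesian shape-function gradients (row 1 = d/dx, row 2 = d/dy) and the
#' 3x6 strain-displacement matrix `B` mapping the interleaved element dof
#' vector `(ux1, uy1, ux2, uy2, ux3, uy3)` to `(eps_xx, eps_yy, gamma_xy)`.
#'
#' @param xy 3x2 matrix of element node coordinates (mm).
#' @return list with `grads` (2x3), `B` (3x6) and `area` (mm^2).
#' @keywords internal
element_bmat <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  area2 <- (x[2L] - x[1L]) * (y[3L] - y[1L]) -
           (x[3L] - x[1L]) * (y[2L] - y[1L])
  if (abs(area2) < .Machine$double.eps * 100 * max(1, sum(xy^2)))
    stop("degenerate (zero-area) triangle")
  b <- c(y[2L] - y[3L], y[3L] - y[1L], y[1L] - y[2L])
  c_ <- c(x[3L] - x[2L], x[1L] - x[3L], x[2L] - x[1L])
  grads <- rbind(b, c_) / area2
  B <- matrix(0, 3L, 6L)
  B[1L, c(1L, 3L, 5L)] <- grads[1L, ]  # eps_xx = dux/dx
  B[2L, c(2L, 4L, 6L)] <- grads[2L, ]  # eps_yy = duy/dy
  B[3L, c(1L, 3L, 5L)] <- grads[2L, ]  # gamma_xy = dux/dy + duy/dx
  B[3L, c(2L, 4L, 6L)] <- grads[1L, ]
  list(grads = grads, B = B, area = area2 / 2)
}

# Internal unit system: lengths mm, moduli kPa, time s. A stiffness entry in
# kPa*mm numerically equals N/m per metre of out-of-plane thickness, so the
# consistent mass is kg per metre of thickness: rho[kg/m^3] * area[mm^2] *
# 1e-6. With tissue-like parameters this puts the structural natural
# frequencies at O(100 rad/s), well scaled for the pseudo-time filtering.
RHO_AREA_SCALE <- 1e-6

#' Assemble the global FEM system of a meshed elastic body
#'
#' Builds the consistent mass matrix `M`, Rayleigh damping
#' `C = alpha_R*M + beta_R*K`, stiffness `K = sum_e area_e B_e' D_e B_e`
#' and the load vector `R` (body forces; zero by default) over all
#' displacement degrees of freedom, two per node. Node `i` owns dofs
#' `2i-1` (lateral, x) and `2i` (axial, y).
#'
#' @param mesh a [tri_mesh()].
#' @param material a [material_field()].
#' @return an object of class `fem_system`: list with `M`, `C`, `K` (dense
#'   matrices), `R` (load vector), `dof_map` (n x 2 matrix, columns =
#'   lateral/axial dof of each node), `mesh`, `material`.
#' @export
assemble_system <- function(mesh, material) {
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$triangles)
  ndof <- 2L * n
  K <- matrix(0, ndof, ndof)
  M <- matrix(0, ndof, ndof)
  # consistent CST mass pattern: (rho*A/12) * (2 on diagonal blocks, 1 off)
  mass_pat <- matrix(1, 3L, 3L) + diag(3L)
  for (e in seq_len(ne)) {
    tri <- mesh$triangles[e, ]
    xy <- mesh$nodes[tri, , drop = FALSE]
    eb <- element_bmat(xy)
    if (eb$area <= 0) stop(sprintf("degenerate triangle %d", e))
    D <- plane_strain_D(material$E[e], material$nu[e])
    Ke <- eb$area * crossprod(eb$B, D %*% eb$B)
    me <- material$rho * eb$area * RHO_AREA_SCALE / 12
    dofs <- as.vector(rbind(2L * tri - 1L, 2L * tri))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
    Mi <- me * mass_pat
    for (a in 1:3) for (b in 1:3) {
      ia <- 2L * tri[a]; ib <- 2L * tri[b]
      M[ia - 1L, ib - 1L] <- M[ia - 1L, ib - 1L] + Mi[a, b]
      M[ia, ib] <- M[ia, ib] + Mi[a, b]
    }
  }
  K <- (K + t(K)) / 2
  M <- (M + t(M)) / 2
  C <- material$alpha_R * M + material$beta_R * K
  R <- numeric(ndof)
  R[seq(1L, ndof, 2L)] <- material$body_force[, 1L]
  R[seq(2L, ndof, 2L)] <- material$body_force[, 2L]
  structure(list(M = M, C = C, K = K, R = R,
                 dof_map = cbind(lateral = 2L * seq_len(n) - 1L,
                                 axial = 2L * seq_len(n)),
                 mesh = mesh, material = material),
            class = "fem_system")
}

#' @export
print.fem_system <- function(x, ...) {
  cat(sprintf("fem_system: %d dofs (%d nodes), %d elements\n",
              nrow(x$K), nrow(x$mesh$nodes), nrow(x$mesh$triangles)))
  if (!is.null(attr(x, "penalized")))
    cat(sprintf("  penalty applied on %d dofs\n", attr(x, "penalized")))
  invisible(x)
}

#' Sparse displacement measurements on system dofs
#'
#' @param indices dof indices carrying data (unique).
#' @param values measured displacements (mm); may be a matrix with one
#'   column per realisation (same dof indices for all columns).
#' @param confidence per-entry penalty weight kappa (positive; large for
#'   trusted points). Recycled to the number of indices.
#' @return an object of class `measurement_set`.
#' @export
measurement_set <- function(indices, values, confidence = 1e6) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("measurement dof indices must be unique")
  values <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  if (nrow(values) != length(indices))
    stop("values length must match indices")
  confidence <- rep_len(as.numeric(confidence), length(indices))
  if (length(indices) > 0 && any(confidence <= 0))
    stop("invalid confidence: kappa must be positive")
  structure(list(indices = indices, values = values,
                 confidence = confidence),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("measurement_set: %d dofs, %d realisation(s)\n",
              length(x$indices), ncol(x$values)))
  invisible(x)
}

#' Enforce measured displacements by the penalty method
#'
#' Adds `kappa_i` to `K[i, i]` and `kappa_i * d_i` to `R[i]` for every
#' measured dof `i`, so that the static equilibrium is pulled toward the
#' measured values with a strength set by the confidence weights. This is
#' how known boundary displacements enter the system dynamics when the
#' external load cannot be measured (freehand compression). If the
#' measurement set carries several realisations (matrix values), `R`
#' becomes a matrix with one column per realisation.
#'
#' @param system a [assemble_system()] result.
#' @param meas a [measurement_set()].
#' @return the augmented `fem_system`.
#' @export
apply_measurement_penalty <- function(system, meas) {
  if (length(meas$indices) == 0L) return(system)
  ndof <- nrow(system$K)
  if (any(meas$indices < 1L) || any(meas$indices > ndof))
    stop("measured dof index outside system dimension")
  K <- system$K
  diag(K)[meas$indices] <- diag(K)[meas$indices] + meas$confidence
  nr <- ncol(meas$values)
  R <- matrix(system$R, ndof, nr)
  R[meas$indices, ] <- R[meas$indices, ] + meas$confidence * meas$values
  if (nr == 1L) R <- drop(R)
  system$K <- K
  system$R <- R
  attr(system, "penalized") <-
    length(meas$indices) + max(0L, attr(system, "penalized"))
  system
}

#' Static solve of the (constrained) FEM system
#'
#' Solves `K U = R`. Dirichlet constraints, when given, are imposed by
#' exact elimination (the constrained rows/columns are removed and moved
#' to the right-hand side), so prescribed values are reproduced to machine
#' precision; penalty-enforced measurements should be applied beforehand
#' with [apply_measurement_penalty()]. The system must have no remaining
#' rigid-body modes.
#'
#' @param system a `fem_system` (possibly penalty-augmented).
#' @param fixed_dofs integer vector of dof indices with prescribed values.
#' @param fixed_values prescribed displacements (mm), recycled.
#' @return a [displacement_field()]; the dof vector and the residual norm
#'   are attached as attributes `"dofs"` and `"residual"`.
#' @export
static_solve <- function(system, fixed_dofs = integer(0),
                         fixed_values = 0) {
  ndof <- nrow(system$K)
  U <- numeric(ndof)
  fixed_dofs <- as.integer(fixed_dofs)
  fixed_values <- rep_len(as.numeric(fixed_values), length(fixed_dofs))
  U[fixed_dofs] <- fixed_values
  free <- setdiff(seq_len(ndof), fixed_dofs)
  R <- if (is.matrix(system$R)) system$R[, 1L] else system$R
  rhs <- R[free] - system$K[free, fixed_dofs, drop = FALSE] %*% fixed_values
  Kff <- system$K[free, free, drop = FALSE]
  Uf <- tryCatch(solve(Kff, rhs),
                 error = function(e)
                   stop("under-constrained system: constrained stiffness is ",
                        "singular (", conditionMessage(e), ")"))
  U[free] <- Uf
  res <- sqrt(sum((Kff %*% Uf - rhs)^2))
  rnorm_ <- sqrt(sum(rhs^2))
  if (rnorm_ > 0 && res > 1e-8 * rnorm_)
    warning(sprintf("static solve residual %.3g exceeds 1e-8 relative", res))
  out <- dofs_to_field(system$mesh, U)
  attr(out, "dofs") <- U
  attr(out, "residual") <- res
  out
}
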