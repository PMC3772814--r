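#' Per-element linear-elastic material description
#'
#' @param mesh a [tri_mesh()].
#' @param E Young's modulus in kPa; scalar or one value per element.
#' @param nu Poisson's ratio, in (0, 0.5); scalar or one value per element.
#' @param rho mass density in kg/m^3 (single value; tissue density is
#'   treated as spatially uniform).
#' @param alpha_R,beta_R Rayleigh damping weights: `C = alpha_R*M + beta_R*K`.
#'   Soft tissue under quasi-static compression is only lightly damped; the
#'   defaults keep the pseudo-dynamics gently dissipative.
#' @param body_force per-node 2-column matrix of body forces; zero by
#'   default (quasi-static, gravity neglected).
#' @return an object of class `material_field`.
#' @export
material_field <- function(mesh, E, nu, rho = 1000,
                           alpha_R = 0.05, beta_R = 0.05,
                           body_force = NULL) {
  ne <- nrow(mesh$triangles)
  E <- rep_len(as.numeric(E), ne)
  nu <- rep_len(as.numeric(nu), ne)
  if (any(E <= 0)) stop("invalid material: Young's modulus must be positive")
  if (any(nu <= 0) || any(nu >= 0.5))
    stop("invalid material: Poisson's ratio must lie in (0, 0.5)")
  if (rho <= 0) stop("invalid material: density must be positive")
  if (alpha_R < 0 || beta_R < 0)
    stop("Rayleigh damping weights must be non-negative")
  if (is.null(body_force))
    body_force <- matrix(0, nrow(mesh$nodes), 2L)
  structure(list(E = E, nu = nu, rho = rho,
                 alpha_R = alpha_R, beta_R = beta_R,
                 body_force = body_force),
            class = "material_field")
}

#' Plane-strain elasticity matrix
#'
#' Hooke's law in matrix form for plane strain, relating
#' `(eps_xx, eps_yy, gamma_xy)` to `(sigma_xx, sigma_yy, sigma_xy)`:
#' \deqn{D = \frac{E}{(1+\nu)(1-2\nu)}
#'   \begin{pmatrix} 1-\nu & \nu & 0 \\ \nu & 1-\nu & 0 \\
#'   0 & 0 & (1-2\nu)/2 \end{pmatrix}}
#'
#' @param E Young's modulus (kPa), positive.
#' @param nu Poisson's ratio in `[0, 0.5)`; the plane-strain prefactor
#'   diverges at the incompressible limit `nu = 0.5`.
#' @return symmetric positive-definite 3x3 matrix (units of `E`).
#' @examples
#' plane_strain_D(1, 0.3)
#' @export
plane_strain_D <- function(E, nu) {
  if (!is.finite(E) || E <= 0)
    stop("invalid material: Young's modulus must be positive")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5)
    stop("invalid material: Poisson's ratio must lie in [0, 0.5); ",
         "nu = 0.5 is the incompressible limit")
  E / ((1 + nu) * (1 - 2 * nu)) *
    matrix(c(1 - nu, nu, 0,
             nu, 1 - nu, 0,
             0, 0, (1 - 2 * nu) / 2), 3L, 3L)
}
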