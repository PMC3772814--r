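#' Continuous/discrete state-space model from the FEM system
#'
#' Writes the second-order equation of motion `M U'' + C U' + K U = R` in
#' first-order form over the state `x = [U; U']`:
#' \deqn{A = \begin{pmatrix} 0 & I \\ -M^{-1}K & -M^{-1}C \end{pmatrix},
#'   \quad b = \begin{pmatrix} 0 \\ M^{-1}R \end{pmatrix}}
#' and discretizes exactly over a sampling interval `dt` via the augmented
#' matrix exponential
#' \deqn{\exp\!\left(\begin{pmatrix} A & b \\ 0 & 0\end{pmatrix} dt\right)
#'   = \begin{pmatrix} F & G \\ 0 & 1 \end{pmatrix}}
#' so `F = exp(A dt)` and `G = (\int_0^{dt} e^{As} ds) b` jointly, which is
#' unconditionally stable even for the stiff penalty-augmented system.
#'
#' @param system a (typically penalty-augmented) `fem_system`.
#' @param dt pseudo-time sampling interval in seconds.
#' @return an object of class `state_space_model`: list with `A`, `b`
#'   (continuous), `F`, `G` (discrete), `dt`, `n_dof`, and the mesh.
#' @export
build_state_space <- function(system, dt = 1e-3) {
  K <- system$K
  Cd <- system$C
  M <- system$M
  ndof <- nrow(K)
  Minv <- tryCatch(solve(M), error = function(e)
    stop("singular mass matrix: ", conditionMessage(e)))
  A <- matrix(0, 2L * ndof, 2L * ndof)
  A[seq_len(ndof), ndof + seq_len(ndof)] <- diag(ndof)
  A[ndof + seq_len(ndof), seq_len(ndof)] <- -Minv %*% K
  A[ndof + seq_len(ndof), ndof + seq_len(ndof)] <- -Minv %*% Cd
  R <- if (is.matrix(system$R)) system$R else matrix(system$R, ncol = 1L)
  nr <- ncol(R)
  b <- rbind(matrix(0, ndof, nr), Minv %*% R)
  # all load columns share one augmented exponential
  aug <- rbind(cbind(A, b), matrix(0, nr, 2L * ndof + nr))
  Ead <- as.matrix(Matrix::expm(Matrix::Matrix(aug * dt)))
  Fd <- Ead[seq_len(2L * ndof), seq_len(2L * ndof)]
  Gd <- Ead[seq_len(2L * ndof), 2L * ndof + seq_len(nr), drop = FALSE]
  if (nr == 1L) { b <- drop(b); Gd <- drop(Gd) }
  structure(list(A = A, b = b, F = Fd, G = Gd, dt = dt,
                 n_dof = ndof, mesh = system$mesh),
            class = "state_space_model")
}

#' @export
print.state_space_model <- function(x, ...) {
  cat(sprintf("state_space_model: %d dofs, state dim %d, dt = %g s\n",
              x$n_dof, 2L * x$n_dof, x$dt))
  invisible(x)
}

#' Measurement matrix and vector for a measurement set
#'
#' Builds the 0/1 selection matrix `H` mapping the state `x = [U; U']` to
#' the measured displacement entries (one unit entry per row, referencing
#' displacement — never velocity — states), and the stacked measurement
#' vector `y` (a matrix when the set carries several realisations).
#'
#' @param meas a [measurement_set()] with dof indices into `U`.
#' @param n_dof number of displacement dofs of the model.
#' @return list with `H` (m x 2 n_dof) and `y`.
#' @export
build_measurement_matrix <- function(meas, n_dof) {
  m <- length(meas$indices)
  if (anyDuplicated(meas$indices)) stop("duplicate measurement indices")
  if (m > 0 && (any(meas$indices < 1L) || any(meas$indices > n_dof)))
    stop("measurement index outside displacement dof range")
  H <- matrix(0, m, 2L * n_dof)
  if (m > 0) H[cbind(seq_len(m), meas$indices)] <- 1
  list(H = H, y = meas$values)
}
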