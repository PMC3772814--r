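test_that("state-space construction matches analytic and series oracles", {
  # single dof m = 1, k = 1, c = 0: undamped oscillator, eigenvalues +- i
  sys1 <- list(M = diag(1), C = matrix(0, 1, 1), K = diag(1), R = 0,
               mesh = NULL)
  ss1 <- build_state_space(sys1, dt = 0.1)
  expect_equal(sort(Im(eigen(ss1$A)$values)), c(-1, 1), tolerance = 1e-12)
  # k = c = 0: A has a nilpotent block; F = exp(A dt), G -> b*dt + O(dt^2)
  sys0 <- list(M = diag(2), C = matrix(0, 2, 2), K = matrix(0, 2, 2),
               R = c(1, 2), mesh = NULL)
  ss0 <- build_state_space(sys0, dt = 0.5)
  A0 <- ss0$A
  expect_equal(ss0$F, diag(4) + A0 * 0.5, tolerance = 1e-12)  # A^2 = 0 here
  b0 <- c(0, 0, 1, 2)
  expect_equal(as.numeric(ss0$G),
               as.numeric((diag(4) * 0.5 + A0 * 0.5^2 / 2) %*% b0),
               tolerance = 1e-12)
  # random stable 2-dof system vs a scaled-and-squared Taylor oracle
  set.seed(17)
  M <- crossprod(matrix(stats::rnorm(4), 2)) + diag(2)
  K <- crossprod(matrix(stats::rnorm(4), 2)) + diag(2)
  sys2 <- list(M = M, C = 0.1 * M + 0.1 * K, K = K, R = c(0.5, -0.2),
               mesh = NULL)
  dt <- 0.05
  ss2 <- build_state_space(sys2, dt)
  taylor_expm <- function(A) {
    m <- ceiling(log2(max(1, max(abs(A)))))
    As <- A / 2^m
    E <- diag(nrow(A)); term <- diag(nrow(A))
    for (k in 1:20) { term <- term %*% As / k; E <- E + term }
    for (i in seq_len(m)) E <- E %*% E
    E
  }
  expect_equal(ss2$F, taylor_expm(ss2$A * dt), tolerance = 1e-8)
  expect_error(build_state_space(list(M = matrix(0, 2, 2),
                                      C = diag(2), K = diag(2), R = c(0, 0),
                                      mesh = NULL), 0.1),
               "singular mass")
})

test_that("measurement matrix is a pure displacement-entry selector", {
  n_dof <- 4L
  # all dofs measured in order: H = [I, 0]
  hm <- build_measurement_matrix(measurement_set(1:4, rep(0, 4)), n_dof)
  expect_equal(hm$H, cbind(diag(4), matrix(0, 4, 4)))
  # empty set: zero-row H allowed
  hm0 <- build_measurement_matrix(measurement_set(integer(0), numeric(0)),
                                  n_dof)
  expect_equal(nrow(hm0$H), 0L)
  # scrambled subset gathers by index
  idx <- c(3L, 1L, 4L)
  hm2 <- build_measurement_matrix(measurement_set(idx, rep(0, 3)), n_dof)
  x <- c(stats::rnorm(4), stats::rnorm(4))
  expect_equal(as.numeric(hm2$H %*% x), x[idx])
  expect_error(build_measurement_matrix(measurement_set(5L, 0), n_dof),
               "outside")
})

test_that("a single scalar step reproduces the Kalman gain of one half", {
  model <- list(F = matrix(1), G = 0)
  st <- hinf_step(list(x_hat = matrix(0), P = diag(1)),
                  y = matrix(1), model, H = diag(1),
                  Q = diag(1), V = diag(1), S = diag(1), gamma = 1e9)
  expect_equal(as.numeric(st$x_hat), 0.5, tolerance = 1e-9)
})

test_that("the gamma -> Inf limit matches the Kalman oracle over 100 steps", {
  rs <- random_system(10, n = 8L, m = 4L, scale = 0.95)
  rs$model$G <- stats::rnorm(8)
  set.seed(11)
  Y <- matrix(stats::rnorm(4 * 100), 4)
  st <- list(x_hat = matrix(0, 8, 1), P = 2 * diag(8), k = 0)
  xs <- matrix(NA_real_, 8, 100)
  Ps <- vector("list", 100)
  for (k in 1:100) {
    st <- hinf_step(st, Y[, k, drop = FALSE], rs$model, rs$H, rs$Q, rs$V,
                    rs$S, gamma = 1e9)
    xs[, k] <- st$x_hat
    Ps[[k]] <- st$P
  }
  kf <- kalman_filter(rs$model, rs$H, Y, rs$Q, rs$V, P0 = 2 * diag(8))
  expect_lt(max(abs(xs - kf$x_hist)) / max(abs(kf$x_hist)), 1e-8)
  pdiff <- vapply(1:100, function(k)
    max(abs(Ps[[k]] - kf$P_hist[[k]])) / max(abs(kf$P_hist[[k]])),
    numeric(1))
  expect_lt(max(pdiff), 1e-8)
})

test_that("zero-row H gives pure prediction", {
  rs <- random_system(12)
  H0 <- matrix(0, 0L, 6L)
  st0 <- list(x_hat = matrix(stats::rnorm(6), 6, 1), P = diag(6) * 0.3)
  out <- hinf_step(st0, matrix(0, 0L, 1L), rs$model, H0,
                   rs$Q, matrix(0, 0, 0), rs$S, gamma = 1e9)
  expect_equal(as.numeric(out$x_hat),
               as.numeric(rs$model$F %*% st0$x_hat), tolerance = 1e-9)
  expect_equal(out$P, rs$model$F %*% st0$P %*% t(rs$model$F) + rs$Q,
               tolerance = 1e-6)
})

test_that("feasibility checking raises the gamma-too-small error", {
  rs <- random_system(13)
  st <- list(x_hat = matrix(0, 6, 1), P = diag(6) * 10)
  expect_error(hinf_step(st, matrix(0, 3, 1), rs$model, rs$H, rs$Q, rs$V,
                         rs$S, gamma = 0.5, check_feasibility = TRUE),
               "gamma too small")
})

test_that("Kalman oracle reaches the discrete Riccati fixed point", {
  rs <- random_system(14)
  kf <- kalman_filter(rs$model, rs$H, matrix(0, 3, 1), rs$Q, rs$V, rs$P0,
                      n_iter = 300L)
  P_inf <- kf$P_hist[[300L]]
  # independent fixed-point iteration from a different start
  P <- diag(6) * 5
  for (i in 1:500) {
    K <- P %*% t(rs$H) %*% solve(rs$H %*% P %*% t(rs$H) + rs$V)
    P <- rs$model$F %*% (diag(6) - K %*% rs$H) %*% P %*% t(rs$model$F) +
      rs$Q
    P <- (P + t(P)) / 2
  }
  expect_lt(max(abs(P_inf - P)) / max(abs(P)), 1e-6)
  # DARE residual of the limit
  K <- P_inf %*% t(rs$H) %*% solve(rs$H %*% P_inf %*% t(rs$H) + rs$V)
  res <- rs$model$F %*% (diag(6) - K %*% rs$H) %*% P_inf %*%
    t(rs$model$F) + rs$Q - P_inf
  expect_lt(max(abs(res)) / max(abs(P_inf)), 1e-6)
})

test_that("P stays symmetric and positive on a feasible phantom run", {
  cfg <- test_phantom_config()
  sim <- simulate_phantom(cfg, seed = 31, snr_axial = 30, snr_lateral = NA)
  fit <- filter_phantom(sim, hinf_config())
  expect_identical(fit$P, t(fit$P))
  expect_true(all(is.finite(fit$P)))
  # innovation settles: non-increasing trend after the first 10 iterations
  inn <- fit$innovation[, 1L]
  expect_lt(inn[length(inn)], inn[10L])
  expect_true(all(diff(inn[10:length(inn)]) < 1e-8 + 0.02 * inn[10L]))
})

test_that("noise-free full measurements reproduce a static truth field", {
  cfg <- test_phantom_config()
  ph <- build_phantom(cfg)
  truth <- ground_truth(cfg, ph)
  sim <- list(phantom = ph, truth = truth,
              meas = sample_measurements(truth, cfg$measurement_grid),
              config = cfg)
  attr(sim$meas, "components") <- c("axial", "lateral")
  fit <- filter_phantom(sim, hinf_config(v_axial = 1e-6, v_lateral = 1e-6),
                        filter_E = ph$material$E)
  est <- fit$fields[[1L]]
  rel <- max(abs(c(est$u_axial - truth$u_axial,
                   est$u_lateral - truth$u_lateral))) /
    max(abs(c(truth$u_axial, truth$u_lateral)))
  expect_lt(rel, 1e-3)
})

test_that("zero measurements with zero load stay at the zero field", {
  mesh <- rect_grid_mesh(10, 10, 4L, 4L)
  sys <- assemble_system(mesh, material_field(mesh, E = 25, nu = 0.3))
  bot <- which(mesh$boundary_tags == "fixed")
  bc <- measurement_set(c(2L * bot, 2L * bot - 1L),
                        rep(0, 2L * length(bot)), 1e6)
  sys <- apply_measurement_penalty(sys, bc)
  fit <- run_filter(sys, measurement_set(integer(0),
                                         matrix(numeric(0), 0L, 1L)),
                    hinf_config(n_iter = 50L))
  expect_lt(max(abs(c(fit$fields[[1L]]$u_axial,
                      fit$fields[[1L]]$u_lateral))), 1e-9)
})
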