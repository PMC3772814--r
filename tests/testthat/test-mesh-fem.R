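test_that("mesh validation enforces geometry and index invariants", {
  nodes <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_s3_class(tri_mesh(nodes, rbind(c(1, 2, 3))), "tri_mesh")
  # clockwise (negative area) triangle rejected, naming the offender
  expect_error(tri_mesh(nodes, rbind(c(1, 3, 2))), "triangle 1")
  expect_error(tri_mesh(nodes, rbind(c(1, 2, 4))), "outside the node set")
  expect_error(tri_mesh(nodes, rbind(c(1, 2, 3)), measurement_nodes = 9L),
               "measurement_nodes")
})

test_that("mesh text export round-trips", {
  mesh <- rect_grid_mesh(10, 20, 4L, 5L)
  stem <- file.path(withr::local_tempdir(), "m")
  write_mesh(mesh, stem)
  back <- read_mesh(stem)
  expect_equal(back$nodes, mesh$nodes, ignore_attr = TRUE)
  expect_equal(back$triangles, mesh$triangles, ignore_attr = TRUE)
  expect_equal(back$boundary_tags, mesh$boundary_tags)
})

test_that("plane-strain elasticity matrix matches its definition and limits", {
  # nu = 0: prefactor and off-diagonals vanish
  expect_equal(plane_strain_D(1, 0),
               diag(c(1, 1, 0.5)), tolerance = 1e-12)
  expect_error(plane_strain_D(1, 0.5), "incompressible")
  expect_error(plane_strain_D(-1, 0.3), "invalid material")
  # compliance-inversion oracle: build the plane-strain compliance matrix
  # independently from E and nu and invert it
  E <- 80; nu <- 0.49
  compliance <- rbind(
    c(1 - nu^2, -nu * (1 + nu), 0),
    c(-nu * (1 + nu), 1 - nu^2, 0),
    c(0, 0, 2 * (1 + nu))) / E
  expect_equal(plane_strain_D(E, nu), solve(compliance), tolerance = 1e-12)
  D <- plane_strain_D(25, 0.3)
  expect_true(all(eigen(D, symmetric = TRUE)$values > 0))
})

test_that("assembled stiffness annihilates rigid modes and matches quadrature", {
  mesh <- jittered_mesh()
  mat <- material_field(mesh, E = 25, nu = 0.49)
  sys <- assemble_system(mesh, mat)
  expect_equal(sys$K, t(sys$K))
  expect_equal(sys$M, t(sys$M))
  n <- nrow(mesh$nodes)
  knorm <- max(abs(sys$K))
  # translations and infinitesimal rotation carry no strain energy
  tx <- rep(c(1, 0), n); ty <- rep(c(0, 1), n)
  cen <- colMeans(mesh$nodes)
  rot <- as.vector(rbind(-(mesh$nodes[, 2L] - cen[2L]),
                         mesh$nodes[, 1L] - cen[1L]))
  for (t in list(tx, ty, rot))
    expect_lt(max(abs(sys$K %*% t)), 1e-9 * knorm)
  # exactly 3 near-zero eigenvalues, none negative beyond tolerance
  ev <- eigen(sys$K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-9 * knorm)
  expect_equal(sum(abs(ev) < 1e-9 * knorm), 3L)

  # independent 3-point Gauss quadrature oracle on the unit square mesh
  usq <- unit_square_mesh()
  mat2 <- material_field(usq, E = 25, nu = 0.49)
  sys2 <- assemble_system(usq, mat2)
  D <- plane_strain_D(25, 0.49)
  K_oracle <- matrix(0, 8L, 8L)
  gauss <- rbind(c(2 / 3, 1 / 6, 1 / 6), c(1 / 6, 2 / 3, 1 / 6),
                 c(1 / 6, 1 / 6, 2 / 3))
  for (e in 1:2) {
    id <- usq$triangles[e, ]
    xy <- usq$nodes[id, ]
    # shape functions from the Vandermonde system [1 x y] a = delta
    Vm <- cbind(1, xy)
    coef <- solve(Vm)               # row 2 = d/dx, row 3 = d/dy per node
    area <- abs(det(Vm)) / 2
    Ke <- matrix(0, 6L, 6L)
    for (gp in 1:3) {               # B constant; quadrature still sums
      B <- matrix(0, 3L, 6L)
      B[1L, c(1, 3, 5)] <- coef[2L, ]
      B[2L, c(2, 4, 6)] <- coef[3L, ]
      B[3L, c(1, 3, 5)] <- coef[3L, ]
      B[3L, c(2, 4, 6)] <- coef[2L, ]
      Ke <- Ke + (1 / 3) * area * t(B) %*% D %*% B
    }
    dofs <- as.vector(rbind(2L * id - 1L, 2L * id))
    K_oracle[dofs, dofs] <- K_oracle[dofs, dofs] + Ke
  }
  expect_equal(sys2$K, K_oracle, tolerance = 1e-12)
  # Rayleigh damping: zero weights give zero C
  mat0 <- material_field(usq, E = 25, nu = 0.3, alpha_R = 0, beta_R = 0)
  expect_equal(assemble_system(usq, mat0)$C, matrix(0, 8L, 8L))
})

test_that("measurement penalty augments exactly the measured dofs", {
  usq <- unit_square_mesh()
  sys <- assemble_system(usq, material_field(usq, E = 10, nu = 0.3))
  expect_identical(apply_measurement_penalty(sys, measurement_set(integer(0),
                                                                  numeric(0))),
                   sys)
  meas <- measurement_set(c(3L, 6L), c(0.2, -0.1), c(1e5, 2e5))
  aug <- apply_measurement_penalty(sys, meas)
  # direct-loop oracle
  K_exp <- sys$K; R_exp <- sys$R
  for (i in 1:2) {
    K_exp[meas$indices[i], meas$indices[i]] <-
      K_exp[meas$indices[i], meas$indices[i]] + meas$confidence[i]
    R_exp[meas$indices[i]] <- R_exp[meas$indices[i]] +
      meas$confidence[i] * meas$values[i, 1L]
  }
  expect_equal(aug$K, K_exp)
  expect_equal(aug$R, R_exp)
  expect_error(measurement_set(1L, 0.5, confidence = -1), "confidence")
  expect_error(measurement_set(c(1L, 1L), c(0, 0)), "unique")
})

test_that("penalty-method limit approaches the prescribed value as 1/kappa", {
  # 1-dof analogue built on a pinned bar: prescribe one free dof by penalty
  usq <- unit_square_mesh()
  sys <- assemble_system(usq, material_field(usq, E = 1, nu = 0.3))
  kappa <- 1e6
  meas <- measurement_set(5L, 0.1, kappa)
  aug <- apply_measurement_penalty(sys, meas)
  sol <- static_solve(aug, fixed_dofs = c(1L, 2L, 3L, 4L))
  got <- attr(sol, "dofs")[5L]
  expect_lt(abs(got - 0.1) / 0.1, 10 / kappa)
})

test_that("static solve reproduces the closed-form uniaxial solution", {
  for (ny in c(3L, 6L, 11L)) {   # affine exactness at any density
    mesh <- rect_grid_mesh(10, 10, ny, ny)
    nu <- 0.4; delta <- 0.2
    sys <- assemble_system(mesh, material_field(mesh, E = 25, nu = nu))
    top <- which(mesh$boundary_tags == "loaded")
    bot <- which(mesh$boundary_tags == "fixed")
    pin <- bot[which.min(abs(mesh$nodes[bot, 1L] - 5))]
    sol <- static_solve(sys, c(2L * top, 2L * bot, 2L * pin - 1L),
                        c(rep(delta, length(top)), rep(0, length(bot)), 0))
    u_ax_exp <- delta * (1 - mesh$nodes[, 2L] / 10)
    eps_lat <- nu / (1 - nu) * delta / 10
    # lateral field vanishes at the pinned node, not necessarily at x = 5
    u_lat_exp <- eps_lat * (mesh$nodes[, 1L] - mesh$nodes[pin, 1L])
    expect_equal(sol$u_axial, u_ax_exp, tolerance = 1e-9)
    expect_equal(sol$u_lateral, u_lat_exp, tolerance = 1e-9)
  }
  # zero load, zero prescribed displacement -> zero field
  mesh <- rect_grid_mesh(10, 10, 4L, 4L)
  sys <- assemble_system(mesh, material_field(mesh, E = 25, nu = 0.3))
  bot <- which(mesh$boundary_tags == "fixed")
  sol0 <- static_solve(sys, c(2L * bot, 2L * bot - 1L,
                              2L * which(mesh$boundary_tags == "loaded")),
                       0)
  expect_equal(max(abs(attr(sol0, "dofs"))), 0)
  # under-constrained system errors
  expect_error(static_solve(sys), "under-constrained")
})

test_that("patch test: affine boundary data reproduced exactly at interior nodes", {
  mesh <- jittered_mesh()
  sys <- assemble_system(mesh, material_field(mesh, E = 30, nu = 0.35))
  a <- c(0.01, -0.02); Bm <- matrix(c(0.003, -0.001, 0.002, 0.004), 2L)
  u_exact <- t(a + Bm %*% t(mesh$nodes))
  bnd <- which(mesh$nodes[, 1L] < 1e-9 | mesh$nodes[, 1L] > 10 - 1e-9 |
               mesh$nodes[, 2L] < 1e-9 | mesh$nodes[, 2L] > 10 - 1e-9)
  fixed <- c(2L * bnd - 1L, 2L * bnd)
  vals <- c(u_exact[bnd, 1L], u_exact[bnd, 2L])
  sol <- static_solve(sys, fixed, vals)
  expect_equal(sol$u_lateral, u_exact[, 1L], tolerance = 1e-9)
  expect_equal(sol$u_axial, u_exact[, 2L], tolerance = 1e-9)
})
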