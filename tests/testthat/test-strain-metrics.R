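test_that("element strains are exact for affine fields and kill rotations", {
  mesh <- jittered_mesh()
  a <- 0.01; b <- -0.004
  f <- displacement_field(mesh, u_axial = a * mesh$nodes[, 2L],
                          u_lateral = b * mesh$nodes[, 1L])
  st <- strain_from_displacement(f)
  expect_equal(st$eps_axial, rep(a, length(st$eps_axial)))
  expect_equal(st$eps_lateral, rep(b, length(st$eps_lateral)))
  expect_equal(st$eps_shear,
               0.5 * (st$eps_axial_shear + st$eps_lateral_shear))
  # infinitesimal rotation: u_lat = -omega*y, u_ax = omega*x
  w <- 0.02
  rot <- displacement_field(mesh, u_axial = w * mesh$nodes[, 1L],
                            u_lateral = -w * mesh$nodes[, 2L])
  str <- strain_from_displacement(rot)
  expect_lt(max(abs(str$eps_shear)), 1e-12)
  expect_lt(max(abs(str$eps_axial)), 1e-12)
  expect_equal(str$eps_axial_shear, rep(w, length(str$eps_axial_shear)))
})

test_that("quadratic fields match a finite-difference oracle within 2 %", {
  mesh <- rect_grid_mesh(10, 10, 61L, 61L)
  ua <- function(x, y) 0.001 * y^2 + 0.0005 * x * y
  ul <- function(x, y) -0.0008 * x^2 + 0.0003 * y * x
  f <- displacement_field(mesh, ua(mesh$nodes[, 1L], mesh$nodes[, 2L]),
                          ul(mesh$nodes[, 1L], mesh$nodes[, 2L]))
  st <- strain_from_displacement(f)
  h <- 1e-4
  # compare where the strain is well away from its zero lines (the
  # constant-strain element carries an O(mesh) bias that dominates only
  # relative errors near zero)
  checked <- 0L
  for (e in seq_along(st$eps_axial)) {
    cx <- st$centroids[e, 1L]; cy <- st$centroids[e, 2L]
    fd_ax <- (ua(cx, cy + h) - ua(cx, cy - h)) / (2 * h)
    fd_lat <- (ul(cx + h, cy) - ul(cx - h, cy)) / (2 * h)
    if (abs(fd_ax) > 0.008) {
      expect_lt(abs(st$eps_axial[e] - fd_ax) / abs(fd_ax), 0.02)
      checked <- checked + 1L
    }
    if (abs(fd_lat) > 0.008)
      expect_lt(abs(st$eps_lateral[e] - fd_lat) / abs(fd_lat), 0.02)
  }
  expect_gt(checked, 50L)
})

test_that("strain computation is linear in the displacement field", {
  mesh <- jittered_mesh()
  set.seed(5)
  f1 <- displacement_field(mesh, stats::rnorm(nrow(mesh$nodes)),
                           stats::rnorm(nrow(mesh$nodes)))
  f2 <- displacement_field(mesh, stats::rnorm(nrow(mesh$nodes)),
                           stats::rnorm(nrow(mesh$nodes)))
  fsum <- displacement_field(mesh, 2 * f1$u_axial + 3 * f2$u_axial,
                             2 * f1$u_lateral + 3 * f2$u_lateral)
  s1 <- strain_from_displacement(f1)
  s2 <- strain_from_displacement(f2)
  ssum <- strain_from_displacement(fsum)
  for (comp in c("eps_axial", "eps_lateral", "eps_shear"))
    expect_equal(ssum[[comp]], 2 * s1[[comp]] + 3 * s2[[comp]],
                 tolerance = 1e-12)
})

test_that("node averaging and rasterisation reproduce constant strains", {
  mesh <- rect_grid_mesh(10, 10, 6L, 6L)
  f <- displacement_field(mesh, 0.01 * mesh$nodes[, 2L],
                          -0.004 * mesh$nodes[, 1L])
  st <- strain_from_displacement(f)
  expect_equal(strain_to_nodes(st, "eps_axial"),
               rep(0.01, nrow(mesh$nodes)))
  r <- strain_raster(st, "eps_lateral", rows = 12L, cols = 12L)
  expect_equal(as.numeric(r[!is.na(r)]),
               rep(-0.004, sum(!is.na(r))), tolerance = 1e-12)
})

test_that("EDR follows its definition and invariances", {
  expect_equal(edr(c(1, -1), c(1, -1)), 0)
  expect_equal(edr(c(0, 0), c(1, -1)), 1)
  expect_equal(edr(c(1.1, -0.9), c(1, -1)), 0.1)
  expect_error(edr(c(0, 0), c(0, 0)), "identically zero")
  expect_error(edr(1:3, 1:4), "node sets")
  set.seed(8)
  a <- stats::rnorm(50); b <- stats::rnorm(50)
  expect_equal(edr(3.7 * a, 3.7 * b), edr(a, b))
})

test_that("CNR matches its formula and homogeneity", {
  set.seed(9)
  s <- c(stats::rnorm(200, 1, 0.3), stats::rnorm(300, 3, 0.4))
  tm <- c(rep(TRUE, 200), rep(FALSE, 300))
  bm <- !tm
  expected <- sqrt(2 * (mean(s[bm]) - mean(s[tm]))^2 /
                   (stats::var(s[bm]) + stats::var(s[tm])))
  expect_equal(cnr(s, tm, bm), expected)
  # identical region statistics (same values in both masks) give zero
  expect_equal(cnr(rep(c(1, 2, 3, 1, 2, 3), 20),
                   rep(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 20),
                   rep(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE), 20)), 0)
  # doubling the mean contrast at fixed variances doubles CNR: shifting
  # the background by the current contrast leaves both variances alone
  shifted <- s
  shifted[bm] <- s[bm] + (mean(s[bm]) - mean(s[tm]))
  expect_equal(cnr(shifted, tm, bm), 2 * cnr(s, tm, bm), tolerance = 1e-9)
  expect_error(cnr(s, tm & FALSE, bm), "empty")
  expect_error(cnr(s, tm, tm), "disjoint")
})

test_that("positional error aggregates repeats with the sample convention", {
  mesh <- rect_grid_mesh(4, 4, 3L, 3L)
  truth <- displacement_field(mesh, rep(0, 9), rep(0, 9))
  mk <- function(e) displacement_field(mesh, rep(e, 9), rep(0, 9))
  expect_equal(positional_error(truth, truth)$pos_err_mean, 0)
  single <- positional_error(mk(0.2), truth)
  expect_equal(single$pos_err_mean, 0.2)
  expect_equal(single$pos_err_std, 0)
  two <- positional_error(list(mk(0.1), mk(0.3)), truth)
  expect_equal(two$pos_err_mean, 0.2)
  expect_equal(two$pos_err_std, stats::sd(c(0.1, 0.3)))
  expect_equal(two$pos_err_std, abs(0.1 - 0.3) / sqrt(2))
  expect_error(positional_error(displacement_field(rect_grid_mesh(4, 4, 2L, 2L),
                                                   rep(0, 4), rep(0, 4)),
                                truth),
               "node counts")
})
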