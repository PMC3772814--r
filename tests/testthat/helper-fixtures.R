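# shared fixtures: small meshes, scaled phantom configs, random systems

# two-triangle unit square
unit_square_mesh <- function() {
  tri_mesh(nodes = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
           triangles = rbind(c(1, 2, 3), c(1, 3, 4)))
}

# scaled-down phantom used throughout the tests: 11x11 node mesh on the
# default 40x40 mm geometry, measurements on the full node lattice
test_phantom_config <- function(...) {
  phantom_config(mesh_density = 4, measurement_grid = c(11L, 11L), ...)
}

# deterministically jittered homogeneous rectangle for patch tests
jittered_mesh <- function(nx = 6L, ny = 6L) {
  mesh <- rect_grid_mesh(10, 10, nx, ny)
  interior <- mesh$nodes[, 1L] > 1e-9 & mesh$nodes[, 1L] < 10 - 1e-9 &
              mesh$nodes[, 2L] > 1e-9 & mesh$nodes[, 2L] < 10 - 1e-9
  set.seed(99)
  jit <- matrix(stats::runif(sum(interior) * 2, -0.3, 0.3), ncol = 2L)
  nodes <- mesh$nodes
  nodes[interior, ] <- nodes[interior, ] + jit
  tri_mesh(nodes, mesh$triangles, mesh$boundary_tags)
}

# random stable discrete system for filter tests
random_system <- function(seed, n = 6L, m = 3L, scale = 0.9) {
  set.seed(seed)
  Fm <- matrix(stats::rnorm(n * n), n)
  Fm <- Fm / max(Mod(eigen(Fm)$values)) * scale
  H <- matrix(0, m, n)
  H[cbind(seq_len(m), sample(n, m))] <- 1
  list(model = list(F = Fm, G = numeric(n)), H = H,
       Q = diag(n) * 0.1, V = diag(m) * 0.1, P0 = diag(n) * 0.1,
       S = diag(n))
}
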