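#' Triangular mesh for a 2-D region of interest
#'
#' Constructs a validated triangular mesh. Coordinates are in millimetres
#' with `x` the lateral direction and `y` the axial direction (depth,
#' increasing away from the probe). Triangles must be counter-clockwise,
#' i.e. have strictly positive signed area.
#'
#' @param nodes numeric matrix, one row per node, columns `(x, y)` in mm.
#' @param triangles integer matrix, one row per element, three node indices
#'   (1-based, counter-clockwise).
#' @param boundary_tags character vector, one tag per node, each one of
#'   `"free"`, `"fixed"` or `"loaded"`.
#' @param measurement_nodes integer vector of node indices where displacement
#'   data may be enforced or assimilated; must be a subset of the node set.
#' @return An object of class `tri_mesh`: a list with fields `nodes`,
#'   `triangles`, `boundary_tags`, `measurement_nodes`.
#' @seealso [rect_grid_mesh()], [build_phantom()]
#' @export
tri_mesh <- function(nodes, triangles, boundary_tags = NULL,
                     measurement_nodes = integer(0)) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 2L) stop("`nodes` must have two columns (x, y)")
  if (!all(is.finite(nodes))) stop("node coordinates must be finite")
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3L) stop("`triangles` must have three columns")
  n <- nrow(nodes)
  if (any(triangles < 1L) || any(triangles > n))
    stop("triangle references a node index outside the node set")
  a <- triangle_areas(nodes, triangles)
  if (any(a <= 0)) {
    bad <- which(a <= 0)[1L]
    stop(sprintf("triangle %d has non-positive signed area (%.3g); %s",
                 bad, a[bad], "nodes must be ordered counter-clockwise"))
  }
  if (is.null(boundary_tags)) boundary_tags <- rep("free", n)
  if (length(boundary_tags) != n) stop("one boundary tag per node required")
  if (!all(boundary_tags %in% c("free", "fixed", "loaded")))
    stop("boundary tags must be 'free', 'fixed' or 'loaded'")
  measurement_nodes <- as.integer(measurement_nodes)
  if (any(measurement_nodes < 1L) || any(measurement_nodes > n))
    stop("measurement_nodes must be a subset of the node set")
  structure(
    list(nodes = nodes, triangles = triangles,
         boundary_tags = boundary_tags,
         measurement_nodes = measurement_nodes),
    class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d nodes, %d triangles\n",
              nrow(x$nodes), nrow(x$triangles)))
  bb <- apply(x$nodes, 2, range)
  cat(sprintf("  extent: x [%g, %g] mm, y [%g, %g] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2]))
  cat(sprintf("  tags: %s\n",
              paste(sprintf("%s=%d", names(table(x$boundary_tags)),
                            table(x$boundary_tags)), collapse = ", ")))
  invisible(x)
}

#' Signed areas of mesh triangles
#'
#' @param nodes node coordinate matrix.
#' @param triangles element index matrix.
#' @return numeric vector of signed areas (mm^2), positive for
#'   counter-clockwise elements.
#' @keywords internal
triangle_areas <- function(nodes, triangles) {
  x1 <- nodes[triangles[, 1L], 1L]; y1 <- nodes[triangles[, 1L], 2L]
  x2 <- nodes[triangles[, 2L], 1L]; y2 <- nodes[triangles[, 2L], 2L]
  x3 <- nodes[triangles[, 3L], 1L]; y3 <- nodes[triangles[, 3L], 2L]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' Structured triangulation of a rectangular domain
#'
#' Builds a regular node lattice on `[0, width] x [0, height]` and splits
#' each cell into two triangles. Diagonal directions alternate and are
#' mirrored about the vertical centerline so the mesh is left-right
#' symmetric (the phantom's lateral displacement field is symmetric about
#' the centerline and an asymmetric mesh would break that at discretisation
#' level). For a rectangular lattice this triangulation is Delaunay.
#'
#' Bottom-edge nodes are tagged `"fixed"`, top-edge nodes `"loaded"`
#' (y = 0 is the top, nearest the probe; y increases with depth).
#'
#' @param width,height domain size in mm.
#' @param nx,ny number of nodes along x and y (>= 2).
#' @return a [tri_mesh()].
#' @export
rect_grid_mesh <- function(width, height, nx, ny) {
  stopifnot(width > 0, height > 0, nx >= 2L, ny >= 2L)
  xs <- seq(0, width, length.out = nx)
  ys <- seq(0, height, length.out = ny)
  # node index: column-major over (row = axial j, col = lateral i)
  nodes <- cbind(x = rep(xs, each = ny), y = rep(ys, times = nx))
  idx <- function(i, j) (i - 1L) * ny + j   # i lateral col, j axial row
  tris <- vector("list", (nx - 1L) * (ny - 1L))
  k <- 0L
  for (i in seq_len(nx - 1L)) {
    for (j in seq_len(ny - 1L)) {
      n00 <- idx(i, j);      n10 <- idx(i + 1L, j)
      n01 <- idx(i, j + 1L); n11 <- idx(i + 1L, j + 1L)
      xc <- (xs[i] + xs[i + 1L]) / 2
      flip <- ((i + j) %% 2L == 0L)
      if (xc > width / 2) flip <- !flip  # mirror right half
      k <- k + 1L
      if (flip) {
        # diagonal n00-n11 (counter-clockwise with y down handled below)
        tris[[k]] <- rbind(c(n00, n11, n10), c(n00, n01, n11))
      } else {
        tris[[k]] <- rbind(c(n00, n01, n10), c(n10, n01, n11))
      }
    }
  }
  triangles <- do.call(rbind, tris)
  # ensure positive signed area in the (x right, y down) frame
  a <- triangle_areas(nodes, triangles)
  flip <- a < 0
  if (any(flip)) triangles[flip, c(2L, 3L)] <- triangles[flip, c(3L, 2L)]
  tags <- rep("free", nrow(nodes))
  tags[abs(nodes[, 2L] - height) < 1e-12] <- "fixed"
  tags[nodes[, 2L] < 1e-12] <- "loaded"
  tri_mesh(nodes, triangles, tags)
}

#' Export a mesh as delimited text
#'
#' Writes two whitespace-delimited files: `<stem>_nodes.txt` with columns
#' `index x y tag` and `<stem>_triangles.txt` with three 0-based node
#' indices per row.
#'
#' @param mesh a [tri_mesh()].
#' @param stem output path stem (no extension).
#' @return invisibly, the two file paths.
#' @export
write_mesh <- function(mesh, stem) {
  nf <- paste0(stem, "_nodes.txt")
  tf <- paste0(stem, "_triangles.txt")
  nd <- data.frame(index = seq_len(nrow(mesh$nodes)) - 1L,
                   x = mesh$nodes[, 1L], y = mesh$nodes[, 2L],
                   tag = mesh$boundary_tags)
  utils::write.table(nd, nf, row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  utils::write.table(mesh$triangles - 1L, tf, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(c(nodes = nf, triangles = tf))
}

#' Read a mesh written by [write_mesh()]
#'
#' @param stem path stem used when writing.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(stem) {
  nd <- utils::read.table(paste0(stem, "_nodes.txt"), header = TRUE,
                          colClasses = c("integer", "numeric", "numeric",
                                         "character"))
  tr <- as.matrix(utils::read.table(paste0(stem, "_triangles.txt"),
                                    header = FALSE)) + 1L
  tri_mesh(cbind(nd$x, nd$y), tr, nd$tag)
}

#' Nodal displacement field on a mesh
#'
#' @param mesh a [tri_mesh()].
#' @param u_axial,u_lateral per-node displacements in mm (axial = depth
#'   direction y, positive away from the probe; lateral = x).
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(mesh, u_axial, u_lateral) {
  n <- nrow(mesh$nodes)
  if (length(u_axial) != n || length(u_lateral) != n)
    stop("displacement component length must equal node count")
  if (!all(is.finite(u_axial)) || !all(is.finite(u_lateral)))
    stop("displacements must be finite")
  structure(list(mesh = mesh, u_axial = as.numeric(u_axial),
                 u_lateral = as.numeric(u_lateral)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement_field on %d nodes\n", length(x$u_axial)))
  cat(sprintf("  axial:   [%.4g, %.4g] mm\n",
              min(x$u_axial), max(x$u_axial)))
  cat(sprintf("  lateral: [%.4g, %.4g] mm\n",
              min(x$u_lateral), max(x$u_lateral)))
  invisible(x)
}

#' Interleave a displacement field into a dof vector
#'
#' Node `i` owns dofs `2i-1` (lateral, x) and `2i` (axial, y).
#'
#' @param field a [displacement_field()].
#' @return numeric vector of length `2 * n_nodes`.
#' @export
field_to_dofs <- function(field) {
  n <- length(field$u_axial)
  u <- numeric(2L * n)
  u[seq(1L, 2L * n, by = 2L)] <- field$u_lateral
  u[seq(2L, 2L * n, by = 2L)] <- field$u_axial
  u
}

#' Split a dof vector back into a displacement field
#'
#' @param mesh a [tri_mesh()].
#' @param u dof vector of length `2 * n_nodes` (lateral, axial interleaved).
#' @return a [displacement_field()].
#' @export
dofs_to_field <- function(mesh, u) {
  n <- nrow(mesh$nodes)
  if (length(u) != 2L * n) stop("dof vector length must be 2 * n_nodes")
  displacement_field(mesh,
                     u_axial = u[seq(2L, 2L * n, by = 2L)],
                     u_lateral = u[seq(1L, 2L * n, by = 2L)])
}
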