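#' All five plane-strain strain images from a displacement field
#'
#' Per-element constant strains from the linear shape functions. The
#' naming convention (the one that keeps the five images distinct and
#' the shear identity exact) is:
#' axial strain `= d u_ax / d axial`,
#' lateral strain `= d u_lat / d lateral`,
#' axial-shear `= d u_ax / d lateral`,
#' lateral-shear `= d u_lat / d axial`,
#' shear `= (axial-shear + lateral-shear) / 2` (the symmetric tensor
#' component, which annihilates rigid rotations).
#'
#' @param field a [displacement_field()].
#' @param mesh the mesh (defaults to the field's own).
#' @return object of class `strain_field`: list of per-element vectors
#'   `eps_axial`, `eps_lateral`, `eps_axial_shear`, `eps_lateral_shear`,
#'   `eps_shear`, with element `centroids` for rendering.
#' @export
strain_from_displacement <- function(field, mesh = field$mesh) {
  tri <- mesh$triangles
  ne <- nrow(tri)
  ea <- el <- eas <- els <- numeric(ne)
  cen <- matrix(0, ne, 2L)
  for (e in seq_len(ne)) {
    id <- tri[e, ]
    xy <- mesh$nodes[id, , drop = FALSE]
    g <- element_bmat(xy)$grads          # row1 = d/dx (lateral), row2 = d/dy
    ux <- field$u_lateral[id]
    uy <- field$u_axial[id]
    ea[e] <- sum(g[2L, ] * uy)          # du_ax/dy
    el[e] <- sum(g[1L, ] * ux)          # du_lat/dx
    eas[e] <- sum(g[1L, ] * uy)         # du_ax/dx
    els[e] <- sum(g[2L, ] * ux)         # du_lat/dy
    cen[e, ] <- colMeans(xy)
  }
  structure(list(eps_axial = ea, eps_lateral = el,
                 eps_axial_shear = eas, eps_lateral_shear = els,
                 eps_shear = (eas + els) / 2,
                 centroids = cen, mesh = mesh),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("strain_field: %d elements\n", length(x$eps_axial)))
  for (nm in c("eps_axial", "eps_lateral", "eps_shear"))
    cat(sprintf("  %-16s [%.4g, %.4g]\n", nm, min(x[[nm]]), max(x[[nm]])))
  invisible(x)
}

#' Area-weighted averaging of element strains to nodes
#'
#' For display: each node receives the area-weighted mean of the strains
#' of its incident elements. Metrics are always computed on the raw
#' element values.
#'
#' @param strain a [strain_field()].
#' @param component name of the strain component.
#' @return numeric vector, one value per node.
#' @export
strain_to_nodes <- function(strain, component = "eps_axial") {
  mesh <- strain$mesh
  vals <- strain[[component]]
  if (is.null(vals)) stop("unknown strain component: ", component)
  a <- triangle_areas(mesh$nodes, mesh$triangles)
  n <- nrow(mesh$nodes)
  num <- den <- numeric(n)
  for (e in seq_along(vals)) {
    id <- mesh$triangles[e, ]
    num[id] <- num[id] + a[e] * vals[e]
    den[id] <- den[id] + a[e]
  }
  num / den
}

#' Resample a strain component to a regular raster
#'
#' Barycentric point location on the mesh: each raster pixel takes the
#' (constant) strain of the element containing it.
#'
#' @param strain a [strain_field()].
#' @param component strain component name.
#' @param rows,cols raster size.
#' @return numeric `rows x cols` matrix (row = axial index); pixels
#'   outside every element are `NA`.
#' @export
strain_raster <- function(strain, component = "eps_axial",
                          rows = 64L, cols = 64L) {
  mesh <- strain$mesh
  vals <- strain[[component]]
  bb <- apply(mesh$nodes, 2L, range)
  xs <- seq(bb[1L, 1L], bb[2L, 1L], length.out = cols)
  ys <- seq(bb[1L, 2L], bb[2L, 2L], length.out = rows)
  tri <- mesh$triangles
  x1 <- mesh$nodes[tri[, 1L], 1L]; y1 <- mesh$nodes[tri[, 1L], 2L]
  x2 <- mesh$nodes[tri[, 2L], 1L]; y2 <- mesh$nodes[tri[, 2L], 2L]
  x3 <- mesh$nodes[tri[, 3L], 1L]; y3 <- mesh$nodes[tri[, 3L], 2L]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  out <- matrix(NA_real_, rows, cols)
  eps <- 1e-9
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      px <- xs[j]; py <- ys[i]
      l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
      l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
      l3 <- 1 - l1 - l2
      hit <- which(l1 >= -eps & l2 >= -eps & l3 >= -eps)
      if (length(hit) > 0L) out[i, j] <- vals[hit[1L]]
    }
  }
  attr(out, "x_mm") <- xs
  attr(out, "y_mm") <- ys
  out
}

#' Render a strain image
#'
#' @param x a [strain_field()].
#' @param component strain component to draw.
#' @param rows,cols raster resolution.
#' @param ... passed to [graphics::image()].
#' @export
plot.strain_field <- function(x, component = "eps_axial",
                              rows = 96L, cols = 96L, ...) {
  r <- strain_raster(x, component, rows, cols)
  graphics::image(attr(r, "x_mm"), attr(r, "y_mm"), t(r[rev(seq_len(rows)), ]),
                  xlab = "lateral (mm)", ylab = "axial depth (mm)",
                  main = component,
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  invisible(r)
}
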