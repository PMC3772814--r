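#' Tissue-incompressibility baseline configuration
#'
#' @param smoothing_weight non-negative first-difference regularization
#'   weight applied to each integrated row.
#' @param origin lateral integration origin: `"left"` (lateral
#'   displacement zero on the left edge) or `"center"` (zero on the
#'   vertical centerline, matching a symmetric compression).
#' @return an object of class `tiam_config`.
#' @export
tiam_config <- function(smoothing_weight = 0.1,
                        origin = c("left", "center")) {
  if (smoothing_weight < 0) stop("smoothing_weight must be >= 0")
  structure(list(smoothing_weight = smoothing_weight,
                 origin = match.arg(origin)),
            class = "tiam_config")
}

#' Lateral displacement from axial strain under tissue incompressibility
#'
#' Classical baseline: assuming the tissue is incompressible
#' (`nu = 0.5`, so in plane strain `eps_xx = -eps_yy`), the lateral
#' strain is taken as the negated axial strain and integrated laterally
#' row by row (cumulative trapezoid from the origin). Each integrated
#' row is then smoothed by regularized least squares with a
#' first-difference penalty: `(I + w D'D) v = v_raw`.
#'
#' The incompressibility assumption makes the baseline increasingly
#' wrong as the true Poisson's ratio falls below 0.5, and the noise in
#' differentiated axial data is only partially removed — exactly the
#' weaknesses the model-constrained filter addresses.
#'
#' @param axial_strain numeric matrix of axial strain; rows = axial
#'   (depth) index, columns = lateral index.
#' @param dx lateral grid spacing (mm).
#' @param cfg a [tiam_config()].
#' @return matrix of lateral displacement (mm), same shape.
#' @export
tiam_lateral <- function(axial_strain, dx, cfg = tiam_config()) {
  eps <- as.matrix(axial_strain)
  if (!all(is.finite(eps))) stop("axial strain must be finite")
  nc <- ncol(eps)
  if (nc < 2L) stop("cannot integrate laterally: single-column grid")
  eps_lat <- -eps
  v <- t(apply(eps_lat, 1L, cumtrapz, dx = dx))
  if (cfg$origin == "center") {
    # subtract the (interpolated) centerline value from each row
    xc <- (nc + 1) / 2
    i0 <- floor(xc); w <- xc - i0
    v0 <- (1 - w) * v[, i0] + w * v[, min(i0 + 1L, nc)]
    v <- v - v0
  }
  if (cfg$smoothing_weight > 0) {
    D <- diff(diag(nc))
    Asm <- diag(nc) + cfg$smoothing_weight * crossprod(D)
    v <- t(solve(Asm, t(v)))
  }
  v
}

# cumulative trapezoidal integral from the first point (value 0 there)
cumtrapz <- function(y, dx) {
  n <- length(y)
  c(0, cumsum((y[-1L] + y[-n]) / 2 * dx))
}
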