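#' Lateral error-to-displacement ratio
#'
#' `EDR = mean(|est - truth|) / mean(|truth|)`: the mean absolute nodal
#' lateral-displacement error normalized by the mean absolute true
#' lateral displacement. Scale-invariant; 0 for a perfect estimate, 1
#' for an all-zero one.
#'
#' @param est_lateral,truth_lateral numeric vectors on matching nodes
#'   (or [displacement_field()]s, whose lateral components are used).
#' @return the ratio (>= 0).
#' @export
edr <- function(est_lateral, truth_lateral) {
  if (inherits(est_lateral, "displacement_field"))
    est_lateral <- est_lateral$u_lateral
  if (inherits(truth_lateral, "displacement_field"))
    truth_lateral <- truth_lateral$u_lateral
  if (length(est_lateral) != length(truth_lateral))
    stop("estimate and truth must share node sets")
  denom <- mean(abs(truth_lateral))
  if (denom == 0) stop("EDR undefined: truth field is identically zero")
  mean(abs(est_lateral - truth_lateral)) / denom
}

#' Contrast-to-noise ratio between target and background regions
#'
#' `CNR = sqrt(2 (mean_bg - mean_target)^2 / (var_bg + var_target))`,
#' the standard elastographic image-quality measure between an inclusion
#' mask and a background mask.
#'
#' @param strain numeric vector/matrix of strain values.
#' @param target_mask,background_mask logical masks (disjoint, nonempty).
#' @return the ratio (>= 0).
#' @export
cnr <- function(strain, target_mask, background_mask) {
  s <- as.vector(strain)
  tm <- as.vector(target_mask); bm <- as.vector(background_mask)
  if (!any(tm) || !any(bm)) stop("empty target or background mask")
  if (any(tm & bm)) stop("target and background masks must be disjoint")
  mt <- mean(s[tm]); mb <- mean(s[bm])
  vt <- stats::var(s[tm]); vb <- stats::var(s[bm])
  sqrt(2 * (mb - mt)^2 / (vb + vt))
}

#' Nodal positional error over repeated noise realisations
#'
#' Per repeat, the mean over nodes of the Euclidean norm of the nodal
#' displacement-vector error `(est - truth)`; reported as mean and
#' sample (n-1) standard deviation across repeats.
#'
#' @param est list of [displacement_field()]s (one per repeat) or a
#'   single field.
#' @param truth the reference [displacement_field()].
#' @return object of class `metric_report` fields `pos_err_mean`,
#'   `pos_err_std`, `per_repeat`.
#' @export
positional_error <- function(est, truth) {
  if (inherits(est, "displacement_field")) est <- list(est)
  if (length(est) < 1L) stop("at least one repeat required")
  per <- vapply(est, function(f) {
    if (length(f$u_axial) != length(truth$u_axial))
      stop("node counts differ between estimate and truth")
    mean(sqrt((f$u_axial - truth$u_axial)^2 +
              (f$u_lateral - truth$u_lateral)^2))
  }, numeric(1))
  structure(list(pos_err_mean = mean(per),
                 pos_err_std = if (length(per) > 1L) stats::sd(per) else 0,
                 per_repeat = per),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("positional error: %.4g +/- %.4g mm (%d repeat(s))\n",
              x$pos_err_mean, x$pos_err_std, length(x$per_repeat)))
  invisible(x)
}
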