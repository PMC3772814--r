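#' Ultrasound probe / acquisition description
#'
#' @param f0 center frequency (MHz).
#' @param fs RF sampling rate (MHz); must exceed `2 * f0`.
#' @param c sound speed (m/s).
#' @param line_pitch lateral spacing between RF lines (mm).
#' @return an object of class `probe_spec`. The wavelength
#'   `lambda = c / f0` (mm) and the depth per RF sample `c / (2 fs)` (mm)
#'   are attached for convenience.
#' @export
probe_spec <- function(f0 = 5, fs = 20, c = 1540, line_pitch = 0.3) {
  stopifnot(f0 > 0, fs > 0, c > 0, line_pitch > 0)
  if (fs <= 2 * f0)
    stop("sampling rate must exceed twice the center frequency")
  structure(list(f0 = f0, fs = fs, c = c, line_pitch = line_pitch,
                 lambda_mm = c / (f0 * 1e3),
                 sample_depth_mm = c / (2 * fs * 1e3)),
            class = "probe_spec")
}

#' @export
print.probe_spec <- function(x, ...) {
  cat(sprintf(paste0("probe_spec: f0 = %g MHz, fs = %g MHz, c = %g m/s, ",
                     "pitch = %g mm\n"), x$f0, x$fs, x$c, x$line_pitch))
  cat(sprintf("  lambda = %.4g mm, depth/sample = %.4g mm\n",
              x$lambda_mm, x$sample_depth_mm))
  invisible(x)
}

#' RF frame container
#'
#' @param samples numeric matrix of real RF amplitudes; rows are depth
#'   samples, columns are lines.
#' @param probe a [probe_spec()].
#' @return an object of class `rf_frame`.
#' @export
rf_frame <- function(samples, probe) {
  samples <- as.matrix(samples)
  if (!all(is.finite(samples))) stop("RF samples must be finite")
  if (ncol(samples) < 2L) stop("an RF frame needs at least 2 lines")
  structure(list(samples = samples, probe = probe), class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("rf_frame: %d depth samples x %d lines (%.3g mm depth)\n",
              nrow(x$samples), ncol(x$samples),
              nrow(x$samples) * x$probe$sample_depth_mm))
  invisible(x)
}

#' Analytic (complex) signal of an RF frame
#'
#' FFT-based analytic signal, column by column: negative frequencies are
#' suppressed and positive frequencies doubled, so the real part equals
#' the input and the magnitude is the envelope. Equivalent to
#' in-phase/quadrature demodulation up to the carrier rotation.
#'
#' @param frame an [rf_frame()] or a numeric matrix/vector.
#' @return complex matrix of the same shape.
#' @export
analytic_signal <- function(frame) {
  x <- if (inherits(frame, "rf_frame")) frame$samples else as.matrix(frame)
  n <- nrow(x)
  if (n < 16L) stop("RF line too short for the analytic signal (< 16 samples)")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  X <- stats::mvfft(x)
  z <- stats::mvfft(X * h, inverse = TRUE) / n
  z
}

#' Zero-lag complex cross-correlation of two segments
#'
#' `R = sum(s1 * Conj(s2))` over the correlation window. The phase of `R`
#' carries the mean carrier phase shift between the segments; swapping
#' the arguments conjugates `R`.
#'
#' @param pre_seg,post_seg complex vectors of equal nonzero length.
#' @return a single complex value.
#' @export
complex_xcorr <- function(pre_seg, post_seg) {
  if (length(pre_seg) == 0L || length(post_seg) == 0L)
    stop("empty correlation window")
  if (length(pre_seg) != length(post_seg))
    stop("correlation segments must have equal length")
  sum(pre_seg * Conj(post_seg))
}

#' Overlapping segment grid for phase-shift estimation
#'
#' Divides the usable depth of a frame into overlapping windows. Default
#' geometry: 1.5 mm windows with 75 % overlap.
#'
#' @param frame an [rf_frame()] (or number of depth samples plus `probe`).
#' @param window_mm window length in mm of depth.
#' @param overlap overlap fraction in `[0, 1)`.
#' @param probe probe spec when `frame` is a sample count.
#' @return object of class `segment_grid`: list with `window_len`
#'   (samples), `hop`, `starts` (first sample of each segment, 1-based),
#'   `centers_mm` (segment center depths).
#' @export
segment_grid <- function(frame, window_mm = 1.5, overlap = 0.75,
                         probe = NULL) {
  if (inherits(frame, "rf_frame")) {
    n <- nrow(frame$samples); probe <- frame$probe
  } else n <- as.integer(frame)
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  wl <- max(8L, round(window_mm / probe$sample_depth_mm))
  hop <- max(1L, round(wl * (1 - overlap)))
  starts <- seq(1L, n - wl + 1L, by = hop)
  if (length(starts) == 0L) stop("frame too short for one segment")
  structure(list(window_len = wl, hop = hop, overlap = overlap,
                 starts = starts,
                 centers_mm = (starts + (wl - 1) / 2) *
                   probe$sample_depth_mm),
            class = "segment_grid")
}

#' Phase-shift estimation of axial displacement with prior-lag unwrapping
#'
#' For every overlapping depth segment of every RF line, estimates the
#' time lag between the pre- and post-compression frames from the phase
#' of the zero-lag complex cross-correlation. Because the phase is only
#' unambiguous for displacements below a quarter wavelength, a prior lag
#' is predicted for each segment from its two already-processed
#' neighbors (the segment above in the same line and the same-depth
#' segment in the previous line; their mean, falling back to whichever
#' single one exists). The post segment is re-windowed at the integer
#' sample shift implied by the prior and only the residual phase is
#' converted back, so displacements well beyond the alias limit are
#' recovered as long as they vary continuously across segments.
#'
#' The very first segment has no processed neighbor; with
#' `seed_lag = "coarse"` (default) it is seeded by an integer-lag
#' normalized cross-correlation search, which also resolves global
#' shifts beyond the alias limit. `seed_lag = "zero"` instead assumes
#' zero displacement at the probe face (and zeroes the prior of the
#' first segment of every line), appropriate for pure compression.
#'
#' @param pre,post [rf_frame()]s sharing shape and probe.
#' @param grid a [segment_grid()]; built from defaults if omitted.
#' @param seed_lag `"coarse"` or `"zero"` (see Details).
#' @param max_seed_lag largest integer lag (samples) tried by the coarse
#'   seed search.
#' @return object of class `axial_disp_map`: list of matrices
#'   (`n_segments x n_lines`) `d` (displacement, mm), `tau` (lag, us),
#'   `tau_prior` (prior lag, us), `corr_mag` (normalized correlation
#'   magnitude), plus `centers_mm` and the probe.
#' @export
estimate_axial_disp <- function(pre, post, grid = NULL,
                                seed_lag = c("coarse", "zero"),
                                max_seed_lag = 40L) {
  seed_lag <- match.arg(seed_lag)
  if (!identical(dim(pre$samples), dim(post$samples)))
    stop("pre and post frames must share shape")
  probe <- pre$probe
  if (is.null(grid)) grid <- segment_grid(pre, probe = probe)
  zpre <- analytic_signal(pre)
  zpost <- analytic_signal(post)
  ns <- length(grid$starts)
  nl <- ncol(pre$samples)
  nd <- nrow(pre$samples)
  wl <- grid$window_len
  omega0 <- 2 * pi * probe$f0 * 1e6      # rad/s
  fs_hz <- probe$fs * 1e6
  d <- tau <- taup <- qual <- matrix(NA_real_, ns, nl)
  for (l in seq_len(nl)) {
    for (s in seq_len(ns)) {
      # prior lag from processed neighbors (seconds); under the "zero"
      # convention the first segment of every line re-seeds at zero
      if (s == 1L && seed_lag == "zero") {
        tp <- 0
      } else {
        nb <- c(if (s > 1L) tau[s - 1L, l],
                if (l > 1L) tau[s, l - 1L])
        nb <- nb[!is.na(nb)]
        if (length(nb) > 0L) {
          tp <- mean(nb)
        } else {
          tp <- coarse_lag_seed(pre$samples[, l], post$samples[, l],
                                grid$starts[s], wl, max_seed_lag) / fs_hz
        }
      }
      # re-window only when the prior exceeds one carrier period of lag:
      # below that the phase can be branch-unwrapped on the common window,
      # which keeps prior-free and prior-based estimates identical in the
      # alias-free range
      k <- round(tp * fs_hz)
      if (abs(k) < round(fs_hz / (probe$f0 * 1e6))) k <- 0L
      i0 <- grid$starts[s]
      i1 <- i0 + wl - 1L
      j0 <- i0 + k; j1 <- i1 + k
      if (j0 < 1L || j1 > nd) {
        # segment runs out of the frame after the prior shift: flag
        # low-quality and fall back to the prior itself
        tau[s, l] <- tp; taup[s, l] <- tp
        d[s, l] <- probe$c / 2 * tp * 1e3
        qual[s, l] <- 0
        next
      }
      p1 <- zpre[i0:i1, l]
      p2 <- zpost[j0:j1, l]
      R <- complex_xcorr(p1, p2)
      phi <- Arg(R)
      # unwrap the residual phase onto the 2*pi branch nearest the prior
      resid_prior <- omega0 * (tp - k / fs_hz)
      phi <- phi + 2 * pi * round((resid_prior - phi) / (2 * pi))
      t_hat <- k / fs_hz + phi / omega0
      tau[s, l] <- t_hat
      taup[s, l] <- tp
      d[s, l] <- probe$c / 2 * t_hat * 1e3   # mm
      qual[s, l] <- Mod(R) /
        sqrt(sum(Mod(p1)^2) * sum(Mod(p2)^2))
    }
  }
  structure(list(d = d, tau = tau * 1e6, tau_prior = taup * 1e6,
                 corr_mag = qual, centers_mm = grid$centers_mm,
                 probe = probe, grid = grid),
            class = "axial_disp_map")
}

#' @export
print.axial_disp_map <- function(x, ...) {
  cat(sprintf("axial_disp_map: %d segments x %d lines\n",
              nrow(x$d), ncol(x$d)))
  cat(sprintf("  displacement range [%.4g, %.4g] mm, median |R| = %.3f\n",
              min(x$d), max(x$d), stats::median(x$corr_mag, na.rm = TRUE)))
  invisible(x)
}

# integer-lag normalized cross-correlation peak over +-max_lag samples
coarse_lag_seed <- function(pre_line, post_line, start, wl, max_lag) {
  nd <- length(pre_line)
  seg <- pre_line[start:(start + wl - 1L)]
  best <- 0L; best_r <- -Inf
  for (k in -max_lag:max_lag) {
    j0 <- start + k; j1 <- j0 + wl - 1L
    if (j0 < 1L || j1 > nd) next
    cand <- post_line[j0:j1]
    r <- sum(seg * cand) / sqrt(sum(seg^2) * sum(cand^2) + 1e-300)
    if (r > best_r) { best_r <- r; best <- k }
  }
  best
}

#' Simulate a pre/post RF frame pair from point scatterers
#'
#' Convolution model: each line is a sum of Gaussian-windowed tones at
#' the probe center frequency, one per point scatterer, at the pulse-echo
#' delay of the scatterer's depth. The post frame moves each scatterer
#' axially by the supplied motion before re-convolving. Used as the test
#' fixture for the phase-shift estimator.
#'
#' @param depth_mm imaged depth (mm).
#' @param n_lines number of RF lines.
#' @param probe a [probe_spec()].
#' @param motion axial displacement in mm as a function
#'   `function(z_mm, x_mm)` (vectorized in `z_mm`), or a single number
#'   for a global shift. Positive displacement is away from the probe.
#' @param scatterers_per_mm linear scatterer density per line (default 18,
#'   about 5-6 per wavelength at 5 MHz).
#' @param pulse_cycles nominal pulse length in carrier cycles (FWHM).
#' @param seed RNG seed for scatterer positions and amplitudes.
#' @return list with `pre` and `post` [rf_frame()]s and the scatterer table.
#' @export
simulate_rf <- function(depth_mm, n_lines = 8L, probe = probe_spec(),
                        motion = 0, scatterers_per_mm = 18,
                        pulse_cycles = 2, seed = 1L) {
  if (scatterers_per_mm * probe$lambda_mm < 5)
    stop("scatterer density below 5 per wavelength per line")
  if (!is.function(motion)) {
    shift <- motion
    motion <- function(z, x) rep_len(shift, length(z))
  }
  nd <- ceiling(depth_mm / probe$sample_depth_mm)
  t_samp <- (seq_len(nd) - 1L) / (probe$fs * 1e6)     # s
  sigma_t <- pulse_cycles / (probe$f0 * 1e6) / 2.355  # FWHM -> sd
  omega0 <- 2 * pi * probe$f0 * 1e6
  margin <- 4 * sigma_t * probe$c / 2 * 1e3            # mm beyond edges
  frames <- with_seed(seed, {
    pre <- post <- matrix(0, nd, n_lines)
    sc <- vector("list", n_lines)
    for (l in seq_len(n_lines)) {
      x_mm <- (l - 1L) * probe$line_pitch
      n_sc <- round(scatterers_per_mm * (depth_mm + 2 * margin))
      z <- stats::runif(n_sc, -margin, depth_mm + margin)
      a <- stats::rnorm(n_sc)
      sc[[l]] <- data.frame(line = l, z_mm = z, amp = a)
      tz <- 2 * z * 1e-3 / probe$c                      # echo delay (s)
      z2 <- z + motion(z, x_mm)
      tz2 <- 2 * z2 * 1e-3 / probe$c
      for (i in seq_len(n_sc)) {
        dt1 <- t_samp - tz[i]
        pre[, l] <- pre[, l] +
          a[i] * exp(-dt1^2 / (2 * sigma_t^2)) * cos(omega0 * dt1)
        dt2 <- t_samp - tz2[i]
        post[, l] <- post[, l] +
          a[i] * exp(-dt2^2 / (2 * sigma_t^2)) * cos(omega0 * dt2)
      }
    }
    list(pre = pre, post = post, scatterers = do.call(rbind, sc))
  })
  list(pre = rf_frame(frames$pre, probe),
       post = rf_frame(frames$post, probe),
       scatterers = frames$scatterers)
}
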