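#' Filtering configuration for the kinematics chain
#'
#' Bundles the parameters of the smoothing/differentiation chain used
#' throughout the pipeline: a Savitzky-Golay local-polynomial smoother for
#' positions and angles, and a zero-phase (forward-backward) Butterworth
#' low-pass for velocity and acceleration series. Defaults are the standard
#' settings for 50 fps velocity-based-training video: SG window 9 frames,
#' polynomial order 3, Butterworth cutoff 6 Hz, order 4.
#'
#' @param fs Sampling frequency in Hz (the video frame rate).
#' @param sg_window Savitzky-Golay window length in frames; must be odd and
#'   greater than `sg_order`.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param butter_cutoff Butterworth low-pass cutoff frequency in Hz; must lie
#'   strictly below the Nyquist frequency `fs / 2`.
#' @param butter_order Butterworth filter order (applied forward and backward,
#'   so the effective attenuation is that of twice the order).
#'
#' @return An object of class `lp_filter_config`.
#' @examples
#' cfg <- filter_config(fs = 50)
#' cfg$sg_window
#' @export
filter_config <- function(fs, sg_window = 9L, sg_order = 3L,
                          butter_cutoff = 6, butter_order = 4L) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).", class = "lp_config_error")
  }
  sg_window <- as.integer(sg_window)
  sg_order <- as.integer(sg_order)
  butter_order <- as.integer(butter_order)
  if (sg_window %% 2L == 0L || sg_window <= sg_order) {
    abort("`sg_window` must be odd and greater than `sg_order`.",
          class = "lp_config_error")
  }
  if (butter_cutoff <= 0 || butter_cutoff >= fs / 2) {
    abort(sprintf("`butter_cutoff` must lie in (0, fs/2) = (0, %g) Hz.", fs / 2),
          class = "lp_config_error")
  }
  structure(
    list(fs = as.numeric(fs), sg_window = sg_window, sg_order = sg_order,
         butter_cutoff = as.numeric(butter_cutoff), butter_order = butter_order),
    class = "lp_filter_config"
  )
}

#' @export
print.lp_filter_config <- function(x, ...) {
  cat(sprintf(
    "<lp_filter_config> fs = %g Hz | SG(window %d, order %d) | Butterworth %g Hz, order %d (zero-phase)\n",
    x$fs, x$sg_window, x$sg_order, x$butter_cutoff, x$butter_order))
  invisible(x)
}

# Largest usable odd SG window for a series of length n: shrink rather than
# fail so short concentric segments stay analysable.
shrink_sg_window <- function(n, window, order) {
  smallest <- order + 2L
  if (smallest %% 2L == 0L) smallest <- smallest + 1L
  if (n < smallest) return(NA_integer_)
  if (n >= window) return(as.integer(window))
  w <- if (n %% 2L == 1L) as.integer(n) else as.integer(n - 1L)
  max(w, smallest)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with polynomial-fit edge handling
#' (edge points come from the polynomial fitted to the first/last full
#' window), so polynomials up to `sg_order` are reproduced exactly at every
#' point. If the series is shorter than the configured window, the window is
#' shrunk to the largest valid odd length (at least `sg_order + 2`) with a
#' warning, rather than failing.
#'
#' @param x Numeric series sampled on a uniform grid.
#' @param cfg An [filter_config()] object.
#' @return A numeric series of the same length as `x`.
#' @examples
#' cfg <- filter_config(fs = 50)
#' t <- seq(0, 1, by = 0.02)
#' all.equal(sg_smooth(t^3, cfg), t^3)
#' @export
sg_smooth <- function(x, cfg) {
  stopifnot(inherits(cfg, "lp_filter_config"))
  x <- as.numeric(x)
  n <- length(x)
  w <- shrink_sg_window(n, cfg$sg_window, cfg$sg_order)
  if (is.na(w)) {
    warn(sprintf(
      "Series of length %d too short for any SG window of order %d; returned unsmoothed.",
      n, cfg$sg_order), class = "lp_short_series")
    return(x)
  }
  if (w < cfg$sg_window) {
    warn(sprintf("SG window shrunk from %d to %d for a series of length %d.",
                 cfg$sg_window, w, n), class = "lp_window_shrunk")
  }
  as.numeric(signal::sgolayfilt(x, p = cfg$sg_order, n = w))
}

# Steady-state-initialised single IIR pass. Initial conditions are the
# steady state for a constant input equal to the first sample, which makes
# the filter exact on constants (unit DC gain).
iir_pass <- function(b, a, x) {
  nb <- length(b)
  x0 <- x[1L]
  # past inputs/outputs all equal to x0 give steady state for DC-gain-1 filters
  init_x <- rep(x0, nb - 1L)
  init_y <- rep(x0 * sum(b) / sum(a), length(a) - 1L)
  as.numeric(signal::filter(b, a, x, init.x = init_x, init.y = init_y))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass forward and then backward so the net phase
#' shift is zero (peak timing is preserved). Edge transients are controlled
#' by even-extension (mirror) padding at each end plus steady-state initial
#' conditions, then trimming back to the original length. DC gain is
#' exactly 1.
#'
#' @inheritParams sg_smooth
#' @return Filtered series, same length as `x`.
#' @examples
#' cfg <- filter_config(fs = 50)
#' max(abs(butter_zerophase(rep(3, 100), cfg) - 3)) < 1e-9
#' @export
butter_zerophase <- function(x, cfg) {
  stopifnot(inherits(cfg, "lp_filter_config"))
  x <- as.numeric(x)
  n <- length(x)
  bf <- signal::butter(cfg$butter_order, cfg$butter_cutoff / (cfg$fs / 2),
                       type = "low")
  # generous even-extension padding keeps edge transients (and the
  # forward/backward asymmetry they cause) negligible
  pad <- min(n - 1L, 20L * (cfg$butter_order + 1L))
  if (n <= 3L * cfg$butter_order) {
    abort(sprintf(
      "Series of length %d too short for an order-%d zero-phase filter (need > %d).",
      n, cfg$butter_order, 3L * cfg$butter_order), class = "lp_short_series")
  }
  # even extension about the end samples
  left <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(left, x, right)
  y <- iir_pass(bf$b, bf$a, xp)
  y <- rev(iir_pass(bf$b, bf$a, rev(y)))
  y[seq(pad + 1L, pad + n)]
}

#' Central-difference derivative
#'
#' First derivative on a uniform grid: interior points use the symmetric
#' central difference `(x[i+1] - x[i-1]) / (2 dt)`; the two endpoints use
#' one-sided first differences. Exact for linear and, at interior points,
#' quadratic series.
#'
#' @param x Numeric series.
#' @param dt Sampling interval in seconds (> 0).
#' @return Derivative series, same length as `x`.
#' @examples
#' central_diff(c(0, 2, 4, 6), dt = 1)
#' @export
central_diff <- function(x, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    abort("`dt` must be a single positive number (seconds).",
          class = "lp_config_error")
  }
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) {
    abort("`central_diff()` needs at least 3 samples.", class = "lp_short_series")
  }
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}

#' Sliding (moving) maximum
#'
#' Each output element is the maximum of `x` over a centred window of `k`
#' samples, truncated to the valid index range at the edges.
#'
#' @param x Numeric series.
#' @param k Odd window length in samples (>= 1).
#' @return Series of windowed maxima, same length as `x`.
#' @examples
#' sliding_max(c(1, 5, 2, 0, 3), k = 3)
#' @export
sliding_max <- function(x, k = 5L) {
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) {
    abort("`k` must be an odd positive integer.", class = "lp_config_error")
  }
  x <- as.numeric(x)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    max(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}
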