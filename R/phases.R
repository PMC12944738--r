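#' Detect concentric phases in a velocity series
#'
#' A frame is a concentric candidate when the linear velocity is positive
#' (upward motion) and exceeds the significance threshold (default
#' 0.5 m/s, filtering noise and incidental motion). Maximal runs of
#' consecutive candidates are merged into intervals, and intervals shorter
#' than `min_frames` (default 5 frames, about 0.1 s at 50 fps) are
#' discarded as transients. Optionally an angle-increase criterion can be
#' added (`theta` strictly increasing across each candidate frame), off by
#' default.
#'
#' @param v Linear velocity series, m/s (typically the low-passed `v`
#'   column of [compute_kinematics()]).
#' @param fps Frame rate, Hz.
#' @param v_threshold Significance threshold, m/s.
#' @param min_frames Minimum interval length in frames.
#' @param theta Optional unwrapped angle series (same length as `v`), used
#'   only when `require_increasing_theta = TRUE`.
#' @param require_increasing_theta Add the optional angle criterion.
#' @return A tibble with one row per phase: `rep_index`, `ts`, `te`
#'   (1-based inclusive frame indices into `v`), `n_frames`,
#'   `duration_s = (te - ts) / fps`. Zero rows when nothing qualifies.
#' @export
detect_concentric_phases <- function(v, fps, v_threshold = 0.5,
                                     min_frames = 5L, theta = NULL,
                                     require_increasing_theta = FALSE) {
  v <- as.numeric(v)
  min_frames <- as.integer(min_frames)
  cand <- v > 0 & v > v_threshold
  if (require_increasing_theta) {
    if (is.null(theta) || length(theta) != length(v)) {
      abort("`theta` of the same length as `v` is required for the angle criterion.",
            class = "lp_config_error")
    }
    dtheta <- c(diff(theta), if (length(theta) > 1) utils::tail(diff(theta), 1) else 0)
    cand <- cand & dtheta > 0
  }
  empty <- tibble::tibble(rep_index = integer(), ts = integer(),
                          te = integer(), n_frames = integer(),
                          duration_s = double())
  if (!any(cand)) return(empty)
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  if (!any(keep)) return(empty)
  tibble::tibble(
    rep_index = seq_len(sum(keep)),
    ts = starts[keep], te = ends[keep],
    n_frames = r$lengths[keep],
    duration_s = (ends[keep] - starts[keep]) / fps)
}

#' Peak value over a concentric phase
#'
#' Restricts the series to the phase, Savitzky-Golay-smooths it (the window
#' auto-shrinks for short phases), applies a sliding maximum of window `k`
#' and returns the overall maximum. The sliding-maximum stage makes the
#' peak robust to single-frame spikes removed by the smoother while leaving
#' the global maximum of the smoothed segment unchanged.
#'
#' @param x Numeric series (velocity or power).
#' @param ts,te 1-based inclusive phase bounds into `x`.
#' @param cfg [filter_config()].
#' @param k Sliding-maximum window, frames (odd).
#' @return Scalar peak value.
#' @export
phase_peak <- function(x, ts, te, cfg, k = 5L) {
  n <- length(x)
  if (ts < 1L || te > n || te < ts) {
    abort(sprintf("Phase [%d, %d] out of bounds for a series of length %d.",
                  ts, te, n), class = "lp_index_error")
  }
  seg <- as.numeric(x[ts:te])
  max(sliding_max(sg_smooth(seg, cfg), k = k))
}

#' Time-weighted mean over a concentric phase
#'
#' Trapezoidal integral of the series over the phase divided by the phase
#' duration `Tc = (te - ts) * dt`; the discrete counterpart of the
#' time-average of the underlying continuous signal.
#'
#' @inheritParams phase_peak
#' @param dt Sampling interval, seconds.
#' @return Scalar time-weighted mean.
#' @export
phase_mean <- function(x, ts, te, dt) {
  n <- length(x)
  if (ts < 1L || te > n || te < ts) {
    abort(sprintf("Phase [%d, %d] out of bounds for a series of length %d.",
                  ts, te, n), class = "lp_index_error")
  }
  if (te == ts) {
    abort("Degenerate phase: zero duration.", class = "lp_degenerate_phase")
  }
  seg <- as.numeric(x[ts:te])
  m <- length(seg)
  integral <- sum((seg[-1] + seg[-m]) / 2) * dt
  integral / ((te - ts) * dt)
}

#' Per-repetition velocity and power indicators
#'
#' For each detected concentric phase, extracts the four standard
#' velocity-based-training indicators: peak velocity, mean velocity, peak
#' power and mean power ([phase_peak()] / [phase_mean()] applied to the
#' velocity and power series).
#'
#' @param kin `lp_kinematics` from [compute_kinematics()].
#' @param phases Phase tibble from [detect_concentric_phases()]; detected
#'   from `kin$v` by default.
#' @param cfg [filter_config()]; defaults to the one stored in `kin`.
#' @param ... Passed on to [detect_concentric_phases()] when `phases` is
#'   not supplied.
#' @return A tibble with one row per repetition: `rep_index`, `ts`, `te`,
#'   `duration_s`, `peak_velocity`, `mean_velocity`, `peak_power`,
#'   `mean_power`.
#' @export
rep_metrics <- function(kin, phases = NULL, cfg = NULL, ...) {
  stopifnot(inherits(kin, "lp_kinematics"))
  dt <- attr(kin, "dt")
  if (is.null(cfg)) cfg <- attr(kin, "config")
  if (is.null(phases)) {
    phases <- detect_concentric_phases(kin$v, fps = 1 / dt, ...)
  }
  if (!nrow(phases)) {
    return(tibble::tibble(rep_index = integer(), ts = integer(),
                          te = integer(), duration_s = double(),
                          peak_velocity = double(), mean_velocity = double(),
                          peak_power = double(), mean_power = double()))
  }
  purrr::pmap(phases, function(rep_index, ts, te, n_frames, duration_s, ...) {
    tibble::tibble(
      rep_index = rep_index, ts = ts, te = te, duration_s = duration_s,
      peak_velocity = phase_peak(kin$v, ts, te, cfg),
      mean_velocity = phase_mean(kin$v, ts, te, dt),
      peak_power = phase_peak(kin$power, ts, te, cfg),
      mean_power = phase_mean(kin$power, ts, te, dt))
  }) |> purrr::list_rbind()
}
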