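#' Bar angle series from a calibrated trajectory
#'
#' The instantaneous bar angle above the horizontal, computed with the
#' four-quadrant inverse tangent of the moving end's position relative to
#' the pivot (the origin of the calibrated y-up frame). Range `(-pi, pi]`.
#'
#' @param traj An `lp_trajectory` from [calibrate()].
#' @return Numeric series of angles in radians, one per frame.
#' @export
angle_series <- function(traj) {
  stopifnot(inherits(traj, "lp_trajectory"))
  if (any(traj$x == 0 & traj$y == 0)) {
    abort(sprintf("Moving end coincides with the pivot at frame %d.",
                  traj$frame[which(traj$x == 0 & traj$y == 0)[1]]),
          class = "lp_degenerate_geometry")
  }
  atan2(traj$y, traj$x)
}

#' Unwrap an angle series
#'
#' Adds integer multiples of `2*pi` to each sample so that successive
#' differences never exceed `pi` in magnitude, removing the artificial
#' jumps where `atan2` crosses the branch cut. The first sample is left
#' unchanged.
#'
#' @param theta Angle series in radians.
#' @return Unwrapped series, same length.
#' @examples
#' unwrap_angles(c(3.0, 3.1, -3.1))
#' @export
unwrap_angles <- function(theta) {
  theta <- as.numeric(theta)
  n <- length(theta)
  if (!n) abort("Empty angle series.", class = "lp_short_series")
  d <- diff(theta)
  k <- cumsum(round(-d / (2 * pi)))
  c(theta[1], theta[-1] + 2 * pi * k)
}

#' Angular velocity from an angle series
#'
#' Central-difference derivative of the Savitzky-Golay-smoothed (already
#' unwrapped) angle series.
#'
#' @param theta Unwrapped angle series, radians.
#' @param cfg [filter_config()].
#' @param dt Sampling interval, seconds.
#' @return Angular velocity in rad/s, same length.
#' @export
angular_velocity <- function(theta, cfg, dt) {
  central_diff(sg_smooth(theta, cfg), dt)
}

#' Angular acceleration from an angular-velocity series
#'
#' Central-difference derivative of the angular velocity, then zero-phase
#' Butterworth low-passed to control differentiation noise.
#'
#' @param omega Angular velocity series, rad/s.
#' @inheritParams angular_velocity
#' @return Angular acceleration in rad/s^2, same length.
#' @export
angular_acceleration <- function(omega, cfg, dt) {
  butter_zerophase(central_diff(omega, dt), cfg)
}

#' Tangential linear velocity of the moving end
#'
#' `v = L * omega` for planar rotation of radius `L`. When a filter
#' configuration is supplied the velocity is additionally zero-phase
#' low-passed (the standard treatment before phase segmentation); with
#' `cfg = NULL` the raw product is returned.
#'
#' @param omega Angular velocity series, rad/s.
#' @param L Rotation radius in metres (the bar length).
#' @param cfg Optional [filter_config()] for the velocity low-pass.
#' @return Linear velocity in m/s, same length.
#' @export
linear_velocity <- function(omega, L, cfg = NULL) {
  if (L <= 0) abort("`L` must be positive (metres).", class = "lp_config_error")
  v <- L * as.numeric(omega)
  if (!is.null(cfg)) v <- butter_zerophase(v, cfg)
  v
}

#' Tangential force at the moving end
#'
#' Point-mass model with inertial and gravitational components:
#' `F = m * L * alpha + m * g * sin(theta)`, with the total load mass `m`
#' concentrated at the moving end.
#'
#' @param alpha Angular acceleration series, rad/s^2.
#' @param theta Unwrapped (smoothed) angle series, radians.
#' @param mass Total load mass in kg (bar plus plates).
#' @param L Bar length in metres.
#' @param g Gravitational acceleration, m/s^2.
#' @return Force series in newtons.
#' @export
tangential_force <- function(alpha, theta, mass, L, g = 9.81) {
  if (mass <= 0 || L <= 0) {
    abort("`mass` and `L` must be positive.", class = "lp_config_error")
  }
  mass * L * as.numeric(alpha) + mass * g * sin(as.numeric(theta))
}

#' Mechanical power
#'
#' Elementwise product `P = F * v`.
#'
#' @param force Force series, newtons.
#' @param v Velocity series, m/s.
#' @return Power series in watts.
#' @export
mechanical_power <- function(force, v) {
  as.numeric(force) * as.numeric(v)
}

#' Full kinematics chain for a calibrated trajectory
#'
#' Runs the complete processing chain on one contiguous block of a
#' calibrated trajectory:
#'
#' 1. Savitzky-Golay smoothing of the raw metre-space coordinates.
#' 2. Bar angle by four-quadrant arctangent, then phase unwrapping.
#' 3. Angular velocity: central difference of the SG-smoothed angle.
#' 4. Linear velocity `v = L * omega`, zero-phase Butterworth low-passed.
#' 5. Angular acceleration: central difference of omega (or, with
#'    `alpha_from = "v"`, of the low-passed `v / L`), low-passed.
#' 6. Force `F = m L alpha + m g sin(theta)` and power `P = F v`.
#'
#' Force and power are model-based estimates of a planar point-mass
#' rotation, not direct measurements.
#'
#' @param traj `lp_trajectory` from [calibrate()]. If it contains several
#'   blocks, pass one block at a time (see `block` column).
#' @param mass Total load mass, kg.
#' @param cfg [filter_config()]; its `fs` must match the trajectory fps.
#' @param g Gravitational acceleration, m/s^2.
#' @param alpha_from Differentiate `"omega"` (default) or the low-passed
#'   linear velocity `"v"` to obtain the angular acceleration.
#' @return A tibble of class `lp_kinematics` with columns `t`, `theta_raw`,
#'   `theta` (unwrapped + smoothed), `omega`, `alpha`, `v_raw` (`L * omega`),
#'   `v` (low-passed), `force`, `power`; attributes `dt`, `mass`, `g`, `L`,
#'   `config`, `alpha_from`.
#' @export
compute_kinematics <- function(traj, mass, cfg = NULL, g = 9.81,
                               alpha_from = c("omega", "v")) {
  stopifnot(inherits(traj, "lp_trajectory"))
  alpha_from <- match.arg(alpha_from)
  fps <- attr(traj, "fps")
  if (is.null(cfg)) cfg <- filter_config(fs = fps)
  if (abs(cfg$fs - fps) > 1e-9) {
    abort(sprintf("Filter config fs (%g) does not match trajectory fps (%g).",
                  cfg$fs, fps), class = "lp_config_error")
  }
  dt <- 1 / fps
  L <- attr(traj, "L_real")
  if (length(unique(traj$block)) > 1L) {
    warn("Trajectory has multiple blocks; analysing the longest one.",
         class = "lp_multi_block")
    keep <- as.integer(names(which.max(table(traj$block))))
    traj <- traj[traj$block == keep, , drop = FALSE]
  }

  smooth_traj <- traj
  smooth_traj$x <- sg_smooth(traj$x, cfg)
  smooth_traj$y <- sg_smooth(traj$y, cfg)
  theta_raw <- atan2(smooth_traj$y, smooth_traj$x)
  theta_u <- unwrap_angles(theta_raw)
  theta_s <- sg_smooth(theta_u, cfg)
  omega <- central_diff(theta_s, dt)
  v_raw <- linear_velocity(omega, L)
  v <- butter_zerophase(v_raw, cfg)
  alpha <- if (alpha_from == "omega") {
    angular_acceleration(omega, cfg, dt)
  } else {
    butter_zerophase(central_diff(v / L, dt), cfg)
  }
  force <- tangential_force(alpha, theta_s, mass, L, g)
  power <- mechanical_power(force, v)

  out <- tibble::tibble(
    t = traj$t, theta_raw = theta_raw, theta = theta_s, omega = omega,
    alpha = alpha, v_raw = v_raw, v = v, force = force, power = power)
  structure(out, dt = dt, mass = mass, g = g, L = L, config = cfg,
            alpha_from = alpha_from,
            class = c("lp_kinematics", class(out)))
}

#' @export
print.lp_kinematics <- function(x, ...) {
  cat(sprintf(
    "<lp_kinematics> %d frames, dt %.4g s | mass %g kg, L %g m, g %g m/s^2 | force/power are model estimates\n",
    nrow(x), attr(x, "dt"), attr(x, "mass"), attr(x, "L"), attr(x, "g")))
  NextMethod()
}

#' Export a kinematic series as tidy CSV
#'
#' @param kin `lp_kinematics` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_kinematics_csv <- function(kin, path) {
  stopifnot(inherits(kin, "lp_kinematics"))
  readr::write_csv(
    dplyr::select(tibble::as_tibble(kin), "t", theta = "theta", omega = "omega",
                  alpha = "alpha", v = "v", F = "force", P = "power"),
    path)
  invisible(path)
}
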