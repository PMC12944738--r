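# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles, not via the package's own
# code paths.

# Savitzky-Golay weights at the centre of a window, by solving the local
# least-squares polynomial fit directly.
oracle_sg_centre_weight <- function(window, order) {
  half <- (window - 1) / 2
  A <- outer(-half:half, 0:order, `^`)
  H <- A %*% solve(t(A) %*% A) %*% t(A)
  H[half + 1, half + 1]
}

# Phase unwrapping by exhaustive search over 2*pi multiples per sample.
oracle_unwrap <- function(theta, k_range = -3:3) {
  out <- theta
  for (i in seq_along(theta)[-1]) {
    cand <- theta[i] + 2 * pi * k_range
    out[i] <- cand[which.min(abs(cand - out[i - 1]))]
  }
  out
}

# O(n k) sliding maximum scan.
oracle_sliding_max <- function(x, k) {
  h <- (k - 1) %/% 2
  n <- length(x)
  sapply(seq_len(n), function(i) max(x[max(1, i - h):min(n, i + h)]))
}

# Central difference evaluated index by index from the defining formula.
oracle_central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- if (i == 1) (x[2] - x[1]) / dt
    else if (i == n) (x[n] - x[n - 1]) / dt
    else (x[i + 1] - x[i - 1]) / (2 * dt)
  }
  d
}

# Total-least-squares (orthogonal regression) line via numeric minimisation
# of the summed squared perpendicular distances. The line passes through the
# centroid; parametrise by its angle.
oracle_tls_slope <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  obj <- function(phi) sum((yc * cos(phi) - xc * sin(phi))^2)
  opt <- optimize(obj, interval = c(-pi / 2 + 1e-9, pi / 2 - 1e-9),
                  tol = 1e-14)
  tan(opt$minimum)
}

# Time-weighted mean via dense trapezoidal quadrature of the same
# piecewise-linear interpolant on a 1000x finer grid.
oracle_phase_mean <- function(x, ts, te, dt) {
  grid <- seq(ts, te, length.out = (te - ts) * 1000 + 1)
  vals <- approx(seq_along(x), x, xout = grid)$y
  h <- (grid[2] - grid[1]) * dt
  integral <- sum((vals[-1] + vals[-length(vals)]) / 2) * h
  integral / ((te - ts) * dt)
}

# Random oblong rectangle with consecutive corners, arbitrary rotation.
random_rectangle <- function(long = runif(1, 5, 50), short = runif(1, 1, 4),
                             angle = runif(1, 0, 2 * pi),
                             centre = runif(2, 100, 900)) {
  u <- c(cos(angle), sin(angle))
  v <- c(-sin(angle), cos(angle))
  p1 <- centre - long / 2 * u - short / 2 * v
  p2 <- centre + long / 2 * u - short / 2 * v
  p3 <- centre + long / 2 * u + short / 2 * v
  p4 <- centre - long / 2 * u + short / 2 * v
  tibble::tibble(frame = 0L, class = "bar",
                 x1 = p1[1], y1 = p1[2], x2 = p2[1], y2 = p2[2],
                 x3 = p3[1], y3 = p3[2], x4 = p4[1], y4 = p4[2],
                 conf = NA_real_)
}

# Detection tibble for a single box given corners as a 4x2 matrix.
det_from_corners <- function(m, class = "bar", frame = 0L) {
  tibble::tibble(frame = frame, class = class,
                 x1 = m[1, 1], y1 = m[1, 2], x2 = m[2, 1], y2 = m[2, 2],
                 x3 = m[3, 1], y3 = m[3, 2], x4 = m[4, 1], y4 = m[4, 2],
                 conf = NA_real_)
}

# Run the full recovery pipeline on a simulated press; returns rep metrics
# and the detected phase count.
recover_press <- function(sim, v_threshold = 0.5) {
  cfg <- sim$config
  track <- build_end_track(sim$detections, fps = cfg$fps,
                           image_height = cfg$image_height)
  traj <- calibrate(track, bar_length = cfg$L_real)
  kin <- compute_kinematics(traj, mass = cfg$mass)
  phases <- detect_concentric_phases(kin$v, fps = cfg$fps,
                                     v_threshold = v_threshold)
  metrics <- suppressWarnings(rep_metrics(kin, phases))
  list(kin = kin, phases = phases, metrics = metrics, traj = traj)
}
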