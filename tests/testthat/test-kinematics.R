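cfg50 <- filter_config(fs = 50)

# minimal calibrated trajectory straight from metre coordinates
traj_from_xy <- function(x, y, fps = 50, L = 2.20) {
  out <- tibble::tibble(frame = seq_along(x) - 1L, t = (seq_along(x) - 1) / fps,
                        x = x, y = y, fixed_x = 0, fixed_y = 0,
                        interpolated = FALSE, block = 1L)
  structure(out, scale_s = 1 / 400, L_pixel_mean = L * 400, L_real = L,
            fps = fps, pivot_px = c(x = 0, y = 0),
            class = c("lp_trajectory", class(tibble::tibble())))
}

test_that("angle series is the four-quadrant arctangent in the y-up frame", {
  traj <- traj_from_xy(c(1, -1, 0), c(1, 0, -1))
  expect_equal(angle_series(traj), c(pi / 4, pi, -pi / 2))
  traj0 <- traj_from_xy(c(1, 0), c(1, 0))
  expect_error(angle_series(traj0), class = "lp_degenerate_geometry")
})

test_that("unwrapping matches the brute-force 2*pi*k search and is shift-equivariant", {
  expect_equal(unwrap_angles(c(3.0, 3.1, -3.1)), c(3.0, 3.1, -3.1 + 2 * pi),
               tolerance = 1e-12)
  ok <- c(0.1, 0.5, 1.2, 0.9) # already within pi steps
  expect_equal(unwrap_angles(ok), ok)
  set.seed(55)
  for (i in 1:25) {
    theta <- atan2(sin(cumsum(rnorm(30, sd = 1.2))), cos(cumsum(rnorm(30, sd = 1.2))))
    u <- unwrap_angles(theta)
    expect_equal(u, oracle_unwrap(theta), tolerance = 1e-12)
    expect_true(all(abs(diff(u)) <= pi + 1e-12))
    expect_equal(unwrap_angles(theta + 2 * pi * 3) - u, rep(2 * pi * 3, 30),
                 tolerance = 1e-12)
  }
})

test_that("angular velocity is exact for linear angle ramps", {
  t <- seq(0, 1, by = 0.02)
  omega <- angular_velocity(0.5 + 2 * t, cfg50, dt = 0.02)
  interior <- 2:(length(t) - 1)
  expect_equal(omega[interior], rep(2, length(interior)), tolerance = 1e-9)
  expect_equal(angular_velocity(rep(0.7, 51), cfg50, dt = 0.02), rep(0, 51),
               tolerance = 1e-12)
})

test_that("angular acceleration recovers linear omega slopes through the low-pass", {
  t <- seq(0, 2, by = 0.02)
  alpha <- angular_acceleration(3 * t, cfg50, dt = 0.02)
  interior <- seq(20, length(t) - 20)
  expect_equal(alpha[interior], rep(3, length(interior)), tolerance = 0.01 * 3)
  expect_equal(max(abs(angular_acceleration(rep(1.5, 100), cfg50, dt = 0.02))),
               0, tolerance = 1e-9)
})

test_that("linear velocity is L * omega, scaling linearly in L", {
  omega <- rep(1, 50)
  expect_equal(linear_velocity(omega, 2.2), rep(2.2, 50))
  expect_equal(linear_velocity(rep(0, 50), 2.2), rep(0, 50))
  set.seed(66)
  w <- rnorm(50)
  expect_equal(linear_velocity(w, 4.4), 2 * linear_velocity(w, 2.2))
})

test_that("tangential force combines inertial and gravitational terms as printed", {
  expect_equal(tangential_force(0, pi / 2, mass = 25, L = 2.2, g = 9.81), 245.25)
  expect_equal(tangential_force(1, 0, mass = 25, L = 2.2, g = 9.81), 55)
  expect_equal(tangential_force(0.5, pi / 6, mass = 20, L = 2.2, g = 9.81),
               22 + 98.1, tolerance = 1e-9)
})

test_that("power is the elementwise product with matching sign structure", {
  expect_equal(mechanical_power(100, 2), 200)
  set.seed(77)
  f <- rnorm(30); v <- rnorm(30)
  p <- mechanical_power(f, v)
  expect_equal(p, f * v)
  expect_equal(sign(p), sign(f) * sign(v))
  expect_equal(mechanical_power(f, rep(0, 30)), rep(0, 30))
})

test_that("static bar: v = 0, F = mg sin(theta), P = 0 within 1e-6", {
  theta0 <- 55 * pi / 180
  x <- rep(2.20 * cos(theta0), 120)
  y <- rep(2.20 * sin(theta0), 120)
  kin <- compute_kinematics(traj_from_xy(x, y), mass = 25, cfg = cfg50)
  expect_lt(max(abs(kin$v)), 1e-6)
  expect_lt(max(abs(kin$force - 25 * 9.81 * sin(theta0))), 1e-6)
  expect_lt(max(abs(kin$power)), 1e-6)
})

test_that("v = L * omega holds elementwise before the velocity low-pass", {
  sim <- simulate_press(press_config(seed = 21))
  res <- recover_press(sim)
  expect_equal(res$kin$v_raw, 2.20 * res$kin$omega, tolerance = 1e-12)
})

test_that("the pipeline is deterministic on identical input", {
  sim <- simulate_press(press_config(seed = 31, corner_noise_sigma = 2))
  r1 <- recover_press(sim)
  r2 <- recover_press(sim)
  expect_identical(r1$kin$v, r2$kin$v)
  expect_identical(r1$metrics, r2$metrics)
})

test_that("noiseless synthetic press recovers analytic omega and alpha profiles", {
  cfgp <- press_config(seed = 41, press_duration = 0.8)
  sim <- simulate_press(cfgp)
  res <- recover_press(sim)
  truth <- sim$truth
  core <- which(truth$omega > 0.2 * max(truth$omega)) # concentric interior
  w_err <- max(abs(res$kin$omega[core] - truth$omega[core]))
  expect_lt(w_err, 0.01 * max(truth$omega))
  a_err <- max(abs(res$kin$alpha[core] - truth$alpha[core]))
  expect_lt(a_err, 0.05 * max(abs(truth$alpha)))
})

test_that("peak velocity recovery: noiseless within 5% over a duration-amplitude grid", {
  for (dur in c(0.6, 0.8, 1.0)) {
    for (amp in c(30, 40, 50)) {
      cfgp <- press_config(press_duration = dur, theta_start = 35,
                           theta_end = 35 + amp, seed = 1000 + dur * 10 + amp)
      sim <- simulate_press(cfgp)
      res <- recover_press(sim)
      expect_equal(nrow(res$phases), 1L)
      v_true <- press_peaks(cfgp)[["v_max"]]
      expect_lt(abs(res$metrics$peak_velocity[1] - v_true) / v_true, 0.05)
    }
  }
})

test_that("work-energy consistency of the point-mass model over the concentric phase", {
  cfgp <- press_config(seed = 51)
  sim <- simulate_press(cfgp)
  res <- recover_press(sim)
  ph <- res$phases[1, ]
  kin <- res$kin
  dt <- attr(kin, "dt")
  idx <- ph$ts:ph$te
  work <- sum((kin$power[idx][-1] + kin$power[idx][-length(idx)]) / 2) * dt
  m <- 25; L <- 2.20; g <- 9.81
  th_s <- kin$theta[ph$ts]; th_e <- kin$theta[ph$te]
  # potential implied by the model's gravitational term mg*sin(theta),
  # plus the rotational kinetic term of the point mass at radius L
  pot <- m * g * L * (cos(th_s) - cos(th_e))
  ke <- 0.5 * m * L^2 * (kin$omega[ph$te]^2 - kin$omega[ph$ts]^2)
  expect_lt(abs(work - (pot + ke)) / abs(pot + ke), 0.10)
})
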