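# Scenario simulator: analytic ground-truth trajectories for the four
# validation scenarios (no-motion, free fall, forced circular motion,
# squatting) and synthesis of baro-IMU sensor logs from them, with
# white gyro/accelerometer noise, an optional constant accelerometer
# bias, serially correlated barometric noise and 1 Pa quantization.
#
# Specific force is generated from the rigid-body model
#   f^b = C^bn (bddot^n - g^n) + [omegadot x] s^b + [omega x][omega x] s^b
# so every truth trajectory is kinematically consistent with its log.

#' Sensor error model
#'
#' @param gyro_noise_sd white gyro noise SD, rad/s (default 1 deg/s).
#' @param accel_noise_sd white accelerometer noise SD, m/s^2 (default 10 mg).
#' @param accel_bias constant accelerometer bias, m/s^2 (length 3).
#' @param baro_noise_sd sample SD of the correlated barometric noise in the
#'   altitude domain, m. The default (0.469 m raw) is calibrated so that
#'   after Method A conditioning (4-point moving average) the altitude
#'   noise SD is 0.30 m, the value the complementary filter assumes: the
#'   moving average attenuates the colored-noise model's sample SD by a
#'   factor 0.640, computed from the coloring and moving-average frequency
#'   responses.
#' @param baro_quantum pressure quantization step, Pa.
#' @param seed integer seed making the generated log reproducible.
#' @return object of class `sensor_errors`.
#' @export
sensor_errors <- function(gyro_noise_sd = pi / 180,
                          accel_noise_sd = 10 * 9.81e-3,
                          accel_bias = c(0, 0, 0),
                          baro_noise_sd = 0.469,
                          baro_quantum = 1,
                          seed = 1L) {
  if (gyro_noise_sd < 0 || accel_noise_sd < 0 || baro_noise_sd < 0) {
    stop("sensor_errors: noise SDs must be >= 0")
  }
  if (baro_quantum <= 0) stop("sensor_errors: baro_quantum must be > 0")
  structure(list(gyro_noise_sd = gyro_noise_sd,
                 accel_noise_sd = accel_noise_sd,
                 accel_bias = accel_bias,
                 baro_noise_sd = baro_noise_sd,
                 baro_quantum = baro_quantum,
                 seed = as.integer(seed)),
            class = "sensor_errors")
}

#' Serially correlated barometric noise
#'
#' Environmental pressure-altitude fluctuations are modeled as white
#' Gaussian noise passed through the inverse of the whitening filter
#' (pole and zero swapped, gain inverted), so that the forward whitening
#' filter restores whiteness by construction. The series is rescaled to
#' the requested sample standard deviation.
#'
#' @param n number of samples.
#' @param wf [design_whitening_filter()] object.
#' @param target_sd sample SD of the output, m.
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @return numeric series of length `n`.
#' @export
colored_baro_noise <- function(n, wf = design_whitening_filter(),
                               target_sd = 0.30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(wf$b) >= 1) stop("colored_baro_noise: inverse filter unstable")
  if (target_sd == 0) return(numeric(n))
  e <- stats::rnorm(n)
  # inverse filter H^-1(z) = (z - a) / (g0 (z - b))
  u <- (e - wf$a * c(0, e[-n])) / wf$g0
  y <- as.numeric(stats::filter(u, wf$b, method = "recursive"))
  y * target_sd / stats::sd(y)
}

# f^b from the rigid-body specific-force model, one sample.
# Note on the tangential sign: with the scalar-last quaternion paired with
# C^bn = I + 2*q4*[q x] + 2*[q x]^2 and the propagator exp(Ts/2 Omega), the
# rotation of a body-fixed point as seen from {n} proceeds with the
# opposite sense to omega, so the tangential lever-arm term enters with a
# minus sign (verified numerically against the propagated kinematics; the
# centripetal term is even in omega and unaffected).
eq14_specific_force <- function(q, b_ddot_n, omega, omega_dot, s_b, g) {
  f <- drop(quat_to_Cbn(q) %*% (b_ddot_n - c(0, 0, g)))
  if (any(s_b != 0)) {
    f <- f - drop(skew(omega_dot) %*% s_b) +
      drop(skew(omega) %*% (skew(omega) %*% s_b))
  }
  f
}

# Assemble a scenario_truth object and synthesize its sensor log.
# height/velocity/accel_up describe the sensor origin (up-positive);
# b_ddot is the n-frame acceleration of the body origin used in the
# specific-force model (for the lever-arm scenarios the two differ).
build_scenario <- function(scenario, t, height, velocity, accel_up,
                           quat, omega, omega_dot, s_b, errors, Ts,
                           g = 9.81, theta = NULL, params = list()) {
  n <- length(t)
  f <- matrix(0, n, 3L)
  lever <- any(s_b != 0)
  b_ddot <- if (lever) matrix(0, n, 3L) else cbind(0, 0, -accel_up)
  for (k in seq_len(n)) {
    f[k, ] <- eq14_specific_force(quat[k, ], b_ddot[k, ], omega[k, ],
                                  omega_dot[k, ], s_b, g)
  }
  truth <- structure(list(scenario = scenario, t = t, height = height,
                          velocity = velocity, accel_up = accel_up,
                          quat = quat, omega = omega, omega_dot = omega_dot,
                          specific_force = f, s_b = s_b, theta = theta,
                          g = g, Ts = Ts, params = params),
                     class = "scenario_truth")
  list(truth = truth, log = synth_log(truth, errors))
}

# Measurement synthesis: truth + noise models, pressure domain last.
synth_log <- function(truth, errors) {
  n <- length(truth$t)
  set.seed(errors$seed)
  gyro <- truth$omega + matrix(stats::rnorm(3L * n, sd = errors$gyro_noise_sd), n, 3L)
  accel <- truth$specific_force +
    matrix(errors$accel_bias, n, 3L, byrow = TRUE) +
    matrix(stats::rnorm(3L * n, sd = errors$accel_noise_sd), n, 3L)
  wf <- design_whitening_filter(fs = 1 / truth$Ts)
  h_meas <- truth$height + colored_baro_noise(n, wf, errors$baro_noise_sd)
  p <- altitude_to_pressure(h_meas)
  p <- round(p / errors$baro_quantum) * errors$baro_quantum
  as_imu_log(data.frame(t = truth$t,
                        gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
                        ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                        p = p))
}

# Minimum-jerk unit step s(u) = 6u^5 - 15u^4 + 10u^3 with derivatives;
# position, velocity and acceleration all continuous at both ends.
min_jerk <- function(u) {
  list(s = 6 * u^5 - 15 * u^4 + 10 * u^3,
       ds = 30 * u^4 - 60 * u^3 + 30 * u^2,
       dds = 120 * u^3 - 180 * u^2 + 60 * u)
}

#' Simulate the no-motion scenario
#'
#' Device at rest on a table: truth height and velocity are identically
#' zero; the log contains gravity plus noise on the accelerometer, pure
#' noise on the gyro, and correlated quantized barometric noise.
#'
#' @param duration trial length, s (default 180 s = 9000 samples at 50 Hz).
#' @param errors [sensor_errors()] model.
#' @param Ts sampling interval, s.
#' @return list with `truth` (`scenario_truth`) and `log` (`imu_log`).
#' @export
simulate_no_motion <- function(duration = 180, errors = sensor_errors(),
                               Ts = 0.02) {
  n <- as.integer(round(duration / Ts))
  t <- (seq_len(n) - 1L) * Ts
  z <- numeric(n)
  build_scenario("no-motion", t, z, z, z,
                 quat = matrix(quat_identity(), n, 4L, byrow = TRUE),
                 omega = matrix(0, n, 3L), omega_dot = matrix(0, n, 3L),
                 s_b = c(0, 0, 0), errors = errors, Ts = Ts,
                 params = list(duration = duration))
}

#' Simulate free fall onto a mattress
#'
#' Phases: rest on the shelf (`rest1`), ballistic fall from height `H`
#' (specific force identically zero), first impact modeled as a half-sine
#' contact-acceleration hump of duration `impact_ms`, a ballistic rebound
#' governed by the restitution coefficient, a second (fully inelastic)
#' impact, a short mattress-settle transition to exactly `-H`, and a final
#' rest phase (`rest3`). The hump peak is derived from the momentum balance
#' so the trajectory is kinematically consistent. With `tumble = TRUE` the
#' case rotates at a constant rate during the ballistic phases, exercising
#' gyro-only attitude coasting.
#'
#' @param H drop height, m.
#' @param errors [sensor_errors()] model.
#' @param Ts sampling interval, s.
#' @param rest1 initial rest duration, s.
#' @param rest3 final rest duration, s.
#' @param restitution rebound speed ratio at the first impact.
#' @param impact_ms contact duration of each impact, ms.
#' @param settle_s duration of the mattress-settle transition, s.
#' @param tumble rotate during ballistic phases?
#' @param tumble_rate body angular rate during tumbling, rad/s.
#' @return list with `truth` and `log`.
#' @export
simulate_free_fall <- function(H = 1.53, errors = sensor_errors(),
                               Ts = 0.02, rest1 = 3, rest3 = 25,
                               restitution = 0.25, impact_ms = 40,
                               settle_s = 0.3, tumble = FALSE,
                               tumble_rate = c(2, 1, 0.5)) {
  if (H <= 0) stop("simulate_free_fall: H must be > 0")
  g <- 9.81
  Tf <- sqrt(2 * H / g)
  v_imp <- g * Tf
  d <- impact_ms / 1000
  e <- restitution
  Ac1 <- pi * ((1 + e) * v_imp + g * d) / (2 * d)
  v0b <- e * v_imp
  Tb <- 2 * v0b / g
  Ac2 <- pi * (v0b + g * d) / (2 * d)
  h1e <- -H + v_imp * d * (e - 1) / 2
  h2e <- h1e - v0b * d / 2

  t_release <- rest1
  t_imp1 <- t_release + Tf
  t_imp1e <- t_imp1 + d
  t_bend <- t_imp1e + Tb
  t_imp2e <- t_bend + d
  t_settle_e <- t_imp2e + settle_s
  total <- t_settle_e + rest3

  n <- as.integer(round(total / Ts))
  t <- (seq_len(n) - 1L) * Ts
  h <- v <- a <- numeric(n)

  seg <- function(lo, hi) which(t >= lo & t < hi)
  # ballistic fall
  i <- seg(t_release, t_imp1); s <- t[i] - t_release
  h[i] <- -g * s^2 / 2; v[i] <- -g * s; a[i] <- -g
  # first impact (half-sine contact acceleration)
  i <- seg(t_imp1, t_imp1e); s <- t[i] - t_imp1
  a[i] <- Ac1 * sin(pi * s / d) - g
  v[i] <- -v_imp + (Ac1 * d / pi) * (1 - cos(pi * s / d)) - g * s
  h[i] <- -H - v_imp * s + (Ac1 * d / pi) * (s - (d / pi) * sin(pi * s / d)) - g * s^2 / 2
  # rebound
  i <- seg(t_imp1e, t_bend); s <- t[i] - t_imp1e
  h[i] <- h1e + v0b * s - g * s^2 / 2; v[i] <- v0b - g * s; a[i] <- -g
  # second impact (fully inelastic)
  i <- seg(t_bend, t_imp2e); s <- t[i] - t_bend
  a[i] <- Ac2 * sin(pi * s / d) - g
  v[i] <- -v0b + (Ac2 * d / pi) * (1 - cos(pi * s / d)) - g * s
  h[i] <- h1e - v0b * s + (Ac2 * d / pi) * (s - (d / pi) * sin(pi * s / d)) - g * s^2 / 2
  # mattress settle to exactly -H
  i <- seg(t_imp2e, t_settle_e); u <- (t[i] - t_imp2e) / settle_s
  mj <- min_jerk(u); dh <- -H - h2e
  h[i] <- h2e + dh * mj$s
  v[i] <- dh * mj$ds / settle_s
  a[i] <- dh * mj$dds / settle_s^2
  # final rest
  i <- which(t >= t_settle_e); h[i] <- -H

  omega <- matrix(0, n, 3L)
  quat <- matrix(quat_identity(), n, 4L, byrow = TRUE)
  if (tumble) {
    ballistic <- (t >= t_release & t < t_imp1) | (t >= t_imp1e & t < t_bend)
    omega[ballistic, ] <- matrix(tumble_rate, sum(ballistic), 3L, byrow = TRUE)
    for (k in 2:n) {
      quat[k, ] <- quat_propagate(quat[k - 1L, ], omega[k - 1L, ], Ts)
    }
  }
  build_scenario("free-fall", t, h, v, a, quat, omega,
                 omega_dot = matrix(0, n, 3L), s_b = c(0, 0, 0),
                 errors = errors, Ts = Ts, g = g,
                 params = list(H = H, rest1 = rest1, rest3 = rest3,
                               restitution = e, impact_s = d,
                               t_release = t_release, t_imp1 = t_imp1,
                               T_fall = Tf, v_impact = v_imp,
                               impact_peak = Ac1, tumble = tumble))
}

#' Simulate forced circular motion
#'
#' The device is fastened to a rod at lever arm `L` from a horizontal
#' motor axis. After an initial rest and a linear spin-up ramp, the rod
#' turns at constant rate `omega0 = 2*pi*f0`; the sensed specific force
#' combines the rotating gravity projection with the centripetal term
#' `-omega0^2 L` on the lever-arm axis, and the sensor height is
#' `L * sin(theta)`. The encoder-style angle series `theta` is stored with
#' the truth for reference generation.
#'
#' @param f0 rotation frequency, Hz (study values 0.25 to 1.25).
#' @param L lever arm, m.
#' @param duration steady-state rotation length, s (default 180 s = 9000
#'   samples).
#' @param errors [sensor_errors()] model.
#' @param Ts sampling interval, s.
#' @param rest1 initial rest, s.
#' @param ramp linear spin-up duration, s.
#' @return list with `truth` and `log`; `truth$params$t_steady` marks the
#'   start of constant-rate rotation.
#' @export
simulate_circular <- function(f0 = 0.5, L = 0.30, duration = 180,
                              errors = sensor_errors(), Ts = 0.02,
                              rest1 = 2, ramp = 0.5) {
  g <- 9.81
  w0 <- 2 * pi * f0
  t_ramp <- rest1 + ramp
  total <- t_ramp + duration
  n <- as.integer(round(total / Ts))
  t <- (seq_len(n) - 1L) * Ts

  theta <- numeric(n); wx <- numeric(n); wdx <- numeric(n)
  i <- which(t >= rest1 & t < t_ramp); s <- t[i] - rest1
  theta[i] <- w0 * s^2 / (2 * ramp); wx[i] <- w0 * s / ramp; wdx[i] <- w0 / ramp
  th_ramp_end <- w0 * ramp / 2
  i <- which(t >= t_ramp); s <- t[i] - t_ramp
  theta[i] <- th_ramp_end + w0 * s; wx[i] <- w0

  h <- L * sin(theta)
  v <- L * wx * cos(theta)
  a <- L * (wdx * cos(theta) - wx^2 * sin(theta))
  quat <- cbind(sin(theta / 2), 0, 0, cos(theta / 2))
  omega <- cbind(wx, 0, 0)
  omega_dot <- cbind(wdx, 0, 0)
  build_scenario("circular", t, h, v, a, quat, omega, omega_dot,
                 s_b = c(0, L, 0), errors = errors, Ts = Ts, g = g,
                 theta = theta,
                 params = list(f0 = f0, L = L, duration = duration,
                               rest1 = rest1, ramp = ramp,
                               t_steady = t_ramp))
}

#' Simulate a squat exercise
#'
#' Trunk-worn sensor during one squat: minimum-jerk descent of the given
#' depth over half a cycle and symmetric ascent, with a proportional small
#' trunk-pitch oscillation, padded by rest on both sides.
#'
#' @param depth squat depth, m.
#' @param cycle_s duration of the down-and-up movement, s.
#' @param errors [sensor_errors()] model.
#' @param Ts sampling interval, s.
#' @param rest rest padding before and after, s.
#' @param pitch_amp peak trunk pitch at full depth, rad.
#' @return list with `truth` and `log`.
#' @export
simulate_squat <- function(depth = 0.60, cycle_s = 4,
                           errors = sensor_errors(), Ts = 0.02,
                           rest = 1.5, pitch_amp = 0.2) {
  if (depth <= 0) stop("simulate_squat: depth must be > 0")
  g <- 9.81
  half <- cycle_s / 2
  total <- 2 * rest + cycle_s
  n <- as.integer(round(total / Ts))
  t <- (seq_len(n) - 1L) * Ts
  w <- dw <- ddw <- numeric(n)  # normalized depth profile in [0, 1]
  i <- which(t >= rest & t < rest + half); u <- (t[i] - rest) / half
  mj <- min_jerk(u)
  w[i] <- mj$s; dw[i] <- mj$ds / half; ddw[i] <- mj$dds / half^2
  i <- which(t >= rest + half & t < rest + cycle_s)
  u <- (t[i] - rest - half) / half
  mj <- min_jerk(u)
  w[i] <- 1 - mj$s; dw[i] <- -mj$ds / half; ddw[i] <- -mj$dds / half^2

  h <- -depth * w; v <- -depth * dw; a <- -depth * ddw
  phi <- pitch_amp * w
  quat <- cbind(0, sin(phi / 2), 0, cos(phi / 2))
  omega <- cbind(0, pitch_amp * dw, 0)
  omega_dot <- cbind(0, pitch_amp * ddw, 0)
  build_scenario("squat", t, h, v, a, quat, omega, omega_dot,
                 s_b = c(0, 0, 0), errors = errors, Ts = Ts, g = g,
                 params = list(depth = depth, cycle_s = cycle_s,
                               rest = rest, pitch_amp = pitch_amp))
}

#' Simulate a named scenario
#'
#' Dispatcher over the four validation scenarios.
#'
#' @param scenario one of "no-motion", "free-fall", "circular", "squat".
#' @param ... scenario-specific arguments (see the individual simulators).
#' @param errors [sensor_errors()] model.
#' @return list with `truth` and `log`.
#' @export
simulate_scenario <- function(scenario = c("no-motion", "free-fall",
                                           "circular", "squat"),
                              ..., errors = sensor_errors()) {
  scenario <- match.arg(scenario)
  switch(scenario,
         "no-motion" = simulate_no_motion(..., errors = errors),
         "free-fall" = simulate_free_fall(..., errors = errors),
         "circular" = simulate_circular(..., errors = errors),
         "squat" = simulate_squat(..., errors = errors))
}

#' Write a simulated scenario to CSV files
#'
#' Writes `<prefix>_log.csv` (sensor log) and `<prefix>_truth.csv`
#' (t, height, velocity, accel_up, quaternion and, for circular motion,
#' the encoder angle theta).
#'
#' @param sim list with `truth` and `log` from a simulator.
#' @param prefix output path prefix.
#' @return named character vector of the written paths.
#' @export
write_scenario <- function(sim, prefix) {
  log_path <- paste0(prefix, "_log.csv")
  truth_path <- paste0(prefix, "_truth.csv")
  write_imu_log(sim$log, log_path)
  tr <- sim$truth
  df <- data.frame(t = tr$t, height = tr$height, velocity = tr$velocity,
                   accel_up = tr$accel_up,
                   q1 = tr$quat[, 1], q2 = tr$quat[, 2],
                   q3 = tr$quat[, 3], q4 = tr$quat[, 4])
  if (!is.null(tr$theta)) df$theta <- tr$theta
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   truth_path, row.names = FALSE, quote = FALSE)
  c(log = log_path, truth = truth_path)
}

#' Read a truth trajectory CSV written by [write_scenario()]
#' @param path CSV path.
#' @return data.frame with t, height, velocity, accel_up, q1..q4 (and
#'   theta when present).
#' @export
read_truth_log <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "height", "velocity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("truth log format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat(sprintf("Scenario truth '%s': %d samples at %g Hz (%.1f s)\n",
              x$scenario, length(x$t), 1 / x$Ts, max(x$t)))
  cat(sprintf("  height range [m]: %.3f .. %.3f\n",
              min(x$height), max(x$height)))
  invisible(x)
}
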