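# Shared fixtures and small utilities for the test suite. All fixtures are
# generated in code; nothing is read from disk.

MG <- 9.81e-3  # 1 milli-g in m/s^2

# Noise-free sensor error model (quantization effectively disabled).
quiet_errors <- function(seed = 1) {
  sensor_errors(gyro_noise_sd = 0, accel_noise_sd = 0, baro_noise_sd = 0,
                baro_quantum = 1e-9, seed = seed)
}

# A configuration with selected fields overridden without revalidation
# (lets tests zero individual noise sources).
cfg_override <- function(cfg = fusion_config(), ...) {
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

# Build a static level sensor log directly (no simulator): constant
# specific force f_b, zero gyro, constant pressure.
static_log <- function(n, f_b = c(0, 0, -9.81), gyro = c(0, 0, 0),
                       height = 0, Ts = 0.02) {
  p <- altitude_to_pressure(height)
  as_imu_log(data.frame(t = (seq_len(n) - 1L) * Ts,
                        gx = gyro[1], gy = gyro[2], gz = gyro[3],
                        ax = f_b[1], ay = f_b[2], az = f_b[3], p = p))
}

# Rotation matrix C^bn from the quadratic quaternion form, written out
# independently of the package implementation (test-side oracle).
oracle_Cbn <- function(q) {
  qv <- q[1:3]; q4 <- q[4]
  S <- matrix(c(0, qv[3], -qv[2], -qv[3], 0, qv[1], qv[2], -qv[1], 0), 3L)
  diag(3L) + 2 * q4 * S + 2 * S %*% S
}

# Run the EKF over a log, returning the per-step states (test-side loop
# giving access to intermediate covariances).
run_ekf <- function(log, cfg = fusion_config(), rest = NULL,
                    collect = c("q", "b")) {
  if (is.null(rest)) rest <- capture_rest(log, cfg)
  state <- ekf_init(rest, cfg)
  n <- nrow(log)
  qs <- matrix(NA_real_, n, 4L)
  bs <- matrix(NA_real_, n, 3L)
  Ps <- vector("list", n)
  upd <- logical(n)
  for (k in seq_len(n)) {
    omega <- c(log$gx[k], log$gy[k], log$gz[k]) - rest$gyro_bias
    state <- ekf_predict(state, omega, cfg)
    up <- ekf_update(state, c(log$ax[k], log$ay[k], log$az[k]), cfg)
    state <- up$state
    qs[k, ] <- state$q; bs[k, ] <- state$b; Ps[[k]] <- state$P
    upd[k] <- up$diagnostics$updated
  }
  list(q = qs, b = bs, P = Ps, updated = upd, rest = rest, final = state)
}

# Inclination error (degrees) between an estimated quaternion and truth:
# angle by which the estimated vertical deviates from the true vertical.
inclination_error_deg <- function(q_est, q_true) {
  v_est <- drop(quat_to_Cnb(q_est) %*% (oracle_Cbn(q_true) %*% c(0, 0, -1)))
  acos(max(-1, min(1, -v_est[3]))) * 180 / pi
}
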