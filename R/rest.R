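# Rest-period bias capture: gyro bias, barometric baseline and initial
# leveling, estimated from the first `rest_window` seconds of a log while
# the device is motionless.

#' Capture rest-period statistics
#'
#' Averages the tri-axial gyro output (gyro bias), the absolute pressure
#' altitude (barometric baseline) and the specific force over the rest
#' window, and levels the initial attitude from the mean specific force
#' (yaw fixed to zero; heading is unobservable without a magnetometer).
#'
#' @param log sensor log (see [as_imu_log()]).
#' @param cfg [fusion_config()]; `rest_window` and `Ts` define the window
#'   length in samples.
#' @return object of class `rest_stats` with fields `gyro_bias` (rad/s),
#'   `baro_baseline` (m), `mean_accel` (m/s^2), `initial_quaternion`,
#'   `n_samples`.
#' @export
capture_rest <- function(log, cfg = fusion_config()) {
  log <- as_imu_log(as.data.frame(log))
  n_rest <- as.integer(round(cfg$rest_window / cfg$Ts))
  if (nrow(log) < n_rest) {
    stop(sprintf("insufficient rest period: need %d samples (%g s), got %d",
                 n_rest, cfg$rest_window, nrow(log)))
  }
  w <- seq_len(n_rest)
  gyro_bias <- c(mean(log$gx[w]), mean(log$gy[w]), mean(log$gz[w]))
  mean_accel <- c(mean(log$ax[w]), mean(log$ay[w]), mean(log$az[w]))
  baro_baseline <- mean(pressure_to_altitude(log$p[w]))
  structure(list(gyro_bias = gyro_bias,
                 baro_baseline = baro_baseline,
                 mean_accel = mean_accel,
                 initial_quaternion = leveling_quaternion(mean_accel),
                 n_samples = n_rest),
            class = "rest_stats")
}

#' @export
print.rest_stats <- function(x, ...) {
  cat("Rest-period statistics (", x$n_samples, " samples)\n", sep = "")
  cat("  gyro bias [rad/s]:     ", paste(format(x$gyro_bias, digits = 4),
                                         collapse = " "), "\n")
  cat("  baro baseline [m]:     ", format(x$baro_baseline, digits = 7), "\n")
  cat("  mean accel [m/s^2]:    ", paste(format(x$mean_accel, digits = 4),
                                         collapse = " "), "\n")
  cat("  initial quaternion:    ", paste(format(x$initial_quaternion,
                                                digits = 4), collapse = " "), "\n")
  invisible(x)
}
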