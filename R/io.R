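# Sensor-log I/O. A log is a data.frame with one 50 Hz record per row:
# t (s), gx gy gz (rad/s), ax ay az (m/s^2), p (Pa).

IMU_LOG_COLUMNS <- c("t", "gx", "gy", "gz", "ax", "ay", "az", "p")

#' Validate and classify a sensor log
#'
#' Checks the column set, finiteness (reporting the first offending row),
#' strictly increasing timestamps and positive pressures.
#'
#' @param df data.frame with columns t, gx, gy, gz, ax, ay, az, p.
#' @return the data.frame with class `imu_log` prepended.
#' @export
as_imu_log <- function(df) {
  missing_cols <- setdiff(IMU_LOG_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("imu log format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[IMU_LOG_COLUMNS]
  for (cn in IMU_LOG_COLUMNS) {
    v <- df[[cn]]
    if (!is.numeric(v)) stop("imu log parse error: column '", cn, "' is not numeric")
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("imu log parse error: non-finite value in column '%s' at row %d",
                   cn, bad[1]))
    }
  }
  if (nrow(df) > 1L && any(diff(df$t) <= 0)) {
    stop("imu log format error: timestamps must be strictly increasing")
  }
  if (any(df$p <= 0)) stop("imu log format error: pressure must be positive")
  class(df) <- c("imu_log", "data.frame")
  df
}

#' Read a baro-IMU sensor log from CSV
#'
#' Expects a header with columns t (s), gx gy gz (rad/s), ax ay az (m/s^2)
#' and p (Pa). Rejects missing columns, non-finite values (with the row
#' index) and non-monotone timestamps.
#'
#' @param path CSV file path.
#' @return data.frame of class `imu_log`.
#' @export
read_imu_log <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  as_imu_log(df)
}

#' Write a baro-IMU sensor log to CSV
#' @param log `imu_log` (or conforming data.frame).
#' @param path output CSV path.
#' @export
write_imu_log <- function(log, path) {
  log <- as_imu_log(as.data.frame(log))
  utils::write.csv(format(log, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
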