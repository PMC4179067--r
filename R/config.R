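# Filter configuration. All values are SI: rad/s, m/s^2, m, s.
# The milli-g unit used for accelerometer quantities converts as
# 1 mg = 9.81e-3 m/s^2.

#' Fusion configuration
#'
#' Bundles every tuning parameter of the tracking pipeline. Defaults are the
#' working tuning for a 50 Hz wearable baro-IMU: gyro noise 1 deg/s,
#' accelerometer measurement noise 10 mg, bias driving noise 5e-4 m/s^3 with
#' correlation rate `alpha = 0` (random-walk limit), vector-selection
#' threshold 150 mg, linear-acceleration noise 15 mg, and pressure-altitude
#' noise 0.30 m for conditioning Method A (moving average only) or 0.15 m
#' for Method B (moving average cascaded with the whitening filter).
#'
#' @param method conditioning method, `"A"` (4-point moving average) or
#'   `"B"` (moving average cascaded with the whitening filter).
#' @param Ts sampling interval, s.
#' @param g gravity magnitude, m/s^2.
#' @param sigma_g gyro measurement noise SD, rad/s.
#' @param sigma_a accelerometer measurement noise SD, m/s^2.
#' @param sigma_ab accelerometer-bias driving noise SD, m/s^3.
#' @param alpha bias correlation rate (reciprocal correlation time), 1/s;
#'   `alpha = 0` gives the random-walk limit.
#' @param lambda_g vector-selection innovation threshold, m/s^2.
#' @param sigma_w linear-acceleration noise SD used by the complementary
#'   filter, m/s^2.
#' @param sigma_v pressure-altitude noise SD used by the complementary
#'   filter, m; defaults to 0.30 (Method A) or 0.15 (Method B).
#' @param rest_window rest-period duration used for bias capture, s.
#' @param p0_quat initial quaternion-block covariance (diagonal value).
#' @param p0_bias initial bias-block covariance (diagonal value), (m/s^2)^2.
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(method = c("A", "B"),
                          Ts = 0.02,
                          g = 9.81,
                          sigma_g = pi / 180,
                          sigma_a = 10 * 9.81e-3,
                          sigma_ab = 5e-4,
                          alpha = 0,
                          lambda_g = 150 * 9.81e-3,
                          sigma_w = 15 * 9.81e-3,
                          sigma_v = NULL,
                          rest_window = 1.0,
                          p0_quat = 1e-4,
                          p0_bias = (1 * 9.81e-3)^2) {
  method <- match.arg(method)
  if (is.null(sigma_v)) sigma_v <- if (method == "A") 0.30 else 0.15
  cfg <- list(method = method, Ts = Ts, g = g, sigma_g = sigma_g,
              sigma_a = sigma_a, sigma_ab = sigma_ab, alpha = alpha,
              lambda_g = lambda_g, sigma_w = sigma_w, sigma_v = sigma_v,
              rest_window = rest_window, p0_quat = p0_quat, p0_bias = p0_bias)
  validate_fusion_config(cfg)
  structure(cfg, class = "fusion_config")
}

validate_fusion_config <- function(cfg) {
  num <- c("Ts", "g", "sigma_g", "sigma_a", "sigma_ab", "lambda_g",
           "sigma_w", "sigma_v", "rest_window", "p0_quat", "p0_bias")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("fusion_config: '%s' must be a positive finite number", f))
    }
  }
  if (!is.numeric(cfg$alpha) || length(cfg$alpha) != 1L ||
      !is.finite(cfg$alpha) || cfg$alpha < 0) {
    stop("fusion_config: 'alpha' must be >= 0")
  }
  if (!cfg$method %in% c("A", "B")) {
    stop("fusion_config: 'method' must be \"A\" or \"B\"")
  }
  invisible(cfg)
}

#' Read a fusion configuration from a key = value text file
#'
#' The file holds one `key = value` pair per line (`#` starts a comment);
#' keys mirror the arguments of [fusion_config()]. Missing keys take their
#' defaults.
#'
#' @param path file path.
#' @param method optional method override applied before file values.
#' @return `fusion_config` object.
#' @export
read_fusion_config <- function(path, method = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("config parse error in line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    args[[key]] <- if (key == "method") val else as.numeric(val)
  }
  if (!is.null(method)) args$method <- method
  bad <- setdiff(names(args), names(formals(fusion_config)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(fusion_config, args)
}

#' Write a fusion configuration as a key = value text file
#' @param cfg `fusion_config` object.
#' @param path file path.
#' @export
write_fusion_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "fusion_config"))
  fmt <- function(v) if (is.character(v)) v else format(v, digits = 15)
  writeLines(sprintf("%s = %s", names(cfg), vapply(cfg, fmt, "")), path)
  invisible(path)
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("Baro-inertial fusion configuration (Method ", x$method, ")\n", sep = "")
  cat(sprintf("  sampling: Ts = %g s (%g Hz), g = %g m/s^2\n",
              x$Ts, 1 / x$Ts, x$g))
  cat(sprintf("  EKF: sigma_g = %.5g rad/s, sigma_a = %.5g m/s^2, lambda_g = %.5g m/s^2\n",
              x$sigma_g, x$sigma_a, x$lambda_g))
  cat(sprintf("  bias model: sigma_ab = %g m/s^3, alpha = %g 1/s\n",
              x$sigma_ab, x$alpha))
  cat(sprintf("  complementary: sigma_w = %.5g m/s^2, sigma_v = %g m\n",
              x$sigma_w, x$sigma_v))
  invisible(x)
}
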