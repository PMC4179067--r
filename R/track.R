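# End-to-end tracking pipeline: rest-period bias capture, attitude EKF,
# strap-down gravity cancellation, barometric conditioning and the
# complementary filter, applied causally sample by sample.

#' Track height and vertical velocity from a baro-IMU log
#'
#' Runs the full fusion pipeline on a 50 Hz sensor log: captures gyro bias,
#' barometric baseline and initial leveling from the rest window; then, for
#' every sample, performs one EKF predict/update with innovation-gated
#' accelerometer leveling, rotates the specific force into the navigation
#' frame and cancels gravity, conditions the pressure altitude (Method A:
#' 4-point moving average; Method B: moving average cascaded with the
#' whitening filter) and advances the two-state complementary filter.
#' Processing is strictly causal: the output at any time depends only on
#' samples up to that time.
#'
#' @param log sensor log (see [as_imu_log()] for the schema).
#' @param method conditioning method `"A"` or `"B"`; ignored when `cfg` is
#'   supplied.
#' @param cfg [fusion_config()]; defaults to the standard tuning for the
#'   chosen method.
#' @param rest optional precomputed [capture_rest()] statistics; computed
#'   from the head of `log` when NULL.
#' @return object of class `vertical_track`: a list with `estimates` (a
#'   data.frame with columns t, height, velocity, a_up, x_p, innovation and
#'   acceptance diagnostics), `rest`, `cfg`, `gain`, `whitening` (Method B
#'   only) and `final_state`.
#' @examples
#' sim <- simulate_no_motion(duration = 5, errors = sensor_errors(seed = 1))
#' trk <- track_vertical(sim$log, method = "A")
#' summary(trk)
#' @export
track_vertical <- function(log, method = c("A", "B"), cfg = NULL, rest = NULL) {
  if (is.null(cfg)) cfg <- fusion_config(method = match.arg(method))
  validate_fusion_config(cfg)
  log <- as_imu_log(as.data.frame(log))
  if (is.null(rest)) rest <- capture_rest(log, cfg)
  n <- nrow(log)
  Ts <- cfg$Ts
  gain <- complementary_gain(cfg$sigma_w, cfg$sigma_v)

  # conditioned pressure altitude is independent of the EKF: vectorized,
  # still causal
  conditioner <- baro_conditioner(rest, cfg)
  x_p <- conditioner$process(log$p)

  gyro <- cbind(log$gx - rest$gyro_bias[1],
                log$gy - rest$gyro_bias[2],
                log$gz - rest$gyro_bias[3])
  accel <- cbind(log$ax, log$ay, log$az)

  state <- ekf_init(rest, cfg)
  vstate <- c(0, 0)
  height <- velocity <- a_up <- numeric(n)
  innov <- matrix(NA_real_, n, 3L)
  acc <- matrix(NA, n, 3L)
  updated <- logical(n)
  prev_xp <- 0
  prev_aup <- 0
  for (k in seq_len(n)) {
    state <- ekf_predict(state, gyro[k, ], cfg)
    up <- ekf_update(state, accel[k, ], cfg)
    state <- up$state
    innov[k, ] <- up$diagnostics$innovation
    acc[k, ] <- up$diagnostics$accepted
    updated[k] <- up$diagnostics$updated
    a_up[k] <- vertical_acceleration(accel[k, ], state$q, cfg$g)
    vstate <- complementary_step(vstate, prev_xp, prev_aup, gain, Ts)
    height[k] <- vstate[1]
    velocity[k] <- vstate[2]
    prev_xp <- x_p[k]
    prev_aup <- a_up[k]
  }

  est <- data.frame(t = log$t, height = height, velocity = velocity,
                    a_up = a_up, x_p = x_p,
                    innov_x = innov[, 1], innov_y = innov[, 2],
                    innov_z = innov[, 3],
                    acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3],
                    updated = updated)
  structure(list(estimates = est, rest = rest, cfg = cfg, gain = gain,
                 whitening = conditioner$filter, final_state = state,
                 n = n, call = match.call()),
            class = "vertical_track")
}

#' @export
print.vertical_track <- function(x, ...) {
  est <- x$estimates
  cat(sprintf("Vertical track (Method %s): %d samples, %.1f s at %g Hz\n",
              x$cfg$method, x$n, diff(range(est$t)), 1 / x$cfg$Ts))
  cat(sprintf("  height   [m]:   range %.3f .. %.3f, final %.3f\n",
              min(est$height), max(est$height), est$height[x$n]))
  cat(sprintf("  velocity [m/s]: range %.3f .. %.3f, final %.3f\n",
              min(est$velocity), max(est$velocity), est$velocity[x$n]))
  cat(sprintf("  leveling updates accepted on %.1f%% of samples\n",
              100 * mean(est$updated)))
  invisible(x)
}

#' @export
summary.vertical_track <- function(object, ...) {
  est <- object$estimates
  out <- list(method = object$cfg$method, n = object$n,
              duration = diff(range(est$t)),
              gain = object$gain,
              height_range = range(est$height),
              velocity_range = range(est$velocity),
              velocity_mean = mean(est$velocity),
              accept_rate = colMeans(est[, c("acc_x", "acc_y", "acc_z")]),
              gyro_bias = object$rest$gyro_bias,
              accel_bias = object$final_state$b)
  class(out) <- "summary.vertical_track"
  out
}

#' @export
print.summary.vertical_track <- function(x, ...) {
  cat(sprintf("Vertical track summary (Method %s, %d samples, %.1f s)\n",
              x$method, x$n, x$duration))
  cat(sprintf("  complementary gain: k1 = %.4g 1/s, k2 = %.4g 1/s^2, tau = %.3g s\n",
              x$gain$k1, x$gain$k2, x$gain$tau))
  cat(sprintf("  height   [m]:   %.3f .. %.3f\n",
              x$height_range[1], x$height_range[2]))
  cat(sprintf("  velocity [m/s]: %.3f .. %.3f (mean %.4f)\n",
              x$velocity_range[1], x$velocity_range[2], x$velocity_mean))
  cat(sprintf("  vector selection acceptance: x %.2f, y %.2f, z %.2f\n",
              x$accept_rate[1], x$accept_rate[2], x$accept_rate[3]))
  cat(sprintf("  final accel-bias estimate [mg]: %s\n",
              paste(format(x$accel_bias / 9.81e-3, digits = 3), collapse = " ")))
  invisible(x)
}

#' @export
coef.vertical_track <- function(object, ...) {
  out <- c(k1 = object$gain$k1, k2 = object$gain$k2, tau = object$gain$tau)
  if (!is.null(object$whitening)) {
    out <- c(out, a = object$whitening$a, b = object$whitening$b,
             g0 = object$whitening$g0)
  }
  out
}

#' @export
fitted.vertical_track <- function(object, ...) {
  object$estimates[, c("t", "height", "velocity")]
}

#' Residuals of a vertical track against a reference trajectory
#'
#' @param object `vertical_track`.
#' @param truth data.frame with columns `t`, `height`, `velocity` (e.g. a
#'   simulator truth trajectory); required.
#' @param ... unused.
#' @return data.frame with `t`, `height` and `velocity` residuals
#'   (estimate minus truth, truth linearly interpolated onto the estimate
#'   time base).
#' @export
residuals.vertical_track <- function(object, truth, ...) {
  if (missing(truth)) stop("residuals.vertical_track needs a reference trajectory ('truth')")
  est <- object$estimates
  h_ref <- stats::approx(truth$t, truth$height, xout = est$t, rule = 2)$y
  v_ref <- stats::approx(truth$t, truth$velocity, xout = est$t, rule = 2)$y
  data.frame(t = est$t, height = est$height - h_ref,
             velocity = est$velocity - v_ref)
}

#' Plot a vertical track
#'
#' Height and vertical velocity as two stacked panels, with an optional
#' reference trajectory overlaid.
#'
#' @param x `vertical_track`.
#' @param truth optional data.frame with `t`, `height`, `velocity`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vertical_track <- function(x, truth = NULL, ...) {
  est <- x$estimates
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(est$t, est$height, type = "l", xlab = "time [s]",
                 ylab = "height [m]",
                 main = sprintf("Method %s", x$cfg$method), ...)
  if (!is.null(truth)) graphics::lines(truth$t, truth$height, col = 2, lty = 2)
  graphics::plot(est$t, est$velocity, type = "l", xlab = "time [s]",
                 ylab = "vertical velocity [m/s]", ...)
  if (!is.null(truth)) graphics::lines(truth$t, truth$velocity, col = 2, lty = 2)
  invisible(x)
}
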