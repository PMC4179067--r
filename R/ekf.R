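# Quaternion-based extended Kalman filter for attitude and accelerometer
# bias. State x = (qbar, ab): unit quaternion of {b} relative to {n}
# (vector-first) and the 3-vector accelerometer bias; P is the 7x7 error
# covariance. Prediction integrates the gyro; the update levels the
# attitude from quasi-static specific-force measurements, gated per axis
# by innovation-based vector selection.

#' Accelerometer-bias transition and process covariance
#'
#' First-order Gauss-Markov bias model: transition `exp(-alpha*Ts)` per
#' axis with process covariance `Qa = I * (1 - exp(-2*alpha*Ts)) /
#' (2*alpha) * sigma_ab^2`. At `alpha = 0` the analytic random-walk limit
#' `Qa = I * Ts * sigma_ab^2` and an identity transition are used.
#'
#' @param alpha correlation rate, 1/s (>= 0).
#' @param Ts sampling interval, s.
#' @param sigma_ab driving-noise SD, m/s^3.
#' @return list with `phi` (scalar per-axis transition) and `Qa` (3x3).
#' @export
bias_transition <- function(alpha, Ts, sigma_ab) {
  if (!is.finite(alpha) || alpha < 0) stop("bias_transition: alpha must be >= 0")
  phi <- exp(-alpha * Ts)
  qa <- if (alpha > 0) {
    (1 - exp(-2 * alpha * Ts)) / (2 * alpha) * sigma_ab^2
  } else {
    Ts * sigma_ab^2
  }
  list(phi = phi, Qa = diag(3L) * qa)
}

#' EKF process-noise covariance
#'
#' Quaternion block `(I * trace(M) - M) * sigma_g^2 * (Ts/2)^2` with
#' `M = q_pred %*% t(q_pred) + Pq_pred`, padded block-diagonally with the
#' bias process covariance `Qa`. The quaternion block is the second moment
#' of the gyro noise mapped through the quaternion kinematics.
#'
#' @param q_pred propagated quaternion (expectation).
#' @param Pq_pred 4x4 propagated quaternion-block covariance.
#' @param sigma_g gyro noise SD, rad/s.
#' @param Ts sampling interval, s.
#' @param Qa 3x3 bias process covariance.
#' @return symmetric positive semidefinite 7x7 matrix.
#' @export
process_noise <- function(q_pred, Pq_pred, sigma_g, Ts, Qa) {
  M <- tcrossprod(q_pred) + Pq_pred
  Qq <- (diag(4L) * sum(diag(M)) - M) * sigma_g^2 * (Ts / 2)^2
  Q <- matrix(0, 7L, 7L)
  Q[1:4, 1:4] <- (Qq + t(Qq)) / 2
  Q[5:7, 5:7] <- Qa
  Q
}

#' Measurement Jacobian of the accelerometer-leveling model
#'
#' Jacobian of `h(x) = C^bn(q) (-g^n) + ab` with respect to the state
#' `(q, ab)`, derived analytically from the quadratic quaternion form of
#' `C^bn` (the derivation is cross-checked against a finite-difference
#' Jacobian in the test suite).
#'
#' @param q unit quaternion.
#' @param gn gravity vector in {n}, typically c(0, 0, g).
#' @return 3x7 matrix.
#' @export
measurement_jacobian <- function(q, gn) {
  # Jacobian of the quadratic rotation form C^bn = I + 2*q4*[q x] + 2*[q x]^2
  # as written (not of its unit-normalized extension): the two differ off
  # the unit sphere, and the filter linearizes the form it evaluates.
  v <- -gn
  qv <- q[1:3]; q4 <- q[4]
  Hq <- 2 * sum(qv * v) * diag(3L) + 2 * tcrossprod(qv, v) -
    4 * tcrossprod(v, qv) - 2 * q4 * skew(v)
  h4 <- 2 * c(qv[2] * v[3] - qv[3] * v[2],
              qv[3] * v[1] - qv[1] * v[3],
              qv[1] * v[2] - qv[2] * v[1])
  H <- cbind(Hq, h4, diag(3L))
  dimnames(H) <- NULL
  H
}

#' Initialize the attitude EKF
#'
#' @param rest rest-period statistics from [capture_rest()]; provides the
#'   leveled initial quaternion.
#' @param cfg [fusion_config()]; provides the initial covariance blocks.
#' @return attitude state: list with `q`, `b` (accelerometer bias) and `P`.
#' @export
ekf_init <- function(rest, cfg = fusion_config()) {
  q0 <- rest$initial_quaternion
  if (q0[4] < 0) q0 <- -q0
  list(q = q0,
       b = c(0, 0, 0),
       P = diag(c(rep(cfg$p0_quat, 4L), rep(cfg$p0_bias, 3L))))
}

#' EKF prediction step
#'
#' Propagates the quaternion with the exact discrete transition, decays the
#' bias with its Gauss-Markov transition, and propagates the covariance
#' `P <- F P F' + Q` with the process noise evaluated at the propagated
#' quaternion mean and covariance.
#'
#' @param state attitude state (list `q`, `b`, `P`).
#' @param omega bias-corrected angular rate, rad/s.
#' @param cfg [fusion_config()].
#' @return propagated attitude state.
#' @export
ekf_predict <- function(state, omega, cfg = fusion_config()) {
  Phi <- quat_propagation_matrix(omega, cfg$Ts)
  q <- quat_normalize(drop(Phi %*% state$q))
  bt <- bias_transition(cfg$alpha, cfg$Ts, cfg$sigma_ab)
  b <- bt$phi * state$b
  F7 <- matrix(0, 7L, 7L)
  F7[1:4, 1:4] <- Phi
  F7[5:7, 5:7] <- diag(3L) * bt$phi
  P <- F7 %*% state$P %*% t(F7)
  P <- P + process_noise(q, P[1:4, 1:4], cfg$sigma_g, cfg$Ts, bt$Qa)
  list(q = q, b = b, P = (P + t(P)) / 2)
}

#' EKF measurement update with vector selection
#'
#' Computes the innovation `nu = f_b - C^bn(q)(-g^n) - ab`, zeroes the rows
#' of the measurement Jacobian whose innovation component exceeds the
#' vector-selection threshold `lambda_g` in magnitude (protecting the
#' leveling update from dynamic acceleration), and applies the Kalman
#' update with `R = I * sigma_a^2` followed by brute-force quaternion
#' normalization. If every axis is rejected the predicted state is
#' returned unchanged with `updated = FALSE`.
#'
#' @param state predicted attitude state.
#' @param f_b measured specific force, m/s^2.
#' @param cfg [fusion_config()].
#' @return list with `state` (updated) and `diagnostics` (fields
#'   `innovation`, `accepted` logical per axis, `updated`).
#' @export
ekf_update <- function(state, f_b, cfg = fusion_config()) {
  gn <- c(0, 0, cfg$g)
  C <- quat_to_Cbn(state$q)
  pred <- drop(C %*% (-gn)) + state$b
  nu <- f_b - pred
  accepted <- abs(nu) <= cfg$lambda_g
  diagnostics <- list(innovation = nu, accepted = accepted, updated = any(accepted))
  if (!any(accepted)) {
    return(list(state = state, diagnostics = diagnostics))
  }
  H <- measurement_jacobian(state$q, gn)
  Ha <- H
  Ha[!accepted, ] <- 0
  P <- state$P
  S <- Ha %*% P %*% t(Ha) + diag(3L) * cfg$sigma_a^2
  K <- P %*% t(Ha) %*% solve(S)
  x <- c(state$q, state$b) + drop(K %*% nu)
  P <- (diag(7L) - K %*% Ha) %*% P
  P <- (P + t(P)) / 2
  list(state = list(q = quat_normalize(x[1:4]), b = x[5:7], P = P),
       diagnostics = diagnostics)
}
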