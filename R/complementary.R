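# Two-state complementary filter for the vertical channel: blends the
# low-frequency content of the conditioned pressure altitude with the
# high-frequency content of the integrated vertical linear acceleration.

#' Complementary-filter gain
#'
#' Fixed gain of the critically damped two-state (height, velocity)
#' filter: `k2 = sigma_w / sigma_v` (1/s^2), `k1 = 2 * sqrt(k2)` (1/s),
#' giving a closed-loop double pole at `-1/tau` with time constant
#' `tau = sqrt(sigma_v / sigma_w)`. Equivalent to the steady-state
#' two-state Kalman filter for white acceleration and altitude noises with
#' the given standard deviations.
#'
#' @param sigma_w linear-acceleration noise SD, m/s^2.
#' @param sigma_v pressure-altitude noise SD, m.
#' @return object of class `comp_gain` with `k1`, `k2`, `tau`.
#' @export
complementary_gain <- function(sigma_w, sigma_v) {
  if (!is.finite(sigma_w) || sigma_w <= 0 || !is.finite(sigma_v) || sigma_v <= 0) {
    stop("complementary_gain: noise SDs must be positive")
  }
  k2 <- sigma_w / sigma_v
  structure(list(k1 = 2 * sqrt(k2), k2 = k2, tau = 1 / sqrt(k2)),
            class = "comp_gain")
}

#' @export
print.comp_gain <- function(x, ...) {
  cat(sprintf("Complementary gain: k1 = %.5g 1/s, k2 = %.5g 1/s^2, tau = %.5g s\n",
              x$k1, x$k2, x$tau))
  invisible(x)
}

#' One step of the complementary filter
#'
#' Discrete state recursion for the state `(x, v)` (height and vertical
#' velocity, up-positive):
#' `state_k = A state_{k-1} + B1 %*% (K * Ts * dx) + B2 * dv`
#' with `A = [1 Ts; 0 1]`, `B1 = [1 Ts/2; 0 1]`, `B2 = c(Ts/2, 1)`,
#' altitude innovation `dx = x_p - x` and velocity increment
#' `dv = Ts * a_up`, both taken from the previous sample (strict one-step
#' indexing: the caller passes the previous step's inputs).
#'
#' @param state numeric length-2: height (m) and velocity (m/s).
#' @param x_p conditioned pressure altitude at the previous step, m.
#' @param a_up vertical linear acceleration at the previous step, m/s^2.
#' @param gain [complementary_gain()] object.
#' @param Ts sampling interval, s.
#' @return updated length-2 state.
#' @export
complementary_step <- function(state, x_p, a_up, gain, Ts) {
  dx <- x_p - state[1]
  dv <- Ts * a_up
  cx <- Ts * dx
  c(state[1] + Ts * state[2] + gain$k1 * cx + (Ts / 2) * gain$k2 * cx + (Ts / 2) * dv,
    state[2] + gain$k2 * cx + dv)
}
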