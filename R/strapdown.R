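# Strap-down rotation and gravity cancellation: rotate the measured
# specific force into the navigation frame and remove gravity, leaving the
# linear acceleration of the sensor origin.

#' Linear acceleration in the navigation frame
#'
#' `xddot = C^nb f^b + g^n` in NED (third component down-positive). At rest
#' with correct attitude the result is zero; in free fall (`f_b = 0`) it
#' equals gravity.
#'
#' @param f_b measured specific force in {b}, m/s^2.
#' @param q unit quaternion of {b} relative to {n}.
#' @param g gravity magnitude, m/s^2.
#' @return length-3 linear acceleration in {n} (NED).
#' @export
linear_acceleration <- function(f_b, q, g = 9.81) {
  drop(quat_to_Cnb(q) %*% f_b) + c(0, 0, g)
}

#' Up-positive vertical linear acceleration
#'
#' Convenience wrapper extracting the vertical channel of
#' [linear_acceleration()] with the up-positive sign convention used for
#' height tracking (`a_up = -` third NED component). The sign conversion is
#' done here, once, and nowhere else in the pipeline.
#'
#' @inheritParams linear_acceleration
#' @return scalar vertical acceleration, m/s^2, up-positive.
#' @export
vertical_acceleration <- function(f_b, q, g = 9.81) {
  -linear_acceleration(f_b, q, g)[3]
}
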