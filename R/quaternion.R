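# Quaternion algebra for attitude representation.
#
# Convention: unit quaternions are length-4 numeric vectors in vector-first
# layout q = c(q1, q2, q3, q4), with q[1:3] the vector part and q[4] the
# scalar part. q represents the orientation of the body frame {b} relative
# to the NED navigation frame {n}; C^bn maps n-frame vectors into {b} and
# C^nb = t(C^bn) maps b-frame vectors into {n}.

#' Skew-symmetric cross-product matrix
#'
#' Returns the 3x3 matrix `[v x]` such that `skew(v) %*% u == v x u`
#' (vector cross product).
#'
#' @param v numeric length-3 vector.
#' @return 3x3 antisymmetric matrix.
#' @examples
#' skew(c(1, 2, 3)) %*% c(0, 0, 1)  # equals c(1,2,3) x c(0,0,1)
#' @export
skew <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), nrow = 3L)
}

#' Identity quaternion
#' @return c(0, 0, 0, 1), vector-first layout.
#' @export
quat_identity <- function() c(0, 0, 0, 1)

#' Normalize a quaternion to unit norm
#' @param q length-4 numeric vector.
#' @return unit-norm quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n < .Machine$double.eps) stop("cannot normalize a zero quaternion")
  q / n
}

#' Quaternion from axis-angle rotation
#' @param axis rotation axis (need not be unit length).
#' @param angle rotation angle in radians.
#' @return unit quaternion, vector part first.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis * axis))
  c(sin(angle / 2) * a, cos(angle / 2))
}

# 4x4 rate matrix Omega(omega) pairing the quaternion kinematics
# d/dt q = 1/2 Omega(omega) q.
quat_omega_matrix <- function(omega) {
  O <- matrix(0, 4L, 4L)
  O[1:3, 1:3] <- -skew(omega)
  O[1:3, 4] <- omega
  O[4, 1:3] <- -omega
  O
}

#' Discrete quaternion propagation matrix
#'
#' Exact one-step transition matrix `Phi = expm(Ts/2 * Omega(omega))`,
#' evaluated in closed form through the rotation angle `|omega| * Ts`
#' (cosine/sinc form); `Phi` is orthogonal, so propagation preserves the
#' quaternion norm to machine precision.
#'
#' @param omega angular rate, rad/s (length 3).
#' @param Ts sampling interval, s.
#' @return 4x4 orthogonal matrix.
#' @export
quat_propagation_matrix <- function(omega, Ts) {
  w <- sqrt(sum(omega * omega))
  half <- w * Ts / 2
  # sin(half)/w with a series guard at w -> 0
  s <- if (w > 1e-12) sin(half) / w else (Ts / 2) * (1 - half * half / 6)
  cos(half) * diag(4L) + s * quat_omega_matrix(omega)
}

#' Propagate a quaternion through one sampling interval
#'
#' Applies the closed-form matrix exponential of the quaternion kinematics
#' for a constant angular rate over `Ts`.
#'
#' @param q unit quaternion (vector-first).
#' @param omega angular rate, rad/s.
#' @param Ts sampling interval, s.
#' @return unit quaternion.
#' @examples
#' quat_propagate(quat_identity(), c(pi, 0, 0), 0.5)  # pi/2 roll about x
#' @export
quat_propagate <- function(q, omega, Ts) {
  quat_normalize(drop(quat_propagation_matrix(omega, Ts) %*% q))
}

#' Rotation matrix from navigation to body frame
#'
#' `C^bn = I + 2*q4*[q x] + 2*[q x]^2`, mapping n-frame vectors into the
#' body frame for the quaternion `q` of {b} relative to {n}.
#'
#' @param q unit quaternion; an error is raised if its norm deviates from 1
#'   by more than 1e-6.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
quat_to_Cbn <- function(q) {
  if (abs(sqrt(sum(q * q)) - 1) > 1e-6) {
    stop("quat_to_Cbn: quaternion is not unit norm")
  }
  S <- skew(q[1:3])
  diag(3L) + 2 * q[4] * S + 2 * S %*% S
}

#' Rotation matrix from body to navigation frame
#'
#' `C^nb = I - 2*q4*[q x] + 2*[q x]^2 = t(C^bn)`.
#'
#' @inheritParams quat_to_Cbn
#' @return 3x3 orthonormal matrix.
#' @export
quat_to_Cnb <- function(q) {
  if (abs(sqrt(sum(q * q)) - 1) > 1e-6) {
    stop("quat_to_Cnb: quaternion is not unit norm")
  }
  S <- skew(q[1:3])
  diag(3L) - 2 * q[4] * S + 2 * S %*% S
}

#' Leveling quaternion from a quasi-static specific-force measurement
#'
#' During rest the accelerometer senses `f^b = C^bn(-g^n)`. The shortest-arc
#' (zero-yaw) quaternion whose rotation maps the n-frame "up" specific-force
#' direction (0, 0, -1) onto the measured direction is returned, so that
#' `quat_to_Cnb(q) %*% f` recovers (0, 0, -|f|). Heading is unobservable
#' from gravity alone and is fixed to zero by the shortest-arc choice.
#'
#' @param f mean specific force during rest, m/s^2 (length 3).
#' @return unit quaternion with non-negative scalar part.
#' @export
leveling_quaternion <- function(f) {
  nf <- sqrt(sum(f * f))
  if (nf < .Machine$double.eps) stop("leveling_quaternion: zero specific force")
  fhat <- f / nf
  u <- c(0, 0, -1)
  w <- 1 + sum(u * fhat)
  if (w < 1e-12) {
    # upside down: 180 degree rotation, axis choice free; pick body x
    return(c(1, 0, 0, 0))
  }
  v <- c(u[2] * fhat[3] - u[3] * fhat[2],
         u[3] * fhat[1] - u[1] * fhat[3],
         u[1] * fhat[2] - u[2] * fhat[1])
  quat_normalize(c(v, w))
}
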