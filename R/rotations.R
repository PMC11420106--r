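# Rotation helpers shared by the simulator, the frame-correction step and
# the heading computation.
#
# Conventions used throughout the package:
#   * body frame: x forward (the animal's heading axis), y right, z down;
#   * world frame: North-East-Down (NED);
#   * heading (yaw) is clockwise-positive from magnetic north, pitch is
#     nose-up positive, roll is right-side-down positive;
#   * the body-to-world rotation is Rz(yaw) %*% Ry(pitch) %*% Rx(roll);
#   * at rest the accelerometer reads the specific force (0, 0, -1) g
#     when level.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE)
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE)
}

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# Body-to-world (NED) rotation from yaw/pitch/roll in degrees.
body_to_world <- function(heading_deg, pitch_deg = 0, roll_deg = 0) {
  rot_z(deg2rad(heading_deg)) %*% rot_y(deg2rad(pitch_deg)) %*%
    rot_x(deg2rad(roll_deg))
}

# Uniformly random rotation matrices via unit quaternions.
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4L * n), ncol = 4L)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) {
    w <- q[i, 1]; x <- q[i, 2]; y <- q[i, 3]; z <- q[i, 4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}

#' Wrap angles to [0, 360)
#'
#' @param deg Numeric vector of angles in degrees.
#' @return Angles wrapped into `[0, 360)`.
#' @export
wrap360 <- function(deg) {
  deg %% 360
}

#' Wrap angles to (-180, 180]
#'
#' @param deg Numeric vector of angles in degrees.
#' @return Angles wrapped into `(-180, 180]`.
#' @export
wrap180 <- function(deg) {
  out <- ((deg + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}
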