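#' Quaternion from axis and angle
#'
#' Unit quaternion representing a right-handed rotation of `angle` radians
#' about `axis`. Quaternions are length-4 numerics `(w, x, y, z)` of class
#' `quat`, kept at unit norm after every operation.
#'
#' @param axis non-zero length-3 numeric.
#' @param angle rotation angle in radians.
#' @return A `quat`.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- as.numeric(axis)
  n <- vnorm(axis)
  if (n == 0) stopf("rotation axis must be non-zero")
  a <- axis / n
  h <- angle / 2
  structure(c(cos(h), sin(h) * a), class = "quat")
}

quat_identity <- function() structure(c(1, 0, 0, 0), class = "quat")

#' Quaternion product
#'
#' Hamilton product `a %q% b`; the composed rotation applies `b` first,
#' then `a`.
#'
#' @param a,b quaternions.
#' @return The product quaternion, re-normalized.
#' @export
`%q%` <- function(a, b) {
  w <- a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4]
  x <- a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3]
  y <- a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2]
  z <- a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  q <- c(w, x, y, z)
  structure(q / vnorm(q), class = "quat")
}

quat_conj <- function(q) structure(c(q[1], -q[2], -q[3], -q[4]), class = "quat")

#' Rotate vectors by a quaternion
#'
#' @param q unit quaternion.
#' @param v length-3 vector or n x 3 matrix of row vectors.
#' @return Rotated vector(s), same shape as `v`.
#' @export
quat_rotate <- function(q, v) {
  R <- quat_to_matrix(q)
  if (is.matrix(v)) v %*% t(R) else as.numeric(R %*% v)
}

#' Rotation matrix of a quaternion
#'
#' @param q unit quaternion.
#' @return 3x3 orthonormal rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)),
         nrow = 3L, byrow = TRUE)
}

# Camera conventions: at identity orientation the camera sits on +z looking
# toward -z (at the focus), with up = +y and right = +x. The azimuth phi
# rotates about world-up (+y); the elevation theta rotates about the negative
# camera-right axis, so positive theta lifts the eye toward +y.
CAM_VIEW_AXIS <- c(0, 0, 1)
CAM_UP_AXIS <- c(0, 1, 0)
CAM_RIGHT_AXIS <- c(1, 0, 0)

#' Create a camera pose from spherical coordinates
#'
#' The camera orbits a focus point `center` at distance `r`, its pose held as
#' a rotation quaternion built from the azimuth `phi` (about world-up) and
#' elevation `theta` (about the camera-right axis). The eye position is
#' `center + r * (orientation applied to +z)`.
#'
#' @param center length-3 focus point (mm).
#' @param r positive camera distance (mm).
#' @param theta elevation angle, radians.
#' @param phi azimuth angle, radians.
#' @return An object of class `camera_pose`.
#' @export
make_camera <- function(center = c(0, 0, 0), r = 100, theta = 0, phi = 0) {
  if (!is_scalar_num(r) || r <= 0) stopf("camera radius must be positive")
  q <- quat_from_axis_angle(CAM_UP_AXIS, phi) %q%
    quat_from_axis_angle(-CAM_RIGHT_AXIS, theta)
  structure(list(center = as.numeric(center), r = as.numeric(r),
                 orientation = q),
            class = "camera_pose")
}

#' @export
print.camera_pose <- function(x, ...) {
  e <- camera_eye(x)
  cat(sprintf("<camera_pose> center (%.3g, %.3g, %.3g), r = %.4g, eye (%.3g, %.3g, %.3g)\n",
              x$center[1], x$center[2], x$center[3], x$r, e[1], e[2], e[3]))
  invisible(x)
}

#' Eye position of a camera pose
#'
#' @param c a `camera_pose`.
#' @return Length-3 world position of the camera.
#' @export
camera_eye <- function(c) {
  c$center + c$r * quat_rotate(c$orientation, CAM_VIEW_AXIS)
}

#' Orbit the camera around its focus point
#'
#' Increments elevation by `d_theta` (about the current camera-right axis)
#' and azimuth by `d_phi` (about world-up); focus and radius are unchanged
#' and the orientation is re-normalized.
#'
#' @param c a `camera_pose`.
#' @param d_theta,d_phi angle increments in radians.
#' @return Updated `camera_pose`.
#' @export
orbit <- function(c, d_theta = 0, d_phi = 0) {
  c$orientation <- quat_from_axis_angle(CAM_UP_AXIS, d_phi) %q%
    c$orientation %q% quat_from_axis_angle(-CAM_RIGHT_AXIS, d_theta)
  c
}

#' Roll the camera about its view axis
#'
#' @param c a `camera_pose`.
#' @param angle roll angle in radians.
#' @return Updated `camera_pose`.
#' @export
roll <- function(c, angle) {
  c$orientation <- c$orientation %q% quat_from_axis_angle(CAM_VIEW_AXIS, angle)
  c
}

#' Zoom the camera
#'
#' Divides the orbit radius by `factor` (factor > 1 magnifies, as a pinch-out
#' gesture would); the result is clamped to [1e-3, 1e6] mm.
#'
#' @param c a `camera_pose`.
#' @param factor positive zoom factor.
#' @return Updated `camera_pose`.
#' @export
zoom <- function(c, factor) {
  if (!is_scalar_num(factor) || factor <= 0)
    stopf("zoom factor must be positive")
  c$r <- clamp(c$r / factor, 1e-3, 1e6)
  c
}

#' Pan the camera focus in screen space
#'
#' Translates the focus point by `dx` along the camera-right direction and
#' `dy` along camera-up, both in mm; radius and orientation are unchanged.
#'
#' @param c a `camera_pose`.
#' @param dx,dy screen-space offsets in mm.
#' @return Updated `camera_pose`.
#' @export
pan <- function(c, dx = 0, dy = 0) {
  right <- quat_rotate(c$orientation, CAM_RIGHT_AXIS)
  up <- quat_rotate(c$orientation, CAM_UP_AXIS)
  c$center <- c$center + dx * right + dy * up
  c
}

#' View (look-at) matrix of a camera pose
#'
#' 4x4 world-to-camera transform: the eye maps to the origin and the focus
#' point to `(0, 0, -r)` (the camera looks along -z in its own frame). The
#' rotation block is orthonormal with determinant +1.
#'
#' @param c a `camera_pose`.
#' @return 4x4 numeric matrix.
#' @export
view_matrix <- function(c) {
  R <- quat_to_matrix(c$orientation)
  right <- R %*% CAM_RIGHT_AXIS
  up <- R %*% CAM_UP_AXIS
  back <- R %*% CAM_VIEW_AXIS   # from focus toward the eye
  eye <- camera_eye(c)
  Rv <- rbind(t(right), t(up), t(back))
  m <- diag(4)
  m[1:3, 1:3] <- Rv
  m[1:3, 4] <- -Rv %*% eye
  m
}
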