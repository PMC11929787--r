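# Unit-quaternion pose on the sphere.  The pose quaternion q maps body
# axes to earth axes (Hamilton convention, active rotation):
#   body z = local up (radial), body x = heading direction,
#   body y = z cross x (points 90 degrees counter-clockwise of heading,
#   i.e. to the animal's left... concretely p x d).
# Earth frame: Z = north pole, X = (0N, 0E), Y = (0N, 90E).
# Yaw (heading change) is a rotation about body z (the k axis of the
# quaternion); forward great-circle travel is a rotation about body y
# (the j axis).  Right-multiplication composes rotations in the body
# frame, so each step is q <- q * q_yaw * q_forward.

quat <- function(w, x, y, z) c(w, x, y, z)

quat_mul <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_normalise <- function(q) q / sqrt(sum(q * q))

# Rotation matrix (body -> earth) from a unit quaternion.
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Unit quaternion from a rotation matrix (Shepperd's method).
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalise(q)
}

# Unit radial vector for (lat, lon) in degrees.
geo_to_vec <- function(lat, lon) {
  la <- deg2rad(lat); lo <- deg2rad(lon)
  c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

#' Pose quaternion from latitude, longitude and heading
#'
#' @param latitude,longitude degrees.
#' @param heading degrees clockwise from true north.
#' @return a unit quaternion (numeric length 4, `c(w, x, y, z)`).
#' @export
pose_from_geo <- function(latitude, longitude, heading) {
  p <- geo_to_vec(latitude, longitude)
  pole <- c(0, 0, 1)
  north <- pole - sum(pole * p) * p
  nn <- sqrt(sum(north * north))
  if (nn < 1e-12) stop("pose undefined at the poles")
  north <- north / nn
  east <- c(pole[2] * p[3] - pole[3] * p[2],
            pole[3] * p[1] - pole[1] * p[3],
            pole[1] * p[2] - pole[2] * p[1])
  east <- east / sqrt(sum(east * east))
  h <- deg2rad(heading)
  d <- cos(h) * north + sin(h) * east
  ybody <- c(p[2] * d[3] - p[3] * d[2],
             p[3] * d[1] - p[1] * d[3],
             p[1] * d[2] - p[2] * d[1])
  R <- cbind(d, ybody, p)  # columns: body x, y, z in earth frame
  matrix_to_quat(R)
}

#' Latitude, longitude and heading from a pose quaternion
#'
#' @param q unit quaternion from [pose_from_geo()] or [step_spherical()].
#' @return list with `latitude`, `longitude` (degrees) and `heading`
#'   (degrees clockwise from north).
#' @export
geo_from_pose <- function(q) {
  R <- quat_to_matrix(q)
  p <- R[, 3]   # body z: radial position
  d <- R[, 1]   # body x: heading direction
  lat <- rad2deg(asin(pmin(1, pmax(-1, p[3]))))
  lon <- rad2deg(atan2(p[2], p[1]))
  pole <- c(0, 0, 1)
  north <- pole - sum(pole * p) * p
  north <- north / sqrt(sum(north * north))
  east <- c(pole[2] * p[3] - pole[3] * p[2],
            pole[3] * p[1] - pole[1] * p[3],
            pole[1] * p[2] - pole[2] * p[1])
  east <- east / sqrt(sum(east * east))
  heading <- wrap360(rad2deg(atan2(sum(d * east), sum(d * north))))
  list(latitude = lat, longitude = wrap180(lon), heading = heading)
}

#' One kinematic step on the sphere
#'
#' Heading is updated before moving: a yaw by `dtheta` about the local
#' vertical (clockwise positive, matching the planar convention), then a
#' great-circle advance of `v * dt` metres (an angle `v dt / R` about the
#' body pitch axis).  The quaternion is renormalised after every step.
#'
#' @param q unit pose quaternion.
#' @param dtheta turn (radians, clockwise positive).
#' @param v speed (m/s).
#' @param dt step duration (s).
#' @param R sphere radius (m).
#' @return the updated unit quaternion.
#' @export
step_spherical <- function(q, dtheta, v, dt, R = EARTH_RADIUS) {
  if (dtheta != 0) {
    q <- quat_mul(q, quat(cos(dtheta / 2), 0, 0, -sin(dtheta / 2)))
  }
  xi <- v * dt / R
  if (xi != 0) {
    q <- quat_mul(q, quat(cos(xi / 2), 0, sin(xi / 2), 0))
  }
  quat_normalise(q)
}
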