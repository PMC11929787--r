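# Embodied kinematics and geometry: great-circle distance and bearing,
# random foraging-route generation, and search-pattern (turning point)
# detection.

#' Great-circle (haversine) distance
#'
#' `rho = 2 R atan2(sqrt(h), sqrt(1 - h))` with
#' `h = sin^2(dphi/2) + cos(phi_s) cos(phi_e) sin^2(dlambda/2)` and
#' `R = 6 378 137` m.
#'
#' @param start,end [geo_point()]s.
#' @param R sphere radius in metres.
#' @return distance in metres.
#' @export
haversine_distance <- function(start, end, R = EARTH_RADIUS) {
  stopifnot(inherits(start, "geo_point"), inherits(end, "geo_point"))
  p1 <- deg2rad(start$latitude); p2 <- deg2rad(end$latitude)
  dphi <- p2 - p1
  dlam <- deg2rad(end$longitude - start$longitude)
  h <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * R * atan2(sqrt(h), sqrt(1 - h))
}

#' Initial great-circle bearing
#'
#' Forward azimuth of the great circle from `start` to `end`,
#' `atan2(sin(dlambda) cos(phi_e),
#'        cos(phi_s) sin(phi_e) - sin(phi_s) cos(phi_e) cos(dlambda))`,
#' normalised to `[0, 360)` degrees clockwise from north.
#'
#' @param start,end [geo_point()]s (distinct, not antipodal).
#' @return bearing in degrees.
#' @export
initial_bearing <- function(start, end) {
  stopifnot(inherits(start, "geo_point"), inherits(end, "geo_point"))
  if (identical(start[c("latitude", "longitude")],
                end[c("latitude", "longitude")]))
    stop("bearing undefined for coincident points")
  p1 <- deg2rad(start$latitude); p2 <- deg2rad(end$latitude)
  dlam <- deg2rad(end$longitude - start$longitude)
  wrap360(rad2deg(atan2(sin(dlam) * cos(p2),
                        cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam))))
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; mean `mu` (radians), concentration
#' `kappa`.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (`> 0`).
#' @return numeric vector of angles (radians, in `(-pi, pi]` around `mu`).
#' @export
rvonmises <- function(n, mu = 0, kappa = 100) {
  stopifnot(kappa > 0)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  out
}

#' Generate a random foraging route
#'
#' A correlated random walk built from von Mises turn increments
#' (`mu = 0, kappa = 100`), low-pass filtered (first-order exponential
#' smoothing), integrated into positions, then affinely rescaled/rotated so
#' the route runs from the nest (`0`) exactly to `endpoint`, and finally
#' resampled at equal `resample_step` metre spacing by linear
#' interpolation.  Headings are recomputed from finite differences of the
#' resampled positions.
#'
#' @param n_samples raw number of turn draws (default 25 000).
#' @param kappa von Mises concentration.
#' @param endpoint complex metres (real = north, imaginary = east);
#'   default 100 m east.
#' @param resample_step spacing of the resampled positions in metres
#'   (0.5 m: one step per second at 0.5 m/s).
#' @param smoothing exponential smoothing factor for the turn sequence.
#' @return data frame with complex `position` and `heading` (degrees).
#' @export
generate_foraging_route <- function(n_samples = 25000, kappa = 100,
                                    endpoint = 0 + 100i,
                                    resample_step = 0.5, smoothing = 0.1) {
  stopifnot(Mod(endpoint) > 0)
  for (attempt in 1:10) {
    turns <- rvonmises(n_samples, 0, kappa)
    sm <- as.numeric(stats::filter(smoothing * turns, 1 - smoothing,
                                   method = "recursive", init = 0))
    theta <- cumsum(sm)
    pos <- cumsum(exp(1i * theta))
    span <- pos[n_samples] - 0  # route starts at the origin
    if (Mod(span) > 1e-9) break
  }
  if (Mod(span) <= 1e-9) stop("degenerate raw route")
  pos <- c(0 + 0i, pos) * (endpoint / span)
  # arc-length resampling
  seg <- Mod(diff(pos))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, by = resample_step)
  re <- stats::approx(cum, Re(pos), xout = s, ties = "ordered")$y
  im <- stats::approx(cum, Im(pos), xout = s, ties = "ordered")$y
  rp <- complex(real = re, imaginary = im)
  # force the exact endpoint as final sample
  if (Mod(rp[length(rp)] - endpoint) > 1e-12) rp <- c(rp, endpoint)
  dz <- diff(rp)
  heading <- wrap360(rad2deg(Arg(dz)))
  data.frame(position = rp, heading = c(heading, heading[length(heading)]))
}

#' Detect turning points along a trajectory
#'
#' A turning point is a sample whose heading differs by more than
#' `angle_threshold` from the heading `lookback` metres earlier along the
#' path, provided no other turning point was detected within the last
#' `refractory` metres of path.  Windows use path (arc) distance, not
#' straight-line displacement.
#'
#' @param position complex positions (metres).
#' @param heading headings in degrees, same length.
#' @param lookback path distance (m) over which the heading change is
#'   measured (25 m).
#' @param angle_threshold minimum absolute heading change (degrees, 120).
#' @param refractory minimum path distance between detections (m, 50).
#' @return integer indices of the turning points (possibly empty).
#' @export
detect_turning_points <- function(position, heading, lookback = 25,
                                  angle_threshold = 120, refractory = 50) {
  n <- length(position)
  if (n < 2) return(integer(0))
  cum <- c(0, cumsum(Mod(diff(position))))
  if (cum[n] < lookback) return(integer(0))
  out <- integer(0)
  last_tp <- -Inf
  j <- 1L
  for (i in seq_len(n)) {
    if (cum[i] < lookback) next
    while (cum[j + 1] <= cum[i] - lookback) j <- j + 1L
    if (abs(angle_diff(heading[i], heading[j])) > angle_threshold &&
        cum[i] - last_tp > refractory) {
      out <- c(out, i)
      last_tp <- cum[i]
    }
  }
  out
}

#' Centroid of the last four turning points
#'
#' @param turns complex positions of exactly four turning points.
#' @return complex centroid.
#' @export
search_centroid <- function(turns) {
  if (length(turns) != 4) stop("need exactly four turning points")
  mean(turns)
}
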