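# Angle helpers. All public angles are degrees; internal trig uses radians.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalise angles to a standard range
#'
#' `wrap360()` maps degrees to `[0, 360)`; `wrap180()` maps to `[-180, 180)`.
#' `angle_diff()` returns the signed circular difference `a - b` in
#' `[-180, 180)` degrees.
#'
#' @param x,a,b angles in degrees.
#' @return numeric vector of degrees.
#' @export
wrap360 <- function(x) x %% 360

#' @rdname wrap360
#' @export
wrap180 <- function(x) ((x + 180) %% 360) - 180

#' @rdname wrap360
#' @export
angle_diff <- function(a, b) wrap180(a - b)

# Compass convention: angles clockwise from true north.  On the complex
# plane the real axis is north and the imaginary axis is east, so a heading
# of psi degrees maps to exp(1i * psi * pi/180).
heading_to_complex <- function(psi_deg) exp(1i * deg2rad(psi_deg))
complex_to_heading <- function(z) wrap360(rad2deg(Arg(z)))
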