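# The trigonometric compass circuit: MeTu2 neurons encode the sun's
# bearing relative to the animal's heading as spatial sinusoids, TuBu1
# neurons gate them multiplicatively with the clock prediction, and ER4m
# ring neurons sum the two streams, implementing
#   sin(a) sin(a' - phi) + cos(a) cos(a' - phi) = cos(a - a' + phi)
# so that the ring encodes the difference between predicted and observed
# solar azimuth: a geocentric heading signal.

#' Preferred angles of a ring population
#'
#' `phi_n = n * (360 / n_neurons)` degrees for `n = 1..n_neurons`
#' (16 neurons at 22.5 degree spacing by default).
#'
#' @param n_neurons population size.
#' @return preferred angles in degrees.
#' @export
preferred_angles <- function(n_neurons = 16) {
  seq_len(n_neurons) * (360 / n_neurons)
}

#' MeTu2 encoding of the retinotopic solar azimuth
#'
#' Two medulla-tubercle populations carry the sine and cosine of the sun
#' bearing relative to the animal's heading, sampled at the ring's
#' preferred angles:
#' `MeTu2a_n = sin(a_sun - heading - phi_n)`,
#' `MeTu2b_n = cos(a_sun - heading - phi_n)`.
#' With `noise_mode = "per_neuron"`, independent `U(-eta, eta)` noise is
#' added to each of the 2 * n responses; with `"angular"`, a single shared
#' draw perturbs the angle argument itself (all neurons see the same
#' angular error).
#'
#' @param sun_azimuth observed solar azimuth (degrees CW from north).
#' @param heading animal heading (degrees CW from north).
#' @param eta_sun noise fraction in `[0, 1]`.
#' @param noise_mode `"per_neuron"` or `"angular"`.
#' @param phi preferred angles (degrees), default 16-neuron ring.
#' @return list with numeric vectors `a` and `b`.
#' @export
metu2_encode <- function(sun_azimuth, heading, eta_sun = 0,
                         noise_mode = c("per_neuron", "angular"),
                         phi = preferred_angles()) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(eta_sun >= 0, eta_sun <= 1)
  arg <- deg2rad(sun_azimuth - heading - phi)
  if (eta_sun > 0 && noise_mode == "angular") {
    arg <- arg + stats::runif(1, -eta_sun, eta_sun)
  }
  a <- sin(arg)
  b <- cos(arg)
  if (eta_sun > 0 && noise_mode == "per_neuron") {
    n <- length(phi)
    a <- a + stats::runif(n, -eta_sun, eta_sun)
    b <- b + stats::runif(n, -eta_sun, eta_sun)
  }
  list(a = a, b = b)
}

#' TuBu1 gating of the sun encoding by the clock signal
#'
#' The clock prediction scales the spatial sinusoids multiplicatively:
#' `TuBu1a_n = -DN1pB_E * MeTu2a_n`, `TuBu1b_n = -DN1pB_N * MeTu2b_n`.
#'
#' @param metu2 output of [metu2_encode()].
#' @param dn1pb named vector `c(E = , N = )`: hour-angle components
#'   ([hour_angle_components()]) or complete-model azimuth components
#'   ([predict_azimuth_complete()]).
#' @return list with numeric vectors `a` and `b`.
#' @export
tubu1_combine <- function(metu2, dn1pb) {
  stopifnot(length(metu2$a) == length(metu2$b))
  list(a = -dn1pb[["E"]] * metu2$a,
       b = -dn1pb[["N"]] * metu2$b)
}

#' ER4m ring-neuron integration
#'
#' Columnwise sum of the two TuBu1 streams:
#' `ER4m_n = TuBu1a_n + TuBu1b_n`.  Noiselessly, with
#' `DN1pB = (-sin(a), -cos(a))`, this equals `cos(a - a' + phi_n)` where
#' `a' = a_sun - heading`.
#'
#' @param tubu1 output of [tubu1_combine()].
#' @return numeric vector of ring responses.
#' @export
er4m_integrate <- function(tubu1) {
  tubu1$a + tubu1$b
}

#' ER4m without time compensation
#'
#' The uncompensated pathway passes the cosine population straight through:
#' `ER4m_n = MeTu2b_n`.  The decoded angle then tracks the sun-relative
#' bearing, not a geocentric one.
#'
#' @param metu2 output of [metu2_encode()].
#' @return numeric vector of ring responses.
#' @export
er4m_no_compensation <- function(metu2) {
  metu2$b
}

#' Population-vector readout of a ring
#'
#' `z = (1/N) sum_n r_n exp(i phi_n) + eps`, with one complex noise draw
#' (real and imaginary parts `U(-eta, eta)`) per decode.  For a noiseless
#' cosine bump `r_n = cos(psi + phi_n)` the readout is `0.5 exp(-i psi)`.
#'
#' @param r ring responses.
#' @param eta noise fraction in `[0, 1]`.
#' @param phi preferred angles (degrees) matching `r`.
#' @return a complex scalar.
#' @export
decode_population <- function(r, eta = 0, phi = preferred_angles(length(r))) {
  stopifnot(length(r) == length(phi))
  z <- mean(r * exp(1i * deg2rad(phi)))
  if (eta > 0) {
    z <- z + complex(real = stats::runif(1, -eta, eta),
                     imaginary = stats::runif(1, -eta, eta))
  }
  z
}

#' Heading estimate of the EPG compass from the ring readout
#'
#' The raw population vector for a bump `cos(psi + phi_n)` is
#' `0.5 exp(-i psi)` with `psi = omega - (a_sun - heading)`; a perfect
#' clock therefore leaves `-conj(z)` pointing along `exp(i heading)`
#' (the residual half-turn between the hour angle and the azimuth is
#' absorbed by the sign).  This readout convention is a fixed constant of
#' the decode; by the ring's offset invariance it does not affect any
#' relative (steering) computation.  The result is normalised to the unit
#' circle (EPG keeps direction only), with fresh complex noise before the
#' normalisation.
#'
#' @param z_er4m complex output of [decode_population()].
#' @param eta noise fraction in `[0, 1]`.
#' @param prev previous unit heading estimate, returned if the vector is
#'   degenerate (zero magnitude).
#' @return a unit-magnitude complex heading estimate.
#' @export
epg_from_er4m <- function(z_er4m, eta = 0, prev = NULL) {
  epg_normalise(-Conj(z_er4m), eta = eta, prev = prev)
}
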