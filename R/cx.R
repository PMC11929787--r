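# The simplified central complex: every processing layer reduced to a
# complex vector.  EPG holds the unit heading estimate, PFN the velocity,
# a leaky-free integrator the vector memory, FC2 the normalised goal
# direction, and a left/right PFL3 pair the steering readout.

#' Central-complex state
#'
#' @param z_G goal vector (complex, metres / `tau_M`; default 0 = home).
#' @param tau_M memory charge constant in metres (40 km).  Memory and goal
#'   are stored in units of metres / `tau_M` so they stay commensurate.
#' @param eta default noise fraction for the CX noise injection points.
#' @return an object of class `cx_state` with fields `z_EPG` (unit complex
#'   heading), `z_M` (memory, starts at 0), `z_G`, `z_FC2` (last valid goal
#'   direction), `tau_M`, `eta`.
#' @export
cx_state <- function(z_G = 0 + 0i, tau_M = 40000, eta = 0.2) {
  structure(list(z_EPG = 1 + 0i, z_M = 0 + 0i, z_G = z_G,
                 z_FC2 = 1 + 0i, tau_M = tau_M, eta = eta),
            class = "cx_state")
}

#' Normalise a compass vector to the unit circle
#'
#' `z_EPG = (z + eps) / |z + eps|`, keeping direction only.  A degenerate
#' (zero-magnitude) vector returns `prev` (or flags with `NA` when no
#' previous estimate is supplied).
#'
#' @param z complex input.
#' @param eta noise fraction; complex noise with `U(-eta, eta)` parts.
#' @param prev fallback unit vector for the degenerate case.
#' @return a unit complex number (or `NA` if degenerate with no fallback).
#' @export
epg_normalise <- function(z, eta = 0, prev = NULL) {
  if (eta > 0) {
    z <- z + complex(real = stats::runif(1, -eta, eta),
                     imaginary = stats::runif(1, -eta, eta))
  }
  m <- Mod(z)
  if (m == 0) {
    if (is.null(prev)) return(NA_complex_)
    return(prev)
  }
  z / m
}

#' Integrate velocity into the vector memory
#'
#' `z_PFN = z_EPG * v`; `tau_M dz_M/dt = z_PFN`, explicit Euler:
#' `z_M <- z_M + z_EPG * v * dt / tau_M`.  After a straight run of length
#' `L` at heading `psi`, `|z_M| = L / tau_M` and `Arg(z_M) = psi`.
#'
#' @param state a [cx_state()].
#' @param v ground speed (m/s), `>= 0`.
#' @param dt step duration (s).
#' @return the updated state.
#' @export
integrate_memory <- function(state, v, dt) {
  stopifnot(v >= 0, dt > 0)
  state$z_M <- state$z_M + state$z_EPG * v * dt / state$tau_M
  state
}

#' Allocentric goal direction
#'
#' `z_FC2 = (z_G - z_M) / |z_G - z_M|`: direction only, no distance.  At
#' the goal (`z_G = z_M`) the direction is undefined; the last valid
#' direction is held, and the noisy steering loop then produces the
#' characteristic search pattern.
#'
#' @param state a [cx_state()].
#' @return list with `z_FC2` (unit complex) and `at_goal` (logical).
#' @export
goal_direction <- function(state) {
  d <- state$z_G - state$z_M
  m <- Mod(d)
  if (m == 0) {
    return(list(z_FC2 = state$z_FC2, at_goal = TRUE))
  }
  list(z_FC2 = d / m, at_goal = FALSE)
}

#' Left/right steering readout
#'
#' The goal direction is compared against the heading estimate projected
#' onto two axes rotated 45 degrees to either side:
#' `z_PFL3,L = z_FC2 - z_EPG cos(-45) exp(-i 45) + eps`,
#' `z_PFL3,R = z_FC2 - z_EPG cos(45) exp(+i 45) + eps`,
#' `dtheta/dt = (|z_PFL3,L| - |z_PFL3,R|) / 4`.
#' Noiselessly the readout is antisymmetric in the goal-heading error and
#' zero when `z_FC2 = z_EPG`.  Positive values are clockwise turns
#' (heading update `theta <- theta + dtheta`).
#'
#' @param z_EPG unit heading estimate.
#' @param z_FC2 unit goal direction.
#' @param eta noise fraction; independent complex draws per branch.
#' @return turn rate in radians per step.
#' @export
steering <- function(z_EPG, z_FC2, eta = 0) {
  rot <- cos(pi / 4) * exp(-1i * pi / 4)
  zl <- z_FC2 - z_EPG * rot
  zr <- z_FC2 - z_EPG * Conj(rot)
  if (eta > 0) {
    zl <- zl + complex(real = stats::runif(1, -eta, eta),
                       imaginary = stats::runif(1, -eta, eta))
    zr <- zr + complex(real = stats::runif(1, -eta, eta),
                       imaginary = stats::runif(1, -eta, eta))
  }
  (Mod(zl) - Mod(zr)) / 4
}
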