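# Performance metrics shared by the behavioural experiments.

#' Desert-ant homing-error reference curve
#'
#' Quadratic fit to measured desert-ant search-to-nest distances as a
#' function of foraging distance: `y = 2e-5 x^2 + 0.083 x + 1.96` metres.
#' Used as a behavioural benchmark for the simulated homing errors.
#'
#' @param x foraging distance in metres.
#' @return expected homing error in metres.
#' @export
ant_reference <- function(x) {
  2e-5 * x^2 + 0.083 * x + 1.96
}

#' Trajectory metrics
#'
#' Tortuosity `C(t) / L(t)` (cumulative path length over straight-line
#' distance from the goal; undefined where `L = 0`), and the Euclidean
#' goal error `|z - z_goal|`.
#'
#' @param position complex trajectory (metres; real = north,
#'   imaginary = east).
#' @param goal complex goal position.
#' @return list with vectors `path_length`, `goal_distance`, `tortuosity`
#'   (NA where the goal distance is zero) and scalars `eps_z_final`,
#'   `eps_z_min`.
#' @export
compute_metrics <- function(position, goal) {
  stopifnot(length(position) >= 1)
  C <- c(0, cumsum(Mod(diff(position))))
  L <- Mod(position - goal)
  tort <- ifelse(L == 0, NA_real_, C / L)
  list(path_length = C, goal_distance = L, tortuosity = tort,
       eps_z_final = L[length(L)], eps_z_min = min(L))
}

#' Day-length estimation error
#'
#' `|T_L - T_L*|` elementwise.
#'
#' @param T_L_est,T_L_true estimated and actual day length (hours).
#' @return absolute errors (hours).
#' @export
day_length_error <- function(T_L_est, T_L_true) {
  abs(T_L_est - T_L_true)
}
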