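# The insect's internal spatiotemporal state: day-length estimation from
# skylight irradiance, the hour-angle clock (CW / CCW / equatorial
# variants), annual declination and latitude encoders, and the complete
# solar-azimuth predictor.

#' Day-length estimator state
#'
#' First-order leaky integrator driven by the light-scaled Cry1 signal:
#' `tau_L dT_L/dt = a I_sky + beta - T_L`, integrated by explicit Euler
#' with a one-hour step.  `T_L` starts at 7 h.
#'
#' @param tau_L time constant (hours).
#' @param gain_a scaling from irradiance to Cry1 (arb. units per W m-2 sr-1,
#'   absorbed into the fit).
#' @param beta constant input (hours).
#' @param T_L0 initial estimate (hours), default 7.
#' @param dt Euler step (hours), default 1.
#' @return an object of class `day_length_estimator`.
#' @export
day_length_estimator <- function(tau_L, gain_a, beta, T_L0 = 7, dt = 1) {
  stopifnot(tau_L > 0, dt > 0)
  structure(list(tau_L = tau_L, gain_a = gain_a, beta = beta,
                 T_L = T_L0, dt = dt),
            class = "day_length_estimator")
}

#' One Euler step of the day-length estimator
#'
#' @param est a [day_length_estimator()].
#' @param irradiance skylight irradiance sample (W m-2 sr-1).
#' @return the updated estimator (pure function; input unchanged).
#' @export
update_day_length <- function(est, irradiance) {
  stopifnot(inherits(est, "day_length_estimator"), is.finite(irradiance))
  est$T_L <- est$T_L +
    est$dt / est$tau_L * (est$gain_a * irradiance + est$beta - est$T_L)
  est
}

#' Simulate the day-length estimate over an irradiance series
#'
#' Vectorised equivalent of repeated [update_day_length()] calls (a linear
#' recursion, evaluated with `stats::filter`).
#'
#' @param irradiance hourly irradiance series.
#' @param tau_L,gain_a,beta estimator parameters.
#' @param T_L0 initial estimate (hours).
#' @return numeric vector of `T_L` after each sample.
#' @export
simulate_day_length <- function(irradiance, tau_L, gain_a, beta, T_L0 = 7) {
  stopifnot(tau_L > 0, all(is.finite(irradiance)))
  drive <- (gain_a * irradiance + beta) / tau_L
  rho <- 1 - 1 / tau_L
  as.numeric(stats::filter(drive, rho, method = "recursive",
                           init = T_L0))
}

#' Fit the day-length estimator to a year of data
#'
#' Nonlinear least squares of the Euler-simulated `T_L` trajectory against
#' the true day length, over `(tau_L, a, beta)`.  Deterministic given the
#' fixed initial guess (100 h, 10, 7 h); parameters are kept positive by
#' optimising on the log scale.
#'
#' @param irradiance hourly irradiance over at least one year.
#' @param day_length_true hourly series of the true day length (hours),
#'   aligned with `irradiance`.
#' @param start initial guess, `c(tau_L, gain_a, beta)`.
#' @param T_L0 initial estimate used in every simulated trajectory.
#' @return list with `tau_L`, `gain_a`, `beta`, `rss` (residual sum of
#'   squares) and `convergence` (0 = converged, from `optim`).
#' @export
fit_day_length_params <- function(irradiance, day_length_true,
                                  start = c(100, 10, 7), T_L0 = 7) {
  stopifnot(length(irradiance) == length(day_length_true),
            length(irradiance) >= 24 * 30)
  sse <- function(logp) {
    p <- exp(logp)
    sim <- simulate_day_length(irradiance, p[1], p[2], p[3], T_L0)
    sum((sim - day_length_true)^2)
  }
  fit <- stats::optim(log(start), sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$convergence != 0)
    warning("day-length fit did not converge: code ", fit$convergence)
  p <- exp(fit$par)
  list(tau_L = p[1], gain_a = p[2], beta = p[3],
       rss = fit$value, convergence = fit$convergence)
}

#' Hour angle from zeitgeber time and day length
#'
#' `omega = (t_z - T_L/2) * 15` degrees: zero at solar noon, advancing 15
#' degrees per hour (the earth's spin rate).
#'
#' @param t_z zeitgeber time: hours since sunrise.
#' @param T_L day length (hours).
#' @return hour angle in degrees (vectorised).
#' @export
hour_angle <- function(t_z, T_L) {
  (t_z - T_L / 2) * 15
}

#' Clock-neuron components of the hour angle
#'
#' East-most and north-most components of the rotating hour-angle arrow,
#' `omega_E = -sin(omega) + eps`, `omega_N = -cos(omega) + eps` (clockwise
#' variant).  The counter-clockwise variant negates the north component
#' (`omega_N = +cos(omega) + eps`, for the southern hemisphere); the
#' equatorial variant has a noise-only north component.  Noise draws are
#' uniform on `[-eta, eta]` and, by default, independent per component.
#'
#' @param omega hour angle in degrees.
#' @param variant `"CW"`, `"CCW"` or `"equatorial"`.
#' @param eta_time noise fraction in `[0, 1]`.
#' @param shared_noise if `TRUE`, one draw is added to both components.
#' @return named numeric vector `c(E = , N = )`.
#' @export
hour_angle_components <- function(omega, variant = c("CW", "CCW", "equatorial"),
                                  eta_time = 0, shared_noise = FALSE) {
  variant <- match.arg(variant)
  stopifnot(eta_time >= 0, eta_time <= 1)
  w <- deg2rad(omega)
  if (eta_time > 0) {
    eps <- stats::runif(2, -eta_time, eta_time)
    if (shared_noise) eps[2] <- eps[1]
  } else eps <- c(0, 0)
  omega_E <- -sin(w) + eps[1]
  omega_N <- switch(variant,
                    CW = -cos(w),
                    CCW = cos(w),
                    equatorial = 0) + eps[2]
  c(E = omega_E, N = omega_N)
}

#' Annual clock components of the solar declination
#'
#' Sine and cosine of the internal declination oscillation,
#' `delta_N = sin(delta)`, `delta_Q = cos(delta)`.
#'
#' @param timestamp hours since Jan 1.
#' @return named numeric vector `c(N = , Q = )`.
#' @export
declination_components <- function(timestamp) {
  d <- deg2rad(solar_declination_true(timestamp))
  c(N = sin(d), Q = cos(d))
}

#' Latitude estimate from the geomagnetic inclination
#'
#' Inverts the dipole approximation: `phi = -atan(0.5 tan(mu + eps))`,
#' with inclination-sensing noise `eps ~ U(-eta*90, eta*90)` degrees.
#' The exact algebraic inverse of [magnetic_inclination()] when noiseless.
#'
#' @param mu geomagnetic inclination (degrees), `|mu| <= 90`.
#' @param eta_mu noise fraction in `[0, 1]`.
#' @return list with `phi` (degrees), and components `phi_N = sin(phi)`,
#'   `phi_Q = cos(phi)`.
#' @export
latitude_from_inclination <- function(mu, eta_mu = 0) {
  stopifnot(abs(mu) <= 90, eta_mu >= 0, eta_mu <= 1)
  if (eta_mu > 0) mu <- mu + stats::runif(1, -eta_mu * 90, eta_mu * 90)
  # clamp away from the tangent singularity
  mu <- pmin(90 - 1e-9, pmax(-90 + 1e-9, wrap180(mu)))
  phi <- -rad2deg(atan(0.5 * tan(deg2rad(mu))))
  p <- deg2rad(phi)
  list(phi = phi, phi_N = sin(p), phi_Q = cos(p))
}

#' Complete-model solar azimuth components
#'
#' Combines the hour-angle components with the annual declination and
#' latitude encoders: `alpha_E = delta_Q * omega_E` and
#' `alpha_N = phi_Q * delta_N + phi_N * delta_Q * omega_N`.  At equinox
#' (`delta_N = 0, delta_Q = 1`) this reduces to `alpha_E = omega_E`,
#' `alpha_N = phi_N * omega_N`, so the sign of `phi_N` alone switches the
#' predicted rotation between clockwise and counter-clockwise across the
#' equator.
#'
#' @param omega_E,omega_N clockwise hour-angle components.
#' @param delta_N,delta_Q declination components.
#' @param phi_N,phi_Q latitude components.
#' @return named numeric vector `c(E = , N = )`.
#' @export
predict_azimuth_complete <- function(omega_E, omega_N, delta_N, delta_Q,
                                     phi_N, phi_Q) {
  stopifnot(is.finite(omega_E), is.finite(omega_N))
  c(E = delta_Q * omega_E,
    N = phi_Q * delta_N + phi_N * delta_Q * omega_N)
}

#' Azimuth angle implied by a component pair
#'
#' Clock components encode the east and north components of the unit
#' vector toward the (predicted) sun, up to magnitude; the implied compass
#' bearing is `atan2(E, N)` (at noon the clockwise components `(0, -1)`
#' give 180 degrees: sun due south).
#'
#' @param comp named vector with elements `E` and `N`.
#' @return bearing in degrees clockwise from north, in `[0, 360)`.
#' @export
components_to_azimuth <- function(comp) {
  wrap360(rad2deg(atan2(comp[["E"]], comp[["N"]])))
}
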