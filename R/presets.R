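# Migration scenario presets: departure/destination coordinates and season
# date windows for the three study species, plus the default noise
# configuration shared by all simulations.

.day_of_year <- function(date) {
  d <- as.Date(date)
  as.integer(d - as.Date(format(d, "%Y-01-01"))) + 1L
}

#' Noise configuration for compass and central-complex simulations
#'
#' Independent uniform noise channels: sun encoding (per neuron or
#' angular), time (hour-angle components), magnetic inclination, and the
#' central-complex processing injections (ring decode, EPG normalisation,
#' steering branches).  The default sets every channel to 20%.
#'
#' @param eta default fraction applied to all channels.
#' @param eta_sun,eta_time,eta_mu,eta_cx per-channel overrides.
#' @param sun_mode `"per_neuron"` or `"angular"`.
#' @return a named list.
#' @export
compass_noise <- function(eta = 0.2, eta_sun = eta, eta_time = eta,
                          eta_mu = eta, eta_cx = eta,
                          sun_mode = c("per_neuron", "angular")) {
  list(eta_sun = eta_sun, eta_time = eta_time, eta_mu = eta_mu,
       eta_cx = eta_cx, sun_mode = match.arg(sun_mode))
}

# Departure points (rows) and destinations for the three species.
.migration_table <- list(
  monarch = list(
    departures = data.frame(
      latitude = c(36.91, 48.24, 50.32, 48.06, 45.76),
      longitude = c(-116.76, -107.95, -100.31, -93.41, -84.72)),
    destination = c(latitude = 19.55, longitude = -101.60),
    default_departure = 5L,
    season_start = "2024-08-29", season_end = "2024-10-31",  # autumn
    variant = "CW"),
  bogong = list(
    departures = data.frame(
      latitude = c(-28.64, -27.00, -27.48, -31.00, -35.24),
      longitude = c(153.29, 150.65, 145.10, 141.16, 138.91)),
    destination = c(latitude = -36.84, longitude = 148.46),
    default_departure = 2L,
    season_start = "2024-09-04", season_end = "2024-10-01",  # autumn
    variant = "CCW"),
  dragonfly = list(
    departures = data.frame(
      latitude = c(11.01, 3.12, -2.04, -10.00, -16.28),
      longitude = c(40.38, 45.61, 40.84, 39.00, 48.54)),
    destination = c(latitude = 10.00, longitude = 78.00),
    default_departure = 4L,
    season_start = "2024-02-04", season_end = "2024-05-01",  # spring
    variant = "equatorial")
)

#' Migration scenario preset
#'
#' Departure and destination coordinates and season dates for the three
#' simulated migrants: the monarch butterfly (autumn, Michigan to
#' Michoacan, clockwise hour-angle variant), the Bogong moth (autumn,
#' Queensland/NSW to Mount Bogong, counter-clockwise variant) and the
#' globe skimmer dragonfly (spring, Tanzania to Madurai crossing the
#' equator, equatorial variant).
#'
#' @param species `"monarch"`, `"bogong"` or `"dragonfly"`.
#' @param departure departure-point row (1-5); default is the route whose
#'   printed length matches the worked example for that species.
#' @return list with `start` and `destination` [geo_point()]s, `start_doy`,
#'   `end_doy`, `year`, `variant`, `species`.
#' @export
migration_preset <- function(species = c("monarch", "bogong", "dragonfly"),
                             departure = NULL) {
  species <- match.arg(species)
  p <- .migration_table[[species]]
  if (is.null(departure)) departure <- p$default_departure
  stopifnot(departure >= 1, departure <= nrow(p$departures))
  dep <- p$departures[departure, ]
  list(species = species,
       start = geo_point(dep$latitude, dep$longitude),
       destination = geo_point(p$destination[["latitude"]],
                               p$destination[["longitude"]]),
       start_doy = .day_of_year(p$season_start),
       end_doy = .day_of_year(p$season_end),
       year = 2024L,
       variant = p$variant)
}
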