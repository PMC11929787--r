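# Synthetic input generation: irradiance years on the hourly grid and
# random light-exposure schedules emulating foraging patterns.

#' Hourly irradiance and true day length over a year
#'
#' Evaluates the clear-sky proxy on every hour of the year (8 784 slots in
#' a leap year, 8 760 otherwise) together with the true day length of each
#' slot's day.
#'
#' @param location a [geo_point()].
#' @param year calendar year.
#' @param I0,gamma proxy parameters, see [sky_irradiance()].
#' @return data frame with columns `timestamp` (hours since Jan 1),
#'   `irradiance`, and `day_length_true` (hours).
#' @export
make_irradiance_year <- function(location, year = 2024, I0 = 1, gamma = 1) {
  nd <- days_in_year(year)
  ts <- seq_len(24 * nd) - 1
  irr <- sky_irradiance(location, ts, year = year, I0 = I0, gamma = gamma)
  tl <- vapply(seq_len(nd), function(d) {
    sunrise_sunset(location, d, year)$day_length
  }, numeric(1))
  data.frame(timestamp = ts, irradiance = irr,
             day_length_true = rep(tl, each = 24))
}

#' Random light-exposure schedule
#'
#' Bernoulli selection of hourly slots with probability `T_F / 12`, so that
#' the expected daily light exposure is `T_F` hours; unselected slots have
#' their irradiance set to zero (time spent inside the nest).  Selection is
#' over all slots; night slots contribute nothing either way.
#'
#' @param T_F mean daily exposure in hours, in `(0, 12]`.
#' @param n_slots number of hourly slots in the year.
#' @return logical mask of length `n_slots` (`TRUE` = exposed).  Uses the
#'   current RNG state; seed with `set.seed()` for reproducibility.
#' @export
make_exposure_schedule <- function(T_F, n_slots = 8784) {
  stopifnot(T_F > 0, T_F <= 12)
  stats::runif(n_slots) < T_F / 12
}
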