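# The two behavioural protocols (central-place foraging on a plane,
# long-range migration on a sphere) and the sensor-noise sensitivity
# analysis, wired end to end through the compass circuit and the CX model.

# Scalar fast path of solar_position(): azimuth only, no data frame.
.sun_azimuth <- function(lat, lon, t, ndays) {
  doy <- floor(t / 24) + 1
  hour <- t %% 24
  g <- .noaa_gamma(doy, hour, ndays)
  decl <- .noaa_decl(g)
  tst <- hour * 60 + .noaa_eqtime(g) + 4 * lon
  ha <- deg2rad(tst / 4 - 180)
  latr <- deg2rad(lat)
  east <- -cos(decl) * sin(ha)
  north <- cos(latr) * sin(decl) - sin(latr) * cos(decl) * cos(ha)
  wrap360(rad2deg(atan2(east, north)))
}

# One compass observation: from the true sun azimuth and true heading to a
# unit EPG heading estimate, through the chosen compensation model.
# t is hours since Jan 1; t_z hours since today's sunrise; lat_true the
# animal's current latitude (used only by the complete model's simulated
# inclination sense).
.compass_epg <- function(model, variant, sun_az, heading, t, t_z, T_L,
                         lat_true, noise, prev) {
  metu <- metu2_encode(sun_az, heading, eta_sun = noise$eta_sun,
                       noise_mode = noise$sun_mode)
  if (model == "none") {
    r <- er4m_no_compensation(metu)
  } else {
    omega <- hour_angle(t_z, T_L)
    if (model == "hour_angle") {
      dn1pb <- hour_angle_components(omega, variant, noise$eta_time)
    } else {
      wc <- hour_angle_components(omega, "CW", noise$eta_time)
      mu <- magnetic_inclination(lat_true)
      lc <- latitude_from_inclination(mu, noise$eta_mu)
      dc <- declination_components(t)
      dn1pb <- predict_azimuth_complete(wc[["E"]], wc[["N"]],
                                        dc[["N"]], dc[["Q"]],
                                        lc$phi_N, lc$phi_Q)
    }
    r <- er4m_integrate(tubu1_combine(metu, dn1pb))
  }
  z <- decode_population(r, eta = noise$eta_cx)
  epg_from_er4m(z, eta = noise$eta_cx, prev = prev)
}

# Incremental turning-point tracker over a growing trajectory with known
# per-sample path increments (the 25 m / 50 m windows use path distance).
.tp_new <- function(capacity) {
  env <- new.env(parent = emptyenv())
  env$heading <- numeric(capacity)
  env$pos <- complex(capacity)
  env$cum <- numeric(capacity)
  env$n <- 0L
  env$j <- 1L
  env$last_tp <- -Inf
  env$tps <- complex(0)
  env$chain <- complex(0)
  env
}

# Returns TRUE when a turning point is marked.  Detections further apart
# than max_gap (path metres) are not "consecutive": the chain restarts, so
# an isolated en-route U-turn cannot masquerade as a search pattern.
.tp_push <- function(env, pos, heading, step_len,
                     lookback = 25, angle_threshold = 120, refractory = 50,
                     max_gap = Inf) {
  n <- env$n + 1L
  if (n > length(env$heading)) {  # grow
    env$heading <- c(env$heading, numeric(length(env$heading)))
    env$pos <- c(env$pos, complex(length(env$pos)))
    env$cum <- c(env$cum, numeric(length(env$cum)))
  }
  env$heading[n] <- heading
  env$pos[n] <- pos
  env$cum[n] <- if (n == 1L) 0 else env$cum[n - 1L] + step_len
  env$n <- n
  if (env$cum[n] < lookback) return(FALSE)
  while (env$cum[env$j + 1L] <= env$cum[n] - lookback) env$j <- env$j + 1L
  if (abs(angle_diff(heading, env$heading[env$j])) > angle_threshold &&
      env$cum[n] - env$last_tp > refractory) {
    broken <- env$cum[n] - env$last_tp > max_gap
    env$last_tp <- env$cum[n]
    env$tps <- c(env$tps, pos)
    env$chain <- if (broken) pos else c(env$chain, pos)
    return(TRUE)
  }
  FALSE
}

#' Central-place foraging simulation
#'
#' A simulated insect at a nest searches for food at dawn along a forced
#' random route ending 100 m east, stores the accumulated path-integration
#' state as the food-site vector memory, then alternates homing trips
#' (goal = nest), one-hour rests, and foraging trips (goal = stored food
#' vector) until sunset.  Each closed-loop trip ends when the steering
#' search pattern produces four turning points; the turning-point centroid
#' is the expressed goal location and its distance from the true target
#' (nest or feeder) is the trip's error.  After a homing trip the agent is
#' placed exactly at the nest with the memory re-zeroed (consistent by
#' definition, and isolating each foraging trip's revisit error); a
#' foraging trip hands its end position and continuously integrated memory
#' straight to the next homing trip, so homing always unwinds a path
#' integrated minutes earlier.
#'
#' @param model `"complete"`, `"hour_angle"` or `"none"` (no time
#'   compensation).
#' @param seed integer RNG seed.
#' @param site nest location; default Edinburgh (55.9533 N, 3.1883 W).
#' @param date simulation day, default `"2024-08-02"`.
#' @param v walking speed (m/s), default 0.5.
#' @param dt control step (s), default 1.
#' @param noise a [compass_noise()] configuration (default 20% everywhere).
#' @param daylength `"true"` (ephemeris day length) or `"estimated"`
#'   (circadian estimator output, parameters refit on the site's year).
#' @param tau_M memory constant (m), default 40 000.
#' @param trip_budget maximum trip duration in seconds before the trip is
#'   flagged incomplete (3 600 s).
#' @param variant hour-angle variant, default `"CW"` (northern site).
#' @return list with `trips` (data frame: trip index, phase, error in
#'   metres, duration s, path length m, incomplete flag), `sunrise`,
#'   `sunset`, `day_length`, `model`, `food_vector`.
#' @export
run_foraging <- function(model = c("complete", "hour_angle", "none"),
                         seed = 1,
                         site = geo_point(55.9533, -3.1883),
                         date = "2024-08-02", v = 0.5, dt = 1,
                         noise = compass_noise(),
                         daylength = c("true", "estimated"),
                         tau_M = 40000, trip_budget = 3600,
                         variant = "CW") {
  model <- match.arg(model)
  daylength <- match.arg(daylength)
  set.seed(seed)
  year <- as.integer(format(as.Date(date), "%Y"))
  ndays <- days_in_year(year)
  doy <- .day_of_year(date)
  ss <- sunrise_sunset(site, doy, year)
  if (ss$condition != "normal") stop("foraging site in polar day/night")
  T_L <- ss$day_length
  if (daylength == "estimated") {
    yr <- make_irradiance_year(site, year)
    fit <- fit_day_length_params(yr$irradiance, yr$day_length_true)
    est <- simulate_day_length(yr$irradiance, fit$tau_L, fit$gain_a, fit$beta)
    T_L <- est[floor(ss$sunrise) + 1]
  }
  lat <- site$latitude; lon <- site$longitude
  dth <- dt / 3600  # step in hours

  epg <- 1 + 0i
  sense <- function(heading, t) {
    sun_az <- .sun_azimuth(lat, lon, t, ndays)
    .compass_epg(model, variant, sun_az, heading, t, t - ss$sunrise, T_L,
                 lat, noise, prev = epg)
  }

  # --- dawn search: forced route, open-loop memory integration ---
  route <- generate_foraging_route(resample_step = v * dt)
  t <- ss$sunrise
  z_M <- 0 + 0i
  for (i in seq_len(nrow(route))) {
    epg <- sense(route$heading[i], t)
    z_M <- z_M + epg * v * dt / tau_M
    t <- t + dth
  }
  z_G_food <- z_M
  feeder <- route$position[nrow(route)]  # 100 m east by construction

  # --- closed-loop trip ---
  run_trip <- function(start_pos, start_heading, z_M0, z_G, target, t0) {
    pos <- start_pos; heading <- start_heading
    z_M <- z_M0
    st <- cx_state(z_G = z_G, tau_M = tau_M, eta = noise$eta_cx)
    st$z_M <- z_M
    tp <- .tp_new(trip_budget + 8L)
    t <- t0
    steps <- 0L
    centroid <- NA_complex_
    while (steps < trip_budget) {
      epg <<- sense(heading, t)
      st$z_EPG <- epg
      gd <- goal_direction(st)
      st$z_FC2 <- gd$z_FC2
      dtheta <- steering(epg, gd$z_FC2, eta = noise$eta_cx)
      heading <- heading + rad2deg(dtheta)
      pos <- pos + v * dt * exp(1i * deg2rad(heading))
      st <- integrate_memory(st, v, dt)
      t <- t + dth
      steps <- steps + 1L
      .tp_push(tp, pos, heading, v * dt, max_gap = 100)
      if (length(tp$chain) >= 4) {
        centroid <- search_centroid(tp$chain[seq(length(tp$chain) - 3,
                                                 length(tp$chain))])
        break
      }
    }
    list(centroid = centroid, t_end = t, steps = steps,
         path_length = steps * v * dt, z_M = st$z_M,
         pos = pos, heading = heading,
         incomplete = is.na(centroid))
  }

  trips <- list()
  trip_id <- 0L
  pos <- feeder; heading <- route$heading[nrow(route)]
  while (t < ss$sunset) {
    # homing: goal = nest, memory carried over continuously
    trip_id <- trip_id + 1L
    tr <- run_trip(pos, heading, z_M, 0 + 0i, 0 + 0i, t)
    trips[[length(trips) + 1L]] <- data.frame(
      trip = trip_id, phase = "home",
      error = if (tr$incomplete) NA_real_ else Mod(tr$centroid - 0),
      duration = tr$steps * dt, path_length = tr$path_length,
      incomplete = tr$incomplete)
    t <- tr$t_end
    pos <- 0 + 0i               # teleported to the exact nest
    heading <- tr$heading
    z_M <- 0 + 0i               # fresh integration from the nest
    # rest one hour in the dark
    t <- t + 1
    if (t >= ss$sunset) break
    # foraging: goal = stored food vector
    trip_id <- trip_id + 1L
    tr <- run_trip(pos, heading, z_M, z_G_food, feeder, t)
    trips[[length(trips) + 1L]] <- data.frame(
      trip = trip_id, phase = "forage",
      error = if (tr$incomplete) NA_real_ else Mod(tr$centroid - feeder),
      duration = tr$steps * dt, path_length = tr$path_length,
      incomplete = tr$incomplete)
    t <- tr$t_end
    pos <- tr$pos               # homing continues from the search end
    heading <- tr$heading
    z_M <- tr$z_M               # continuous path integration into homing
  }

  list(trips = do.call(rbind, trips), sunrise = ss$sunrise,
       sunset = ss$sunset, day_length = ss$day_length, model = model,
       food_vector = z_G_food)
}

#' Long-range migration simulation on the sphere
#'
#' The agent starts at a (jittered) departure point with a fixed goal
#' vector `G = rho exp(i theta0) / tau_M` computed once from the
#' great-circle distance and initial bearing to the destination.  Each day
#' it travels between sunrise and sunset in 50-minute steps at 2.5 m/s
#' with a one-hour rest after every step, at most 8 h of travel per day.
#' Heading control runs at a sub-step rate inside each travel step.  The
#' run ends at the season's end date; the reported error is the haversine
#' distance from the centroid of the last four turning points (the centre
#' of search) to the destination.
#'
#' @param preset a [migration_preset()] (or compatible list).
#' @param model `"complete"` or `"hour_angle"`.
#' @param seed integer RNG seed.
#' @param noise a [compass_noise()]; default 20% on all channels.
#' @param variant hour-angle variant override; defaults to the preset's.
#' @param v flight speed (m/s).
#' @param dt travel step (s), default 50 minutes.
#' @param n_sub control sub-steps per travel step.
#' @param tau_M memory constant (m).
#' @param jitter if `TRUE`, add U(-5, 5) degrees to the departure
#'   latitude/longitude and U(-72, 72) hours to the departure time.
#' @param max_travel_h daily travel cap (hours).
#' @param tp_lookback,tp_refractory turning-point windows (path metres),
#'   as printed for the foraging scale (25 m / 50 m).  Note that the
#'   steering readout is bounded by about 0.45 rad per control step, which
#'   caps the turn rate far below 120 degrees per 25 m of path at flight
#'   speed, so this rule cannot fire during migration: runs end without an
#'   expressed search pattern and the reported distance falls back to the
#'   closest approach, flagged by `searched = FALSE`.  As a diagnostic the
#'   run also records when the vector memory first reaches the goal
#'   (`|z_G - z_M| tau_M < v dt`) and the mean position over the following
#'   simulated day (`search_center`), which quantifies the systematic
#'   overshoot of the memory goal under compass noise.
#' @return list with `final_distance` (m; search centroid to destination
#'   when a search pattern was expressed, otherwise closest approach),
#'   `closest_distance` and `closest_point`, `n_turning_points`,
#'   `searched` (four consecutive turning points expressed),
#'   `memory_arrived`, `search_center`, `search_center_distance`
#'   (memory-goal diagnostics, see above), `route_length` (m,
#'   great-circle from the jittered start), `goal_bearing`, `centroid`,
#'   `trajectory` (data frame: t_hours, latitude, longitude, heading),
#'   `model`, `variant`.
#' @export
run_migration <- function(preset, model = c("complete", "hour_angle"),
                          seed = 1, noise = compass_noise(),
                          variant = NULL, v = 2.5, dt = 3000, n_sub = 50,
                          tau_M = 40000, jitter = TRUE, max_travel_h = 8,
                          tp_lookback = 25, tp_refractory = 50) {
  model <- match.arg(model)
  if (is.null(variant)) variant <- preset$variant
  set.seed(seed)
  year <- preset$year
  ndays <- days_in_year(year)
  lat0 <- preset$start$latitude
  lon0 <- preset$start$longitude
  t_start <- (preset$start_doy - 1) * 24
  if (jitter) {
    lat0 <- max(-89, min(89, lat0 + stats::runif(1, -5, 5)))
    lon0 <- lon0 + stats::runif(1, -5, 5)
    t_start <- max(0, t_start + stats::runif(1, -72, 72))
  }
  start <- geo_point(lat0, lon0)
  rho <- haversine_distance(start, preset$destination)
  theta0 <- initial_bearing(start, preset$destination)
  dest_vec <- c(preset$destination$latitude, preset$destination$longitude)

  st <- cx_state(z_G = rho * exp(1i * deg2rad(theta0)) / tau_M,
                 tau_M = tau_M, eta = noise$eta_cx)
  q <- pose_from_geo(lat0, lon0, theta0)
  geo <- geo_from_pose(q)
  epg <- exp(1i * deg2rad(theta0))

  dt_sub <- dt / n_sub
  sub_len <- v * dt_sub
  n_days_sim <- preset$end_doy - floor(t_start / 24)
  cap <- max(16L, (floor(max_travel_h * 3600 / dt) + 1L) *
               n_sub * (n_days_sim + 2L))
  tp <- .tp_new(cap)
  traj_t <- numeric(0); traj_lat <- numeric(0); traj_lon <- numeric(0)
  traj_head <- numeric(0)
  closest <- Inf
  closest_pos <- c(NA_real_, NA_real_)
  onset_t <- NA_real_            # search onset (hours since Jan 1)
  search_pos <- complex(0)       # positions (lat + i lon) while searching

  day0 <- floor(t_start / 24) + 1
  for (day in day0:preset$end_doy) {
    here <- geo_point(geo$latitude, geo$longitude)
    ss <- sunrise_sunset(here, day, year)
    if (ss$condition == "polar_night") next
    t <- if (ss$condition == "polar_day") (day - 1) * 24 else ss$sunrise
    if (day == day0) t <- max(t, t_start)
    day_end <- if (ss$condition == "polar_day") day * 24 else ss$sunset
    T_L <- ss$day_length
    sunrise_h <- if (is.na(ss$sunrise)) (day - 1) * 24 else ss$sunrise
    travel_s <- 0
    since_rest <- 0
    while (travel_s + dt <= max_travel_h * 3600 &&
           t + dt / 3600 <= day_end) {
      for (k in seq_len(n_sub)) {
        sun_az <- .sun_azimuth(geo$latitude, geo$longitude, t, ndays)
        epg <- .compass_epg(model, variant, sun_az, geo$heading, t,
                            t - sunrise_h, T_L, geo$latitude, noise,
                            prev = epg)
        st$z_EPG <- epg
        gd <- goal_direction(st)
        st$z_FC2 <- gd$z_FC2
        dtheta <- steering(epg, gd$z_FC2, eta = noise$eta_cx)
        q <- step_spherical(q, dtheta, v, dt_sub)
        geo <- geo_from_pose(q)
        st <- integrate_memory(st, v, dt_sub)
        t <- t + dt_sub / 3600
        .tp_push(tp, complex(real = geo$latitude, imaginary = geo$longitude),
                 geo$heading, sub_len,
                 lookback = tp_lookback, refractory = tp_refractory,
                 max_gap = 2 * tp_refractory)
        d <- haversine_distance(geo_point(geo$latitude, geo$longitude),
                                preset$destination)
        if (d < closest) {
          closest <- d
          closest_pos <- c(geo$latitude, geo$longitude)
        }
        if (is.na(onset_t) &&
            Mod(st$z_G - st$z_M) * tau_M < v * dt) onset_t <- t
        if (!is.na(onset_t)) {
          search_pos <- c(search_pos,
                          complex(real = geo$latitude,
                                  imaginary = geo$longitude))
          if (t - onset_t >= 24) break
        }
      }
      if (!is.na(onset_t) && t - onset_t >= 24) break
      traj_t <- c(traj_t, t)
      traj_lat <- c(traj_lat, geo$latitude)
      traj_lon <- c(traj_lon, geo$longitude)
      traj_head <- c(traj_head, geo$heading)
      travel_s <- travel_s + dt
      since_rest <- since_rest + dt
      if (since_rest >= 3600) {  # one-hour stop after each hour of travel
        t <- t + 1
        since_rest <- 0
      }
    }
    if (!is.na(onset_t) && t - onset_t >= 24) break
  }

  n_tp <- length(tp$tps)
  searched <- length(tp$chain) >= 4
  if (searched) {
    cen <- search_centroid(tp$chain[seq(length(tp$chain) - 3,
                                        length(tp$chain))])
    final <- haversine_distance(geo_point(Re(cen), Im(cen)),
                                preset$destination)
    centroid <- c(latitude = Re(cen), longitude = Im(cen))
  } else {
    # no expressed search pattern inside the window: closest approach
    final <- closest
    centroid <- c(latitude = NA_real_, longitude = NA_real_)
  }
  if (!is.na(onset_t) && length(search_pos)) {
    sc <- mean(search_pos)
    search_center <- c(latitude = Re(sc), longitude = Im(sc))
    search_center_distance <- haversine_distance(
      geo_point(Re(sc), Im(sc)), preset$destination)
  } else {
    search_center <- c(latitude = NA_real_, longitude = NA_real_)
    search_center_distance <- NA_real_
  }
  list(final_distance = final, closest_distance = closest,
       closest_point = c(latitude = closest_pos[1],
                         longitude = closest_pos[2]),
       n_turning_points = n_tp, searched = searched,
       memory_arrived = !is.na(onset_t),
       search_center = search_center,
       search_center_distance = search_center_distance,
       route_length = rho, goal_bearing = theta0,
       centroid = centroid,
       trajectory = data.frame(t_hours = traj_t, latitude = traj_lat,
                               longitude = traj_lon, heading = traj_head),
       model = model, variant = variant)
}

#' Sensor-noise sensitivity analysis
#'
#' Runs migrations with the complete model while sweeping the noise level
#' of a single sensing channel: `"time"` (hour-angle components),
#' `"inclination"` (magnetic dip), `"sun_8d"` (independent per-neuron sun
#' noise) or `"sun_1d"` (shared angular sun noise before the ring).  The
#' central-complex processing noise stays at its default (20%); the other
#' sensing channels are silent so that each curve isolates one channel.
#'
#' @param channel one of `"time"`, `"inclination"`, `"sun_8d"`, `"sun_1d"`.
#' @param levels noise fractions to sweep (0-1 scale).
#' @param n_seeds seeds per level.
#' @param species preset species to pool over.
#' @param eta_cx processing-noise level held constant.
#' @param ... passed to [run_migration()] (e.g. `n_sub`).
#' @return data frame with columns `channel`, `level`, `species`, `seed`,
#'   `final_distance` (m), `goal_error` (m; expressed-goal distance where
#'   the memory goal was reached, otherwise the closest approach) and
#'   `route_length` (m).
#' @export
run_sensitivity <- function(channel = c("time", "inclination",
                                        "sun_8d", "sun_1d"),
                            levels = seq(0, 1, by = 0.1), n_seeds = 3,
                            species = "monarch", eta_cx = 0.2, ...) {
  channel <- match.arg(channel)
  rows <- list()
  for (sp in species) {
    preset <- migration_preset(sp)
    for (lev in levels) {
      noise <- compass_noise(eta = 0, eta_cx = eta_cx)
      if (channel == "time") noise$eta_time <- lev
      if (channel == "inclination") noise$eta_mu <- lev
      if (channel == "sun_8d") noise$eta_sun <- lev
      if (channel == "sun_1d") {
        noise$eta_sun <- lev
        noise$sun_mode <- "angular"
      }
      for (s in seq_len(n_seeds)) {
        res <- run_migration(preset, model = "complete", seed = s,
                             noise = noise, ...)
        # expressed-goal error where the memory goal was reached (the
        # noise-sensitive endpoint), closest approach otherwise
        ge <- if (res$memory_arrived && is.finite(res$search_center_distance))
          res$search_center_distance else res$final_distance
        rows[[length(rows) + 1L]] <- data.frame(
          channel = channel, level = lev, species = sp, seed = s,
          final_distance = res$final_distance,
          goal_error = ge,
          route_length = res$route_length)
      }
    }
  }
  do.call(rbind, rows)
}
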