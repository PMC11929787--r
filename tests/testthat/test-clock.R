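test_that("day-length estimator steps and fixed points follow the leaky integrator", {
  est <- day_length_estimator(tau_L = 10, gain_a = 1, beta = 2, T_L0 = 7)
  # one hand-evaluated Euler step: a*I + beta = 12 -> 7 + (12-7)/10 = 7.5
  est1 <- update_day_length(est, 10)
  expect_equal(est1$T_L, 7.5)
  expect_equal(est$T_L, 7)  # pure function

  # constant input converges to a*I + beta
  e <- est
  for (i in 1:500) e <- update_day_length(e, 10)
  expect_equal(e$T_L, 12, tolerance = 1e-4)
  # zero input converges to beta
  e <- est
  for (i in 1:500) e <- update_day_length(e, 0)
  expect_equal(e$T_L, 2, tolerance = 1e-4)
  expect_error(update_day_length(est, NaN))

  # vectorised simulation equals the stepwise loop
  irr <- runif(50)
  e <- est; tl <- numeric(50)
  for (i in 1:50) { e <- update_day_length(e, irr[i]); tl[i] <- e$T_L }
  expect_equal(simulate_day_length(irr, 10, 1, 2), tl, tolerance = 1e-12)
})

test_that("parameter fitting recovers known parameters and responds to exposure", {
  loc <- geo_point(55.9533, -3.1883)
  yr <- make_irradiance_year(loc, 2024)
  sim <- simulate_day_length(yr$irradiance, 300, 15, 5)
  fit <- fit_day_length_params(yr$irradiance, sim)
  expect_lt(abs(fit$tau_L / 300 - 1), 0.01)
  expect_lt(abs(fit$gain_a / 15 - 1), 0.01)
  expect_lt(abs(fit$beta / 5 - 1), 0.01)

  # shorter foraging exposure needs a longer time constant and higher gain
  set.seed(31)
  f1 <- fit_day_length_params(yr$irradiance * make_exposure_schedule(1, nrow(yr)),
                              yr$day_length_true)
  f8 <- fit_day_length_params(yr$irradiance * make_exposure_schedule(8, nrow(yr)),
                              yr$day_length_true)
  expect_gt(f1$tau_L, f8$tau_L)
  expect_gt(f1$gain_a, f8$gain_a)
})

test_that("hour angle is linear, 15 deg/h, zero at solar noon", {
  expect_equal(hour_angle(6, 12), 0)
  expect_equal(hour_angle(12, 12), 90)
  expect_equal(hour_angle(0, 12), -90)
  tz <- seq(0, 24, by = 0.5)
  w <- hour_angle(tz, 16)
  expect_equal(unique(round(diff(w) / 0.5, 9)), 15)
})

test_that("hour-angle components implement the three variants", {
  expect_equal(hour_angle_components(0, "CW"), c(E = 0, N = -1))
  expect_equal(hour_angle_components(-90, "CW"), c(E = 1, N = 0),
               tolerance = 1e-12)
  expect_equal(hour_angle_components(0, "CCW"), c(E = 0, N = 1))
  expect_equal(hour_angle_components(0, "equatorial"), c(E = 0, N = 0))
  # unit norm for the rotating variants, noiseless
  for (w in seq(-180, 180, by = 30)) {
    for (v in c("CW", "CCW")) {
      cmp <- hour_angle_components(w, v)
      expect_equal(sum(cmp^2), 1, tolerance = 1e-12)
    }
  }
  # noise draws stay within the stated bounds
  set.seed(5)
  for (i in 1:50) {
    cmp <- hour_angle_components(runif(1, -180, 180), "CW", eta_time = 0.3)
    base <- hour_angle_components(0, "CW")  # bounded check only
    expect_true(all(abs(cmp) <= 1 + 0.3 + 1e-12))
  }
})

test_that("declination components are unit-norm with the right seasonal sign", {
  # equinox of the internal model: argument = 360 deg
  t0 <- (365 - 284) * 24
  expect_equal(declination_components(t0), c(N = 0, Q = 1), tolerance = 1e-9)
  # internal-model June maximum: argument = 90 deg (mod 360)
  tmax <- (365 * (90 / 360) - 284 + 365) * 24
  dc <- declination_components(tmax)
  expect_equal(dc[["N"]], sin(23.45 * pi / 180), tolerance = 1e-9)
  # December minimum: antisymmetric
  tmin <- (365 * (270 / 360) - 284 + 365) * 24
  expect_equal(declination_components(tmin)[["N"]], -sin(23.45 * pi / 180),
               tolerance = 1e-9)
  # unit norm everywhere
  for (t in seq(0, 8760, by = 730)) {
    expect_equal(sum(declination_components(t)^2), 1, tolerance = 1e-12)
  }
})

test_that("latitude from inclination inverts the dipole model exactly", {
  expect_equal(latitude_from_inclination(0)$phi, 0)
  expect_equal(latitude_from_inclination(0)$phi_Q, 1)
  expect_equal(latitude_from_inclination(oracle$incl_45)$phi, 45,
               tolerance = 1e-9)
  for (phi in seq(-89, 89, by = 3.7)) {
    back <- latitude_from_inclination(magnetic_inclination(phi))
    expect_lt(abs(back$phi - phi), 1e-9)
    expect_equal(back$phi_N, sin(phi * pi / 180), tolerance = 1e-9)
  }
})

test_that("complete-model algebra reduces correctly in limiting cases", {
  # equinox + equator: pure east component, matches the equatorial variant
  out <- predict_azimuth_complete(0.3, -0.95, 0, 1, 0, 1)
  expect_equal(out, c(E = 0.3, N = 0))
  # equinox, 45N, noon: alpha_N = phi_N * omega_N = -sin(45)
  p45 <- sin(45 * pi / 180)
  out <- predict_azimuth_complete(0, -1, 0, 1, p45, p45)
  expect_equal(out[["N"]], -p45, tolerance = 1e-12)
  # June solstice at the equator, noon: sun north of zenith
  dN <- sin(23.45 * pi / 180)
  out <- predict_azimuth_complete(0, -1, dN, cos(23.45 * pi / 180), 0, 1)
  expect_equal(out[["N"]], dN, tolerance = 1e-12)
  expect_gt(out[["N"]], 0)
})

test_that("noon null and hemisphere switch hold for every model variant", {
  # at solar noon (omega = 0) the east component of the prediction is zero
  for (m in c("hour_angle", "complete")) {
    for (lat in c(-40, 0, 50)) {
      cmp <- predict_components(m, 0, 4000, lat)
      expect_lt(abs(cmp[["E"]]), 1e-12)
    }
  }
  # equinox noon: sign of alpha_N flips with the hemisphere alone
  t0 <- (365 - 284) * 24
  n_north <- predict_components("complete", 0, t0, 45)[["N"]]
  n_south <- predict_components("complete", 0, t0, -45)[["N"]]
  expect_lt(n_north, 0)  # sun to the south
  expect_gt(n_south, 0)  # sun to the north
  expect_equal(n_north, -n_south, tolerance = 1e-9)
})

test_that("complete model tracks the real azimuth better than the CW hour angle", {
  loc <- geo_point(46, -85)   # northern mid-latitude, August
  ss <- sunrise_sunset(loc, 215, 2024)
  ts <- seq(ss$sunrise + 0.3, ss$sunset - 0.3, by = 0.25)
  err <- sapply(ts, function(t) {
    sun <- solar_position(loc, t, 2024)$azimuth
    w <- hour_angle(t - ss$sunrise, ss$day_length)
    e_ha <- angle_diff(components_to_azimuth(
      predict_components("hour_angle", w, t, 46)), sun)
    e_co <- angle_diff(components_to_azimuth(
      predict_components("complete", w, t, 46)), sun)
    c(ha = e_ha, co = e_co)
  })
  rms <- sqrt(rowMeans(err^2))
  expect_lt(rms[["co"]], rms[["ha"]])
})
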