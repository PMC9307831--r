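test_that("shortwave attenuation follows the closed form and composes over slabs", {
  # no canopy: everything reaches the ground
  none <- attenuate_shortwave(500, numeric(20))
  expect_equal(none$ground_incident, 500)
  # single-slab closed form: 500 * exp(-0.5 * 2)
  slab <- attenuate_shortwave(500, 2, extinction_k = 0.5)
  expect_equal(slab$ground_incident, 500 * exp(-1), tolerance = 1e-12)
  # splitting the slab into 20 sub-layers changes nothing
  split20 <- attenuate_shortwave(500, rep(0.1, 20), extinction_k = 0.5)
  expect_lt(abs(split20$ground_incident - slab$ground_incident), 1e-9)
  # absorbed + reflected + transmitted accounts for the incident flux
  prof <- attenuate_shortwave(640, c(0.5, 1, 0.2, 0.8), extinction_k = 0.5,
                              leaf_reflectance = 0.12, ground_albedo = 0.25)
  expect_equal(sum(prof$layer_abs) + sum(prof$layer_reflected) +
                 prof$ground_incident, 640, tolerance = 1e-9)
  expect_equal(prof$ground_absorbed, prof$ground_incident * 0.75)
  expect_error(attenuate_shortwave(-1, 1), "SW_in")
})

test_that("ground shortwave is non-increasing in total leaf area", {
  lais <- seq(0, 8, by = 0.4)
  ground <- vapply(lais, function(L)
    attenuate_shortwave(700, rep(L / 20, 20))$ground_incident, 0)
  expect_true(all(diff(ground) <= 0))
})

test_that("aerodynamic resistance matches the log-profile hand calculation", {
  # ln((10 - 0.67)/0.1)^2 / (0.41^2 * 3) for a 1 m canopy
  expect_equal(aerodynamic_resistance(3, 10, 1),
               log(9.33 / 0.1)^2 / (0.41^2 * 3), tolerance = 1e-12)
  # monotone decreasing in wind above the floor
  ra <- aerodynamic_resistance(c(1, 2, 4, 8), 10, 1)
  expect_true(all(diff(ra) < 0))
  # wind below the floor behaves like the floor value
  expect_equal(aerodynamic_resistance(0.1, 10, 1),
               aerodynamic_resistance(0.5, 10, 1))
  expect_error(aerodynamic_resistance(3, 5, 10), "measurement_height")
  expect_error(aerodynamic_resistance(-1, 10, 1), "wind")
})

test_that("leaf energy balance hits its fixed points and sign constraints", {
  # no absorbed radiation at saturation: leaf sits at air temperature
  eq <- leaf_energy_balance(0, 285, RH = 100, r_a = 50)
  expect_equal(eq$T_leaf, 285, tolerance = 1e-6)
  expect_equal(eq$LE, 0, tolerance = 1e-6)
  expect_equal(eq$H, 0, tolerance = 1e-6)
  # absorbed radiation at saturation warms the leaf and drives H upward
  warm <- leaf_energy_balance(300, 285, RH = 100, r_a = 50)
  expect_gt(warm$T_leaf, 285)
  expect_gt(warm$H, 0)
  expect_lt(abs(warm$residual), 0.01)
  # closed stomata suppress the latent flux
  dry_open <- leaf_energy_balance(300, 285, RH = 40, r_a = 50, TRUE)
  dry_closed <- leaf_energy_balance(300, 285, RH = 40, r_a = 50, FALSE)
  expect_gt(dry_open$LE, dry_closed$LE)
  # an unbalanceable load is reported as a solver failure with diagnostics
  expect_error(leaf_energy_balance(1e7, 285, 50, 50), "no sign change")
})

test_that("leaf solver agrees with an exhaustive residual scan", {
  set.seed(77)
  n <- 200 # the full 1000-case sweep runs in the acceptance suite
  for (k in seq_len(n)) {
    absorbed <- stats::runif(1, -50, 400)
    T_air <- stats::runif(1, 250, 305)
    RH <- stats::runif(1, 20, 100)
    r_a <- stats::runif(1, 10, 150)
    open <- stats::runif(1) < 0.5
    pres <- stats::runif(1, 60, 101)
    got <- leaf_energy_balance(absorbed, T_air, RH, r_a, open, pres)$T_leaf
    want <- oracle_leaf_temperature(absorbed, T_air, RH, r_a, open, pres)
    expect_lt(abs(got - want), 0.002)
  }
})

test_that("snowpack accumulates, melts by the latent heat of fusion, and caps", {
  p <- physics_params()
  # pure accumulation
  s0 <- snow_state(0)
  acc <- step_snowpack(s0, snowfall = 5, available_energy = 0)
  expect_equal(acc$snow$swe, 5)
  expect_equal(acc$melt, 0)
  # 3.34 MJ/m2 melts exactly 10 mm
  s10 <- snow_state(10)
  melted <- step_snowpack(s10, 0, available_energy = 3.34e6 / 1800,
                          dt = 1800)
  expect_equal(melted$melt, 10, tolerance = 1e-9)
  expect_equal(melted$snow$swe, 0, tolerance = 1e-9)
  expect_equal(melted$snow$surface_temp, 273.15)
  # melt is capped at the stored mass; surplus energy is returned
  s2 <- snow_state(2)
  capped <- step_snowpack(s2, 0, available_energy = 5 * 0.334e6 / 1800,
                          dt = 1800)
  expect_equal(capped$melt, 2)
  expect_equal(capped$surplus_energy,
               (5 - 2) * 0.334e6 / 1800, tolerance = 1e-9)
  # surface temperature relaxes toward air but never above freezing
  cold <- snow_state(50, surface_temp = 263)
  relaxed <- step_snowpack(cold, 0, 0, T_air = 280)
  expect_lte(relaxed$snow$surface_temp, 273.15)
  expect_gt(relaxed$snow$surface_temp, 263)
  # albedo decays with age and depth follows the fixed bulk density
  fresh <- snow_state(100, age = 0, params = p)
  old <- snow_state(100, age = 40, params = p)
  expect_equal(fresh$albedo, p$snow_albedo_fresh)
  expect_lt(old$albedo, 0.62)
  expect_equal(fresh$depth, 100 / p$snow_density)
})

test_that("soil conduction conserves energy with a zero-flux bottom", {
  p <- physics_params()
  s <- soil_state(278, p)
  # equilibrium: uniform column with no surface flux is unchanged
  expect_equal(step_soil_heat(s, 0)$layer_temps, s$layer_temps)
  # sustained surface flux: column energy gain equals the integral of G
  G <- 55
  n <- 400
  for (i in seq_len(n)) s <- step_soil_heat(s, G, 1800)
  gained <- sum((s$layer_temps - 278) * p$soil_C * p$soil_dz)
  expect_lt(abs(gained - G * 1800 * n) / (G * 1800 * n), 1e-6)
  # step response: a short column relaxes to a uniform warmer state at the
  # new equilibrium set by the injected energy (zero-flux bottom)
  p2 <- physics_params(soil_dz = rep(0.05, 12))
  s2 <- soil_state(278, p2)
  for (i in seq_len(200)) s2 <- step_soil_heat(s2, G, 1800)
  for (i in seq_len(3000)) s2 <- step_soil_heat(s2, 0, 1800)
  expect_lt(diff(range(s2$layer_temps)), 0.02)
  expect_equal(mean(s2$layer_temps),
               278 + G * 1800 * 200 / (p2$soil_C * sum(p2$soil_dz)),
               tolerance = 1e-9)
  # instability is rejected with the required step reported
  bad <- physics_params(soil_k = 50)
  expect_error(step_soil_heat(soil_state(278, bad), 0), "unstable")
})

test_that("isothermal equilibrium is preserved by the full simulator", {
  f <- tt_constant_forcing(n_days = 2, T_air = 280)
  sc <- scenario_set("US")[["US-Tr"]]
  run <- simulate_ecosystem(f, sc)
  expect_lt(max(abs(run$T_surf - 280)), 1e-6)
  expect_lt(max(abs(run$LE)), 1e-6)
  expect_lt(max(abs(run$H)), 1e-6)
  expect_lt(max(abs(run$closure)), 1e-6)
})

test_that("the simulator is deterministic and respects physical bounds", {
  f <- generate_forcing(archetype_defaults("arctic"), n_years = 1, seed = 55)
  f60 <- f[1:(60 * 48), ]
  class(f60) <- class(f)
  attr(f60, "archetype") <- attr(f, "archetype")
  sc <- scenario_set("CA")[["CA-Tr"]]
  r1 <- simulate_ecosystem(f60, sc)
  r2 <- simulate_ecosystem(f60, sc)
  expect_identical(r1, r2)
  expect_true(all(r1$T_surf > 180 & r1$T_surf < 340))
  expect_true(all(r1$swe >= 0))
  # melt-limited surface: T_surf is exactly 273.15 whenever melt occurs
  melting <- r1$melt > 0
  if (any(melting))
    expect_true(all(r1$T_surf[melting] == 273.15))
  # per-step snow mass balance is exact
  expect_lt(max(abs(diff(r1$swe) -
                      (r1$snowfall[-1] - r1$melt[-1]))), 1e-9)
  # energy closure within tolerance on a snowy window
  expect_lt(max(abs(r1$closure)), 1)
})
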