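# Simplified 1-D canopy-snow-soil physics core. Per half-hourly step:
# Beer-Lambert shortwave attenuation through the leaf area profile, a
# big-leaf-per-layer energy balance solved for leaf temperature, a ground /
# snow-surface balance whose temperature is capped at the melting point with
# the excess routed to melt energy, and explicit heat conduction through a
# 12-layer soil column with a zero-flux bottom boundary.

#' Physics parameters of the simulator
#'
#' All tunables of the simplified physics core, config-exposed with
#' engineering defaults. Override individual entries via \code{...}.
#'
#' @param ... named overrides of the defaults.
#' @return named list of parameters.
#' @export
physics_params <- function(...) {
  p <- list(
    k_ext = 0.5,            # canopy extinction coefficient
    clump = 0.5,            # foliage clumping index (effective k = k_ext*clump)
    ground_albedo = 0.2,    # snow-free ground shortwave albedo
    emis_leaf = 0.97,       # leaf emissivity
    emis_surf = 0.97,       # ground/snow surface emissivity
    r_bl = 50,              # leaf boundary-layer resistance, s/m per unit LAI
    r_stom_open = 200,      # stomatal resistance when open, s/m per unit LAI
    r_stom_closed = 5000,   # cuticular resistance when dormant, s/m
    snow_density = 250,     # bulk snow density, kg/m3
    snow_albedo_fresh = 0.85,
    snow_albedo_old = 0.6,
    snow_albedo_efold = 10, # e-folding snow age for albedo decay, days
    k_snow = 0.3,           # snow thermal conductivity, W/m/K
    r_snow_evap = 100,      # surface resistance for sublimation, s/m
    r_soil_evap = 800,      # surface resistance for soil evaporation, s/m
    soil_k = 1.0,           # soil thermal conductivity, W/m/K
    soil_C = 2.2e6,         # soil volumetric heat capacity, J/m3/K
    soil_dz = c(0.05, 0.05, 0.1, 0.1, 0.15, 0.2, 0.25, 0.3,
                0.4, 0.6, 0.8, 1.0), # 12 below-ground layer thicknesses, m
    shelter_coef = 1.0,     # e-folding of under-canopy exchange with LAI
    wind_floor = 0.5,       # minimum wind speed used in resistances, m/s
    z0_bare = 0.005,        # roughness length of bare/snow surface, m
    swe_eps = 0.1,          # snow presence threshold, mm SWE
    par_frac = 0.45,        # PAR fraction of absorbed shortwave
    par_half = 100,         # half-saturation absorbed PAR, W/m2 leaf
    t_dorm = 278.15,        # 5-day mean air temperature to leave dormancy, K
    q10 = 2.0,              # respiration Q10
    t_resp_ref = 283.15,    # respiration reference temperature, K
    buried_resp_frac = 0.1, # respiration multiplier for snow-buried leaf area
    greenup_earliest = 60,  # earliest day of year green-up may start
    leaf_tol = 0.01,        # leaf energy-balance residual tolerance, W/m2
    ra_surf_max = 5000      # cap on under-canopy surface resistance, s/m
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown physics parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p
}

#' Beer-Lambert shortwave attenuation through a canopy profile
#'
#' Irradiance below cumulative (from the top) leaf area L is
#' \code{SW_in * exp(-k L)}; each layer absorbs the irradiance difference
#' across it times \code{1 - leaf_reflectance} (the reflected part leaves the
#' system); the ground absorbs the transmitted flux times
#' \code{1 - ground_albedo}.
#'
#' @param SW_in incident shortwave above the canopy, W/m2 (>= 0).
#' @param lad_profile per-layer leaf area, bottom layer first, m2/m2.
#' @param extinction_k extinction coefficient (> 0).
#' @param leaf_reflectance scalar or per-layer shortwave reflectance.
#' @param ground_albedo ground shortwave albedo.
#' @return list with \code{layer_abs}, \code{layer_reflected} (per layer,
#'   bottom first), \code{ground_incident}, \code{ground_absorbed}.
#' @export
attenuate_shortwave <- function(SW_in, lad_profile, extinction_k = 0.5,
                                leaf_reflectance = 0.1, ground_albedo = 0.2) {
  if (!.is_number(SW_in) || SW_in < 0) stop("SW_in must be a number >= 0")
  if (extinction_k <= 0) stop("extinction_k must be > 0")
  nz <- length(lad_profile)
  # cumulative LAI above the top of each layer (bottom-first ordering)
  above <- rev(c(0, cumsum(rev(lad_profile)))[seq_len(nz)])
  I_top <- SW_in * exp(-extinction_k * above)
  I_bot <- SW_in * exp(-extinction_k * (above + lad_profile))
  dI <- I_top - I_bot
  refl <- rep_len(leaf_reflectance, nz)
  ground_incident <- SW_in * exp(-extinction_k * sum(lad_profile))
  list(layer_abs = dI * (1 - refl),
       layer_reflected = dI * refl,
       ground_incident = ground_incident,
       ground_absorbed = ground_incident * (1 - ground_albedo))
}

#' Bulk aerodynamic resistance from a neutral log profile
#'
#' Roughness length \code{0.1 h} and displacement height \code{0.67 h}; the
#' wind speed is floored (default 0.5 m/s) to bound the resistance.
#'
#' @param wind wind speed at the measurement height, m/s (vectorized, >= 0).
#' @param measurement_height height of the wind measurement, m; must exceed
#'   the displacement height plus roughness length.
#' @param h_canopy canopy height, m; 0 selects a bare/snow surface roughness.
#' @param params [physics_params()].
#' @return aerodynamic resistance, s/m.
#' @export
aerodynamic_resistance <- function(wind, measurement_height, h_canopy,
                                   params = physics_params()) {
  if (any(wind < 0)) stop("wind must be >= 0")
  d <- 0.67 * h_canopy
  z0 <- if (h_canopy > 0) 0.1 * h_canopy else params$z0_bare
  if (measurement_height <= d + z0)
    stop("measurement_height must exceed displacement + roughness height")
  u <- pmax(wind, params$wind_floor)
  log((measurement_height - d) / z0)^2 / (.const$vonk^2 * u)
}

# Leaf energy-balance flux components at leaf temperature T (vectorized).
# absorbed: net absorbed radiation per unit leaf area, W/m2
# H = rho cp (T - Ta)/r_a ; LE = rho cp/gamma (es(T) - e_air)/(r_a + r_s)
# Rlw = emis sigma (T^4 - Ta^4) ; residual = absorbed - H - LE - Rlw
.leaf_flux <- function(T_leaf, absorbed, T_air_local, e_air, gamma, r_a, r_s,
                       emis = 0.97) {
  hc <- .const$rho_air * .const$cp / r_a
  H <- hc * (T_leaf - T_air_local)
  LE <- .const$rho_air * .const$cp / gamma * (.esat(T_leaf) - e_air) /
    (r_a + r_s)
  Rlw <- emis * .const$sigma * (T_leaf^4 - T_air_local^4)
  list(H = H, LE = LE, Rlw = Rlw, resid = absorbed - H - LE - Rlw)
}

# Vectorized damped-Newton solve of the leaf balance with bisection fallback.
# Returns leaf temperatures; errors if any cell fails to converge.
.solve_leaf <- function(absorbed, T_air_local, e_air, gamma, r_a, r_s,
                        emis, tol = 0.01) {
  hc <- .const$rho_air * .const$cp / r_a
  ce <- .const$rho_air * .const$cp / (gamma * (r_a + r_s))
  Tl <- T_air_local
  lo <- T_air_local - 40
  hi <- T_air_local + 40
  for (it in 1:12) {
    f <- absorbed - hc * (Tl - T_air_local) - ce * (.esat(Tl) - e_air) -
      emis * .const$sigma * (Tl^4 - T_air_local^4)
    if (all(abs(f) <= tol)) return(Tl)
    df <- -(hc + ce * .desat(Tl) + 4 * emis * .const$sigma * Tl^3)
    step <- pmax(-5, pmin(5, -f / df))
    Tl <- pmin(hi, pmax(lo, Tl + step))
  }
  f <- absorbed - hc * (Tl - T_air_local) - ce * (.esat(Tl) - e_air) -
    emis * .const$sigma * (Tl^4 - T_air_local^4)
  bad <- which(abs(f) > tol)
  for (j in bad) {
    res <- function(T) absorbed[j] - hc[j] * (T - T_air_local[j]) -
      ce[j] * (.esat(T) - e_air[j]) -
      emis * .const$sigma * (T^4 - T_air_local[j]^4)
    flo <- res(lo[j]); fhi <- res(hi[j])
    if (flo * fhi > 0)
      stop(sprintf(paste0("leaf energy balance: no sign change in bracket ",
                          "[%.2f, %.2f] K (absorbed = %.1f W/m2, ",
                          "T_air = %.2f K)"),
                   lo[j], hi[j], absorbed[j], T_air_local[j]))
    a <- lo[j]; b <- hi[j]
    for (it in 1:60) {
      m <- (a + b) / 2
      fm <- res(m)
      if (abs(fm) <= tol) break
      if (flo * fm <= 0) b <- m else { a <- m; flo <- fm }
    }
    Tl[j] <- m
  }
  Tl
}

#' Leaf-layer energy balance
#'
#' Solves \code{absorbed = H + LE + emis * sigma * (T_leaf^4 -
#' T_air_local^4)} for the leaf temperature by bracketed root finding on
#' \code{[T_air_local - 40, T_air_local + 40]} to a residual of at most 0.01
#' W/m2, with \code{H = rho c_p (T_leaf - T_air_local)/r_a} and a
#' vapour-pressure-deficit latent flux through stomatal plus aerodynamic
#' resistance. When stomata are closed the latent flux is limited to the
#' cuticular minimum.
#'
#' @param absorbed net absorbed radiation per unit leaf area, W/m2.
#' @param T_air_local local air temperature, K.
#' @param RH relative humidity, percent.
#' @param r_a aerodynamic (boundary-layer) resistance, s/m.
#' @param stomata_open logical.
#' @param pressure air pressure, kPa.
#' @param params [physics_params()].
#' @return list with \code{T_leaf} (K), \code{LE}, \code{H} (W/m2 per unit
#'   leaf area) and the achieved \code{residual}.
#' @export
leaf_energy_balance <- function(absorbed, T_air_local, RH, r_a,
                                stomata_open = TRUE, pressure = 85,
                                params = physics_params()) {
  stopifnot(is.finite(absorbed), is.finite(T_air_local), is.finite(RH),
            is.finite(r_a), r_a > 0)
  e_air <- RH / 100 * .esat(T_air_local)
  gamma <- .gamma_psy(pressure)
  r_s <- if (isTRUE(stomata_open)) params$r_stom_open else
    params$r_stom_closed
  res <- function(T) .leaf_flux(T, absorbed, T_air_local, e_air, gamma, r_a,
                                r_s, params$emis_leaf)$resid
  lo <- T_air_local - 40
  hi <- T_air_local + 40
  flo <- res(lo); fhi <- res(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop(sprintf(paste0("leaf energy balance: no sign change in bracket ",
                        "[%.2f, %.2f] K (absorbed = %.2f, T_air = %.2f, ",
                        "RH = %.1f, r_a = %.1f)"),
                 lo, hi, absorbed, T_air_local, RH, r_a))
  root <- stats::uniroot(res, c(lo, hi), tol = 1e-8)$root
  fl <- .leaf_flux(root, absorbed, T_air_local, e_air, gamma, r_a, r_s,
                   params$emis_leaf)
  list(T_leaf = root, LE = fl$LE, H = fl$H, residual = fl$resid)
}

#' Create a snowpack state
#'
#' @param swe snow water equivalent, mm.
#' @param surface_temp snow surface temperature, K.
#' @param age snow surface age, days (drives albedo decay).
#' @param params [physics_params()].
#' @return list of class \code{snow_state} with \code{swe}, \code{depth} (m,
#'   from the fixed bulk snow density), \code{surface_temp}, \code{albedo},
#'   \code{age}.
#' @export
snow_state <- function(swe = 0, surface_temp = 273.15, age = 0,
                       params = physics_params()) {
  stopifnot(swe >= 0)
  s <- list(swe = swe, depth = swe / params$snow_density, # mm * m3/kg = m
            surface_temp = min(surface_temp, if (swe > 0) 273.15 else Inf),
            age = age)
  s$albedo <- params$snow_albedo_old +
    (params$snow_albedo_fresh - params$snow_albedo_old) *
    exp(-age / params$snow_albedo_efold)
  class(s) <- "snow_state"
  s
}

#' Advance the snowpack one step
#'
#' Snowfall accumulates; positive available energy melts at most the stored
#' water equivalent (latent heat of fusion 0.334 MJ/kg) and any surplus
#' energy is returned for the surface balance; the surface temperature is
#' 273.15 K while melt occurs, otherwise relaxes toward the air temperature
#' without exceeding 273.15 K while snow is present; albedo decays with snow
#' age and is refreshed by snowfall.
#'
#' @param snow a [snow_state()].
#' @param snowfall snowfall this step, mm water equivalent (>= 0).
#' @param available_energy energy available at the snow surface, W/m2.
#' @param dt step length, s.
#' @param T_air air temperature, K (drives the no-melt surface relaxation).
#' @param params [physics_params()].
#' @return list with \code{snow} (updated state), \code{melt} (mm),
#'   \code{melt_energy_used} and \code{surplus_energy} (W/m2).
#' @export
step_snowpack <- function(snow, snowfall, available_energy, dt = 1800,
                          T_air = 273.15, params = physics_params()) {
  stopifnot(inherits(snow, "snow_state"), snowfall >= 0)
  swe <- snow$swe + snowfall
  age <- if (snowfall * 86400 / dt > 1) 0 else snow$age + dt / 86400
  melt <- 0
  energy_used <- 0
  surplus <- 0
  if (swe > 0 && available_energy > 0) {
    potential <- available_energy * dt / .const$lambda_f # mm
    melt <- min(swe, potential)
    energy_used <- melt * .const$lambda_f / dt
    surplus <- available_energy - energy_used
    swe <- swe - melt
  }
  Ts <- if (melt > 0) 273.15 else
    min(273.15, snow$surface_temp + 0.25 * (T_air - snow$surface_temp))
  list(snow = snow_state(swe, surface_temp = Ts, age = age, params = params),
       melt = melt, melt_energy_used = energy_used,
       surplus_energy = surplus)
}

#' Create a soil column state
#'
#' @param layer_temps temperatures of the 12 below-ground layers, K (a scalar
#'   is recycled).
#' @param params [physics_params()] (supplies thicknesses, conductivity and
#'   heat capacity).
#' @return list of class \code{soil_state}.
#' @export
soil_state <- function(layer_temps, params = physics_params()) {
  nz <- length(params$soil_dz)
  layer_temps <- rep_len(layer_temps, nz)
  structure(list(layer_temps = layer_temps, thickness = params$soil_dz,
                 conductivity = params$soil_k, heat_capacity = params$soil_C),
            class = "soil_state")
}

#' Advance soil heat conduction one step
#'
#' Explicit conduction across the 12 layers with the surface flux
#' \code{G_surface} imposed at the top and a zero-flux bottom boundary. The
#' stability condition \code{dt <= 0.5 min(dz)^2 C / k} is checked.
#'
#' @param soil a [soil_state()].
#' @param G_surface heat flux into the soil at the surface, W/m2.
#' @param dt step length, s.
#' @return updated [soil_state()].
#' @export
step_soil_heat <- function(soil, G_surface, dt = 1800) {
  stopifnot(inherits(soil, "soil_state"))
  dz <- soil$thickness
  k <- soil$conductivity
  C <- soil$heat_capacity
  dt_max <- 0.5 * min(dz)^2 * C / k
  if (dt > dt_max)
    stop(sprintf("soil conduction unstable: dt = %g s exceeds %g s", dt,
                 dt_max))
  T <- soil$layer_temps
  n <- length(T)
  # interface fluxes between layers (positive downward)
  flux <- k * (T[-n] - T[-1]) / ((dz[-n] + dz[-1]) / 2)
  dT <- (c(G_surface, flux) - c(flux, 0)) * dt / (C * dz)
  soil$layer_temps <- T + dT
  soil
}

# Internal: solve the ground/snow surface energy balance for Ts.
# f(Ts) = SWg_abs + emis*(LW_eff - sigma Ts^4) - H(Ts) - LE(Ts) - G(Ts)
# Monotone decreasing; damped Newton with bisection fallback.
.solve_surface <- function(SWg_abs, LW_eff, T_air, e_air, gamma, ra_s,
                           r_evap, T_soil1, R_G, emis, tol = 0.01) {
  hc <- .const$rho_air * .const$cp / ra_s
  ce <- .const$rho_air * .const$cp / (gamma * (ra_s + r_evap))
  f <- function(T) SWg_abs + emis * (LW_eff - .const$sigma * T^4) -
    hc * (T - T_air) - ce * (.esat(T) - e_air) - (T - T_soil1) / R_G
  Ts <- max(T_air, T_soil1)
  for (it in 1:15) {
    fv <- f(Ts)
    if (abs(fv) <= tol) return(Ts)
    dfv <- -(4 * emis * .const$sigma * Ts^3 + hc + ce * .desat(Ts) + 1 / R_G)
    Ts <- Ts - max(-10, min(10, fv / dfv))
    Ts <- max(180, min(340, Ts))
  }
  if (abs(f(Ts)) <= tol) return(Ts)
  a <- 180; b <- 340
  fa <- f(a)
  for (it in 1:80) {
    m <- (a + b) / 2
    fm <- f(m)
    if (abs(fm) <= tol) return(m)
    if (fa * fm <= 0) b <- m else { a <- m; fa <- fm }
  }
  stop("surface energy balance failed to converge")
}

#' Run the canopy-snow-soil simulator over a forcing series
#'
#' Per half-hourly step: phenology and snow burial set the leaf area profile;
#' shortwave is attenuated through it; each occupied (layer, group) cell
#' solves a leaf energy balance against the within-canopy air temperature
#' (interpolated between the surface and above-canopy air); the ground or
#' snow surface balance partitions available energy into ground heat flux,
#' melt and upward turbulent fluxes, with the surface temperature capped at
#' 273.15 K while snow melts; snow mass and the soil column are then advanced.
#' Leaf CO2 exchange (photosynthesis under the dormancy switch, Q10
#' respiration) is computed from the same leaf states. The run is
#' deterministic given its inputs.
#'
#' @param forcing a \code{forcing_series} (see [generate_forcing()]).
#' @param scenario a [vegetation_scenario()].
#' @param params [physics_params()].
#' @return a \code{data.frame} of class \code{ecosystem_run} with one row per
#'   forcing step: surface and canopy temperatures, snowpack, canopy-top
#'   fluxes (LE, H, absorbed net radiation, ground heat flux, melt energy),
#'   energy-closure residual, effective LAI and leaf CO2 fluxes. The scenario
#'   and parameters are attached as attributes.
#' @export
simulate_ecosystem <- function(forcing, scenario, params = physics_params()) {
  .validate_forcing(forcing)
  stopifnot(inherits(scenario, "vegetation_scenario"))
  cs <- .const
  dt <- 1800
  n <- nrow(forcing)

  SW <- forcing$SW_in; LWd <- forcing$LW_in; Ta <- forcing$T_air
  precip <- forcing$precip; phase <- as.character(forcing$phase)
  RH <- forcing$RH; Pres <- forcing$pressure
  if (!is.null(forcing$doy) && !is.null(forcing$year)) {
    doy <- forcing$doy
    yr <- forcing$year
  } else {
    lt <- as.POSIXlt(forcing$timestamp, tz = "UTC")
    doy <- lt$yday + 1L
    yr <- lt$year + 1900L
  }
  T5 <- .trailing_mean(Ta, 240L)
  e_air_all <- RH / 100 * .esat(Ta)
  gamma_all <- .gamma_psy(Pres)

  gs <- scenario$groups
  ng <- length(gs)
  g_bot <- vapply(gs, `[[`, 0, "canopy_bottom")
  g_top <- vapply(gs, `[[`, 0, "canopy_top")
  g_max <- vapply(gs, `[[`, 0, "max_LAI")
  g_ever <- vapply(gs, `[[`, TRUE, "evergreen")
  g_refl <- vapply(gs, `[[`, 0, "leaf_reflectance")
  g_cap <- vapply(gs, `[[`, 0, "photosynthetic_capacity")
  g_resp <- vapply(gs, `[[`, 0, "respiration_base")
  h_top <- max(g_top)
  grid <- canopy_grid(h_top)
  zc <- grid$centers
  edges <- grid$edges

  # soil column and stability check
  soil_dz <- params$soil_dz
  if (length(soil_dz) != 12) stop("soil column must have 12 layers")
  dt_max <- 0.5 * min(soil_dz)^2 * params$soil_C / params$soil_k
  if (dt > dt_max)
    stop(sprintf("soil conduction unstable at dt = %d s (max %.0f s)", dt,
                 dt_max))
  arch <- attr(forcing, "archetype")
  T_init <- if (!is.null(arch)) arch$mean_annual_temp else mean(Ta)
  Tsoil <- rep(T_init, 12)
  Ts_prev <- T_init
  Tcan_prev <- T_init

  # aerodynamic resistances precomputed from the wind series
  zm <- max(2 * h_top, 10)
  ra_can_v <- aerodynamic_resistance(forcing$wind, zm, h_top, params)
  ra_bare_v <- aerodynamic_resistance(forcing$wind, zm, 0, params)

  swe <- 0; snow_age <- 0
  greenup <- NA_real_
  cur_day <- -1L
  cur_yr <- yr[1]
  phen <- numeric(ng)

  out_names <- c("T_surf", "T_can", "swe", "snow_depth", "lai", "LE", "H",
                 "Rn_abs", "G", "M", "SW_ground", "closure", "A", "R_a",
                 "T_soil_top", "snowfall", "melt")
  O <- matrix(0, n, length(out_names), dimnames = list(NULL, out_names))

  sig <- cs$sigma
  rhocp <- cs$rho_air * cs$cp

  for (i in seq_len(n)) {
    if (yr[i] != cur_yr) { cur_yr <- yr[i]; greenup <- NA_real_ }
    d <- doy[i]
    snow_depth <- swe / params$snow_density
    if (d != cur_day) {
      cur_day <- d
      if (is.na(greenup) && d >= params$greenup_earliest &&
          swe <= params$swe_eps)
        greenup <- d
      for (g in seq_len(ng))
        phen[g] <- g_max[g] * (if (g_ever[g]) 1 else
          .phenology_frac(d, greenup))
    }

    # effective leaf area under burial
    eb <- pmax(g_bot, pmin(snow_depth, g_top))
    frac <- (g_top - eb) / (g_top - g_bot)
    eff <- phen * frac
    buried_lai <- phen - eff
    lad <- matrix(0, grid$n_above, ng)
    for (g in seq_len(ng))
      if (eff[g] > 1e-9)
        lad[, g] <- .lad_one_group(eff[g], eb[g], g_top[g], edges)
    lad_tot <- rowSums(lad)
    Ltot <- sum(eff)

    # shortwave through the canopy (clumped effective extinction)
    swi <- SW[i]
    k_eff <- params$k_ext * params$clump
    if (Ltot > 1e-9 && swi > 0) {
      nz <- grid$n_above
      above <- rev(c(0, cumsum(rev(lad_tot)))[seq_len(nz)])
      I_top <- swi * exp(-k_eff * above)
      I_bot <- swi * exp(-k_eff * (above + lad_tot))
      dI <- I_top - I_bot
      ground_inc <- swi * exp(-k_eff * Ltot)
    } else {
      dI <- numeric(grid$n_above)
      ground_inc <- swi
    }

    # within-canopy air temperature profile (lagged surface anchor)
    Ta_i <- Ta[i]
    Ta_z <- Ts_prev + (Ta_i - Ts_prev) * pmin(1, zc / max(h_top, 0.5))

    # dormancy switch per group
    open_g <- (eff > 1e-6) & (T5[i] > params$t_dorm) &
      (g_ever | phen > 1e-6)

    # leaf cells: one per (layer, group) with leaf area present
    LE_can <- 0; H_can <- 0; Rlw_can <- 0; SWabs_can <- 0
    A_tot <- 0; R_tot <- 0
    Tcan_eff <- Tcan_prev
    Tcan_ground4 <- Tcan_prev^4
    if (Ltot > 1e-9) {
      idx <- which(lad > 1e-8, arr.ind = TRUE)
      lay <- idx[, 1]; grp <- idx[, 2]
      cell_lad <- lad[idx]
      share <- cell_lad / lad_tot[lay]
      cell_abs_ground <- dI[lay] * share * (1 - g_refl[grp]) # W/m2 ground
      absPL <- cell_abs_ground / cell_lad                    # W/m2 leaf
      TaL <- Ta_z[lay]
      r_s <- ifelse(open_g[grp], params$r_stom_open, params$r_stom_closed)
      Tl <- .solve_leaf(absPL, TaL, e_air_all[i], gamma_all[i],
                        params$r_bl, r_s, params$emis_leaf, params$leaf_tol)
      hcl <- rhocp / params$r_bl
      Hpl <- hcl * (Tl - TaL)
      LEpl <- rhocp / gamma_all[i] * (.esat(Tl) - e_air_all[i]) /
        (params$r_bl + r_s)
      Rlwpl <- params$emis_leaf * sig * (Tl^4 - TaL^4)
      H_can <- sum(cell_lad * Hpl)
      LE_can <- sum(cell_lad * LEpl)
      Rlw_can <- sum(cell_lad * Rlwpl)
      SWabs_can <- sum(cell_abs_ground)
      Tcan_eff <- sum(cell_lad * Tl) / sum(cell_lad)
      # canopy emission seen by the ground: layers weighted by their leaf
      # area attenuated through the foliage below them
      L_below <- cumsum(lad_tot) - lad_tot
      w_gr <- cell_lad * exp(-k_eff * L_below[lay])
      Tcan_ground4 <- sum(w_gr * Tl^4) / sum(w_gr)
      # carbon exchange from the same leaf states
      par <- params$par_frac * absPL
      ft <- pmax(0, 1 - ((Tl - 293.15) / 20)^2)
      A_cell <- ifelse(open_g[grp],
                       g_cap[grp] * par / (par + params$par_half) * ft, 0)
      R_cell <- g_resp[grp] * params$q10^((Tl - params$t_resp_ref) / 10)
      A_tot <- sum(cell_lad * A_cell)
      R_tot <- sum(cell_lad * R_cell)
    }
    # buried leaf area respires at a reduced rate at the surface temperature
    if (any(buried_lai > 1e-9))
      R_tot <- R_tot + sum(g_resp * buried_lai) * params$buried_resp_frac *
        params$q10^((Ts_prev - params$t_resp_ref) / 10)

    # snowfall accumulates before the surface balance
    snowfall <- if (phase[i] == "snow") precip[i] else 0
    if (snowfall > 0) {
      swe <- swe + snowfall
      if (snowfall * 86400 / dt > 1) snow_age <- 0
    }
    snow_age <- snow_age + dt / 86400
    snow_now <- swe > params$swe_eps
    snow_depth <- swe / params$snow_density

    alb_g <- if (snow_now)
      params$snow_albedo_old +
        (params$snow_albedo_fresh - params$snow_albedo_old) *
        exp(-snow_age / params$snow_albedo_efold)
    else params$ground_albedo
    SWg_abs <- ground_inc * (1 - alb_g)

    tau <- exp(-k_eff * Ltot)
    LW_eff <- if (Ltot > 1e-3) tau * LWd[i] + (1 - tau) * sig * Tcan_ground4
      else LWd[i]

    canopy_buried <- Ltot <= 1e-3
    ra_s <- if (canopy_buried) ra_bare_v[i] else
      min(params$ra_surf_max, ra_can_v[i] * exp(params$shelter_coef * Ltot))
    r_evap <- if (snow_now) params$r_snow_evap else params$r_soil_evap
    R_G <- (if (snow_now) snow_depth / params$k_snow else 0) +
      (soil_dz[1] / 2) / params$soil_k

    Ts <- .solve_surface(SWg_abs, LW_eff, Ta_i, e_air_all[i], gamma_all[i],
                         ra_s, r_evap, Tsoil[1], R_G, params$emis_surf)
    M_avail <- 0
    # any stored snow (trace amounts included) caps the surface at the
    # melting point and routes the excess balance into melt energy
    if (swe > 0 && Ts > 273.15) {
      Ts <- 273.15
      M_avail <- SWg_abs + params$emis_surf * (LW_eff - sig * Ts^4) -
        rhocp * (Ts - Ta_i) / ra_s -
        rhocp / gamma_all[i] * (.esat(Ts) - e_air_all[i]) /
          (ra_s + r_evap) - (Ts - Tsoil[1]) / R_G
    }
    melt <- 0; E_used <- 0; surplus <- 0
    if (swe > 0 && M_avail > 0) {
      potential <- M_avail * dt / cs$lambda_f
      melt <- min(swe, potential)
      E_used <- melt * cs$lambda_f / dt
      surplus <- M_avail - E_used
      swe <- swe - melt
    }
    Hs <- rhocp * (Ts - Ta_i) / ra_s
    LEs <- rhocp / gamma_all[i] * (.esat(Ts) - e_air_all[i]) / (ra_s + r_evap)
    G <- (Ts - Tsoil[1]) / R_G + surplus

    # soil column update (explicit conduction, zero-flux bottom)
    Tn <- Tsoil
    fluxes <- params$soil_k * (Tn[-12] - Tn[-1]) /
      ((soil_dz[-12] + soil_dz[-1]) / 2)
    Tsoil <- Tn + (c(G, fluxes) - c(fluxes, 0)) * dt /
      (params$soil_C * soil_dz)

    LWnet_s <- params$emis_surf * (LW_eff - sig * Ts^4)
    Rn <- SWabs_can + SWg_abs + LWnet_s - Rlw_can
    LEt <- LE_can + LEs
    Ht <- H_can + Hs
    closure <- Rn - LEt - Ht - G - E_used

    O[i, ] <- c(Ts, Tcan_eff, swe, swe / params$snow_density, Ltot, LEt, Ht,
                Rn, G, E_used, ground_inc, closure, A_tot, R_tot, Tsoil[1],
                snowfall, melt)
    Ts_prev <- Ts
    Tcan_prev <- Tcan_eff
  }

  out <- data.frame(timestamp = forcing$timestamp, doy = doy, year = yr,
                    T_air = Ta, SW_in = SW, O, check.names = FALSE)
  out$co2_net <- out$A - out$R_a
  attr(out, "scenario") <- scenario
  attr(out, "params") <- params
  class(out) <- c("ecosystem_run", "data.frame")
  out
}
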