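# Synthetic half-hourly meteorological forcing for treeline climate archetypes.
#
# The generator emulates the statistical structure of flux-tower driver records
# (seasonal + diurnal cycles, autocorrelated weather anomalies, two-state
# precipitation occurrence) so that no data accession is required. All
# randomness is controlled by a single master seed with per-variable
# substreams.

#' Define a climate archetype
#'
#' A climate archetype is the parameter set from which synthetic half-hourly
#' forcing is generated: site geometry (latitude, elevation), the mean annual
#' temperature and the amplitudes of its seasonal and diurnal cycles,
#' precipitation climatology, and cloud persistence.
#'
#' @param name label for the archetype.
#' @param latitude degrees north, in \code{[-90, 90]}.
#' @param elevation metres above sea level (sets the constant air pressure).
#' @param mean_annual_temp mean annual air temperature, K.
#' @param seasonal_amplitude amplitude of the seasonal temperature sinusoid, K
#'   (peak deviation from the annual mean; must be > 0).
#' @param diurnal_amplitude peak-to-trough amplitude of the diurnal
#'   temperature cycle, K (>= 0).
#' @param annual_precip expected annual precipitation, mm water equivalent.
#' @param wet_day_fraction stationary probability that a day is wet, in (0,1).
#' @param cloud_persistence lag-1 autocorrelation of the cloudiness process at
#'   the half-hourly step, in \code{[0, 1)}.
#' @param snow_threshold_temp air temperature below which precipitation falls
#'   as snow, K.
#' @return an object of class \code{climate_archetype}.
#' @seealso [archetype_defaults()] for the four built-in treeline archetypes.
#' @export
climate_archetype <- function(name, latitude, elevation, mean_annual_temp,
                              seasonal_amplitude, diurnal_amplitude,
                              annual_precip, wet_day_fraction,
                              cloud_persistence, snow_threshold_temp = 274.15) {
  stopifnot(.is_number(latitude), .is_number(elevation),
            .is_number(mean_annual_temp), .is_number(seasonal_amplitude),
            .is_number(diurnal_amplitude), .is_number(annual_precip),
            .is_number(wet_day_fraction), .is_number(cloud_persistence),
            .is_number(snow_threshold_temp))
  if (latitude < -90 || latitude > 90)
    stop("latitude must be in [-90, 90]")
  if (seasonal_amplitude <= 0) stop("seasonal_amplitude must be > 0")
  if (diurnal_amplitude < 0) stop("diurnal_amplitude must be >= 0")
  if (annual_precip <= 0) stop("annual_precip must be > 0")
  if (wet_day_fraction <= 0 || wet_day_fraction >= 1)
    stop("wet_day_fraction must be in (0, 1)")
  if (cloud_persistence < 0 || cloud_persistence >= 1)
    stop("cloud_persistence must be in [0, 1)")
  structure(list(name = name, latitude = latitude, elevation = elevation,
                 mean_annual_temp = mean_annual_temp,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_amplitude = diurnal_amplitude,
                 annual_precip = annual_precip,
                 wet_day_fraction = wet_day_fraction,
                 cloud_persistence = cloud_persistence,
                 snow_threshold_temp = snow_threshold_temp),
            class = "climate_archetype")
}

#' Built-in treeline climate archetypes
#'
#' Parameter sets that stand in for the climates of the paired flux-tower
#' sites: a subalpine forest belt and the alpine zone above it (Rocky
#' Mountains / Alps style), and a sub-Arctic forest-tundra and Arctic tundra
#' pair (taiga-tundra ecotone style). Values are plausible climatologies for
#' such sites, not measurements.
#'
#' @param name one of \code{"subalpine"}, \code{"alpine"}, \code{"subarctic"},
#'   \code{"arctic"}.
#' @return a [climate_archetype()].
#' @export
archetype_defaults <- function(name = c("subalpine", "alpine", "subarctic",
                                        "arctic")) {
  name <- match.arg(name)
  switch(name,
    subalpine = climate_archetype("subalpine", latitude = 40.0,
      elevation = 3050, mean_annual_temp = 274.7, seasonal_amplitude = 9,
      diurnal_amplitude = 9, annual_precip = 800, wet_day_fraction = 0.35,
      cloud_persistence = 0.92),
    alpine = climate_archetype("alpine", latitude = 40.05,
      elevation = 3480, mean_annual_temp = 271.7, seasonal_amplitude = 10,
      diurnal_amplitude = 8, annual_precip = 950, wet_day_fraction = 0.40,
      cloud_persistence = 0.92),
    subarctic = climate_archetype("subarctic", latitude = 68.32,
      elevation = 80, mean_annual_temp = 264.7, seasonal_amplitude = 20,
      diurnal_amplitude = 5, annual_precip = 300, wet_day_fraction = 0.30,
      cloud_persistence = 0.90),
    arctic = climate_archetype("arctic", latitude = 68.75,
      elevation = 85, mean_annual_temp = 264.2, seasonal_amplitude = 21,
      diurnal_amplitude = 5, annual_precip = 250, wet_day_fraction = 0.28,
      cloud_persistence = 0.90))
}

#' Solar elevation angle
#'
#' Standard declination / hour-angle geometry. Timestamps are interpreted as
#' local solar time (the synthetic calendar places all archetypes at solar
#' longitude zero, so clock time equals solar time).
#'
#' @param latitude degrees north, in \code{[-90, 90]}.
#' @param timestamp a \code{POSIXct} vector (UTC).
#' @return solar elevation in radians, in \code{[-pi/2, pi/2]}.
#' @export
solar_elevation <- function(latitude, timestamp) {
  if (!is.numeric(latitude) || any(latitude < -90 | latitude > 90))
    stop("latitude must be in [-90, 90]")
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  .solar_elevation_doy(latitude, doy, hour)
}

# doy/hour form used internally by the generator (no POSIX conversion cost).
.solar_elevation_doy <- function(latitude, doy, hour) {
  phi <- latitude * pi / 180
  decl <- -0.4092797 * cos(2 * pi * (doy + 10) / 365) # 23.44 deg in rad
  hang <- (hour - 12) / 12 * pi
  asin(pmin(1, pmax(-1,
    sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(hang))))
}

#' Partition precipitation phase
#'
#' Precipitation falls as snow strictly below the threshold temperature; a
#' value exactly at the threshold is rain (fixed convention).
#'
#' @param T_air air temperature, K (vectorized).
#' @param threshold phase-transition temperature, K.
#' @return character vector, \code{"snow"} or \code{"rain"}.
#' @export
partition_precip <- function(T_air, threshold) {
  ifelse(T_air < threshold, "snow", "rain")
}

# AR(1) series with stationary sd `sd_stat` and lag-1 autocorrelation `phi`.
.ar1 <- function(n, phi, sd_stat) {
  innov <- stats::rnorm(n, sd = sd_stat * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Generate synthetic half-hourly forcing
#'
#' Builds a seeded, reproducible half-hourly meteorological driver record for
#' \code{n_years} 365-day years. Air temperature is mean + seasonal sinusoid +
#' diurnal sinusoid + an AR(1) anomaly; shortwave is a clear-sky flux
#' (top-of-atmosphere times bulk transmissivity 0.75) reduced by an
#' autocorrelated cloud factor; longwave follows a bulk effective emissivity
#' increasing with cloudiness (Brutsaert clear-sky base); precipitation uses a
#' two-state wet/dry day occurrence chain with exponential daily amounts
#' spread evenly over the wet day. Temperature, cloud, wind, humidity and
#' precipitation use independent random substreams derived from the master
#' seed.
#'
#' @param archetype a [climate_archetype()].
#' @param n_years number of 365-day years (>= 1).
#' @param seed integer master seed.
#' @param start_year first calendar year of the synthetic record (the
#'   365-day model calendar drops Dec 31 of leap years).
#' @return a \code{data.frame} of class \code{forcing_series} with columns
#'   \code{timestamp, SW_in, LW_in, T_air, precip, phase, wind, RH, pressure,
#'   cloud} plus the model-calendar \code{doy} (1..365) and \code{year}
#'   (1..n_years); the generating archetype is attached as attribute
#'   \code{"archetype"}.
#' @export
generate_forcing <- function(archetype, n_years = 1, seed = 1,
                             start_year = 2001) {
  stopifnot(inherits(archetype, "climate_archetype"))
  if (!.is_number(n_years) || n_years < 1 || n_years != round(n_years))
    stop("n_years must be a positive whole number")
  a <- archetype
  steps_day <- 48L
  n_days <- 365L * n_years
  n <- n_days * steps_day

  # independent substreams per variable from the master seed
  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max - 1L, 6L)

  day_index <- rep(seq_len(n_days), each = steps_day)
  doy <- (day_index - 1L) %% 365L + 1L
  year <- (day_index - 1L) %/% 365L + 1L
  hour <- rep(seq(0, 23.5, by = 0.5), n_days)

  # model calendar: continuous half-hourly instants; the 365-day model year
  # is carried explicitly in the doy/year columns
  origin <- as.POSIXct(sprintf("%d-01-01 00:00:00", start_year), tz = "UTC")
  timestamp <- origin + 1800 * (0:(n - 1))

  # air temperature: mean + seasonal + diurnal + AR(1) anomaly
  set.seed(sub[1])
  t_anom <- .ar1(n, phi = 0.993, sd_stat = 3) # ~3-day decorrelation
  T_air <- a$mean_annual_temp +
    a$seasonal_amplitude * cos(2 * pi * (doy - 202) / 365) +
    (a$diurnal_amplitude / 2) * cos(2 * pi * (hour - 14.5) / 24) +
    t_anom

  # cloudiness: probit-transformed AR(1), in [0, 1]
  set.seed(sub[2])
  z_cloud <- .ar1(n, phi = a$cloud_persistence, sd_stat = 1)
  cloud <- stats::pnorm(z_cloud)

  # shortwave: TOA x bulk transmissivity 0.75 x cloud reduction
  elev <- .solar_elevation_doy(a$latitude, doy, hour)
  sw_clear <- .const$S0 * pmax(0, sin(elev)) * 0.75
  SW_in <- sw_clear * (1 - 0.7 * cloud)

  # longwave: Brutsaert clear-sky emissivity, enhanced by cloudiness
  set.seed(sub[3])
  rh_noise <- .ar1(n, phi = 0.98, sd_stat = 8)
  RH <- pmin(100, pmax(5, 45 + 45 * cloud + rh_noise))
  e_air <- RH / 100 * .esat(T_air) # kPa
  emis <- pmin(1, 1.24 * (10 * e_air / T_air)^(1 / 7) * (1 + 0.22 * cloud^2))
  LW_in <- emis * .const$sigma * T_air^4

  # wind: Weibull marginal over an AR(1) driver
  set.seed(sub[4])
  z_wind <- .ar1(n, phi = 0.97, sd_stat = 1)
  wind <- stats::qweibull(stats::pnorm(z_wind), shape = 2, scale = 3.5)

  # precipitation: two-state daily occurrence chain, exponential amounts
  set.seed(sub[5])
  p_ww <- 0.65
  p_dw <- a$wet_day_fraction * (1 - p_ww) / (1 - a$wet_day_fraction)
  u <- stats::runif(n_days)
  wet <- logical(n_days)
  wet[1] <- u[1] < a$wet_day_fraction
  for (d in 2:n_days) wet[d] <- u[d] < (if (wet[d - 1]) p_ww else p_dw)
  set.seed(sub[6])
  amounts <- numeric(n_days)
  mean_amt <- a$annual_precip / (365 * a$wet_day_fraction)
  amounts[wet] <- stats::rexp(sum(wet), rate = 1 / mean_amt)
  precip <- amounts[day_index] / steps_day

  pressure <- rep(101.325 * exp(-a$elevation / 8434), n)
  phase <- partition_precip(T_air, a$snow_threshold_temp)
  phase[precip <= 0] <- "rain" # phase is meaningless without precipitation

  out <- data.frame(timestamp = timestamp, SW_in = SW_in, LW_in = LW_in,
                    T_air = T_air, precip = precip, phase = phase,
                    wind = wind, RH = RH, pressure = pressure, cloud = cloud,
                    doy = doy, year = year)
  attr(out, "archetype") <- a
  class(out) <- c("forcing_series", "data.frame")
  out
}

# Validate the structural invariants of a forcing series.
.validate_forcing <- function(x) {
  need <- c("timestamp", "SW_in", "LW_in", "T_air", "precip", "phase",
            "wind", "RH", "pressure")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("forcing series missing columns: ",
                         paste(miss, collapse = ", "))
  dt <- diff(as.numeric(x$timestamp))
  if (any(dt != 1800)) stop("timestamps must be strictly increasing at 1800 s")
  if (any(x$SW_in < 0)) stop("SW_in must be >= 0")
  if (any(x$precip < 0)) stop("precip must be >= 0")
  if (any(x$RH < 0 | x$RH > 100)) stop("RH must be in [0, 100]")
  invisible(TRUE)
}

#' Write / read a forcing series as delimited text
#'
#' Plain tab-separated text with a header; ISO-8601 UTC timestamps. The
#' generating archetype is not serialized.
#'
#' @param x a \code{forcing_series}.
#' @param path file path.
#' @return \code{read_forcing} returns a \code{forcing_series}.
#' @export
write_forcing <- function(x, path) {
  stopifnot(inherits(x, "forcing_series"))
  out <- as.data.frame(x)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_forcing <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  x$timestamp <- as.POSIXct(x$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  class(x) <- c("forcing_series", "data.frame")
  .validate_forcing(x)
  x
}

#' Read a climate archetype from a key: value config file
#'
#' One \code{key: value} pair per line; \code{#} starts a comment. All keys of
#' [climate_archetype()] are required except \code{snow_threshold_temp}.
#'
#' @param path file path.
#' @return a [climate_archetype()].
#' @export
read_archetype <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) stop("malformed archetype config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = ":"), ""))
  named <- stats::setNames(as.list(vals), keys)
  num <- function(k, default = NULL) {
    if (is.null(named[[k]])) {
      if (is.null(default)) stop("archetype config missing key: ", k)
      return(default)
    }
    v <- suppressWarnings(as.numeric(named[[k]]))
    if (is.na(v)) stop("archetype config key not numeric: ", k)
    v
  }
  climate_archetype(
    name = named[["name"]] %||% "custom",
    latitude = num("latitude"), elevation = num("elevation"),
    mean_annual_temp = num("mean_annual_temp"),
    seasonal_amplitude = num("seasonal_amplitude"),
    diurnal_amplitude = num("diurnal_amplitude"),
    annual_precip = num("annual_precip"),
    wet_day_fraction = num("wet_day_fraction"),
    cloud_persistence = num("cloud_persistence"),
    snow_threshold_temp = num("snow_threshold_temp", 274.15))
}
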