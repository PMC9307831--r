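# Leaf CO2 exchange: light- and temperature-limited photosynthesis gated by a
# winter/snow dormancy switch, against Q10 above-ground autotrophic
# respiration that never switches off while leaf area is present. The
# asymmetry between the two is what turns an extended snow season into an
# annual carbon deficit.

#' Winter/snow dormancy switch for photosynthesis
#'
#' Stomata (and with them photosynthesis) are open only when the layer is not
#' buried by snow, the trailing 5-day mean air temperature exceeds +5 C, and
#' the group is inside its phenology window. Respiration is not affected by
#' this switch.
#'
#' @param T_air_mean5 trailing 5-day mean air temperature, K.
#' @param snow_depth snow depth, m.
#' @param layer_top height of the top of the canopy element, m (the element
#'   is buried when the snow surface reaches it).
#' @param in_window logical; whether the group is inside its phenology window
#'   (always \code{TRUE} for evergreens).
#' @param params [physics_params()].
#' @return logical.
#' @export
dormancy_switch <- function(T_air_mean5, snow_depth, layer_top,
                            in_window = TRUE, params = physics_params()) {
  (snow_depth < layer_top) & (T_air_mean5 > params$t_dorm) & in_window
}

#' Leaf photosynthesis: saturating light response with temperature envelope
#'
#' Zero when dormant; otherwise a rectangular-hyperbola response to absorbed
#' PAR capped at \code{capacity}, multiplied by a symmetric temperature
#' response that peaks at 20 C and is zero at or below 0 C and at or above
#' 40 C.
#'
#' @param absorbed_PAR absorbed photosynthetically active radiation, W/m2
#'   leaf (>= 0).
#' @param T_leaf leaf temperature, K.
#' @param capacity light-saturated uptake, umol CO2 m-2 leaf s-1.
#' @param open logical; output of [dormancy_switch()].
#' @param par_half half-saturation absorbed PAR, W/m2.
#' @return CO2 uptake, umol m-2 leaf s-1.
#' @export
leaf_photosynthesis <- function(absorbed_PAR, T_leaf, capacity, open = TRUE,
                                par_half = 100) {
  if (any(absorbed_PAR < 0)) stop("absorbed_PAR must be >= 0")
  ft <- pmax(0, 1 - ((T_leaf - 293.15) / 20)^2)
  ifelse(open, capacity * absorbed_PAR / (absorbed_PAR + par_half) * ft, 0)
}

#' Above-ground autotrophic respiration (Q10)
#'
#' \code{R = base * LAI * Q10^((T_leaf - 283.15)/10)}. Respiration continues
#' regardless of dormancy; snow-buried leaf area respires at a reduced rate
#' (see [physics_params()]).
#'
#' @param T_leaf leaf temperature, K.
#' @param base respiration at the 10 C reference, umol m-2 leaf s-1.
#' @param LAI_layer leaf area in the layer, m2/m2.
#' @param q10,t_ref Q10 factor and reference temperature.
#' @return respiration, umol CO2 m-2 ground s-1.
#' @export
autotrophic_respiration <- function(T_leaf, base, LAI_layer, q10 = 2,
                                    t_ref = 283.15) {
  base * LAI_layer * q10^((T_leaf - t_ref) / 10)
}

#' Annual net leaf CO2 flux
#'
#' Time integral of photosynthesis minus above-ground autotrophic respiration
#' over each complete half-hourly year; positive values are net uptake.
#'
#' @param x a \code{data.frame} with columns \code{A} and \code{R_a} (umol
#'   CO2 m-2 s-1) and a \code{year} column (for example an
#'   \code{ecosystem_run}).
#' @param dt step length, s.
#' @return named numeric vector, one value per year, mol CO2 m-2 yr-1.
#' @export
annual_net_co2 <- function(x, dt = 1800) {
  stopifnot(all(c("A", "R_a", "year") %in% names(x)))
  steps_year <- 365L * 86400L / dt
  counts <- table(x$year)
  if (any(counts != steps_year))
    stop("annual_net_co2 requires complete years (",
         steps_year, " steps each); got ",
         paste(counts, collapse = ", "))
  net <- (x$A - x$R_a) * dt * 1e-6 # umol -> mol per step
  tapply(net, x$year, sum)
}
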