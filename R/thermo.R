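# Thermodynamic diagnostics: the resultant temperature gradient, signed
# ecosystem work and its four-case classification, inversion episodes, daily
# work series, work-gradient-LAI summaries and the feasibility verdicts.

#' Resultant temperature gradient
#'
#' \code{(T_air - T_surf) / h_e}: the vertical temperature gradient from the
#' earth (or snow) surface to the air above the canopy, normalized by the
#' ecosystem height. Positive values are temperature inversions.
#'
#' @param T_air air temperature above the canopy, K (vectorized).
#' @param T_surf surface temperature, K.
#' @param h_e ecosystem height, m (> 0).
#' @return gradient, K/m.
#' @export
temperature_gradient <- function(T_air, T_surf, h_e) {
  if (!.is_number(h_e) || h_e <= 0) stop("h_e must be > 0")
  (T_air - T_surf) / h_e
}

#' Signed ecosystem work flux
#'
#' \code{Work = (LE + H) * -sign(delta_T)}: the net turbulent heat export is
#' positive work when it moves heat from high to low temperature (down the
#' resultant gradient) and negative work when it opposes the gradient. At
#' \code{delta_T = 0} the sign is zero and so is the work.
#'
#' @param LE,H latent and sensible heat flux at the canopy top, W/m2
#'   (positive upward).
#' @param delta_T \code{T_air - T_surf}, K.
#' @return work, W/m2.
#' @export
work_flux <- function(LE, H, delta_T) {
  (LE + H) * -sign(delta_T)
}

#' Classify the work regime
#'
#' Four cases by the sign of the resultant gradient and of the net heat
#' loss/gain: (1) surface warmer, net heat loss -> positive work; (2) surface
#' warmer, net heat gain -> negative work; (3) inversion, net heat gain ->
#' positive work; (4) inversion (typically snowmelt), net heat loss ->
#' negative work. A zero gradient or a zero net flux is outside the four
#' cases and returns \code{NA} ("neutral").
#'
#' @param net_heat \code{LE + H}, W/m2.
#' @param delta_T \code{T_air - T_surf}, K.
#' @return integer vector in \code{1:4}, \code{NA} for neutral records.
#' @export
classify_work_case <- function(net_heat, delta_T) {
  out <- rep(NA_integer_, length(delta_T))
  out[delta_T < 0 & net_heat > 0] <- 1L
  out[delta_T < 0 & net_heat < 0] <- 2L
  out[delta_T > 0 & net_heat < 0] <- 3L
  out[delta_T > 0 & net_heat > 0] <- 4L
  out
}

#' Thermodynamic record of a simulation run
#'
#' Joins the surface/flux state of an [simulate_ecosystem()] run into the
#' per-timestep thermodynamic diagnostics.
#'
#' @param run an \code{ecosystem_run}.
#' @param h_e ecosystem height, m; defaults to the scenario's \code{h_e}.
#' @return \code{data.frame} with \code{timestamp, doy, year, delta_T,
#'   gradient, net_heat, work, case, swe, lai}.
#' @export
thermo_record <- function(run, h_e = NULL) {
  stopifnot(inherits(run, "ecosystem_run"))
  h_e <- h_e %||% attr(run, "scenario")$h_e
  delta_T <- run$T_air - run$T_surf
  net <- run$LE + run$H
  data.frame(timestamp = run$timestamp, doy = run$doy, year = run$year,
             delta_T = delta_T,
             gradient = temperature_gradient(run$T_air, run$T_surf, h_e),
             net_heat = net,
             work = work_flux(run$LE, run$H, delta_T),
             case = classify_work_case(net, delta_T),
             swe = run$swe, lai = run$lai)
}

#' Daily mean work
#'
#' Arithmetic mean of the 48 half-hourly work values of each calendar day;
#' partial days are dropped with a warning.
#'
#' @param thermo output of [thermo_record()] (needs \code{timestamp},
#'   \code{work}; \code{doy}/\code{year} are carried along if present).
#' @return \code{data.frame} with one row per complete day: \code{date},
#'   \code{work} and, when available, \code{doy} and \code{year}.
#' @export
daily_mean_work <- function(thermo) {
  day <- as.Date(thermo$timestamp, tz = "UTC")
  counts <- table(day)
  complete <- names(counts)[counts == 48L]
  if (length(complete) < length(counts))
    warning(sum(counts != 48L), " partial day(s) excluded")
  keep <- day %in% as.Date(complete)
  d <- day[keep]
  out <- data.frame(date = as.Date(names(tapply(thermo$work[keep], d, mean))),
                    work = as.numeric(tapply(thermo$work[keep], d, mean)))
  if (!is.null(thermo$doy)) {
    out$doy <- as.numeric(tapply(thermo$doy[keep], d, `[`, 1L))
    out$year <- as.numeric(tapply(thermo$year[keep], d, `[`, 1L))
  }
  out[order(out$date), , drop = FALSE]
}

#' Temperature-inversion episodes
#'
#' Maximal runs of consecutive timesteps with a positive resultant gradient,
#' annotated with duration, mean work over the episode and whether snow was
#' present at any step.
#'
#' @param thermo output of [thermo_record()] (chronological).
#' @param swe optional snow water equivalent series overriding
#'   \code{thermo$swe}.
#' @return \code{data.frame} with one row per episode: \code{start},
#'   \code{end}, \code{duration_hours}, \code{mean_work}, \code{snow_present}.
#' @export
inversion_episodes <- function(thermo, swe = NULL) {
  swe <- swe %||% thermo$swe %||% rep(0, nrow(thermo))
  inv <- thermo$gradient > 0
  r <- rle(inv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  if (!length(sel))
    return(data.frame(start = thermo$timestamp[0], end = thermo$timestamp[0],
                      duration_hours = numeric(0), mean_work = numeric(0),
                      snow_present = logical(0)))
  data.frame(
    start = thermo$timestamp[starts[sel]],
    end = thermo$timestamp[ends[sel]],
    duration_hours = r$lengths[sel] * 0.5,
    mean_work = vapply(sel, function(j)
      mean(thermo$work[starts[j]:ends[j]]), 0),
    snow_present = vapply(sel, function(j)
      any(swe[starts[j]:ends[j]] > 0), TRUE))
}

#' Longest run of negative-work days
#'
#' The longest run of consecutive days whose daily mean work is negative,
#' flagged when it reaches the persistence threshold.
#'
#' @param daily_work output of [daily_mean_work()] (or any data.frame with a
#'   \code{work} column in day order).
#' @param threshold_days persistence threshold, days (>= 1; default 14).
#' @return list with \code{longest_run} (days), \code{total_negative_days}
#'   and \code{flagged}.
#' @export
negative_work_persistence <- function(daily_work, threshold_days = 14) {
  if (!.is_number(threshold_days) || threshold_days < 1)
    stop("threshold_days must be >= 1")
  neg <- daily_work$work < 0
  longest <- if (!any(neg)) 0L else {
    r <- rle(neg)
    max(r$lengths[r$values])
  }
  list(longest_run = as.integer(longest),
       total_negative_days = sum(neg),
       flagged = longest >= threshold_days)
}

#' Binned work versus gradient versus leaf area summary
#'
#' Bins the half-hourly records by the negative of the resultant gradient
#' (plotting convention: positive x means the surface is warmer than the air)
#' and by total LAI, reporting per-bin counts and mean work.
#'
#' @param thermo output of [thermo_record()].
#' @param lai total LAI series aligned with \code{thermo} (defaults to
#'   \code{thermo$lai}).
#' @param gradient_breaks monotone bin edges on \code{-gradient}, K/m.
#' @param lai_breaks monotone bin edges on LAI.
#' @return \code{data.frame} with \code{minus_gradient_bin}, \code{lai_bin}
#'   (bin midpoints), \code{n}, \code{mean_work}.
#' @export
work_gradient_summary <- function(thermo, lai = NULL, gradient_breaks = NULL,
                                  lai_breaks = NULL) {
  lai <- lai %||% thermo$lai
  if (length(lai) != nrow(thermo))
    stop("lai series must align with the thermo record")
  mg <- -thermo$gradient
  gradient_breaks <- gradient_breaks %||% {
    r <- range(mg)
    seq(floor(r[1] / 0.25) * 0.25, ceiling(r[2] / 0.25) * 0.25 + 0.25,
        by = 0.25)
  }
  lai_breaks <- lai_breaks %||% seq(0, max(lai) + 1, by = 1)
  if (is.unsorted(gradient_breaks, strictly = TRUE) ||
      is.unsorted(lai_breaks, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  gb <- cut(mg, gradient_breaks, include.lowest = TRUE)
  lb <- cut(lai, lai_breaks, include.lowest = TRUE)
  agg <- stats::aggregate(thermo$work, list(g = gb, l = lb),
                          function(w) c(n = length(w), mean = mean(w)))
  mids <- function(breaks) (breaks[-1] + breaks[-length(breaks)]) / 2
  data.frame(
    minus_gradient_bin = mids(gradient_breaks)[as.integer(agg$g)],
    lai_bin = mids(lai_breaks)[as.integer(agg$l)],
    n = as.integer(agg$x[, "n"]),
    mean_work = agg$x[, "mean"])
}

#' Thermodynamic feasibility verdict for a scenario
#'
#' A scenario is infeasible when its daily mean work stays negative for at
#' least \code{threshold_days} consecutive days, or when its mean annual net
#' leaf CO2 flux is negative. A feasible scenario whose net CO2 gain is
#' positive but below its paired existing-vegetation scenario is
#' "disadvantaged".
#'
#' @param daily_work output of [daily_mean_work()] for the scenario
#'   (post-spin-up years).
#' @param annual_co2 per-year net leaf CO2 flux, mol m-2 yr-1 (see
#'   [annual_net_co2()]).
#' @param paired_annual_co2 the same for the paired existing-vegetation
#'   scenario, or \code{NULL} when no pair exists.
#' @param threshold_days negative-work persistence threshold (default 14).
#' @param label scenario label carried into the report.
#' @return list of class \code{feasibility_report}: the two verdicts, the
#'   run statistics and the overall status (\code{"feasible"},
#'   \code{"infeasible"} or \code{"disadvantaged"}).
#' @export
assess_feasibility <- function(daily_work, annual_co2,
                               paired_annual_co2 = NULL, threshold_days = 14,
                               label = "scenario") {
  pers <- negative_work_persistence(daily_work, threshold_days)
  verdict_work <- pers$flagged
  mean_co2 <- mean(annual_co2)
  verdict_co2 <- mean_co2 < 0
  co2_below_pair <- if (is.null(paired_annual_co2)) NA else
    mean_co2 < mean(paired_annual_co2)
  overall <- if (verdict_work || verdict_co2) "infeasible" else
    if (isTRUE(co2_below_pair)) "disadvantaged" else "feasible"
  structure(list(label = label,
                 longest_negative_work_run = pers$longest_run,
                 negative_work_days_total = pers$total_negative_days,
                 threshold_days = threshold_days,
                 annual_net_co2 = annual_co2,
                 mean_annual_net_co2 = mean_co2,
                 verdict_negative_work = verdict_work,
                 verdict_co2 = verdict_co2,
                 co2_below_pair = co2_below_pair,
                 overall = overall),
            class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat(sprintf("Feasibility report: %s\n", x$label))
  cat(sprintf("  longest negative-work run : %d days (threshold %d)\n",
              x$longest_negative_work_run, x$threshold_days))
  cat(sprintf("  negative-work days total  : %d\n",
              x$negative_work_days_total))
  cat(sprintf("  mean annual net leaf CO2  : %.2f mol m-2 yr-1\n",
              x$mean_annual_net_co2))
  cat(sprintf("  verdicts: negative work = %s, CO2 loss = %s\n",
              x$verdict_negative_work, x$verdict_co2))
  cat(sprintf("  overall : %s\n", toupper(x$overall)))
  invisible(x)
}
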