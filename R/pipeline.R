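# Orchestration: build the four scenarios of a site pair, run spin-up plus
# study years under shared forcing, and produce the comparison and
# feasibility reports.

#' Configuration for a site-pair run
#'
#' @param site_pair \code{"IT"}, \code{"US"} or \code{"CA"}.
#' @param n_years total simulated years per scenario (>= 2, so that at least
#'   one post-spin-up year remains).
#' @param spinup_years years discarded as spin-up (default 1).
#' @param seed master seed; forcing for the two sites of the pair uses
#'   substreams derived from it.
#' @param threshold_days negative-work persistence threshold, days.
#' @param params [physics_params()].
#' @param out_dir optional directory for delimited-text outputs.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(site_pair = c("US", "IT", "CA"), n_years = 3,
                       spinup_years = 1, seed = 1, threshold_days = 14,
                       params = physics_params(), out_dir = NULL) {
  site_pair <- match.arg(site_pair)
  if (!.is_number(n_years) || n_years < 2)
    stop("n_years must be >= 2 (at least one post-spin-up year)")
  if (spinup_years < 1 || spinup_years >= n_years)
    stop("spinup_years must be >= 1 and < n_years")
  structure(list(site_pair = site_pair, n_years = n_years,
                 spinup_years = spinup_years, seed = as.integer(seed),
                 threshold_days = threshold_days, params = params,
                 out_dir = out_dir),
            class = "run_config")
}

# Melt-out day of the winter snowpack: for each year, the last day of the
# continuous snow-cover spell that contains day 60 (a day is snow-covered
# when snow is present at every step). Years without snow cover on day 60
# report 0; a spell lasting to the year end reports 365.
.last_snow_doy <- function(run, swe_eps = 0.1) {
  vapply(split(seq_len(nrow(run)), run$year), function(ii) {
    covered <- tapply(run$swe[ii] > swe_eps, run$doy[ii], all)
    covered <- as.logical(covered[order(as.integer(names(covered)))])
    if (length(covered) < 60 || !covered[60]) return(0)
    after <- which(!covered & seq_along(covered) > 60)
    if (!length(after)) length(covered) else min(after) - 1
  }, 0)
}

#' Run all four scenarios of a treeline site pair
#'
#' Generates forcing for the two sites of the pair (independent substreams of
#' the master seed), runs X-For and X-Un under the below-treeline forcing and
#' X-Alp/Arc and X-Tr under the above-treeline forcing (a counterfactual
#' shares its site's forcing object bit-for-bit), discards the spin-up years
#' and derives per-scenario thermodynamic and carbon diagnostics plus
#' feasibility reports (X-Tr is paired with the existing X-Alp/Arc, X-Un with
#' X-For).
#'
#' @param config a [run_config()].
#' @return list of class \code{site_pair_result} with \code{bundles} (one per
#'   scenario: run, thermo record, daily work, episodes, annual CO2,
#'   feasibility report), \code{comparison} (see [compare_scenarios()]),
#'   \code{forcing} and the \code{config}.
#' @export
run_site_pair <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L)
  pair <- config$site_pair
  ps <- .pair_sites(pair)
  forcing <- list(
    below = generate_forcing(archetype_defaults(ps$below_arch),
                             n_years = config$n_years, seed = sub[1]),
    above = generate_forcing(archetype_defaults(ps$above_arch),
                             n_years = config$n_years, seed = sub[2]))
  scenarios <- scenario_set(pair)
  bundles <- lapply(scenarios, function(sc) {
    side <- attr(sc, "forcing_side")
    run <- simulate_ecosystem(forcing[[side]], sc, config$params)
    post <- run[run$year > config$spinup_years, , drop = FALSE]
    attr(post, "scenario") <- sc
    class(post) <- class(run)
    th <- thermo_record(post, h_e = sc$h_e)
    dw <- daily_mean_work(th)
    list(scenario = sc, forcing_side = side, run = post, thermo = th,
         daily_work = dw, episodes = inversion_episodes(th),
         annual_co2 = annual_net_co2(post),
         last_snow_doy = .last_snow_doy(post,
                                        config$params$swe_eps %||% 0.1))
  })
  # feasibility with pairing: counterfactual vs existing vegetation
  existing_above <- grep("-(Alp|Arc)$", names(bundles), value = TRUE)
  pairing <- list()
  pairing[[paste0(pair, "-Tr")]] <- existing_above
  pairing[[paste0(pair, "-Un")]] <- paste0(pair, "-For")
  for (lab in names(bundles)) {
    paired <- pairing[[lab]]
    bundles[[lab]]$feasibility <- assess_feasibility(
      bundles[[lab]]$daily_work, bundles[[lab]]$annual_co2,
      paired_annual_co2 = if (!is.null(paired))
        bundles[[paired]]$annual_co2 else NULL,
      threshold_days = config$threshold_days, label = lab)
  }
  comparison <- compare_scenarios(bundles)
  res <- structure(list(bundles = bundles, comparison = comparison,
                        forcing = forcing, config = config),
                   class = "site_pair_result")
  if (!is.null(config$out_dir)) write_site_pair(res, config$out_dir)
  res
}

#' Compare the scenario bundles of one site pair
#'
#' One row per scenario: mean annual net CO2, negative-work statistics,
#' snowpack melt-out day, annual mean LAI, work magnitudes and the
#' feasibility verdicts. The schema is fixed across runs.
#'
#' @param bundles the \code{bundles} element of a [run_site_pair()] result
#'   (at least two, all from the same site pair).
#' @return \code{data.frame}, one row per scenario.
#' @export
compare_scenarios <- function(bundles) {
  if (length(bundles) < 2) stop("need at least two scenario bundles")
  pairs <- unique(vapply(bundles, function(b)
    sub("-.*$", "", b$scenario$label), ""))
  if (length(pairs) != 1) stop("bundles mix site pairs: ",
                               paste(pairs, collapse = ", "))
  rows <- lapply(bundles, function(b) {
    th <- b$thermo
    pers <- negative_work_persistence(b$daily_work,
                                      b$feasibility$threshold_days %||% 14)
    data.frame(
      label = b$scenario$label,
      counterfactual = b$scenario$is_counterfactual,
      mean_annual_net_co2 = mean(b$annual_co2),
      negative_work_days = pers$total_negative_days,
      longest_negative_run = pers$longest_run,
      negative_work_halfhours = sum(th$work < 0),
      inversion_halfhours = sum(th$gradient > 0),
      mean_last_snow_doy = mean(b$last_snow_doy),
      annual_mean_lai = mean(b$run$lai),
      mean_work = mean(th$work),
      p95_abs_work = as.numeric(stats::quantile(abs(th$work), 0.95)),
      verdict_negative_work = isTRUE(b$feasibility$verdict_negative_work),
      verdict_co2 = isTRUE(b$feasibility$verdict_co2),
      overall = b$feasibility$overall %||% NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean work difference within matched negative-gradient bins
#'
#' Bins two thermo records on the negative of the resultant gradient
#' (restricted to negative gradients, i.e. surface warmer than air) with
#' shared edges and compares mean work in every bin occupied by both.
#'
#' @param thermo_a,thermo_b [thermo_record()] outputs.
#' @param bin_width bin width on \code{-gradient}, K/m.
#' @param min_n minimum half-hours per bin on both sides for a bin to count.
#' @return \code{data.frame} with one row per matched bin: bin midpoint,
#'   counts and mean work of each side, and their difference (a - b).
#' @export
matched_bin_work <- function(thermo_a, thermo_b, bin_width = 0.1,
                             min_n = 10) {
  mg_a <- -thermo_a$gradient
  mg_b <- -thermo_b$gradient
  hi <- max(mg_a[mg_a > 0], mg_b[mg_b > 0], bin_width)
  breaks <- seq(0, ceiling(hi / bin_width) * bin_width, by = bin_width)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin_stat <- function(mg, w) {
    sel <- mg > 0
    b <- cut(mg[sel], breaks, include.lowest = FALSE)
    list(n = tabulate(as.integer(b), length(mids)),
         mean = vapply(seq_along(mids), function(j) {
           wj <- w[sel][as.integer(b) == j & !is.na(b)]
           if (length(wj)) mean(wj) else NA_real_
         }, 0))
  }
  a <- bin_stat(mg_a, thermo_a$work)
  b <- bin_stat(mg_b, thermo_b$work)
  keep <- a$n >= min_n & b$n >= min_n
  data.frame(minus_gradient_bin = mids[keep], n_a = a$n[keep],
             n_b = b$n[keep], mean_work_a = a$mean[keep],
             mean_work_b = b$mean[keep],
             diff = a$mean[keep] - b$mean[keep])
}

#' Write the tables of a site-pair result as delimited text
#'
#' Per scenario: the half-hourly run table, the daily work series, the
#' inversion episodes and a key-value feasibility report; plus the pair-level
#' comparison table and the two forcing series.
#'
#' @param result a \code{site_pair_result}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_site_pair <- function(result, dir) {
  stopifnot(inherits(result, "site_pair_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(result$comparison, "comparison.tsv")
  for (lab in names(result$bundles)) {
    b <- result$bundles[[lab]]
    wt(format(as.data.frame(b$run), digits = 10), paste0(lab, "_run.tsv"))
    wt(b$daily_work, paste0(lab, "_daily_work.tsv"))
    wt(b$episodes, paste0(lab, "_episodes.tsv"))
    fr <- b$feasibility
    kv <- data.frame(
      key = c("label", "longest_negative_work_run",
              "negative_work_days_total", "threshold_days",
              "mean_annual_net_co2", "verdict_negative_work", "verdict_co2",
              "overall"),
      value = c(fr$label, fr$longest_negative_work_run,
                fr$negative_work_days_total, fr$threshold_days,
                sprintf("%.6f", fr$mean_annual_net_co2),
                fr$verdict_negative_work, fr$verdict_co2, fr$overall))
    wt(kv, paste0(lab, "_feasibility.tsv"))
  }
  for (side in names(result$forcing))
    write_forcing(result$forcing[[side]],
                  file.path(dir, paste0("forcing_", side, ".tsv")))
  invisible(dir)
}
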