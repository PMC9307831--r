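# Shared simulation runs, built once per test session and reused across
# files (expensive multi-year runs back several independent checks).

.tt_cache <- new.env(parent = emptyenv())

tt_cached <- function(key, expr) {
  if (!exists(key, envir = .tt_cache, inherits = FALSE))
    assign(key, expr, envir = .tt_cache)
  get(key, envir = .tt_cache, inherits = FALSE)
}

# Drop spin-up years, preserving the run class and scenario attribute.
tt_post <- function(run, spinup_years = 1) {
  p <- run[run$year > spinup_years, , drop = FALSE]
  attr(p, "scenario") <- attr(run, "scenario")
  class(p) <- class(run)
  p
}

# Alpine-archetype study: 3 years (1 spin-up + 2), grass/sedge vs the
# trees-added counterfactual under identical forcing.
tt_alpine_forcing <- function() tt_cached("alp_f", generate_forcing(
  archetype_defaults("alpine"), n_years = 3, seed = 101))

tt_alp_run <- function() tt_cached("alp_run", simulate_ecosystem(
  tt_alpine_forcing(), scenario_set("US")[["US-Alp"]]))

tt_tr_run <- function() tt_cached("tr_run", simulate_ecosystem(
  tt_alpine_forcing(), scenario_set("US")[["US-Tr"]]))

# Subalpine-archetype study: existing forest vs understory-only, 2 years
# (1 spin-up + 1) under identical forcing.
tt_subalpine_forcing <- function() tt_cached("sub_f", generate_forcing(
  archetype_defaults("subalpine"), n_years = 2, seed = 102))

tt_for_run <- function() tt_cached("for_run", simulate_ecosystem(
  tt_subalpine_forcing(), scenario_set("US")[["US-For"]]))

tt_un_run <- function() tt_cached("un_run", simulate_ecosystem(
  tt_subalpine_forcing(), scenario_set("US")[["US-Un"]]))

# LAI ladder under the alpine forcing: the study's other vegetation
# structures (shrub understory, sparse taiga forest) run between the grass
# fellfield and the full counterfactual forest.
tt_shrub_run <- function() tt_cached("shrub_run", simulate_ecosystem(
  tt_alpine_forcing(), scenario_set("US")[["US-Un"]]))

tt_sparse_forest_run <- function() tt_cached("sparse_run", simulate_ecosystem(
  tt_alpine_forcing(), scenario_set("CA")[["CA-For"]]))

# Full pipeline result for the Canadian taiga-tundra pair (shortest pair run).
tt_ca_pair <- function() tt_cached("ca_pair", run_site_pair(
  run_config("CA", n_years = 2, spinup_years = 1, seed = 7)))

# Constant-forcing series for equilibrium/unit tests.
tt_constant_forcing <- function(n_days = 2, T_air = 280, SW_in = 0,
                                LW_in = NULL, RH = 100, wind = 2,
                                precip = 0) {
  n <- n_days * 48
  LW_in <- LW_in %||% (5.670374419e-8 * T_air^4)
  x <- data.frame(
    timestamp = as.POSIXct("2001-01-01", tz = "UTC") + 1800 * (0:(n - 1)),
    SW_in = SW_in, LW_in = LW_in, T_air = T_air, precip = precip,
    phase = "rain", wind = wind, RH = RH, pressure = 70,
    doy = rep(seq_len(n_days), each = 48), year = 1L)
  class(x) <- c("forcing_series", "data.frame")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
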