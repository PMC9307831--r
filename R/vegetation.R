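# Vegetation scenarios on a fixed 20-layer canopy grid: functional groups,
# seasonal leaf area with snow burial, and the counterfactual construction
# that adds trees above a treeline / removes them below it.

# Overstory trees are the group added/removed by the counterfactuals; the
# suppressed deciduous trees are an understory group (beneath the canopy).
.overstory_groups <- "evergreen_needleleaf_tree"
.group_names <- c("evergreen_needleleaf_tree", "deciduous_tree_suppressed",
                  "shrub", "grass_or_sedge")

#' Define a plant functional group
#'
#' @param name one of \code{"evergreen_needleleaf_tree"},
#'   \code{"deciduous_tree_suppressed"}, \code{"shrub"},
#'   \code{"grass_or_sedge"}.
#' @param max_LAI maximum one-sided leaf area index, m2/m2 (>= 0).
#' @param canopy_top,canopy_bottom vertical extent of the foliage, m
#'   (\code{0 <= canopy_bottom < canopy_top}).
#' @param evergreen logical; evergreen groups hold \code{max_LAI} year-round,
#'   others follow a green-up/senescence phenology.
#' @param leaf_reflectance shortwave reflectance of the foliage.
#' @param photosynthetic_capacity light-saturated CO2 uptake, umol m-2 leaf s-1.
#' @param respiration_base above-ground autotrophic respiration at the
#'   reference temperature (10 C), umol m-2 leaf s-1.
#' @return an object of class \code{functional_group}.
#' @export
functional_group <- function(name, max_LAI, canopy_top, canopy_bottom = 0,
                             evergreen = FALSE, leaf_reflectance = 0.1,
                             photosynthetic_capacity = 12,
                             respiration_base = 0.5) {
  name <- match.arg(name, .group_names)
  stopifnot(.is_number(max_LAI), .is_number(canopy_top),
            .is_number(canopy_bottom))
  if (max_LAI < 0) stop("max_LAI must be >= 0")
  if (canopy_bottom < 0 || canopy_bottom >= canopy_top)
    stop("need 0 <= canopy_bottom < canopy_top")
  structure(list(name = name, max_LAI = max_LAI, canopy_top = canopy_top,
                 canopy_bottom = canopy_bottom, evergreen = evergreen,
                 leaf_reflectance = leaf_reflectance,
                 photosynthetic_capacity = photosynthetic_capacity,
                 respiration_base = respiration_base),
            class = "functional_group")
}

#' Define a vegetation scenario
#'
#' A labelled set of functional groups with the ecosystem height \code{h_e}
#' used in the resultant-temperature-gradient calculation. \code{h_e} is the
#' maximum canopy height in a site pair, so it may exceed the tallest group of
#' this particular scenario.
#'
#' @param label scenario label, e.g. \code{"US-Tr"}.
#' @param groups list of [functional_group()] objects (at least one).
#' @param h_e ecosystem height, m; defaults to the tallest canopy top.
#' @param is_counterfactual logical; whether the vegetation is hypothetical at
#'   the site that provides the forcing.
#' @return an object of class \code{vegetation_scenario}.
#' @export
vegetation_scenario <- function(label, groups, h_e = NULL,
                                is_counterfactual = FALSE) {
  if (inherits(groups, "functional_group")) groups <- list(groups)
  if (!length(groups)) stop("scenario needs at least one functional group")
  if (!all(vapply(groups, inherits, TRUE, "functional_group")))
    stop("groups must be functional_group objects")
  top <- max(vapply(groups, `[[`, 0, "canopy_top"))
  h_e <- h_e %||% top
  if (h_e < top) stop("h_e must be >= the tallest canopy top")
  structure(list(label = label, groups = groups, h_e = h_e,
                 is_counterfactual = is_counterfactual),
            class = "vegetation_scenario")
}

#' Above-ground canopy grid
#'
#' Twenty equal-thickness layers from the ground surface to \code{h_top}.
#' The accompanying below-ground column (12 layers) lives in
#' [physics_params()].
#'
#' @param h_top top of the grid, m (> 0).
#' @param n_above number of above-ground layers.
#' @return list with \code{edges} (length \code{n_above + 1}), \code{centers}
#'   and \code{n_above}.
#' @export
canopy_grid <- function(h_top, n_above = 20L) {
  stopifnot(.is_number(h_top), h_top > 0)
  edges <- seq(0, h_top, length.out = n_above + 1L)
  list(edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2,
       n_above = as.integer(n_above))
}

# Phenology multiplier in [0, 1] for a non-evergreen group: 30-day cosine
# green-up starting at the first snow-free day, plateau, 30-day senescence
# ending day 300. Returns NA-free scalar.
.phenology_frac <- function(day_of_year, greenup_doy, sen_start = 270,
                            ramp = 30) {
  if (is.na(greenup_doy) || day_of_year < greenup_doy) return(0)
  up <- if (day_of_year >= greenup_doy + ramp) 1 else
    0.5 * (1 - cos(pi * (day_of_year - greenup_doy) / ramp))
  down <- if (day_of_year <= sen_start) 1 else
    if (day_of_year >= sen_start + ramp) 0 else
      0.5 * (1 + cos(pi * (day_of_year - sen_start) / ramp))
  min(up, down)
}

# Unburied fraction of a group's vertical extent for a given snow depth.
.unburied_frac <- function(group, snow_depth) {
  eb <- max(group$canopy_bottom, min(snow_depth, group$canopy_top))
  (group$canopy_top - eb) / (group$canopy_top - group$canopy_bottom)
}

#' Seasonal effective leaf area of a functional group
#'
#' Evergreen groups hold \code{max_LAI} year-round; non-evergreen groups
#' follow a 30-day cosine green-up beginning at the (supplied) first snow-free
#' day and a 30-day senescence ending on day 300. Snow burial removes the
#' buried fraction of the extent; a fully buried group (canopy top at or below
#' the snow surface) contributes zero.
#'
#' @param group a [functional_group()].
#' @param day_of_year 1..365.
#' @param snow_depth snow depth, m.
#' @param greenup_doy day of year at which green-up begins (in simulation this
#'   is the first snow-free day of the year; default 140).
#' @return effective LAI, m2/m2.
#' @export
seasonal_lai <- function(group, day_of_year, snow_depth = 0,
                         greenup_doy = 140) {
  stopifnot(inherits(group, "functional_group"))
  if (day_of_year < 1 || day_of_year > 365)
    stop("day_of_year must be in 1..365")
  phen <- if (group$evergreen) 1 else .phenology_frac(day_of_year, greenup_doy)
  group$max_LAI * phen * .unburied_frac(group, snow_depth)
}

# Distribute one group's effective LAI uniformly over the layers intersecting
# its unburied extent. Returns a vector over layers (bottom -> top).
.lad_one_group <- function(eff_lai, eff_bottom, top, edges) {
  nz <- length(edges) - 1L
  if (eff_lai <= 0 || top - eff_bottom <= 0) return(numeric(nz))
  lo <- pmax(edges[-length(edges)], eff_bottom)
  hi <- pmin(edges[-1], top)
  len <- pmax(0, hi - lo)
  tot <- top - eff_bottom
  eff_lai * len / tot
}

#' Per-layer leaf area density profile of a scenario
#'
#' Each group's current effective LAI (phenology and burial applied) is
#' distributed uniformly over the canopy layers intersecting its unburied
#' extent. The column sum over layers equals the sum of group effective LAIs.
#'
#' @param scenario a [vegetation_scenario()].
#' @param day_of_year 1..365.
#' @param snow_depth snow depth, m.
#' @param grid a [canopy_grid()]; defaults to a grid up to the tallest group.
#' @param greenup_doy see [seasonal_lai()].
#' @return list with \code{lad} (layers x groups matrix), \code{total}
#'   (per-layer sum), \code{grid} and per-group \code{effective_lai}.
#' @export
leaf_area_density_profile <- function(scenario, day_of_year, snow_depth = 0,
                                      grid = NULL, greenup_doy = 140) {
  stopifnot(inherits(scenario, "vegetation_scenario"))
  tops <- vapply(scenario$groups, `[[`, 0, "canopy_top")
  grid <- grid %||% canopy_grid(max(tops))
  if (any(vapply(scenario$groups, `[[`, 0, "canopy_bottom") >=
          max(grid$edges)))
    stop("group extent does not overlap the canopy grid")
  ng <- length(scenario$groups)
  lad <- matrix(0, grid$n_above, ng)
  eff <- numeric(ng)
  for (g in seq_len(ng)) {
    gr <- scenario$groups[[g]]
    eff[g] <- seasonal_lai(gr, day_of_year, snow_depth, greenup_doy)
    eb <- max(gr$canopy_bottom, min(snow_depth, gr$canopy_top))
    lad[, g] <- .lad_one_group(eff[g], eb, gr$canopy_top, grid$edges)
  }
  list(lad = lad, total = rowSums(lad), grid = grid, effective_lai = eff)
}

#' Build the trees-added and understory-only counterfactuals for a site pair
#'
#' Given the existing vegetation below the treeline (which must contain at
#' least one overstory tree group) and above it (which must contain none),
#' returns the pair of counterfactual scenarios: \code{X_Tr} carries the
#' below-treeline group list, to be driven by the above-treeline forcing;
#' \code{X_Un} carries the below-treeline understory (overstory trees
#' removed; suppressed deciduous trees are understory and stay), driven by
#' the below-treeline forcing. Both members of the pair receive \code{h_e}
#' equal to the maximum canopy height in the pair.
#'
#' @param below_treeline,above_treeline [vegetation_scenario()] objects.
#' @param pair label prefix for the counterfactuals (default: the part of
#'   \code{below_treeline$label} before the first \code{"-"}).
#' @return list with elements \code{X_Tr} and \code{X_Un}.
#' @export
make_counterfactual <- function(below_treeline, above_treeline, pair = NULL) {
  stopifnot(inherits(below_treeline, "vegetation_scenario"),
            inherits(above_treeline, "vegetation_scenario"))
  is_tree <- function(s)
    vapply(s$groups, `[[`, "", "name") %in% .overstory_groups
  if (!any(is_tree(below_treeline)))
    stop("below-treeline scenario must contain a tree group")
  if (any(is_tree(above_treeline)))
    stop("above-treeline scenario must not contain a tree group")
  pair <- pair %||% sub("-.*$", "", below_treeline$label)
  h_pair <- max(below_treeline$h_e, above_treeline$h_e,
                vapply(below_treeline$groups, `[[`, 0, "canopy_top"),
                vapply(above_treeline$groups, `[[`, 0, "canopy_top"))
  understory <- below_treeline$groups[!is_tree(below_treeline)]
  if (!length(understory))
    stop("below-treeline scenario has no understory group")
  list(
    X_Tr = vegetation_scenario(paste0(pair, "-Tr"), below_treeline$groups,
                               h_e = h_pair, is_counterfactual = TRUE),
    X_Un = vegetation_scenario(paste0(pair, "-Un"), understory,
                               h_e = h_pair, is_counterfactual = TRUE))
}

# Site definitions for the three treeline pairs. Group parameters are
# documented defaults; only the sparse sub-Arctic tree LAI (0.5) is anchored
# to the forest-tundra ecotone setting the scenarios emulate.
.sites <- function() {
  ent <- function(lai, top, bottom) functional_group(
    "evergreen_needleleaf_tree", max_LAI = lai, canopy_top = top,
    canopy_bottom = bottom, evergreen = TRUE, photosynthetic_capacity = 12,
    respiration_base = 0.5)
  list(
    Lav  = list(groups = list(
             functional_group("deciduous_tree_suppressed", 1.0, 2.5, 0.3,
                              photosynthetic_capacity = 10),
             ent(4.0, 20, 2)),
           archetype = "subalpine"),
    MBo  = list(groups = list(
             functional_group("grass_or_sedge", 1.5, 0.3,
                              photosynthetic_capacity = 15)),
           archetype = "alpine"),
    NR1  = list(groups = list(
             functional_group("shrub", 1.0, 0.8, 0.05,
                              photosynthetic_capacity = 10),
             ent(4.0, 12, 2)),
           archetype = "subalpine"),
    `T-Van` = list(groups = list(
             functional_group("grass_or_sedge", 1.5, 0.25,
                              photosynthetic_capacity = 15)),
           archetype = "alpine"),
    HPC  = list(groups = list(
             functional_group("shrub", 1.0, 0.6, 0.05,
                              photosynthetic_capacity = 10),
             ent(0.5, 8, 1)),
           archetype = "subarctic"),
    TVC  = list(groups = list(
             functional_group("shrub", 1.0, 0.5, 0.05,
                              photosynthetic_capacity = 10)),
           archetype = "arctic"))
}

.pair_sites <- function(pair) {
  switch(pair,
    IT = list(below = "Lav", above = "MBo",
              below_arch = "subalpine", above_arch = "alpine"),
    US = list(below = "NR1", above = "T-Van",
              below_arch = "subalpine", above_arch = "alpine"),
    CA = list(below = "HPC", above = "TVC",
              below_arch = "subarctic", above_arch = "arctic"),
    stop("unknown site pair: ", pair))
}

#' The four simulation scenarios of a treeline site pair
#'
#' Builds the X-For (existing forest), X-Un (understory-only counterfactual),
#' X-Alp/Arc (existing alpine/Arctic vegetation) and X-Tr (trees-added
#' counterfactual) scenarios for one of the three site pairs. Each scenario
#' carries a \code{forcing_side} attribute (\code{"below"} or \code{"above"})
#' indicating which site's forcing drives it, and a \code{site_id} attribute.
#'
#' @param pair one of \code{"IT"}, \code{"US"}, \code{"CA"}.
#' @return named list of four [vegetation_scenario()] objects in the order
#'   For, Un, Alp/Arc, Tr.
#' @export
scenario_set <- function(pair = c("IT", "US", "CA")) {
  pair <- match.arg(pair)
  ps <- .pair_sites(pair)
  sites <- .sites()
  below <- vegetation_scenario(paste0(pair, "-For"),
                               sites[[ps$below]]$groups)
  above_label <- if (pair == "CA") paste0(pair, "-Arc") else
    paste0(pair, "-Alp")
  above <- vegetation_scenario(above_label, sites[[ps$above]]$groups)
  cf <- make_counterfactual(below, above, pair)
  h_pair <- cf$X_Tr$h_e
  below$h_e <- h_pair
  above$h_e <- h_pair
  ann <- function(s, side, site) {
    attr(s, "forcing_side") <- side
    attr(s, "site_id") <- site
    s
  }
  out <- list(ann(below, "below", ps$below),
              ann(cf$X_Un, "below", ps$below),
              ann(above, "above", ps$above),
              ann(cf$X_Tr, "above", ps$above))
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

#' Scenario table for all three site pairs
#'
#' One row per simulation scenario: label, understory and overstory functional
#' groups, counterfactual flag and the site whose forcing drives it.
#'
#' @return a \code{data.frame} with 12 rows.
#' @export
scenario_table <- function() {
  rows <- list()
  abbrev_fg <- c(evergreen_needleleaf_tree = "ENT",
                 deciduous_tree_suppressed = "suppr DT",
                 shrub = "shrubs", grass_or_sedge = "grasses/sedges")
  order_for_pair <- c("Alp", "Tr", "For", "Un")
  for (pair in c("IT", "US", "CA")) {
    ss <- scenario_set(pair)
    want <- paste0(pair, "-", sub("Alp", if (pair == "CA") "Arc" else "Alp",
                                  order_for_pair))
    for (lab in want) {
      s <- ss[[lab]]
      nm <- vapply(s$groups, `[[`, "", "name")
      over <- nm %in% "evergreen_needleleaf_tree"
      rows[[length(rows) + 1L]] <- data.frame(
        abbrev = s$label,
        understory = paste(abbrev_fg[nm[!over]], collapse = "+"),
        overstory = if (any(over)) abbrev_fg[nm[over][1]] else "-",
        counterfactual = s$is_counterfactual,
        site_id = attr(s, "site_id"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write vegetation scenarios from a plain-text config
#'
#' One block per scenario, started by \code{[label]}, followed by
#' \code{key: value} lines (\code{site}, \code{counterfactual}, \code{h_e},
#' \code{forcing_side}) and one \code{group:} line per functional group of the
#' form \code{group: name max_LAI top bottom evergreen reflectance capacity
#' respiration}.
#'
#' @param path file path.
#' @param scenarios named list of [vegetation_scenario()] objects.
#' @return \code{read_scenario_config} returns a named list of scenarios.
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  cur <- NULL
  flush <- function(cur, out) {
    if (is.null(cur)) return(out)
    s <- vegetation_scenario(cur$label, cur$groups, h_e = cur$h_e,
                             is_counterfactual = isTRUE(cur$counterfactual))
    attr(s, "site_id") <- cur$site
    attr(s, "forcing_side") <- cur$forcing_side
    out[[cur$label]] <- s
    out
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      out <- flush(cur, out)
      cur <- list(label = gsub("^\\[|\\]$", "", ln), groups = list(),
                  h_e = NULL, counterfactual = FALSE, site = NA_character_,
                  forcing_side = NA_character_)
    } else if (grepl("^group:", ln)) {
      if (is.null(cur)) stop("group line before any [scenario] block")
      f <- strsplit(trimws(sub("^group:", "", ln)), "\\s+")[[1]]
      if (length(f) != 8) stop("malformed group line: ", ln)
      cur$groups[[length(cur$groups) + 1L]] <- functional_group(
        name = f[1], max_LAI = as.numeric(f[2]), canopy_top = as.numeric(f[3]),
        canopy_bottom = as.numeric(f[4]), evergreen = f[5] %in% c("yes", "TRUE"),
        leaf_reflectance = as.numeric(f[6]),
        photosynthetic_capacity = as.numeric(f[7]),
        respiration_base = as.numeric(f[8]))
    } else if (grepl(":", ln, fixed = TRUE)) {
      if (is.null(cur)) stop("key line before any [scenario] block")
      kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = ":"))
      cur[[key]] <- switch(key,
        h_e = as.numeric(val),
        counterfactual = val %in% c("yes", "TRUE", "true"),
        val)
    } else stop("unparseable scenario config line: ", ln)
  }
  flush(cur, out)
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(scenarios, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in scenarios) {
    writeLines(sprintf("[%s]", s$label), con)
    if (!is.null(attr(s, "site_id")))
      writeLines(sprintf("site: %s", attr(s, "site_id")), con)
    if (!is.null(attr(s, "forcing_side")))
      writeLines(sprintf("forcing_side: %s", attr(s, "forcing_side")), con)
    writeLines(sprintf("counterfactual: %s",
                       if (s$is_counterfactual) "yes" else "no"), con)
    writeLines(sprintf("h_e: %g", s$h_e), con)
    for (g in s$groups)
      writeLines(sprintf("group: %s %g %g %g %s %g %g %g", g$name, g$max_LAI,
                         g$canopy_top, g$canopy_bottom,
                         if (g$evergreen) "yes" else "no", g$leaf_reflectance,
                         g$photosynthetic_capacity, g$respiration_base), con)
    writeLines("", con)
  }
  invisible(path)
}
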