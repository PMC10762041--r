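#' Default grassland plant parameters
#'
#' Spatially constant parameters of the NPP-based grassland P uptake model:
#' carbon content of dry matter, dry:fresh matter ratio, P concentration of
#' aboveground biomass (bounds span published foliage stoichiometry at the
#' low end and forage-crop concentrations at the high end; belowground is half
#' the aboveground value), organ lifespans, growing-season length, and the
#' belowground share of NPP.
#'
#' @param p_pct_above P concentration of aboveground biomass, gP per 100 gFM.
#' @return list of grass parameters.
#' @export
grass_parameters <- function(p_pct_above = 8.8e-2) {
  list(gamma = 0.45, dry = 0.20,
       p_pct_above = p_pct_above, p_pct_above_bounds = c(2.5e-2, 1.5e-1),
       p_pct_below = 0.5 * p_pct_above,
       lifespan_above = 0.8, lifespan_below = 0.7, season_length = 1,
       npp_below_share = 0.54)
}

#' Default manure/residue/sludge composition fractions
#'
#' Fractions of each P source reaching the inorganic labile, organic labile
#' and organic stable pools; each triple sums to 1. Sludge shares the manure
#' composition.
#' @return list with elements `manure`, `residues`, `sludge`, each a named
#'   numeric vector `(i_lab, o_lab, o_sta)`.
#' @export
composition_fractions <- function() {
  manure <- c(i_lab = 0.8, o_lab = 0.1, o_sta = 0.1)
  residues <- c(i_lab = 0.4, o_lab = 0.4, o_sta = 0.2)
  list(manure = manure, residues = residues, sludge = manure)
}

#' P in manure reaching the soil
#'
#' Estimate 1 converts gridded N-in-manure fields to P with a constant P:N
#' ratio. Estimate 2 rescales estimate 1 so that, for each country, its mean
#' over the rescaling window (cropland + grassland pooled, area-weighted)
#' matches the country-scale P-manure production table; the within-country
#' spatial pattern and the year-to-year variability of estimate 1 are kept.
#'
#' @param n_manure list with matrices `crop` and `grass` (cells x years) of N
#'   in manure, kgN/ha/yr.
#' @param pn_ratio P:N ratio of manure, kgP/kgN (0.20).
#' @param country integer country id per cell.
#' @param years simulation years (columns of the fields).
#' @param country_table data frame `country`, `year`, `manure_p` (kgP, total
#'   produced) -- required for `mode = "estimate2"`.
#' @param mode `"estimate1"` or `"estimate2"`.
#' @param area_ha list with per-cell cropland and grassland areas (matrices
#'   cells x years, ha) used for the country pooling of estimate 2.
#' @param window rescaling window, default 1950:2017.
#' @return list with matrices `crop` and `grass`, kgP/ha/yr.
#' @export
manure_forcing <- function(n_manure, pn_ratio = 0.20, country, years,
                           country_table = NULL,
                           mode = c("estimate1", "estimate2"),
                           area_ha = NULL, window = 1950:2017) {
  mode <- match.arg(mode)
  if (anyNA(country)) stop("cell without country assignment")
  est1 <- list(crop = pn_ratio * n_manure$crop,
               grass = pn_ratio * n_manure$grass)
  if (mode == "estimate1") return(est1)
  stopifnot(!is.null(country_table), !is.null(area_ha))
  win <- intersect(window, years)
  wi <- match(win, years)
  scale <- rep(NA_real_, max(country))
  for (co in sort(unique(country))) {
    cells <- which(country == co)
    # country total P in manure from estimate 1, pooled crop+grass, per year
    tot1 <- colSums(est1$crop[cells, wi, drop = FALSE] *
                      area_ha$crop[cells, wi, drop = FALSE]) +
      colSums(est1$grass[cells, wi, drop = FALSE] *
                area_ha$grass[cells, wi, drop = FALSE])
    tab <- country_table[country_table$country == co &
                           country_table$year %in% win, ]
    if (mean(tot1) <= 0) {
      warning("country ", co, " has zero estimate-1 manure over the window; ",
              "estimate 2 set to 0")
      scale[co] <- 0
    } else {
      scale[co] <- mean(tab$manure_p) / mean(tot1)
    }
  }
  s <- scale[country]
  list(crop = est1$crop * s, grass = est1$grass * s)
}

#' P in chemical fertilizer per land cover
#'
#' Grassland chemical P is N-in-fertilizer times a constant P:N ratio (0.22).
#' The total-fertilizer field assumes all fertilizer goes to cropland, so the
#' cropland rate is corrected by subtracting the grassland share:
#' `crop = (P_total * frac_crop - grass * frac_grass) / frac_crop`, floored at
#' 0; cells without cropland get 0.
#'
#' @param n_chem_grass N fertilizer on grassland, kgN/ha/yr.
#' @param p_chem_total total P fertilizer (all attributed to cropland),
#'   kgP/ha of cropland/yr.
#' @param frac_crop,frac_grass land-cover fractions.
#' @param pn_ratio P:N ratio of fertilizer (0.22).
#' @return list with `crop` and `grass` chemical P, kgP/ha/yr.
#' @export
fertilizer_forcing <- function(n_chem_grass, p_chem_total, frac_crop,
                               frac_grass, pn_ratio = 0.22) {
  grass <- pn_ratio * n_chem_grass
  crop <- ifelse(frac_crop > 0,
                 pmax(0, (p_chem_total * frac_crop - grass * frac_grass) /
                        frac_crop),
                 0)
  list(crop = crop, grass = grass)
}

#' Grassland P uptake and residues from NPP and grazing intensity
#'
#' Uptake converts above/belowground NPP (carbon) to P through the carbon and
#' dry-matter contents, organ P concentrations and organ lifespans relative to
#' the growing season; residues are the non-appropriated share `(1 - GI)` of
#' the uptake.
#'
#' @param npp_tot total (above + below) NPP, kgC/ha/yr.
#' @param gi grazing intensity in [0, 1] (fraction of NPP appropriated).
#' @param params [grass_parameters()].
#' @param npp_mode `"kastner"` uses `npp_tot` as-is; `"sun_scaled"` rescales
#'   it by the ratio of the two published global-mean NPP estimates (979/460).
#' @return list with `uptake` and `residues_total`, kgP/ha/yr.
#' @export
grassland_plant_forcing <- function(npp_tot, gi, params = grass_parameters(),
                                    npp_mode = c("kastner", "sun_scaled")) {
  npp_mode <- match.arg(npp_mode)
  stopifnot(all(gi >= 0 & gi <= 1))
  if (npp_mode == "sun_scaled") npp_tot <- npp_tot * 979 / 460
  npp_below <- params$npp_below_share * npp_tot
  npp_above <- (1 - params$npp_below_share) * npp_tot
  uptake <- (1 / params$gamma) * (1 / params$dry) *
    ((params$p_pct_above / 100) * (params$lifespan_above / params$season_length) *
       npp_above +
       (params$p_pct_below / 100) * (params$lifespan_below / params$season_length) *
       npp_below)
  list(uptake = uptake, residues_total = (1 - gi) * uptake)
}

#' Per-crop yield and harvested-area series from a reference-year map
#'
#' The reference-year (2000) gridded map is scaled by the country series
#' relative to its reference-year value. Before 1961 the yield is further
#' scaled by the population ratio to 1961 and the harvested area is held at
#' its 1961 value.
#'
#' @param map2000 per-cell reference-year value (yield kgFM/ha or area ha).
#' @param country integer country id per cell.
#' @param country_series data frame `country`, `year`, `value`.
#' @param years years to produce.
#' @param population optional data frame `country`, `year`, `value` used for
#'   the pre-1961 yield scaling (omit for areas).
#' @param pre1961 `"population"` (yield rule) or `"hold"` (area rule).
#' @param ref_year reference year of the gridded map (2000).
#' @return matrix cells x years.
#' @export
crop_yield_area_series <- function(map2000, country, country_series, years,
                                   population = NULL,
                                   pre1961 = c("hold", "population"),
                                   ref_year = 2000) {
  pre1961 <- match.arg(pre1961)
  n <- length(map2000)
  out <- matrix(0, n, length(years))
  for (co in sort(unique(country))) {
    cells <- which(country == co)
    cs <- country_series[country_series$country == co, ]
    ref <- cs$value[cs$year == ref_year]
    if (length(ref) != 1) stop("missing reference-year entry for country ", co)
    if (ref == 0) {
      warning("country ", co, " has zero reference-year value; series set to 0")
      next
    }
    v1961 <- cs$value[cs$year == 1961]
    for (j in seq_along(years)) {
      y <- years[j]
      if (y >= 1961) {
        vy <- cs$value[cs$year == y]
        if (length(vy) != 1) stop("country series lacks year ", y)
      } else if (pre1961 == "hold") {
        vy <- v1961
      } else {
        pop <- population[population$country == co, ]
        vy <- v1961 * pop$value[pop$year == y] / pop$value[pop$year == 1961]
      }
      out[cells, j] <- map2000[cells] * vy / ref
    }
  }
  out
}

#' Default crop parameter table for the synthetic world
#'
#' Three representative crop types: a cereal, a forage crop (residue fraction
#' 0, all aboveground biomass removed) and a root crop (harvested organ
#' belowground). Root-organ P concentration is 0.75 times the aboveground
#' residue concentration; the root:shoot ratio derives from the aboveground
#' biomass fraction as `RSR = 1/frac_above - 1`; residue fraction is 0 for
#' forage and 0.5 otherwise. Organs share the same dry-matter proportion.
#'
#' @return data frame, one row per crop.
#' @export
crop_parameters <- function() {
  frac_above <- c(cereal = 0.85, forage = 0.80, rootcrop = 0.55)
  p_abov <- c(cereal = 0.08, forage = 0.15, rootcrop = 0.18)
  data.frame(
    crop = names(frac_above),
    p_pct_harvest = c(0.30, 0.15, 0.05),
    p_pct_abov_ex_harvest = unname(p_abov),
    p_pct_root = unname(0.75 * p_abov),
    harvest_index = c(0.45, 0.90, 0.60),
    root_shoot_ratio = unname(1 / frac_above - 1),
    frac_resid = c(0.5, 0, 0.5),
    is_forage = c(FALSE, TRUE, FALSE),
    is_root_crop = c(FALSE, FALSE, TRUE),
    row.names = NULL
  )
}

# per-crop uptake and residues, kgP/ha/yr, from fresh-matter yield (kgFM/ha).
# Organs share the same dry proportion, so the dry-matter ratios cancel.
# For root crops the harvested organ is belowground: the roles of the root
# and aboveground terms are swapped (the residue fraction then applies to the
# aboveground biomass, which is not harvested).
crop_uptake_residues <- function(yield, cp) {
  if (any(cp$harvest_index <= 0)) stop("harvest index must be positive")
  hi <- cp$harvest_index
  rsr <- cp$root_shoot_ratio
  if (isTRUE(cp$is_root_crop)) {
    # harvested organ belowground: total belowground = Y/HI, aboveground
    # biomass = belowground / RSR; the residue fraction applies aboveground
    below_resid <- cp$p_pct_root * (1 / hi - 1)
    above_term <- cp$p_pct_abov_ex_harvest / (hi * rsr)
    uptake <- yield / 100 * (below_resid + above_term + cp$p_pct_harvest)
    resid <- yield / 100 * (below_resid + cp$frac_resid * above_term)
  } else {
    root_term <- cp$p_pct_root * rsr / hi
    above_term <- cp$p_pct_abov_ex_harvest * (1 / hi - 1)
    uptake <- yield / 100 * (root_term + above_term + cp$p_pct_harvest)
    resid <- yield / 100 * (root_term + cp$frac_resid * above_term)
  }
  list(uptake = uptake, residues = resid)
}

#' Cropland P uptake and residues aggregated over crops
#'
#' Per-crop uptake and residues are computed from fresh-matter yield, organ P
#' concentrations, the harvest index and the root:shoot ratio, then aggregated
#' across crops with harvested-area weights.
#'
#' @param yield matrix cells x crops, kgFM/ha.
#' @param area matrix cells x crops, ha (harvested area).
#' @param crop_params data frame as [crop_parameters()], rows matching the
#'   columns of `yield`/`area`.
#' @return list with per-cell `uptake` and `residues_total`, kgP/ha/yr (0
#'   where no crop has positive area).
#' @export
cropland_plant_forcing <- function(yield, area, crop_params = crop_parameters()) {
  yield <- as.matrix(yield); area <- as.matrix(area)
  n <- nrow(yield)
  upt <- res <- matrix(0, n, ncol(yield))
  for (k in seq_len(ncol(yield))) {
    ur <- crop_uptake_residues(yield[, k], crop_params[k, ])
    upt[, k] <- ur$uptake
    res[, k] <- ur$residues
  }
  atot <- rowSums(area)
  w <- ifelse(atot > 0, 1 / atot, 0)
  list(uptake = w * rowSums(area * upt),
       residues_total = w * rowSums(area * res))
}

#' Split a source total across destination pools
#'
#' @param totals numeric vector of source totals, kgP/ha/yr.
#' @param fractions named vector `(i_lab, o_lab, o_sta)` summing to 1.
#' @return data frame `i_lab`, `o_lab`, `o_sta`; rows sum to `totals` exactly
#'   (the stable-pool share is taken as the remainder).
#' @export
split_composition <- function(totals, fractions) {
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  i_lab <- fractions[["i_lab"]] * totals
  o_lab <- fractions[["o_lab"]] * totals
  # the remainder can round to -eps when the two fractions sum to 1
  data.frame(i_lab = i_lab, o_lab = o_lab,
             o_sta = pmax(totals - i_lab - o_lab, 0))
}

#' Atmospheric P deposition split into labile and primary inputs
#'
#' A labile fraction of 0.1 of the dust component and 0.5 of all other
#' components (sea salt, primary biogenic particles, natural and anthropogenic
#' combustion) enters labile inorganic P; the remainder enters primary P.
#' Non-anthropogenic components are static in time; the anthropogenic
#' combustion component follows the normalized emission series, spliced with a
#' single multiplicative correction so that its mean over the overlap period
#' matches the static estimate.
#'
#' @param components list of per-cell deposition fields (kgP/ha/yr):
#'   `dust`, `seasalt`, `pbap`, `natcomb`, `anthcomb`.
#' @param years years to produce.
#' @param anthcomb_series optional data frame `year`, `value` of anthropogenic
#'   combustion emissions; scaled to mean 1 over `overlap` and applied to the
#'   `anthcomb` component. When omitted, deposition is static.
#' @param overlap years over which the series is normalized (default
#'   1997:2007).
#' @return list of matrices (cells x years) `to_ilab`, `to_iprim`.
#' @export
deposition_forcing <- function(components, years, anthcomb_series = NULL,
                               overlap = 1997:2007) {
  comp <- lapply(components, as.numeric)
  stopifnot(all(vapply(comp, function(x) all(x >= 0), TRUE)))
  n <- length(comp$dust)
  scale <- rep(1, length(years))
  if (!is.null(anthcomb_series)) {
    ov <- intersect(overlap, anthcomb_series$year)
    if (!length(ov)) ov <- anthcomb_series$year
    norm <- mean(anthcomb_series$value[anthcomb_series$year %in% ov])
    idx <- match(years, anthcomb_series$year)
    s <- anthcomb_series$value[idx] / norm
    # hold the series value at the ends outside its coverage
    s[is.na(s) & years < min(anthcomb_series$year)] <-
      anthcomb_series$value[which.min(anthcomb_series$year)] / norm
    s[is.na(s)] <- anthcomb_series$value[which.max(anthcomb_series$year)] / norm
    scale <- s
  }
  other_static <- comp$seasalt + comp$pbap + comp$natcomb
  to_ilab <- outer(0.1 * comp$dust + 0.5 * other_static, rep(1, length(years))) +
    outer(0.5 * comp$anthcomb, scale)
  to_iprim <- outer(0.9 * comp$dust + 0.5 * other_static, rep(1, length(years))) +
    outer(0.5 * comp$anthcomb, scale)
  list(to_ilab = to_ilab, to_iprim = to_iprim)
}

#' P in sewage sludge applied to cropland
#'
#' Country-scale human P excretion routed through three wastewater-treatment
#' types with P removal efficiencies `NR = (0.10, 0.45, 0.90)`, divided by the
#' country's cropland area; all cropland cells of a country receive the same
#' rate. Excretion rates and treatment fractions are linearly interpolated
#' between 1970 and 2010 and held constant outside that interval.
#'
#' @param sludge_table data frame `country`, `year` (1970 and 2010 at least),
#'   `excretion` (kgP/capita/yr), `frac_treat1`, `frac_treat2`, `frac_treat3`.
#' @param population data frame `country`, `year`, `value` (inhabitants).
#' @param crop_area_country data frame `country`, `year`, `value` (ha).
#' @param country integer country id per cell.
#' @param years years to produce.
#' @param removal_nr P removal efficiencies of treatment types 1..3.
#' @return matrix cells x years of sludge P on cropland, kgP/ha/yr.
#' @export
sludge_forcing <- function(sludge_table, population, crop_area_country,
                           country, years, removal_nr = c(0.10, 0.45, 0.90)) {
  interp <- function(tab, col, y) {
    yy <- pmin(pmax(y, 1970), 2010)
    stats::approx(tab$year, tab[[col]], xout = yy, rule = 2)$y
  }
  n <- length(country)
  out <- matrix(0, n, length(years))
  for (co in sort(unique(country))) {
    tab <- sludge_table[sludge_table$country == co, ]
    pop <- population[population$country == co, ]
    ar <- crop_area_country[crop_area_country$country == co, ]
    cells <- which(country == co)
    for (j in seq_along(years)) {
      y <- years[j]
      fr <- c(interp(tab, "frac_treat1", y), interp(tab, "frac_treat2", y),
              interp(tab, "frac_treat3", y))
      excr <- interp(tab, "excretion", y)
      popy <- pop$value[pop$year == y]
      area <- ar$value[ar$year == y]
      total <- sum(fr * removal_nr) * excr * popy
      if (area <= 0) {
        if (total > 0) warning("country ", co, " year ", y,
                               ": sludge with zero cropland area; set to 0")
        next
      }
      out[cells, j] <- total / area
    }
  }
  out
}

#' Annual topsoil mass fraction lost to water erosion
#'
#' Gross soil loss divided by the mass of the 0-0.3 m fine-earth layer,
#' capped at 1.
#'
#' @param gross_loss gross soil loss, kg soil/ha/yr.
#' @param soil soil-property data frame (`bulk_density`, `coarse_frag_frac`).
#' @param depth layer depth, m.
#' @return per-cell fraction lost, 1/yr.
#' @export
erosion_fraction <- function(gross_loss, soil, depth = 0.3) {
  stopifnot(all(gross_loss >= 0))
  pmin(gross_loss /
         (soil$bulk_density * (1 - soil$coarse_frag_frac) * depth * 1e4), 1)
}
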