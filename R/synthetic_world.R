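#' Configuration for the synthetic world generator
#'
#' @param nx,ny grid size (default 10 x 10 = 100 cells).
#' @param n_countries number of (contiguous, equal-area) countries.
#' @param years simulation years (default 1950:2018; a 1900 start is
#'   available by passing `years = 1900:2018`).
#' @param n_crops number of crops (>= 3 includes one forage and one root
#'   crop).
#' @return list of class `world_config`.
#' @export
world_config <- function(nx = 10, ny = 10, n_countries = 4,
                         years = 1950:2018, n_crops = 3) {
  if (nx < 1 || ny < 1 || n_countries < 1 || n_crops < 1 ||
      length(years) < 2 || any(diff(years) != 1)) {
    stop("invalid world configuration")
  }
  structure(list(nx = nx, ny = ny, n_countries = n_countries, years = years,
                 n_crops = n_crops), class = "world_config")
}

#' Generate a self-consistent synthetic world
#'
#' Builds a complete toy input bundle -- grid with contiguous countries, soil
#' properties, natural-soil pools, climate series, land-use fractions and
#' transitions satisfying the year-to-year consistency identity, and every
#' driver the pipeline consumes (manure with two estimates, fertilizer, NPP
#' and grazing intensity, crop yield/area with country tables and population,
#' deposition components with an emission series, sludge-treatment tables,
#' gross erosion) -- with magnitudes in plausible agronomic ranges, so the
#' full pipeline runs with no external data. Reproducible given `seed`.
#'
#' @param config [world_config()].
#' @param seed integer RNG seed.
#' @return list of class `world`.
#' @export
make_world <- function(config = world_config(), seed = 1) {
  set.seed(seed)
  n <- config$nx * config$ny
  years <- config$years
  ny <- length(years)

  # contiguous blocks of cells as countries; uniform land area per cell
  country <- as.integer(cut(seq_len(n), config$n_countries, labels = FALSE))
  grid <- data.frame(cell = seq_len(n),
                     lon = rep(seq_len(config$nx), config$ny),
                     lat = rep(seq_len(config$ny), each = config$nx),
                     country = country,
                     land_area_ha = rep(250000, n))

  sand <- runif(n, 20, 70)
  clay <- runif(n, 5, pmin(40, 95 - sand))
  soil <- data.frame(
    sand_pct = sand, clay_pct = clay, silt_pct = 100 - sand - clay,
    ph_water = runif(n, 4.5, 8.2), soil_carbon = runif(n, 5, 30),
    bulk_density = runif(n, 1100, 1500), coarse_frag_frac = runif(n, 0, 0.2),
    depth = 0.3)

  # natural-soil pools: total 100-3000 kgP/ha spread over Hedley-type shares
  ctx <- areal_context(soil$bulk_density, soil$coarse_frag_frac)
  tot_kgha <- runif(n, 100, 3000)
  shares <- cbind(i_lab = runif(n, 0.10, 0.20), i_sec = runif(n, 0.15, 0.30),
                  i_prim = runif(n, 0.15, 0.30), o_lab = runif(n, 0.05, 0.15),
                  o_sta = runif(n, 0.10, 0.20), x_occ = runif(n, 0.10, 0.25))
  shares <- shares / rowSums(shares)
  natural <- as.data.frame(shares * tot_kgha / ctx$kg_ha_per_mg_kg)

  t_soil0 <- runif(n, 4, 26)
  climate <- list(
    t_soil = matrix(t_soil0, n, ny) + matrix(rnorm(n * ny, 0, 0.3), n, ny),
    w_rel = pmin(pmax(matrix(runif(n, 0.35, 0.9), n, ny) +
                        matrix(rnorm(n * ny, 0, 0.02), n, ny), 0.05), 1),
    w_abs = pmax(matrix(runif(n, 0.8, 3.5), n, ny) +
                   matrix(rnorm(n * ny, 0, 0.05), n, ny), 0.1),
    t_air = matrix(t_soil0 - 1, n, ny))

  # land-use series built forward from random transitions (consistency holds
  # by construction)
  frac <- array(0, c(n, 4, ny), dimnames = list(NULL, landuse_categories(), NULL))
  f_crop <- runif(n, 0.1, 0.35); f_grass <- runif(n, 0.1, 0.35)
  f_urban <- runif(n, 0, 0.04)
  frac[, , 1] <- cbind(f_crop, f_grass, 1 - f_crop - f_grass - f_urban, f_urban)
  delta <- array(0, c(n, 4, 4, ny - 1),
                 dimnames = list(NULL, landuse_categories(),
                                 landuse_categories(), NULL))
  for (j in seq_len(ny - 1)) {
    f <- frac[, , j]
    d <- array(0, c(n, 4, 4))
    d[, 3, 1] <- runif(n, 0, 0.003) * f[, 3]   # nonagri -> crop
    d[, 3, 2] <- runif(n, 0, 0.003) * f[, 3]   # nonagri -> grass
    d[, 1, 2] <- runif(n, 0, 0.002) * f[, 1]   # crop -> grass
    d[, 2, 1] <- runif(n, 0, 0.002) * f[, 2]   # grass -> crop
    d[, 1, 4] <- runif(n, 0, 0.0005) * f[, 1]  # crop -> urban
    delta[, , , j] <- d
    frac[, , j + 1] <- f - apply(d, c(1, 2), sum) + apply(d, c(1, 3), sum)
  }

  ramp <- pmin(pmax((years - 1945) / 60, 0.05), 1)  # intensification ramp
  field <- function(base_lo, base_hi, time_profile = ramp) {
    outer(runif(n, base_lo, base_hi), time_profile) *
      matrix(runif(n * ny, 0.9, 1.1), n, ny)
  }

  n_manure <- list(crop = field(5, 60), grass = field(2, 25))
  # country manure-production table, deliberately offset from estimate 1
  est1 <- list(crop = 0.20 * n_manure$crop, grass = 0.20 * n_manure$grass)
  area_crop <- frac[, 1, ] * grid$land_area_ha
  area_grass <- frac[, 2, ] * grid$land_area_ha
  country_table <- do.call(rbind, lapply(sort(unique(country)), function(co) {
    cells <- which(country == co)
    tot <- colSums(est1$crop[cells, , drop = FALSE] *
                     area_crop[cells, , drop = FALSE]) +
      colSums(est1$grass[cells, , drop = FALSE] *
                area_grass[cells, , drop = FALSE])
    data.frame(country = co, year = years,
               manure_p = tot * runif(1, 0.8, 1.8))
  }))

  crops <- crop_parameters()[seq_len(min(config$n_crops, 3)), , drop = FALSE]
  if (config$n_crops > 3) {
    extra <- crop_parameters()[rep(1, config$n_crops - 3), , drop = FALSE]
    extra$crop <- paste0("cereal", seq_len(nrow(extra)) + 1)
    crops <- rbind(crops, extra)
  }
  ncr <- nrow(crops)
  yield_map2000 <- matrix(runif(n * ncr, 1500, 9000), n, ncr)
  area_map2000 <- matrix(runif(n * ncr, 100, 4000), n, ncr)
  ref_year <- if (2000 %in% years) 2000 else years[ceiling(ny / 2)]
  mk_series <- function(ref_mult_lo, ref_mult_hi) {
    do.call(rbind, lapply(sort(unique(country)), function(co) {
      prof <- cumprod(c(1, 1 + rnorm(ny - 1, 0.01, 0.01)))
      prof <- prof / prof[match(ref_year, years)]
      data.frame(country = co, year = years,
                 value = prof * runif(1, ref_mult_lo, ref_mult_hi))
    }))
  }
  country_yield <- lapply(seq_len(ncr), function(k) mk_series(2000, 8000))
  country_area <- lapply(seq_len(ncr), function(k) mk_series(1e4, 1e5))
  population <- do.call(rbind, lapply(sort(unique(country)), function(co) {
    data.frame(country = co, year = years,
               value = runif(1, 1e6, 5e7) * (1 + 0.012)^(years - years[1]))
  }))

  depo_components <- list(dust = runif(n, 0.02, 0.3),
                          seasalt = runif(n, 0.001, 0.02),
                          pbap = runif(n, 0.005, 0.05),
                          natcomb = runif(n, 0.002, 0.03),
                          anthcomb = runif(n, 0.005, 0.08))
  anth_years <- max(1960, years[1]):min(2013, years[ny])
  anthcomb_series <- data.frame(
    year = anth_years,
    value = (1 + 0.02)^(anth_years - anth_years[1]) *
      (1 + rnorm(length(anth_years), 0, 0.03)))

  sludge_table <- do.call(rbind, lapply(sort(unique(country)), function(co) {
    data.frame(country = co, year = c(1970, 2010),
               excretion = c(runif(1, 0.3, 0.5), runif(1, 0.4, 0.6)),
               frac_treat1 = c(runif(1, 0.05, 0.2), runif(1, 0.1, 0.3)),
               frac_treat2 = c(runif(1, 0, 0.1), runif(1, 0.1, 0.3)),
               frac_treat3 = c(0, runif(1, 0.1, 0.4)))
  }))
  crop_area_country <- do.call(rbind, lapply(sort(unique(country)), function(co) {
    cells <- which(country == co)
    data.frame(country = co, year = years,
               value = colSums(area_crop[cells, , drop = FALSE]))
  }))

  erosion_loss <- list(crop = runif(n, 0, 5000), grass = runif(n, 0, 1500))

  structure(list(
    config = config, years = years, ref_year = ref_year,
    grid = grid, soil = soil,
    natural = natural, climate = climate,
    landuse = list(frac = frac, delta = delta),
    drivers = list(n_manure = n_manure, country_table_manure = country_table,
                   n_chem_grass = field(1, 12), p_chem_total = field(2, 40),
                   npp_tot = outer(runif(n, 2000, 8000), rep(1, ny)) *
                     matrix(runif(n * ny, 0.95, 1.05), n, ny),
                   gi = matrix(pmin(pmax(runif(n, 0.05, 0.3), 0), 1), n, ny),
                   yield_map2000 = yield_map2000, area_map2000 = area_map2000,
                   country_yield = country_yield, country_area = country_area,
                   population = population,
                   depo_components = depo_components,
                   anthcomb_series = anthcomb_series,
                   sludge_table = sludge_table,
                   crop_area_country = crop_area_country,
                   erosion_loss = erosion_loss),
    params = list(grass = grass_parameters(), crops = crops,
                  composition = composition_fractions(),
                  flux = flux_config())
  ), class = "world")
}

#' Generate a steady-state test world
#'
#' Same structure as [make_world()] but with all annual inputs/outputs set to
#' zero, constant climate, no land-use transitions, and rates chosen so the
#' occlusion/de-occlusion pair balances exactly at the start: a harness for
#' conservation and closed-form decay checks.
#'
#' @inheritParams make_world
#' @return list of class `world`.
#' @export
make_steady_world <- function(config = world_config(), seed = 1) {
  w <- make_world(config, seed)
  n <- nrow(w$grid)
  ny <- length(w$years)
  for (v in c("t_soil", "w_rel", "w_abs", "t_air")) {
    w$climate[[v]] <- matrix(w$climate[[v]][, 1], n, ny)
  }
  w$landuse$delta[] <- 0
  for (j in seq_len(ny)) w$landuse$frac[, , j] <- w$landuse$frac[, , 1]
  z <- matrix(0, n, ny)
  w$drivers$n_manure <- list(crop = z, grass = z)
  w$drivers$country_table_manure$manure_p <- 0
  w$drivers$n_chem_grass <- z
  w$drivers$p_chem_total <- z
  w$drivers$npp_tot <- z
  w$drivers$yield_map2000[] <- 0
  w$drivers$depo_components <- lapply(w$drivers$depo_components, function(x) x * 0)
  w$drivers$sludge_table$excretion <- 0
  w$drivers$erosion_loss <- list(crop = rep(0, n), grass = rep(0, n))
  w$steady <- TRUE
  w
}
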