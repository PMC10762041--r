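#' Resolve driver fields of a world into annual P fluxes
#'
#' Turns the raw driver inputs of a [make_world()] bundle into the resolved
#' per-cell-per-year P flux fields (manure, fertilizer, plant uptake and
#' residues per land cover, deposition, sludge, erosion fraction), using the
#' mean of the two estimates wherever an uncertain driver provides a pair.
#' `samples` (produced by the uncertainty machinery) can replace individual
#' resolved inputs.
#'
#' @param world a `world`.
#' @param samples optional named list of sampled replacements (see
#'   [sample_world_drivers()]).
#' @return named list of resolved fields, each a cells x years matrix unless
#'   noted; plus the composition fractions used.
#' @export
resolve_drivers <- function(world, samples = list()) {
  d <- world$drivers
  n <- nrow(world$grid)
  years <- world$years
  ny <- length(years)
  country <- world$grid$country
  frac <- world$landuse$frac
  area_ha <- list(crop = frac[, 1, ] * world$grid$land_area_ha,
                  grass = frac[, 2, ] * world$grid$land_area_ha)

  manure <- samples$manure
  if (is.null(manure)) {
    e1 <- manure_forcing(d$n_manure, 0.20, country, years, mode = "estimate1")
    e2 <- manure_forcing(d$n_manure, 0.20, country, years,
                         country_table = d$country_table_manure,
                         mode = "estimate2", area_ha = area_ha)
    manure <- list(crop = (e1$crop + e2$crop) / 2,
                   grass = (e1$grass + e2$grass) / 2)
  }

  chem <- fertilizer_forcing(d$n_chem_grass, d$p_chem_total,
                             frac[, 1, ], frac[, 2, ])
  if (!is.null(samples$chem_crop_mult)) chem$crop <- chem$crop * samples$chem_crop_mult
  if (!is.null(samples$chem_grass_mult)) chem$grass <- chem$grass * samples$chem_grass_mult

  npp <- samples$npp
  if (is.null(npp)) npp <- d$npp_tot * (1 + 979 / 460) / 2  # mean of estimates
  gparams <- world$params$grass
  if (!is.null(samples$p_pct_above)) {
    gparams <- grass_parameters(p_pct_above = samples$p_pct_above)
  }
  gr <- grassland_plant_forcing(npp, d$gi, gparams)

  ncr <- nrow(world$params$crops)
  yield_all <- lapply(seq_len(ncr), function(k) crop_yield_area_series(
    d$yield_map2000[, k], country, d$country_yield[[k]], years,
    population = d$population, pre1961 = "population",
    ref_year = world$ref_year))
  area_all <- lapply(seq_len(ncr), function(k) crop_yield_area_series(
    d$area_map2000[, k], country, d$country_area[[k]], years,
    pre1961 = "hold", ref_year = world$ref_year))
  crop_upt <- crop_res <- matrix(0, n, ny)
  for (j in seq_len(ny)) {
    yield_j <- vapply(yield_all, function(m) m[, j], numeric(n))
    area_j <- vapply(area_all, function(m) m[, j], numeric(n))
    cf <- cropland_plant_forcing(yield_j, area_j, world$params$crops)
    crop_upt[, j] <- cf$uptake
    crop_res[, j] <- cf$residues_total
  }
  if (!is.null(samples$crop_uptake_mult)) crop_upt <- crop_upt * samples$crop_uptake_mult
  if (!is.null(samples$crop_resi_mult)) crop_res <- crop_res * samples$crop_resi_mult

  depo <- deposition_forcing(d$depo_components, years, d$anthcomb_series)
  if (!is.null(samples$depo_mult)) {
    depo$to_ilab <- depo$to_ilab * samples$depo_mult
    depo$to_iprim <- depo$to_iprim * samples$depo_mult
  }

  sludge <- sludge_forcing(d$sludge_table, d$population, d$crop_area_country,
                           country, years)
  if (!is.null(samples$sludge_mult)) sludge <- sludge * samples$sludge_mult

  loss <- d$erosion_loss
  if (!is.null(samples$loss_mult)) {
    loss <- list(crop = loss$crop * samples$loss_mult$crop,
                 grass = loss$grass * samples$loss_mult$grass)
  }
  eros <- list(crop = erosion_fraction(loss$crop, world$soil),
               grass = erosion_fraction(loss$grass, world$soil))

  comp <- world$params$composition
  if (!is.null(samples$resi_fracs)) {
    comp$residues <- c(i_lab = samples$resi_fracs[["i_lab"]],
                       o_lab = samples$resi_fracs[["o_lab"]],
                       o_sta = max(0, 1 - samples$resi_fracs[["i_lab"]] -
                                     samples$resi_fracs[["o_lab"]]))
  }

  list(manure = manure, chem = chem,
       grass_uptake = gr$uptake, grass_residues = gr$residues_total,
       crop_uptake = crop_upt, crop_residues = crop_res,
       depo_ilab = depo$to_ilab, depo_iprim = depo$to_iprim,
       sludge = sludge, erosion_frac = eros, composition = comp)
}

#' Assemble per-land-cover annual forcings from resolved drivers
#'
#' Applies the composition splits and collects every field the core model
#' consumes. All fluxes are non-negative by construction (negative sampled
#' inputs are floored upstream).
#'
#' @param drv resolved drivers from [resolve_drivers()].
#' @param n_cells,n_years dimensions.
#' @return list with elements `crop` and `grass`; each a list of cells x
#'   years matrices named after `forcing_fields()`.
#' @export
build_forcing <- function(drv, n_cells, n_years) {
  out <- list()
  for (lu in c("crop", "grass")) {
    manu <- split_composition(as.vector(drv$manure[[lu]]), drv$composition$manure)
    if (lu == "crop") {
      resi <- split_composition(as.vector(drv$crop_residues), drv$composition$residues)
      slud <- split_composition(as.vector(drv$sludge), drv$composition$sludge)
      uptake <- drv$crop_uptake
    } else {
      resi <- split_composition(as.vector(drv$grass_residues), drv$composition$residues)
      slud <- split_composition(rep(0, n_cells * n_years), drv$composition$sludge)
      uptake <- drv$grass_uptake
    }
    mm <- function(x) matrix(x, n_cells, n_years)
    out[[lu]] <- list(
      chem_to_ilab = drv$chem[[lu]],
      manure_to_ilab = mm(manu$i_lab), manure_to_olab = mm(manu$o_lab),
      manure_to_osta = mm(manu$o_sta),
      residues_to_ilab = mm(resi$i_lab), residues_to_olab = mm(resi$o_lab),
      residues_to_osta = mm(resi$o_sta),
      sludge_to_ilab = mm(slud$i_lab), sludge_to_olab = mm(slud$o_lab),
      sludge_to_osta = mm(slud$o_sta),
      depo_to_ilab = drv$depo_ilab, depo_to_iprim = drv$depo_iprim,
      uptake_from_ilab = uptake,
      erosion_frac_loss = matrix(drv$erosion_frac[[lu]], n_cells, n_years))
  }
  out
}

forcing_year <- function(forcing_lu, j) {
  as.data.frame(lapply(forcing_lu, function(m) m[, j]))
}

#' Run the full simulation on a world
#'
#' Pipeline per year: land-use transition mixing of the cropland and
#' grassland pools, then the annual P input/output, then 365 daily steps of
#' the pool dynamics. Pools are initialized from the natural-soil background.
#'
#' @param world a `world` from [make_world()].
#' @param samples optional sampled driver replacements (uncertainty runs).
#' @param n_days days per year.
#' @param steps_per_day sub-daily refinement factor (rates rescaled
#'   accordingly).
#' @return list of class `simulation`: `pools` array (cells x land-cover x
#'   pool x years, kgP/ha), `diagnostics` (list of per-land-cover data frames
#'   of annual diagnostics stacked over years), `params`
#'   (`flux_parameters`), `consistency` (the [check_parameter_consistency()]
#'   report), `world` metadata (`years`, `grid`).
#' @export
run_simulation <- function(world, samples = list(), n_days = 365,
                           steps_per_day = 1) {
  n <- nrow(world$grid)
  years <- world$years
  ny <- length(years)
  soil <- if (!is.null(samples$soil)) samples$soil else world$soil
  climate <- if (!is.null(samples$climate)) samples$climate else world$climate
  natural <- if (!is.null(samples$natural)) samples$natural else world$natural

  w_abs_mean <- rowMeans(climate$w_abs)
  t_air_mean <- rowMeans(climate$t_air)
  cfg <- world$params$flux
  ssf <- steady_state_fractions(natural, w_abs_mean, cfg$p_c_inf)
  params <- suppressWarnings(
    build_flux_parameters(soil, ssf, t_air_mean, w_abs_mean, cfg))
  ctx <- areal_context(soil$bulk_density, soil$coarse_frag_frac)
  nat_kgha <- natural_pool_matrix(natural, w_abs_mean, cfg$p_c_inf) *
    ctx$kg_ha_per_mg_kg

  drv <- resolve_drivers(world, samples)
  forcing <- build_forcing(drv, n, ny)
  frac <- world$landuse$frac
  delta <- world$landuse$delta

  pools_kgha <- initialize_pools(natural, w_abs_mean, cfg$p_c_inf, ctx)
  pools <- array(0, c(n, 2, 7, ny),
                 dimnames = list(NULL, c("crop", "grass"), pool_names(), years))
  diag_list <- list(crop = vector("list", ny), grass = vector("list", ny))
  params2 <- rbind(params, params)  # crop rows then grass rows
  climate2 <- function(j) list(t_soil = rep(climate$t_soil[, j], 2),
                               w_rel = rep(climate$w_rel[, j], 2),
                               w_abs = rep(climate$w_abs[, j], 2))
  ctx2 <- areal_context(rep(soil$bulk_density, 2), rep(soil$coarse_frag_frac, 2))

  for (j in seq_len(ny)) {
    if (j > 1) {
      pools_kgha <- apply_lucc(pools_kgha, frac[, , j - 1], frac[, , j],
                               delta[, , , j - 1], nat_kgha)
    }
    state <- rbind(pools_kgha$crop, pools_kgha$grass) / ctx2$kg_ha_per_mg_kg
    fc <- rbind(forcing_year(forcing$crop, j), forcing_year(forcing$grass, j))
    yr <- integrate_year(state, params2, climate2(j), fc, ctx2,
                         n_days = n_days, steps_per_day = steps_per_day)
    st_kgha <- yr$state * ctx2$kg_ha_per_mg_kg
    pools_kgha <- list(crop = st_kgha[seq_len(n), , drop = FALSE],
                       grass = st_kgha[n + seq_len(n), , drop = FALSE])
    pools[, 1, , j] <- pools_kgha$crop
    pools[, 2, , j] <- pools_kgha$grass
    diag_list$crop[[j]] <- cbind(year = years[j], cell = seq_len(n),
                                 yr$diagnostics[seq_len(n), ])
    diag_list$grass[[j]] <- cbind(year = years[j], cell = seq_len(n),
                                  yr$diagnostics[n + seq_len(n), ])
  }
  structure(list(
    pools = pools,
    diagnostics = list(crop = do.call(rbind, diag_list$crop),
                       grass = do.call(rbind, diag_list$grass)),
    params = params, consistency = check_parameter_consistency(params),
    years = years, grid = world$grid, frac = frac
  ), class = "simulation")
}
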