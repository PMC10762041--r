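#' Convert soil P concentration to areal content (and back)
#'
#' `areal = conc * bulk_density * (1 - coarse_frag_frac) * depth * 1e4 * 1e-6`
#' maps mgP per kg soil to kgP per ha for the 0-0.3 m layer; the inverse is
#' an exact round trip.
#'
#' @param conc_mg_per_kg concentration, mgP/kg.
#' @param ctx [areal_context()].
#' @return kgP/ha.
#' @export
concentration_to_areal <- function(conc_mg_per_kg, ctx) {
  stopifnot(all(conc_mg_per_kg >= 0))
  conc_mg_per_kg * ctx$kg_ha_per_mg_kg
}

#' @rdname concentration_to_areal
#' @param areal_kg_per_ha areal content, kgP/ha.
#' @export
areal_to_concentration <- function(areal_kg_per_ha, ctx) {
  stopifnot(all(areal_kg_per_ha >= 0))
  areal_kg_per_ha / ctx$kg_ha_per_mg_kg
}

#' Convert Olsen P to Colwell P
#'
#' Published linear conversions between the two bicarbonate soil P tests:
#' `2.869 * Olsen - 2.93` for non-calcareous soils and
#' `1.376 * Olsen + 8.80` for calcareous soils.
#'
#' @param olsen_value Olsen P (mgP/kg).
#' @param soil_class `"non_calcareous"` or `"calcareous"`.
#' @return Colwell P (mgP/kg).
#' @export
olsen_colwell_convert <- function(olsen_value,
                                  soil_class = c("non_calcareous",
                                                 "calcareous")) {
  soil_class <- match.arg(soil_class)
  if (soil_class == "non_calcareous") 2.869 * olsen_value - 2.93
  else 1.376 * olsen_value + 8.80
}

#' Decile maps and rank correlation between two gridded fields
#'
#' Labels each unmasked cell of both maps by its empirical decile (1-10) and
#' computes the Spearman rank correlation on the raw values (average ranks on
#' ties; tied plateaus, e.g. detection limits, are kept rather than dropped).
#'
#' @param map_a,map_b numeric vectors on a common grid.
#' @param mask logical vector; `TRUE` cells are used (default all).
#' @return list with integer vectors `decile_a`, `decile_b` (`NA` where
#'   masked) and `rank_correlation`.
#' @export
decile_rank_compare <- function(map_a, map_b, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(map_a))
  mask <- mask & is.finite(map_a) & is.finite(map_b)
  if (sum(mask) < 10) stop("fewer than 10 unmasked cells")
  decile <- function(x) {
    r <- rank(x, ties.method = "average")
    as.integer(pmin(ceiling(r / length(x) * 10), 10L))
  }
  da <- db <- rep(NA_integer_, length(map_a))
  da[mask] <- decile(map_a[mask])
  db[mask] <- decile(map_b[mask])
  rho <- stats::cor(map_a[mask], map_b[mask], method = "spearman")
  list(decile_a = da, decile_b = db, rank_correlation = rho)
}

#' Grid-average a site table onto cells
#'
#' Averages point observations (e.g. soil monitoring network sites) within
#' each grid cell, separately per land cover.
#'
#' @param sites data frame with `lon`, `lat`, `land_cover`, `value`.
#' @param grid data frame with `cell`, `lon`, `lat` (cell centres; unit
#'   spacing assumed).
#' @return data frame `cell`, `land_cover`, `value` (cell means).
#' @export
grid_average_sites <- function(sites, grid) {
  ix <- round(sites$lon); iy <- round(sites$lat)
  cell <- grid$cell[match(paste(ix, iy), paste(grid$lon, grid$lat))]
  ok <- !is.na(cell)
  agg <- stats::aggregate(
    list(value = sites$value[ok]),
    by = list(cell = cell[ok], land_cover = sites$land_cover[ok]), FUN = mean)
  agg[order(agg$land_cover, agg$cell), , drop = FALSE]
}
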