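#' Default uncertainty specification per driver variable
#'
#' Which distribution family is attached to each uncertain driver variable.
#' Where two estimates E1/E2 exist, either a normal with 4 sigma spanning
#' them (about 95.4% of draws inside the pair) or, for the most uncertain
#' variables, a uniform; variables with a single estimate E get a normal with
#' a standard deviation of `x/2 * E` (15% or 25% of the mean). Soil P
#' input/output samples are truncated below at 0; background, climate and
#' soil-property samples are truncated at the spatial min/max of the mean
#' field. The table can be edited and passed to [run_ensemble()].
#'
#' @return data frame with columns `variable`, `driver`, `family`, `x`.
#' @export
uncertainty_spec <- function() {
  data.frame(
    variable = c("manure", "chem_grass", "chem_crop", "npp", "grass_p_pct",
                 "resi_comp", "crop_uptake", "crop_residues", "sludge",
                 "depo", "loss", "biog", "clim", "spro"),
    driver = c("FARM", "FARM", "FARM", "FARM", "FARM", "FARM", "FARM",
               "FARM", "SLUD", "DEPO", "LOSS", "BIOG", "CLIM", "SPRO"),
    family = c("uniform", "relative_normal", "relative_normal",
               "normal_4sigma", "normal_4sigma", "uniform",
               "relative_normal", "relative_normal", "relative_normal",
               "relative_normal", "relative_normal", "relative_normal",
               "relative_normal", "relative_normal"),
    x = c(NA, 0.30, 0.30, NA, NA, NA, 0.30, 0.30, 0.50,
          0.30, 0.30, 0.30, 0.30, 0.30)
  )
}

#' Draw a random value for an uncertain driver variable
#'
#' Families: `normal_4sigma` draws from a normal with mean `(E1+E2)/2` and
#' standard deviation `(E2-E1)/4` (so the two estimates sit 2 sigma either
#' side of the mean and about 95.4% of draws fall between them); `uniform`
#' draws from U(E1, E2); `relative_normal` draws from a normal with mean `E`
#' and standard deviation `x/2 * E`. Truncation is enforced by re-drawing
#' out-of-bounds values (no probability mass piles up at the bounds); after
#' 100 re-draws the stragglers are clipped with a warning. Elements are
#' independent (all cells and time steps).
#'
#' @param spec list with `family`; `e1`, `e2` (vectors, for the two-estimate
#'   families) or `e` and `x` (for `relative_normal`); optional `lower`,
#'   `upper` truncation bounds.
#' @return numeric vector of draws, one per element of the estimate inputs.
#' @export
sample_driver_value <- function(spec) {
  fam <- match.arg(spec$family,
                   c("normal_4sigma", "uniform", "relative_normal"))
  lower <- if (is.null(spec$lower)) -Inf else spec$lower
  upper <- if (is.null(spec$upper)) Inf else spec$upper
  if (fam == "relative_normal") {
    e <- as.numeric(spec$e)
    stopifnot(is.numeric(spec$x), spec$x > 0)
    draw <- function(k, idx) stats::rnorm(k, e[idx], spec$x / 2 * abs(e[idx]))
    n <- length(e)
  } else {
    e1 <- as.numeric(spec$e1); e2 <- as.numeric(spec$e2)
    if (any(e1 > e2)) stop("E1 must not exceed E2")
    n <- length(e1)
    draw <- if (fam == "uniform") {
      function(k, idx) stats::runif(k, e1[idx], e2[idx])
    } else {
      function(k, idx) stats::rnorm(k, (e1[idx] + e2[idx]) / 2,
                                    (e2[idx] - e1[idx]) / 4)
    }
  }
  out <- draw(n, seq_len(n))
  lo <- rep_len(lower, n); hi <- rep_len(upper, n)
  bad <- which(out < lo | out > hi)
  tries <- 0
  while (length(bad) && tries < 100) {
    out[bad] <- draw(length(bad), bad)
    bad <- which(out < lo | out > hi)
    tries <- tries + 1
  }
  if (length(bad)) {
    warning(length(bad), " draw(s) clipped to the truncation bounds after ",
            "100 re-draws")
    out[bad] <- pmin(pmax(out[bad], lo[bad]), hi[bad])
  }
  out
}

span_bounds <- function(x) list(lower = min(x), upper = max(x))

#' Sample one ensemble member's driver replacements
#'
#' Draws, for every driver not in `frozen`, the sampled fields consumed by
#' [resolve_drivers()] / [run_simulation()]. Frozen drivers keep their mean
#' values.
#'
#' @param world a `world`.
#' @param frozen character vector among
#'   `c("BIOG","FARM","DEPO","SLUD","LOSS","CLIM","SPRO")`.
#' @param spec uncertainty table from [uncertainty_spec()].
#' @return named list of sampled replacements (`samples` argument of
#'   [run_simulation()]).
#' @export
sample_world_drivers <- function(world, frozen = character(),
                                 spec = uncertainty_spec()) {
  n <- nrow(world$grid)
  ny <- length(world$years)
  country <- world$grid$country
  frac <- world$landuse$frac
  area_ha <- list(crop = frac[, 1, ] * world$grid$land_area_ha,
                  grass = frac[, 2, ] * world$grid$land_area_ha)
  fam <- function(v) spec$family[spec$variable == v]
  xof <- function(v) spec$x[spec$variable == v]
  samples <- list()
  d <- world$drivers

  if (!"FARM" %in% frozen) {
    e1 <- manure_forcing(d$n_manure, 0.20, country, world$years,
                         mode = "estimate1")
    e2 <- manure_forcing(d$n_manure, 0.20, country, world$years,
                         country_table = d$country_table_manure,
                         mode = "estimate2", area_ha = area_ha)
    samples$manure <- list(
      crop = matrix(sample_driver_value(list(
        family = fam("manure"), e1 = pmin(e1$crop, e2$crop),
        e2 = pmax(e1$crop, e2$crop), lower = 0)), n, ny),
      grass = matrix(sample_driver_value(list(
        family = fam("manure"), e1 = pmin(e1$grass, e2$grass),
        e2 = pmax(e1$grass, e2$grass), lower = 0)), n, ny))
    one <- rep(1, n * ny)
    samples$chem_crop_mult <- matrix(pmax(0, sample_driver_value(list(
      family = fam("chem_crop"), e = one, x = xof("chem_crop")))), n, ny)
    samples$chem_grass_mult <- matrix(pmax(0, sample_driver_value(list(
      family = fam("chem_grass"), e = one, x = xof("chem_grass")))), n, ny)
    npp1 <- d$npp_tot
    npp2 <- d$npp_tot * 979 / 460
    samples$npp <- matrix(sample_driver_value(list(
      family = fam("npp"), e1 = npp1, e2 = npp2, lower = 0)), n, ny)
    bounds <- world$params$grass$p_pct_above_bounds
    samples$p_pct_above <- sample_driver_value(list(
      family = fam("grass_p_pct"), e1 = bounds[1], e2 = bounds[2], lower = 0))
    cr <- world$params$composition$residues
    ri <- sample_driver_value(list(family = fam("resi_comp"),
                                   e1 = 0.5 * cr[["i_lab"]],
                                   e2 = 1.5 * cr[["i_lab"]], lower = 0))
    ro <- sample_driver_value(list(family = fam("resi_comp"),
                                   e1 = 0.5 * cr[["o_lab"]],
                                   e2 = 1.5 * cr[["o_lab"]], lower = 0))
    s <- max(ri + ro, 1)  # keep the triple a valid composition
    samples$resi_fracs <- c(i_lab = ri / s, o_lab = ro / s)
    samples$crop_uptake_mult <- matrix(pmax(0, sample_driver_value(list(
      family = fam("crop_uptake"), e = one, x = xof("crop_uptake")))), n, ny)
    samples$crop_resi_mult <- matrix(pmax(0, sample_driver_value(list(
      family = fam("crop_residues"), e = one, x = xof("crop_residues")))), n, ny)
  }
  if (!"SLUD" %in% frozen) {
    samples$sludge_mult <- matrix(pmax(0, sample_driver_value(list(
      family = fam("sludge"), e = rep(1, n * ny), x = xof("sludge")))), n, ny)
  }
  if (!"DEPO" %in% frozen) {
    samples$depo_mult <- matrix(pmax(0, sample_driver_value(list(
      family = fam("depo"), e = rep(1, n * ny), x = xof("depo")))), n, ny)
  }
  if (!"LOSS" %in% frozen) {
    samples$loss_mult <- list(
      crop = pmax(0, sample_driver_value(list(
        family = fam("loss"), e = rep(1, n), x = xof("loss")))),
      grass = pmax(0, sample_driver_value(list(
        family = fam("loss"), e = rep(1, n), x = xof("loss")))))
  }
  if (!"BIOG" %in% frozen) {
    nat <- world$natural
    for (p in names(nat)) {
      b <- span_bounds(nat[[p]])
      nat[[p]] <- sample_driver_value(list(
        family = fam("biog"), e = nat[[p]], x = xof("biog"),
        lower = b$lower, upper = b$upper))
    }
    samples$natural <- nat
  }
  if (!"CLIM" %in% frozen) {
    cl <- world$climate
    for (v in c("t_soil", "w_rel", "w_abs")) {
      b <- span_bounds(cl[[v]])
      cl[[v]] <- matrix(sample_driver_value(list(
        family = fam("clim"), e = cl[[v]], x = xof("clim"),
        lower = max(b$lower, if (v == "w_abs") 1e-6 else -Inf),
        upper = b$upper)), n, ny)
    }
    samples$climate <- cl
  }
  if (!"SPRO" %in% frozen) {
    so <- world$soil
    for (v in c("ph_water", "soil_carbon")) {
      b <- span_bounds(so[[v]])
      so[[v]] <- sample_driver_value(list(
        family = fam("spro"), e = so[[v]], x = xof("spro"),
        lower = b$lower, upper = b$upper))
    }
    # texture sampled jointly, then renormalized so sand+clay+silt = 100
    tex <- sapply(c("sand_pct", "clay_pct", "silt_pct"), function(v) {
      b <- span_bounds(so[[v]])
      sample_driver_value(list(family = fam("spro"), e = so[[v]],
                               x = xof("spro"), lower = max(b$lower, 0),
                               upper = b$upper))
    })
    tex <- tex / rowSums(tex) * 100
    so$sand_pct <- tex[, 1]; so$clay_pct <- tex[, 2]; so$silt_pct <- tex[, 3]
    samples$soil <- so
  }
  samples
}

#' Run a driver-uncertainty ensemble
#'
#' Performs `n` simulations, each with fresh random draws for every driver
#' not in `frozen_drivers`, plus one mean run using mean values for all
#' drivers. Reproducible given `seed`.
#'
#' @param world a `world`.
#' @param n ensemble size (100 in the reference design).
#' @param seed integer seed.
#' @param frozen_drivers drivers to hold at their mean values.
#' @param spec uncertainty table, see [uncertainty_spec()].
#' @param n_days days per year.
#' @return list of class `ensemble`: `members` array (member x cells x
#'   land-cover x pool) of final-year pools in kgP/ha, `mean_run` (the full
#'   `simulation` for mean drivers), `seed`, `frozen_drivers`.
#' @export
run_ensemble <- function(world, n = 100, seed = 1,
                         frozen_drivers = character(),
                         spec = uncertainty_spec(), n_days = 365) {
  bad <- setdiff(frozen_drivers,
                 c("BIOG", "FARM", "DEPO", "SLUD", "LOSS", "CLIM", "SPRO"))
  if (length(bad)) stop("unknown driver(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  ncell <- nrow(world$grid)
  members <- array(NA_real_, c(n, ncell, 2, 7),
                   dimnames = list(NULL, NULL, c("crop", "grass"), pool_names()))
  ny <- length(world$years)
  for (i in seq_len(n)) {
    samples <- suppressWarnings(
      sample_world_drivers(world, frozen_drivers, spec))
    sim <- suppressWarnings(run_simulation(world, samples, n_days = n_days))
    members[i, , , ] <- sim$pools[, , , ny]
  }
  mean_run <- suppressWarnings(run_simulation(world, n_days = n_days))
  structure(list(members = members, mean_run = mean_run, seed = seed,
                 frozen_drivers = frozen_drivers, n = n),
            class = "ensemble")
}

#' Coefficient of variation across ensemble members
#'
#' Population standard deviation divided by the mean, per cell, land cover
#' and pool; entries with non-positive mean are masked (`NA`), not propagated
#' as NaN.
#'
#' @param ensemble an `ensemble` from [run_ensemble()], or a bare array whose
#'   first dimension indexes members.
#' @return array (cells x land-cover x pool) of CVs with `NA` where masked.
#' @export
coefficient_of_variation <- function(ensemble) {
  x <- if (inherits(ensemble, "ensemble")) ensemble$members else ensemble
  n <- dim(x)[1]
  if (n < 2) stop("ensemble size must be at least 2")
  mu <- apply(x, 2:length(dim(x)), mean)
  sd_pop <- sqrt(apply(x, 2:length(dim(x)), function(v) mean((v - mean(v))^2)))
  cv <- sd_pop / mu
  cv[mu <= 0] <- NA_real_
  cv
}
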