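#' Steady-state pool fractions of the inorganic exchange subsystem
#'
#' Computes, per grid cell, the steady-state fractions of the four pools that
#' take part in the inorganic exchange subsystem (solution, labile, secondary,
#' occluded). The solution pool is never observed directly: its steady-state
#' value is reconstructed as the steady-state solution concentration times the
#' mean soil water content. The fractions are the pedotransfer predictors used
#' by [build_flux_parameters()].
#'
#' @param natural data frame (one row per cell) of natural-soil P pools in
#'   mgP per kg soil, with columns `i_lab`, `i_sec`, `i_prim`, `o_lab`,
#'   `o_sta`, `x_occ`. The solution pool is derived, not read.
#' @param w_abs_mean mean soil liquid water content over the simulation
#'   period, L per kg soil (scalar or per-cell vector, > 0).
#' @param p_c_inf steady-state P concentration of the soil solution,
#'   mgP per L (default 0.1).
#' @return data frame with columns `f_i_sol`, `f_i_lab`, `f_i_sec`, `f_x_occ`
#'   (summing to 1 per row), `p_itot_noprim_inf` (the denominator: total
#'   inorganic P excluding primary, mgP/kg) and `p_otot_inf`
#'   (`o_lab + o_sta`, mgP/kg).
#' @export
steady_state_fractions <- function(natural, w_abs_mean, p_c_inf = 0.1) {
  stopifnot(all(w_abs_mean > 0), all(p_c_inf >= 0))
  req <- c("i_lab", "i_sec", "i_prim", "o_lab", "o_sta", "x_occ")
  if (!all(req %in% names(natural))) {
    stop("natural pools must have columns: ", paste(req, collapse = ", "))
  }
  if (any(vapply(natural[req], function(x) any(!is.finite(x) | x < 0), TRUE))) {
    stop("natural pools must be finite and non-negative")
  }
  i_sol <- p_c_inf * w_abs_mean
  denom <- i_sol + natural$i_lab + natural$i_sec + natural$x_occ
  if (any(denom <= 0)) {
    stop("degenerate steady state: all four inorganic exchange pools are zero",
         " for cell(s) ", paste(which(denom <= 0), collapse = ", "))
  }
  data.frame(
    f_i_sol = i_sol / denom,
    f_i_lab = natural$i_lab / denom,
    f_i_sec = natural$i_sec / denom,
    f_x_occ = natural$x_occ / denom,
    p_itot_noprim_inf = denom,
    p_otot_inf = natural$o_lab + natural$o_sta
  )
}

#' Configuration of the flux parameterization
#'
#' @param p_c_inf steady-state solution P concentration, mgP/L.
#' @param mineralization_preset `"v1.1"` (default; organic residence times of
#'   15 and 2 years) or `"v1.0"` (100 and 10 years).
#' @param k_weathering apatite weathering rate, day^-1.
#' @return list of configuration values.
#' @export
flux_config <- function(p_c_inf = 0.1, mineralization_preset = c("v1.1", "v1.0"),
                        k_weathering = 2.7e-7) {
  mineralization_preset <- match.arg(mineralization_preset)
  rates <- switch(mineralization_preset,
    "v1.0" = c(k_min_stable = 2.7e-5, k_min_labile = 2.7e-4),
    "v1.1" = c(k_min_stable = 1.8e-4, k_min_labile = 1.4e-3)
  )
  list(p_c_inf = p_c_inf, mineralization_preset = mineralization_preset,
       k_weathering = k_weathering,
       k_min_stable = unname(rates["k_min_stable"]),
       k_min_labile = unname(rates["k_min_labile"]))
}

#' Build cell-level flux parameters from soil properties
#'
#' Evaluates the pedotransfer regressions (fitted against the isotope-exchange
#' database with oxalate concentrations excluded, so they can be applied where
#' oxalate data are unavailable) for the Freundlich exponent `b`, the
#' labile-to-solution rate, the solution-to-secondary rate and the occlusion
#' rate; the reverse rates then follow from the steady-state ratio identities,
#' which hold exactly by construction:
#' \deqn{k^{sol \to lab}/k^{lab \to sol} = f_{i.lab}\bar W / (b P_c^{b-1} f_{i.sol})}
#' \deqn{k^{sol \to sec}/k^{sec \to sol} = f_{i.sec}\bar W / (b P_c^{b-1} f_{i.sol})}
#' \deqn{k^{occ \to sec}/k^{sec \to occ} = f_{i.sec}/f_{x.occ}}
#' Weathering and mineralization rates are taken from `config`. Parameters are
#' time-invariant and shared between cropland and grassland.
#'
#' The linear regression for the labile-to-solution rate can return
#' non-positive values; these are floored at 1e-6 day^-1 (with a warning
#' identifying the cells), because a non-positive rate makes the
#' solution-labile equilibrium ill-posed.
#'
#' @param soil data frame (one row per cell) with columns `sand_pct`,
#'   `clay_pct`, `silt_pct`, `ph_water`, `soil_carbon` (gC/kg),
#'   `bulk_density` (kg/m^3), `coarse_frag_frac`.
#' @param frac steady-state fractions from [steady_state_fractions()].
#' @param t_air_mean mean annual near-surface air temperature, degrees C.
#' @param w_abs_mean mean soil liquid water content, L/kg.
#' @param config list from [flux_config()].
#' @return data frame of class `flux_parameters`: `b`, `k_lab_to_sol`,
#'   `k_sol_to_lab`, `k_sol_to_sec`, `k_sec_to_sol`, `k_sec_to_occ`,
#'   `k_occ_to_sec`, `k_weathering`, `k_min_stable`, `k_min_labile`,
#'   `p_c_inf`, `w_abs_mean`.
#' @export
build_flux_parameters <- function(soil, frac, t_air_mean, w_abs_mean,
                                  config = flux_config()) {
  validate_soil_properties(soil)
  n <- nrow(frac)
  p_c_inf <- config$p_c_inf
  b <- freundlich_b(frac$f_i_sol, frac$f_i_lab, soil$sand_pct)
  k_lab_to_sol <- -4.82 + 209 * frac$f_i_sol + 14.64 * frac$f_x_occ +
    9.26 * frac$f_i_sec - 0.008 * soil$soil_carbon -
    0.0003 * frac$p_itot_noprim_inf - 0.018 * soil$silt_pct
  low <- which(k_lab_to_sol < 1e-6)
  if (length(low)) {
    warning("k_lab_to_sol regression non-positive for cell(s) ",
            paste(low, collapse = ", "), "; floored at 1e-6 day^-1")
    k_lab_to_sol[low] <- 1e-6
  }
  k_sol_to_sec <- exp(0.002 + 4.0 * frac$f_i_sec + 0.0008 * frac$p_otot_inf +
                        0.012 * soil$soil_carbon + 0.108 * t_air_mean -
                        0.0002 * frac$p_itot_noprim_inf)
  k_sec_to_occ <- 3.68e-5 + 9.60e-5 * frac$f_x_occ - 1.47e-4 * frac$f_i_sec +
    1.22e-5 * soil$ph_water - 4.07e-7 * soil$clay_pct +
    5.16e-8 * soil$soil_carbon
  # ratio identities; the common factor of the two sorption ratios
  ratio_core <- w_abs_mean / (b * p_c_inf^(b - 1) * frac$f_i_sol)
  k_sol_to_lab <- k_lab_to_sol * frac$f_i_lab * ratio_core
  k_sec_to_sol <- k_sol_to_sec / (frac$f_i_sec * ratio_core)
  k_occ_to_sec <- k_sec_to_occ * frac$f_i_sec / frac$f_x_occ
  out <- data.frame(
    b = b, k_lab_to_sol = k_lab_to_sol, k_sol_to_lab = k_sol_to_lab,
    k_sol_to_sec = k_sol_to_sec, k_sec_to_sol = k_sec_to_sol,
    k_sec_to_occ = k_sec_to_occ, k_occ_to_sec = k_occ_to_sec,
    k_weathering = rep_len(config$k_weathering, n),
    k_min_stable = rep_len(config$k_min_stable, n),
    k_min_labile = rep_len(config$k_min_labile, n),
    p_c_inf = rep_len(p_c_inf, n),
    w_abs_mean = rep_len(w_abs_mean, n)
  )
  bad <- which(!stats::complete.cases(out) |
                 rowSums(as.matrix(out[1:10]) <= 0) > 0)
  if (length(bad)) {
    stop("non-finite or non-positive flux parameter for cell(s) ",
         paste(bad, collapse = ", "))
  }
  class(out) <- c("flux_parameters", class(out))
  out
}

#' Flag flux parameters inconsistent with a daily time step
#'
#' A gross flux leaving a pool in one day should not exceed the pool itself.
#' For the secondary-to-solution rate this requires `k_sec_to_sol < 1` day^-1;
#' for the Freundlich sorption rate it requires
#' `k_sol_to_sec < w_abs_mean * p_c_inf^(1 - b)`. Cells above these bounds are
#' flagged (the daily integrator then relies on flux clamping there); the
#' parameters themselves are never modified.
#'
#' @param params `flux_parameters` from [build_flux_parameters()].
#' @return list with per-cell logical vectors `flag_sec_to_sol`,
#'   `flag_sol_to_sec`, the numeric `bound_sol_to_sec`, and integer counts
#'   `n_flagged_sec_to_sol`, `n_flagged_sol_to_sec`.
#' @export
check_parameter_consistency <- function(params) {
  bound <- params$w_abs_mean * params$p_c_inf^(1 - params$b)
  f1 <- params$k_sec_to_sol >= 1
  f2 <- params$k_sol_to_sec >= bound
  list(flag_sec_to_sol = f1, flag_sol_to_sec = f2, bound_sol_to_sec = bound,
       n_flagged_sec_to_sol = sum(f1), n_flagged_sol_to_sec = sum(f2))
}

# Freundlich exponent regression (oxalate-free form)
freundlich_b <- function(f_i_sol, f_i_lab, sand_pct) {
  exp(-0.628 - 36.702 * f_i_sol + 1.102 * f_i_lab + 0.0024 * sand_pct)
}

validate_soil_properties <- function(soil) {
  req <- c("sand_pct", "clay_pct", "silt_pct", "ph_water", "soil_carbon",
           "bulk_density", "coarse_frag_frac")
  if (!all(req %in% names(soil))) {
    stop("soil properties must have columns: ", paste(req, collapse = ", "))
  }
  tex <- soil$sand_pct + soil$clay_pct + soil$silt_pct
  if (any(abs(tex - 100) > 0.5)) stop("texture percentages must sum to 100 +/- 0.5")
  if (any(soil$ph_water < 2 | soil$ph_water > 12)) stop("pH out of [2, 12]")
  num <- vapply(soil[req], function(x) any(!is.finite(x) | x < 0), TRUE)
  if (any(num)) stop("soil properties must be finite and non-negative")
  if (any(soil$coarse_frag_frac >= 1)) stop("coarse_frag_frac must be < 1")
  invisible(TRUE)
}
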