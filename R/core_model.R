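#' Names of the seven soil P pools
#'
#' Solution inorganic P, labile inorganic P, secondary (moderately labile)
#' inorganic P, primary (apatite) P, labile organic P, stable organic P, and
#' occluded P, in the fixed internal order.
#' @return character vector of length 7.
#' @export
pool_names <- function() {
  c("i_sol", "i_lab", "i_sec", "i_prim", "o_lab", "o_sta", "x_occ")
}

as_pool_matrix <- function(state) {
  m <- as.matrix(state)
  if (is.null(dim(m)) || ncol(m) != 7) stop("state must have 7 pool columns")
  colnames(m) <- pool_names()
  storage.mode(m) <- "double"
  m
}

#' Temperature and moisture response scalars
#'
#' Weathering responds to soil temperature with a Q10 of 2.4 referenced to
#' 15 degrees C (`g1`) and linearly to relative soil water (`g2 = w_rel`).
#' Mineralization responds with a Q10 of 2 referenced to 30 degrees C (`h1`)
#' and through the moisture polynomial
#' `h2 = -1.1 w^2 + 2.4 w - 0.29`, clamped at 0 where the polynomial is
#' negative (very dry soils, w_rel below about 0.13) so mineralization cannot
#' reverse direction.
#'
#' @param t_soil soil temperature, degrees C.
#' @param w_rel relative soil water content (fraction of field capacity, >= 0).
#' @return list with numeric vectors `g1`, `g2`, `h1`, `h2`.
#' @export
response_scalars <- function(t_soil, w_rel) {
  stopifnot(all(w_rel >= 0))
  list(
    g1 = 2.4^((t_soil - 15) / 10),
    g2 = w_rel,
    h1 = 2^((t_soil - 30) / 10),
    h2 = pmax(0, -1.1 * w_rel^2 + 2.4 * w_rel - 0.29)
  )
}

#' Redistribute solution + labile P at the Freundlich equilibrium
#'
#' Assuming a daily steady state between solution and labile inorganic P
#' (desorption `k_lab_to_sol * P_lab` balancing Freundlich sorption
#' `k_sol_to_lab * (P_sol / W)^b`), the total `P_sol + P_lab` is split by
#' solving, for `P_sol` in `[0, total]`,
#' \deqn{k^{sol\to lab} P_{sol}^b + k^{lab\to sol} W^b P_{sol}
#'       - k^{lab\to sol} W^b (P_{sol}+P_{lab}) = 0.}
#' The left-hand side is strictly increasing, so the root is unique; it is
#' found by safeguarded Newton iteration with a bisection bracket.
#'
#' @param total_sol_lab total solution + labile P, mgP/kg (vector).
#' @param params `flux_parameters` rows aligned with `total_sol_lab`.
#' @param w_abs soil water content, L/kg (> 0).
#' @return list with `p_i_sol` and `p_i_lab`; the two sum to the input total
#'   exactly and are both non-negative.
#' @export
solve_sol_lab_equilibrium <- function(total_sol_lab, params, w_abs) {
  stopifnot(all(total_sol_lab >= 0), all(w_abs > 0))
  n <- length(total_sol_lab)
  b <- rep_len(params$b, n)
  k_sl <- rep_len(params$k_sol_to_lab, n)
  k_ls <- rep_len(params$k_lab_to_sol, n)
  w <- rep_len(w_abs, n)
  p_sol <- .eq_solve_cpp(as.numeric(total_sol_lab), b, k_sl, k_ls, w)
  resid <- k_sl * p_sol^b + k_ls * w^b * (p_sol - total_sol_lab)
  tol <- 1e-10 * pmax(1, total_sol_lab) * pmax(1, k_ls * w^b)
  if (any(abs(resid) > tol)) {
    i <- which.max(abs(resid) / tol)
    stop(sprintf(paste0("equilibrium solver did not converge: total=%g, b=%g, ",
                        "k_sol_to_lab=%g, k_lab_to_sol=%g, w_abs=%g, resid=%g"),
                 total_sol_lab[i], b[i], k_sl[i], k_ls[i], w[i], resid[i]))
  }
  list(p_i_sol = p_sol, p_i_lab = total_sol_lab - p_sol)
}

#' One daily step of the seven-pool dynamics
#'
#' Gross fluxes (occlusion, de-occlusion, Freundlich sorption to the secondary
#' pool, desorption, weathering, mineralization) are computed from
#' start-of-day pools; each pool's outflows are then scaled by a common factor
#' where they would otherwise drive the pool negative; pools are updated; and
#' finally the solution-labile equilibrium redistributes `i_sol + i_lab`. All
#' fluxes are internal, so the step conserves total P exactly.
#'
#' @param state matrix (units x 7) of pools in mgP/kg, columns in
#'   [pool_names()] order.
#' @param params `flux_parameters` rows aligned with `state`.
#' @param climate data frame/list with `t_soil`, `w_rel`, `w_abs` per unit.
#' @return list with updated `state` and the day's gross `fluxes`
#'   (mgP/kg/day, after clamping).
#' @export
daily_pool_update <- function(state, params, climate) {
  out <- integrate_days(state, params, climate, n_days = 1)
  list(state = out$state, fluxes = out$fluxes)
}

integrate_days <- function(state, params, climate, n_days, steps_per_day = 1) {
  m <- as_pool_matrix(state)
  if (any(m < 0)) stop("negative pool on entry to daily dynamics")
  n <- nrow(m)
  rs <- response_scalars(rep_len(climate$t_soil, n), rep_len(climate$w_rel, n))
  pm <- cbind(params$b, params$k_lab_to_sol, params$k_sol_to_lab,
              params$k_sol_to_sec, params$k_sec_to_sol, params$k_sec_to_occ,
              params$k_occ_to_sec, params$k_weathering, params$k_min_stable,
              params$k_min_labile)
  if (nrow(pm) != n) pm <- pm[rep_len(seq_len(nrow(pm)), n), , drop = FALSE]
  res <- .integrate_days_cpp(m, pm, rs$g1, rs$g2, rs$h1, rs$h2,
                             rep_len(as.numeric(climate$w_abs), n),
                             as.integer(n_days * steps_per_day),
                             1 / steps_per_day)
  colnames(res$pools) <- pool_names()
  res$state <- res$pools
  res
}

#' Conversion context between concentration and areal units
#'
#' @param bulk_density fine-earth bulk density, kg/m^3.
#' @param coarse_frag_frac volumetric coarse-fragment fraction in [0, 1).
#' @param depth soil layer depth, m (0.3 by default; the plough layer).
#' @return list of class `areal_ctx` with the inputs and the factor
#'   `kg_ha_per_mg_kg` (kgP/ha per mgP/kg).
#' @export
areal_context <- function(bulk_density, coarse_frag_frac, depth = 0.3) {
  stopifnot(all(bulk_density > 0), all(coarse_frag_frac >= 0),
            all(coarse_frag_frac < 1))
  structure(list(bulk_density = bulk_density,
                 coarse_frag_frac = coarse_frag_frac, depth = depth,
                 kg_ha_per_mg_kg =
                   bulk_density * (1 - coarse_frag_frac) * depth * 1e4 * 1e-6),
            class = "areal_ctx")
}

#' Field names of an annual forcing record
#'
#' P fluxes in kgP/ha/yr; `erosion_frac_loss` is a fraction per year.
#' @return character vector of the 14 field names.
#' @export
forcing_fields <- function() {
  c("chem_to_ilab", "manure_to_ilab", "manure_to_olab", "manure_to_osta",
    "residues_to_ilab", "residues_to_olab", "residues_to_osta",
    "sludge_to_ilab", "sludge_to_olab", "sludge_to_osta",
    "depo_to_ilab", "depo_to_iprim", "uptake_from_ilab", "erosion_frac_loss")
}

#' An all-zero annual forcing for `n` units
#' @param n number of simulation units (rows).
#' @return data frame of zeros with the [forcing_fields()] columns.
#' @export
zero_forcing <- function(n) {
  as.data.frame(matrix(0, n, length(forcing_fields()),
                       dimnames = list(NULL, forcing_fields())))
}

validate_forcing <- function(forcing) {
  miss <- setdiff(forcing_fields(), names(forcing))
  if (length(miss)) stop("forcing lacks fields: ", paste(miss, collapse = ", "))
  if (any(as.matrix(forcing[forcing_fields()]) < 0)) {
    stop("forcing fields must be non-negative (uptake is a positive magnitude)")
  }
  invisible(TRUE)
}

#' Apply the annual P input/output to the pools
#'
#' On the first day of each year: erosion removes `erosion_frac_loss` of each
#' pool except solution P (solution-P erosion is set to zero); the year's
#' inputs are added to their destination pools; and plant uptake is removed
#' from labile inorganic P. If solution + labile P cannot sustain the uptake,
#' both are set to 0, the shortfall is recorded as unsatisfied uptake
#' (`fP_upns`) and the satisfied uptake is reduced accordingly -- a recorded
#' outcome, not an error.
#'
#' @param state matrix (units x 7) of pools in mgP/kg.
#' @param forcing data frame with the fields of `forcing_fields()`; P fluxes
#'   in kgP/ha/yr, `erosion_frac_loss` in 1/yr.
#' @param ctx [areal_context()] aligned with the units.
#' @return list: updated `state`, `fP_upns` (kgP/ha/yr),
#'   `uptake_satisfied` (kgP/ha/yr), `erosion_losses` (units x 7, kgP/ha/yr)
#'   and `inputs_total` (kgP/ha/yr).
#' @export
apply_annual_io <- function(state, forcing, ctx) {
  m <- as_pool_matrix(state)
  validate_forcing(forcing)
  n <- nrow(m)
  cf <- rep_len(ctx$kg_ha_per_mg_kg, n)
  fr <- pmin(rep_len(forcing$erosion_frac_loss, n), 1)

  eros <- m * fr
  eros[, "i_sol"] <- 0
  m <- m - eros
  eros_kgha <- eros * cf

  add <- function(pool, kgha) m[, pool] <<- m[, pool] + kgha / cf
  add("i_lab", forcing$chem_to_ilab + forcing$manure_to_ilab +
        forcing$residues_to_ilab + forcing$sludge_to_ilab +
        forcing$depo_to_ilab)
  add("o_lab", forcing$manure_to_olab + forcing$residues_to_olab +
        forcing$sludge_to_olab)
  add("o_sta", forcing$manure_to_osta + forcing$residues_to_osta +
        forcing$sludge_to_osta)
  add("i_prim", forcing$depo_to_iprim)

  uptake <- rep_len(forcing$uptake_from_ilab, n)
  m[, "i_lab"] <- m[, "i_lab"] - uptake / cf
  # any split of (i_sol + i_lab) is immaterial: the equilibrium re-splits it
  neg_lab <- m[, "i_lab"] < 0
  m[neg_lab, "i_sol"] <- m[neg_lab, "i_sol"] + m[neg_lab, "i_lab"]
  m[neg_lab, "i_lab"] <- 0
  shortfall <- pmax(0, -m[, "i_sol"])
  m[, "i_sol"] <- pmax(0, m[, "i_sol"])
  fP_upns <- shortfall * cf

  inputs_total <- rowSums(forcing[c("chem_to_ilab", "manure_to_ilab",
    "manure_to_olab", "manure_to_osta", "residues_to_ilab", "residues_to_olab",
    "residues_to_osta", "sludge_to_ilab", "sludge_to_olab", "sludge_to_osta",
    "depo_to_ilab", "depo_to_iprim")])
  list(state = m, fP_upns = fP_upns, uptake_satisfied = uptake - fP_upns,
       erosion_losses = eros_kgha, inputs_total = rep_len(inputs_total, n))
}

#' Integrate one simulation year
#'
#' Applies the annual input/output once, then runs `n_days` daily steps of the
#' pool dynamics. The annual mass balance closes by construction:
#' change in total P (kgP/ha) = inputs - erosion - satisfied uptake.
#'
#' @inheritParams apply_annual_io
#' @param params `flux_parameters` aligned with the units.
#' @param climate per-unit `t_soil`, `w_rel`, `w_abs` for the year.
#' @param n_days days per year (365; no leap years).
#' @param steps_per_day sub-daily refinement factor: the year is integrated in
#'   `n_days * steps_per_day` steps with rates scaled by `1/steps_per_day`.
#' @return list: `state`, `diagnostics` (data frame with inputs, erosion,
#'   uptake, unsatisfied uptake, annual internal fluxes in kgP/ha/yr,
#'   `clamp_events`, and the mass-balance residual `balance_residual`).
#' @export
integrate_year <- function(state, params, climate, forcing, ctx,
                           n_days = 365, steps_per_day = 1) {
  stopifnot(n_days >= 1)
  m0 <- as_pool_matrix(state)
  n <- nrow(m0)
  cf <- rep_len(ctx$kg_ha_per_mg_kg, n)
  io <- apply_annual_io(m0, forcing, ctx)
  dyn <- integrate_days(io$state, params, climate, n_days, steps_per_day)
  total0 <- rowSums(m0) * cf
  total1 <- rowSums(dyn$state) * cf
  eros_tot <- rowSums(io$erosion_losses)
  resid <- (total1 - total0) - (io$inputs_total - eros_tot - io$uptake_satisfied)
  diagnostics <- data.frame(
    inputs_total = io$inputs_total, erosion_total = eros_tot,
    uptake_prescribed = rep_len(forcing$uptake_from_ilab, n),
    uptake_satisfied = io$uptake_satisfied, fP_upns = io$fP_upns,
    dyn$fluxes * cf, clamp_events = dyn$clamp_events,
    balance_residual = resid)
  list(state = dyn$state, diagnostics = diagnostics,
       erosion_losses = io$erosion_losses)
}
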