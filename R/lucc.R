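#' Land-use categories of the simulation
#' @return `c("crop", "grass", "nonagri", "urban")`
#' @export
landuse_categories <- function() c("crop", "grass", "nonagri", "urban")

raw_landuse_categories <- function() {
  c("c3ann", "c3nfx", "c3per", "c4ann", "c4per", "pastr", "range",
    "primf", "primn", "secdf", "secdn", "urban")
}

#' Aggregate raw land-use classes to the four simulation categories
#'
#' Cropland sums the five crop classes, grassland is managed pasture plus
#' rangeland, non-agricultural land pools the primary/secondary classes, and
#' urban maps to itself; transitions are summed consistently.
#'
#' @param raw_fractions array cells x 12 x years (raw class names on dim 2).
#' @param raw_transitions array cells x 12 x 12 x years (from, to).
#' @return list with `frac` (cells x 4 x years) and `delta`
#'   (cells x 4 x 4 x years, from j to i).
#' @export
aggregate_landuse <- function(raw_fractions, raw_transitions = NULL) {
  map <- list(crop = c("c3ann", "c3nfx", "c3per", "c4ann", "c4per"),
              grass = c("pastr", "range"),
              nonagri = c("primf", "primn", "secdf", "secdn"),
              urban = "urban")
  raw_names <- dimnames(raw_fractions)[[2]]
  if (is.null(raw_names)) raw_names <- raw_landuse_categories()
  unknown <- setdiff(raw_names, raw_landuse_categories())
  if (length(unknown)) stop("unknown land-use category: ",
                            paste(unknown, collapse = ", "))
  lus <- landuse_categories()
  d <- dim(raw_fractions)
  frac <- array(0, c(d[1], 4, d[3]), dimnames = list(NULL, lus, NULL))
  for (lu in lus) {
    idx <- match(map[[lu]], raw_names)
    frac[, lu, ] <- apply(raw_fractions[, idx, , drop = FALSE], c(1, 3), sum)
  }
  delta <- NULL
  if (!is.null(raw_transitions)) {
    dt <- dim(raw_transitions)
    delta <- array(0, c(dt[1], 4, 4, dt[4]),
                   dimnames = list(NULL, lus, lus, NULL))
    for (j in lus) for (i in lus) {
      jj <- match(map[[j]], raw_names); ii <- match(map[[i]], raw_names)
      delta[, j, i, ] <- apply(raw_transitions[, jj, ii, , drop = FALSE],
                               c(1, 4), sum)
      if (i == j) delta[, j, i, ] <- 0  # within-category moves are not LUCC
    }
  }
  list(frac = frac, delta = delta)
}

#' Natural-soil pool matrix including the derived solution pool
#'
#' @param natural data frame of natural pools, mgP/kg.
#' @param w_abs_mean mean soil water content, L/kg.
#' @param p_c_inf steady-state solution concentration, mgP/L.
#' @return matrix cells x 7 in mgP/kg, [pool_names()] order; the solution
#'   pool is `p_c_inf * w_abs_mean`.
#' @export
natural_pool_matrix <- function(natural, w_abs_mean, p_c_inf = 0.1) {
  n <- nrow(natural)
  cbind(i_sol = rep_len(p_c_inf * w_abs_mean, n), i_lab = natural$i_lab,
        i_sec = natural$i_sec, i_prim = natural$i_prim, o_lab = natural$o_lab,
        o_sta = natural$o_sta, x_occ = natural$x_occ)
}

#' Initial cropland and grassland pools
#'
#' At the simulation start both agricultural covers inherit the natural-soil
#' pools; the solution pool is initialized at the steady-state concentration
#' times the mean water content.
#'
#' @inheritParams natural_pool_matrix
#' @param ctx [areal_context()] (kgP/ha output) or `NULL` for mgP/kg.
#' @return list with matrices `crop` and `grass` (cells x 7).
#' @export
initialize_pools <- function(natural, w_abs_mean, p_c_inf = 0.1, ctx = NULL) {
  m <- natural_pool_matrix(natural, w_abs_mean, p_c_inf)
  if (!is.null(ctx)) m <- m * rep_len(ctx$kg_ha_per_mg_kg, nrow(m))
  list(crop = m, grass = m)
}

#' Mix cropland/grassland pools across one year of land-use transitions
#'
#' Area-weighted pool bookkeeping: the P stock of a cover after transitions is
#' the stock retained from the previous year plus the stock imported by
#' incoming conversions, divided by the new cover fraction. Land converted
#' from non-agricultural cover imports the natural-soil pools; land from
#' urban cover imports zero P. A cover whose fraction reaches 0 stores zeroed
#' pools (they carry weight 0 and are never read).
#'
#' @param pools list with matrices `crop` and `grass` (cells x 7, kgP/ha).
#' @param frac_prev,frac_now matrices cells x 4 of land-cover fractions for
#'   the previous and the current year (columns [landuse_categories()]).
#' @param delta array cells x 4 x 4 (from j to i) of transitions during the
#'   previous year.
#' @param natural_kgha matrix cells x 7 of natural pools in kgP/ha (with the
#'   derived solution pool).
#' @return list with updated `crop` and `grass` pool matrices (kgP/ha).
#' @export
apply_lucc <- function(pools, frac_prev, frac_now, delta, natural_kgha) {
  lus <- landuse_categories()
  n <- nrow(frac_prev)
  out_tot <- apply(delta, c(1, 2), sum)  # total leaving each source cover
  if (any(out_tot > frac_prev + 1e-9)) {
    stop("transitions exceed the source land-cover fraction")
  }
  pool_of <- function(lu) {
    switch(lu, crop = pools$crop, grass = pools$grass,
           nonagri = natural_kgha, urban = matrix(0, n, 7))
  }
  res <- list()
  for (lu in c("crop", "grass")) {
    others <- setdiff(lus, lu)
    leaving <- rowSums(delta[, lu, others, drop = FALSE])
    incoming <- rowSums(delta[, others, lu, drop = FALSE])
    stock <- (frac_prev[, lu] - leaving) * pool_of(lu)
    for (j in others) stock <- stock + delta[, j, lu] * pool_of(j)
    newp <- matrix(0, n, 7, dimnames = list(NULL, pool_names()))
    pos <- frac_now[, lu] > 0
    newp[pos, ] <- stock[pos, , drop = FALSE] / frac_now[pos, lu]
    untouched <- pos & leaving == 0 & incoming == 0 &
      frac_prev[, lu] == frac_now[, lu]
    newp[untouched, ] <- pool_of(lu)[untouched, , drop = FALSE]
    if (any(newp < -1e-9)) stop("negative pool after land-use mixing")
    newp[newp < 0] <- 0
    res[[lu]] <- newp
  }
  res
}
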