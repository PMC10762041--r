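test_that("manure: P:N conversion and country rescaling", {
  n_manure <- list(crop = matrix(10, 2, 3), grass = matrix(5, 2, 3))
  e1 <- manure_forcing(n_manure, 0.20, country = c(1, 1), years = 2000:2002)
  expect_equal(e1$crop, matrix(2, 2, 3))
  expect_equal(e1$grass, matrix(1, 2, 3))

  # estimate 2 scales every cell of a country by table-mean / estimate1-mean
  area <- list(crop = matrix(100, 2, 3), grass = matrix(50, 2, 3))
  # estimate-1 country total per year: 2*(2*100) + 2*(1*50) = 500 kgP
  tab <- data.frame(country = 1, year = 2000:2002, manure_p = 1000)
  e2 <- manure_forcing(n_manure, 0.20, c(1, 1), 2000:2002, tab, "estimate2",
                       area_ha = area, window = 2000:2002)
  expect_equal(e2$crop, 2 * e1$crop)
  expect_equal(e2$grass, 2 * e1$grass)

  # zero N everywhere -> both estimates zero (with a warning for estimate 2)
  zero <- list(crop = matrix(0, 2, 3), grass = matrix(0, 2, 3))
  expect_equal(manure_forcing(zero, 0.20, c(1, 1), 2000:2002)$crop,
               matrix(0, 2, 3))
  expect_warning(
    e0 <- manure_forcing(zero, 0.20, c(1, 1), 2000:2002, tab, "estimate2",
                         area_ha = area, window = 2000:2002),
    "zero")
  expect_equal(e0$crop, matrix(0, 2, 3))
  expect_error(manure_forcing(n_manure, 0.20, c(1, NA), 2000:2002),
               "country")
})

test_that("manure estimate-2 country means reproduce the country table", {
  w <- tiny_world(seed = 3)
  area <- list(crop = w$landuse$frac[, 1, ] * w$grid$land_area_ha,
               grass = w$landuse$frac[, 2, ] * w$grid$land_area_ha)
  e2 <- manure_forcing(w$drivers$n_manure, 0.20, w$grid$country, w$years,
                       w$drivers$country_table_manure, "estimate2",
                       area_ha = area, window = w$years)
  for (co in unique(w$grid$country)) {
    cells <- w$grid$country == co
    tot2 <- colSums(e2$crop[cells, ] * area$crop[cells, ]) +
      colSums(e2$grass[cells, ] * area$grass[cells, ])
    tab <- w$drivers$country_table_manure
    expect_equal(mean(tot2),
                 mean(tab$manure_p[tab$country == co]), tolerance = 1e-10)
  }
})

test_that("fertilizer: grassland P:N ratio and cropland correction", {
  f <- fertilizer_forcing(10, 0, frac_crop = 0.5, frac_grass = 0.25)
  expect_equal(f$grass, 2.2)
  f <- fertilizer_forcing(10 / 2.2, 5, frac_crop = 0.5, frac_grass = 0.25)
  expect_equal(f$grass, 1, tolerance = 1e-12)
  expect_equal(f$crop, (5 * 0.5 - 1 * 0.25) / 0.5, tolerance = 1e-12)
  # no grassland: cropland keeps the whole total; no cropland: zero
  expect_equal(fertilizer_forcing(0, 7, 0.4, 0)$crop, 7)
  expect_equal(fertilizer_forcing(10, 7, 0, 0.3)$crop, 0)
  # over-subtraction is floored at zero
  expect_equal(fertilizer_forcing(100, 1, 0.1, 0.9)$crop, 0)
})

test_that("grassland uptake follows the NPP/stoichiometry form", {
  gp <- grass_parameters(p_pct_above = 0.088)
  npp_tot <- 2000 + 2348
  out <- grassland_plant_forcing(npp_tot, gi = 0.2, gp)
  above <- 0.46 * npp_tot; below <- 0.54 * npp_tot
  expected <- (1 / 0.45) * (1 / 0.20) *
    (0.088 / 100 * 0.8 * above + 0.044 / 100 * 0.7 * below)
  expect_equal(out$uptake, expected, tolerance = 1e-12)
  expect_equal(expected, 23.68, tolerance = 0.01)
  expect_equal(out$residues_total, 0.8 * expected, tolerance = 1e-12)
  # full appropriation leaves no residues
  expect_equal(grassland_plant_forcing(npp_tot, 1, gp)$residues_total, 0)
  # the scaled NPP estimate applies the global-mean ratio
  expect_equal(grassland_plant_forcing(100, 0, gp, "sun_scaled")$uptake,
               grassland_plant_forcing(100 * 979 / 460, 0, gp)$uptake)
})

test_that("cropland uptake and residues per crop and aggregated", {
  cp <- data.frame(crop = "x", p_pct_harvest = 0.3,
                   p_pct_abov_ex_harvest = 0.1, p_pct_root = 0.075,
                   harvest_index = 0.5, root_shoot_ratio = 0.2,
                   frac_resid = 0.5, is_forage = FALSE, is_root_crop = FALSE)
  out <- cropland_plant_forcing(matrix(5000), matrix(10), cp)
  expect_equal(out$uptake,
               50 * (0.075 * 0.2 / 0.5 + 0.1 * (1 / 0.5 - 1) + 0.3))
  expect_equal(out$uptake, 21.5)
  expect_equal(out$residues_total,
               50 * (0.075 * 0.2 / 0.5 + 0.5 * 0.1 * (1 / 0.5 - 1)))

  # a single-crop world reduces the aggregation to the per-crop value
  two <- cropland_plant_forcing(cbind(c(5000, 5000)), cbind(c(10, 40)), cp)
  expect_equal(two$uptake, rep(21.5, 2))
  # no area -> zero forcing
  expect_equal(cropland_plant_forcing(matrix(5000), matrix(0), cp)$uptake, 0)
  cp0 <- cp; cp0$harvest_index <- 0
  expect_error(cropland_plant_forcing(matrix(5000), matrix(10), cp0),
               "harvest index")

  # default table conventions
  tab <- crop_parameters()
  expect_equal(tab$root_shoot_ratio[tab$crop == "forage"], 1 / 0.8 - 1)
  expect_equal(tab$frac_resid[tab$is_forage], 0)
  expect_equal(tab$frac_resid[!tab$is_forage], rep(0.5, 2))
  expect_equal(tab$p_pct_root, 0.75 * tab$p_pct_abov_ex_harvest)
})

test_that("yield/area series: reference year, population scaling, area hold", {
  years <- c(1950, 1955, 1961, 1980, 2000)
  cs <- data.frame(country = 1, year = years, value = c(NA, NA, 2, 3, 4))
  cs$value[1:2] <- 2  # values before 1961 present but overridden by the rules
  pop <- data.frame(country = 1, year = years, value = c(8, 9, 10, 15, 20))
  map <- c(100, 200)
  y <- crop_yield_area_series(map, c(1, 1), cs, years, population = pop,
                              pre1961 = "population")
  expect_equal(y[, 5], map)                      # reference year exact
  expect_equal(y[, 4], map * 3 / 4)
  expect_equal(y[, 1], map * (2 / 4) * (8 / 10)) # population-scaled
  a <- crop_yield_area_series(map, c(1, 1), cs, years, pre1961 = "hold")
  expect_equal(a[, 1], a[, 3])                   # held at the 1961 value
  expect_error(crop_yield_area_series(map, c(1, 1),
                                      cs[cs$year != 2000, ], years),
               "reference-year")
  cs0 <- cs; cs0$value[cs0$year == 2000] <- 0
  expect_warning(y0 <- crop_yield_area_series(map, c(1, 1), cs0, years),
                 "zero")
  expect_equal(y0, matrix(0, 2, 5))
})

test_that("composition splits sum exactly to their totals", {
  comp <- composition_fractions()
  m <- split_composition(10, comp$manure)
  expect_equal(unlist(m, use.names = FALSE), c(8, 1, 1))
  r <- split_composition(10, comp$residues)
  expect_equal(unlist(r, use.names = FALSE), c(4, 4, 2))
  expect_equal(unlist(split_composition(0, comp$manure), use.names = FALSE),
               c(0, 0, 0))
  set.seed(2)
  tot <- runif(20, 0, 50)
  s <- split_composition(tot, comp$residues)
  expect_equal(s$i_lab + s$o_lab + s$o_sta, tot)
  expect_identical(comp$sludge, comp$manure)
})

test_that("deposition: labile shares and emission-series splice", {
  comp <- list(dust = 1, seasalt = 0, pbap = 0, natcomb = 0, anthcomb = 0)
  d <- deposition_forcing(comp, years = 2000)
  expect_equal(c(d$to_ilab, d$to_iprim), c(0.1, 0.9))
  comp$seasalt <- 1
  d <- deposition_forcing(comp, years = 2000)
  expect_equal(c(d$to_ilab, d$to_iprim), c(0.6, 1.4))
  d0 <- deposition_forcing(lapply(comp, function(x) 0), years = 2000)
  expect_equal(c(d0$to_ilab, d0$to_iprim), c(0, 0))

  # splice: over the overlap years the scaled series averages to the static
  # estimate; a constant series collapses to scale 1
  comp <- list(dust = 2, seasalt = 0.5, pbap = 0, natcomb = 0, anthcomb = 1)
  ser <- data.frame(year = 1997:2010, value = seq(1, 2.3, by = 0.1))
  d <- deposition_forcing(comp, years = 1997:2007, anthcomb_series = ser,
                          overlap = 1997:2007)
  static <- deposition_forcing(comp, years = 1997:2007)
  expect_equal(rowMeans(d$to_ilab), rowMeans(static$to_ilab), tolerance = 1e-12)
  serc <- data.frame(year = 1997:2010, value = 3)
  dc <- deposition_forcing(comp, years = 2000:2005, anthcomb_series = serc)
  expect_equal(dc$to_ilab, deposition_forcing(comp, years = 2000:2005)$to_ilab)
})

test_that("sludge: removal efficiencies, interpolation, degenerate area", {
  tab <- data.frame(country = 1, year = c(1970, 2010), excretion = 0.5,
                    frac_treat1 = 0.2, frac_treat2 = 0.3, frac_treat3 = 0.5)
  pop <- data.frame(country = 1, year = 1990, value = 1e6)
  area <- data.frame(country = 1, year = 1990, value = 1e5)
  s <- sludge_forcing(tab, pop, area, country = c(1, 1), years = 1990)
  expect_equal(s[, 1], rep((0.2 * 0.1 + 0.3 * 0.45 + 0.5 * 0.9) * 0.5 * 10, 2))
  expect_equal(s[1, 1], 3.025)

  # linear interpolation: 1990 sits midway between the 1970 and 2010 entries
  tab2 <- tab; tab2$excretion <- c(0.4, 0.6)
  s2 <- sludge_forcing(tab2, pop, area, c(1, 1), 1990)
  expect_equal(s2[1, 1], s[1, 1], tolerance = 1e-12)
  # held constant outside the 1970-2010 interval
  s3 <- sludge_forcing(tab2, data.frame(country = 1, year = 1950, value = 1e6),
                       data.frame(country = 1, year = 1950, value = 1e5),
                       c(1, 1), 1950)
  expect_equal(s3[1, 1], 3.025 * 0.4 / 0.5, tolerance = 1e-12)

  tab3 <- tab; tab3[, c("frac_treat1", "frac_treat2", "frac_treat3")] <- 0
  expect_equal(sludge_forcing(tab3, pop, area, c(1, 1), 1990)[1, 1], 0)
  area0 <- data.frame(country = 1, year = 1990, value = 0)
  expect_warning(s0 <- sludge_forcing(tab, pop, area0, c(1, 1), 1990),
                 "zero cropland")
  expect_equal(s0[1, 1], 0)
})

test_that("erosion fraction from gross loss and topsoil mass", {
  soil <- data.frame(bulk_density = 1300, coarse_frag_frac = 0.1)
  expect_equal(erosion_fraction(2000, soil), 2000 / 3.51e6)
  expect_equal(erosion_fraction(0, soil), 0)
  expect_equal(erosion_fraction(1e10, soil), 1)  # capped
})
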