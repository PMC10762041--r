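test_that("raw land-use classes aggregate to the four categories", {
  raw <- array(0, c(1, 12, 1),
               dimnames = list(NULL, soilphos:::raw_landuse_categories(), NULL))
  raw[1, c("pastr", "range"), 1] <- c(0.1, 0.2)
  raw[1, c("c3ann", "c4ann"), 1] <- c(0.05, 0.05)
  raw[1, "primf", 1] <- 0.55
  raw[1, "urban", 1] <- 0.05
  ag <- aggregate_landuse(raw)
  expect_equal(unname(ag$frac[1, "grass", 1]), 0.3)
  expect_equal(unname(ag$frac[1, "crop", 1]), 0.1)
  expect_equal(sum(ag$frac[1, , 1]), sum(raw[1, , 1]))

  tr <- array(0, c(1, 12, 12, 1),
              dimnames = list(NULL, soilphos:::raw_landuse_categories(),
                              soilphos:::raw_landuse_categories(), NULL))
  tr[1, "primf", "c3ann", 1] <- 0.01
  tr[1, "secdf", "pastr", 1] <- 0.02
  tr[1, "c3ann", "c4ann", 1] <- 0.5  # within-category, not a transition
  ag <- aggregate_landuse(raw, tr)
  expect_equal(ag$delta[1, "nonagri", "crop", 1], 0.01)
  expect_equal(ag$delta[1, "nonagri", "grass", 1], 0.02)
  expect_equal(ag$delta[1, "crop", "crop", 1], 0)

  dimnames(raw)[[2]][1] <- "bogus"
  expect_error(aggregate_landuse(raw), "unknown land-use category")
})

test_that("pool mixing across transitions: worked case and conventions", {
  lus <- landuse_categories()
  nat <- matrix(300, 1, 7, dimnames = list(NULL, pool_names()))
  pools <- list(crop = matrix(200, 1, 7), grass = matrix(100, 1, 7))
  frac_prev <- matrix(c(0.2, 0.3, 0.45, 0.05), 1, dimnames = list(NULL, lus))

  # no transitions: unchanged (bit-identical)
  delta <- array(0, c(1, 4, 4), dimnames = list(NULL, lus, lus))
  out <- apply_lucc(pools, frac_prev, frac_prev, delta, nat)
  expect_equal(out$crop, pools$crop, ignore_attr = TRUE)

  # cropland gains 0.05 from grassland
  delta[1, "grass", "crop"] <- 0.05
  frac_now <- frac_prev
  frac_now[1, "crop"] <- 0.25; frac_now[1, "grass"] <- 0.25
  out <- apply_lucc(pools, frac_prev, frac_now, delta, nat)
  expect_equal(unname(out$crop[1, 1]), (0.2 * 200 + 0.05 * 100) / 0.25)
  expect_equal(unname(out$crop[1, 1]), 180)
  expect_equal(unname(out$grass[1, 1]), 100)  # donor keeps its concentration

  # expansion into natural land imports the natural pools
  delta2 <- array(0, c(1, 4, 4), dimnames = list(NULL, lus, lus))
  delta2[1, "nonagri", "crop"] <- 0.05
  frac_now2 <- frac_prev
  frac_now2[1, "crop"] <- 0.25; frac_now2[1, "nonagri"] <- 0.40
  out2 <- apply_lucc(pools, frac_prev, frac_now2, delta2, nat)
  expect_equal(unname(out2$crop[1, 1]), (0.2 * 200 + 0.05 * 300) / 0.25)

  # a fully converted-away cover stores zeros
  delta3 <- array(0, c(1, 4, 4), dimnames = list(NULL, lus, lus))
  delta3[1, "crop", "nonagri"] <- 0.2
  frac_now3 <- frac_prev
  frac_now3[1, "crop"] <- 0; frac_now3[1, "nonagri"] <- 0.65
  out3 <- apply_lucc(pools, frac_prev, frac_now3, delta3, nat)
  expect_equal(out3$crop[1, ], setNames(rep(0, 7), pool_names()))

  # transitions larger than the source fraction are rejected
  delta4 <- array(0, c(1, 4, 4), dimnames = list(NULL, lus, lus))
  delta4[1, "crop", "grass"] <- 0.5
  expect_error(apply_lucc(pools, frac_prev, frac_prev, delta4, nat),
               "exceed")
})

test_that("crop-grass transitions conserve fraction-weighted P", {
  set.seed(21)
  lus <- landuse_categories()
  for (i in 1:20) {
    n <- 5
    nat <- matrix(runif(n * 7, 50, 500), n, 7,
                  dimnames = list(NULL, pool_names()))
    pools <- list(crop = matrix(runif(n * 7, 0, 400), n, 7),
                  grass = matrix(runif(n * 7, 0, 400), n, 7))
    fc <- runif(n, 0.2, 0.4); fg <- runif(n, 0.2, 0.4)
    frac_prev <- cbind(crop = fc, grass = fg, nonagri = 1 - fc - fg, urban = 0)
    delta <- array(0, c(n, 4, 4), dimnames = list(NULL, lus, lus))
    delta[, "crop", "grass"] <- runif(n, 0, 0.1) * fc
    delta[, "grass", "crop"] <- runif(n, 0, 0.1) * fg
    frac_now <- frac_prev
    frac_now[, "crop"] <- fc - delta[, "crop", "grass"] + delta[, "grass", "crop"]
    frac_now[, "grass"] <- fg - delta[, "grass", "crop"] + delta[, "crop", "grass"]
    out <- apply_lucc(pools, frac_prev, frac_now, delta, nat)
    before <- frac_prev[, "crop"] * pools$crop + frac_prev[, "grass"] * pools$grass
    after <- frac_now[, "crop"] * out$crop + frac_now[, "grass"] * out$grass
    expect_equal(after, before, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("initial pools inherit the natural background with derived solution P", {
  nat <- data.frame(i_lab = 50, i_sec = 30, i_prim = 100, o_lab = 20,
                    o_sta = 60, x_occ = 40)
  init <- initialize_pools(nat, w_abs_mean = 2)
  expect_equal(init$crop, init$grass)
  expect_equal(unname(init$crop[1, "i_lab"]), 50)
  expect_equal(unname(init$crop[1, "i_sol"]), 0.1 * 2)
  ctx <- areal_context(1300, 0.1)
  init_kg <- initialize_pools(nat, 2, ctx = ctx)
  expect_equal(init_kg$crop, init$crop * ctx$kg_ha_per_mg_kg)
  nat0 <- nat; nat0[1, ] <- 0
  expect_equal(sum(initialize_pools(nat0, 2, p_c_inf = 0)$crop), 0)
})
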