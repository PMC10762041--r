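test_that("temperature/moisture response scalars match their printed forms", {
  expect_equal(response_scalars(15, 0.5)$g1, 1)
  expect_equal(response_scalars(25, 0.5)$g1, 2.4)
  expect_equal(response_scalars(30, 0.5)$h1, 1)
  expect_equal(response_scalars(20, 0.5)$h1, 2^(-1))
  expect_equal(response_scalars(15, 0.7)$g2, 0.7)
  expect_equal(response_scalars(15, 1.0)$h2, 1.01)
  # the moisture polynomial is clamped at 0 in very dry soils
  expect_equal(response_scalars(15, 0.05)$h2, 0)
  expect_equal(response_scalars(15, 0.1)$h2, 0)
})

test_that("solution-labile equilibrium: trivial, closed-form and oracle cases", {
  p <- manual_params(b = 1, k_sol_to_lab = 0.1, k_lab_to_sol = 0.1)
  eq <- solve_sol_lab_equilibrium(0, p, 1)
  expect_equal(c(eq$p_i_sol, eq$p_i_lab), c(0, 0))

  # symmetric linear case: closed form x = k_ls W T / (k_sl + k_ls W)
  eq <- solve_sol_lab_equilibrium(2, p, 1)
  expect_equal(eq$p_i_sol, 1, tolerance = 1e-12)
  expect_equal(eq$p_i_lab, 1, tolerance = 1e-12)

  # general b = 1 closed form on random draws
  set.seed(11)
  for (i in 1:50) {
    ksl <- runif(1, 1e-3, 10); kls <- runif(1, 1e-3, 10)
    w <- runif(1, 0.2, 8); tot <- runif(1, 0, 500)
    p1 <- manual_params(b = 1, k_sol_to_lab = ksl, k_lab_to_sol = kls)
    eq <- solve_sol_lab_equilibrium(tot, p1, w)
    expect_equal(eq$p_i_sol, kls * w * tot / (ksl + kls * w),
                 tolerance = 1e-10)
  }

  # specific non-linear case against the bisection oracle
  p2 <- manual_params(b = 0.5, k_sol_to_lab = 2, k_lab_to_sol = 1)
  eq <- solve_sol_lab_equilibrium(10, p2, 4)
  expect_equal(eq$p_i_sol, bisect_eq8(10, 0.5, 2, 1, 4), tolerance = 1e-8)
  expect_equal(eq$p_i_sol + eq$p_i_lab, 10)
})

test_that("frozen dynamics leave the state unchanged", {
  p <- manual_params(b = 1, k_lab_to_sol = 0, k_sol_to_lab = 0,
                     k_sol_to_sec = 0, k_sec_to_sol = 0, k_sec_to_occ = 0,
                     k_occ_to_sec = 0, k_weathering = 0, k_min_stable = 0,
                     k_min_labile = 0)
  s <- state_row(1, 50, 30, 200, 20, 60, 40)
  out <- daily_pool_update(s, p, const_climate())
  expect_identical(out$state[1, ], s[1, ])
  expect_true(all(out$fluxes == 0))
})

test_that("occlusion and de-occlusion balance at the steady pool ratio", {
  # k_occ_to_sec = k_sec_to_occ * (P_sec_inf / P_occ_inf)
  p <- manual_params(k_sec_to_occ = 1.6e-5, k_occ_to_sec = 1.6e-5 * 100 / 150,
                     k_sol_to_sec = 1e-9, k_sec_to_sol = 1e-9)
  s <- state_row(i_sol = 0.2, i_lab = 50, i_sec = 100, x_occ = 150)
  out <- daily_pool_update(s, p, const_climate())
  expect_equal(unname(out$fluxes[1, "occlusion"]),
               unname(out$fluxes[1, "deocclusion"]), tolerance = 1e-14)
})

test_that("weathering flux follows its rate law into labile P", {
  p <- manual_params(k_weathering = 2.7e-7, k_min_stable = 0, k_min_labile = 0,
                     k_sol_to_sec = 0, k_sec_to_sol = 0, k_sec_to_occ = 0,
                     k_occ_to_sec = 0, k_lab_to_sol = 0, k_sol_to_lab = 0)
  s <- state_row(i_prim = 500)
  out <- daily_pool_update(s, p, const_climate(t_soil = 15, w_rel = 1))
  expect_equal(unname(out$fluxes[1, "weathering"]), 1.35e-4, tolerance = 1e-6)
  expect_equal(unname(out$state[1, "i_lab"] - s[1, "i_lab"]),
               unname(out$fluxes[1, "weathering"]))
})

test_that("daily step conserves total P and keeps pools non-negative", {
  set.seed(5)
  for (i in 1:30) {
    p <- manual_params(b = runif(1, 0.3, 1.5), k_lab_to_sol = runif(1, 0.01, 5),
                       k_sol_to_lab = runif(1, 0.01, 5),
                       k_sol_to_sec = runif(1, 0.001, 20),
                       k_sec_to_sol = runif(1, 1e-5, 2),
                       k_sec_to_occ = runif(1, 1e-6, 1e-3),
                       k_occ_to_sec = runif(1, 1e-6, 1e-3))
    s <- matrix(runif(7, 0, 300), 1, 7, dimnames = list(NULL, pool_names()))
    out <- integrate_days(s, p, const_climate(t_soil = 20, w_rel = 0.8), 30)
    expect_true(all(out$state >= 0))
    expect_equal(sum(out$state), sum(s), tolerance = 1e-12)
  }
  expect_error(daily_pool_update(state_row(i_lab = -1), manual_params(),
                                 const_climate()),
               "negative pool")
})

test_that("annual input/output application: identity, splits, shortfall", {
  ctx <- areal_context(1300, 0.1)
  cf <- ctx$kg_ha_per_mg_kg
  s <- state_row(0.5, 40, 30, 200, 20, 60, 50)

  io <- apply_annual_io(s, zero_forcing(1), ctx)
  expect_identical(io$state[1, ], s[1, ])
  expect_equal(io$fP_upns, 0)

  # manure composition split reaches the three destination pools
  f <- zero_forcing(1)
  f$manure_to_ilab <- 8; f$manure_to_olab <- 1; f$manure_to_osta <- 1
  io <- apply_annual_io(s, f, ctx)
  expect_equal(unname((io$state - s)[1, c("i_lab", "o_lab", "o_sta")] * cf),
               c(8, 1, 1), tolerance = 1e-12)

  # shortfall: 5 kgP/ha available as solution+labile, 8 demanded
  s2 <- state_row(i_sol = 1 / cf, i_lab = 4 / cf, i_prim = 100)
  f2 <- zero_forcing(1); f2$uptake_from_ilab <- 8
  io2 <- apply_annual_io(s2, f2, ctx)
  expect_equal(unname(io2$state[1, c("i_sol", "i_lab")]), c(0, 0))
  expect_equal(io2$fP_upns, 3, tolerance = 1e-10)
  expect_equal(io2$uptake_satisfied, 5, tolerance = 1e-10)

  # erosion spares the solution pool
  f3 <- zero_forcing(1); f3$erosion_frac_loss <- 0.01
  io3 <- apply_annual_io(s, f3, ctx)
  expect_equal(unname(io3$state[1, "i_sol"]), unname(s[1, "i_sol"]))
  expect_equal(unname(io3$state[1, "i_sec"]), unname(s[1, "i_sec"]) * 0.99)
  expect_equal(unname(io3$erosion_losses[1, "i_sec"]),
               unname(s[1, "i_sec"]) * 0.01 * cf)
})

test_that("organic pools decay at the closed-form exponential rate", {
  p <- manual_params(k_min_stable = 1.8e-4, k_min_labile = 1.4e-3,
                     k_sol_to_sec = 1e-9, k_sec_to_sol = 1e-9,
                     k_sec_to_occ = 1e-9, k_occ_to_sec = 1e-9)
  cl <- const_climate(t_soil = 22, w_rel = 0.8)
  h <- response_scalars(22, 0.8)
  s <- state_row(0.2, 50, 30, 100, 40, 80, 60)
  ctx <- areal_context(1300, 0.1)
  yr <- integrate_year(s, p, cl, zero_forcing(1), ctx)
  expect_equal(unname(yr$state[1, "o_lab"] / s[1, "o_lab"]),
               exp(-1.4e-3 * h$h1 * h$h2 * 365), tolerance = 1e-9)
  expect_equal(unname(yr$state[1, "o_sta"] / s[1, "o_sta"]),
               exp(-1.8e-4 * h$h1 * h$h2 * 365), tolerance = 1e-9)
})

test_that("annual mass balance closes on randomized forcing", {
  set.seed(9)
  ctx <- areal_context(1300, 0.1)
  for (i in 1:10) {
    p <- manual_params(b = runif(1, 0.4, 1.2), k_lab_to_sol = runif(1, 0.1, 2),
                       k_sol_to_lab = runif(1, 0.1, 2),
                       k_sol_to_sec = runif(1, 0.01, 15),
                       k_sec_to_sol = runif(1, 1e-4, 0.5))
    s <- matrix(runif(7, 0, 200), 1, 7, dimnames = list(NULL, pool_names()))
    f <- zero_forcing(1)
    for (v in setdiff(forcing_fields(), "erosion_frac_loss")) {
      f[[v]] <- runif(1, 0, 20)
    }
    f$erosion_frac_loss <- runif(1, 0, 0.01)
    yr <- integrate_year(s, p, const_climate(t_soil = 18, w_rel = 0.7), f, ctx)
    total0 <- sum(s) * ctx$kg_ha_per_mg_kg
    total1 <- sum(yr$state) * ctx$kg_ha_per_mg_kg
    d <- yr$diagnostics
    expect_lt(abs(d$balance_residual) / max(1, total0), 1e-9)
    expect_equal(total1 - total0,
                 d$inputs_total - d$erosion_total - d$uptake_satisfied,
                 tolerance = 1e-9)
  }
})

test_that("refining the time step moves input-year mass from labile toward secondary", {
  # sorption rate far above its daily consistency bound + positive P budget:
  # with the coarse step the labile pool retains more of the input
  p <- manual_params(b = 0.6, k_sol_to_sec = 12.6, k_sec_to_sol = 1e-3,
                     k_lab_to_sol = 0.5, k_sol_to_lab = 5)
  expect_true(check_parameter_consistency(p)$flag_sol_to_sec)
  s <- state_row(0.2, 30, 40, 100, 10, 30, 40)
  ctx <- areal_context(1300, 0.1)
  f <- zero_forcing(1); f$chem_to_ilab <- 40
  cl <- const_climate(t_soil = 18, w_rel = 0.7)
  coarse <- integrate_year(s, p, cl, f, ctx, steps_per_day = 1)
  fine <- integrate_year(s, p, cl, f, ctx, steps_per_day = 2)
  expect_gt(coarse$state[1, "i_lab"], fine$state[1, "i_lab"])
  expect_lt(coarse$state[1, "i_sec"], fine$state[1, "i_sec"])
})
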