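# Independent bisection oracle for the solution-labile equilibrium:
# root of k_sl * x^b + k_ls * W^b * x - k_ls * W^b * total on [0, total].
bisect_eq8 <- function(total, b, k_sl, k_ls, w) {
  if (total <= 0) return(0)
  f <- function(x) k_sl * x^b + k_ls * w^b * x - k_ls * w^b * total
  lo <- 0; hi <- total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# hand-built flux parameter rows for unit tests (bypasses the regressions)
manual_params <- function(n = 1, b = 1, k_lab_to_sol = 0.1, k_sol_to_lab = 0.1,
                          k_sol_to_sec = 0.01, k_sec_to_sol = 1e-4,
                          k_sec_to_occ = 1e-5, k_occ_to_sec = 1e-5,
                          k_weathering = 2.7e-7, k_min_stable = 1.8e-4,
                          k_min_labile = 1.4e-3, p_c_inf = 0.1,
                          w_abs_mean = 2) {
  data.frame(b = rep_len(b, n), k_lab_to_sol = rep_len(k_lab_to_sol, n),
             k_sol_to_lab = rep_len(k_sol_to_lab, n),
             k_sol_to_sec = rep_len(k_sol_to_sec, n),
             k_sec_to_sol = rep_len(k_sec_to_sol, n),
             k_sec_to_occ = rep_len(k_sec_to_occ, n),
             k_occ_to_sec = rep_len(k_occ_to_sec, n),
             k_weathering = rep_len(k_weathering, n),
             k_min_stable = rep_len(k_min_stable, n),
             k_min_labile = rep_len(k_min_labile, n),
             p_c_inf = rep_len(p_c_inf, n), w_abs_mean = rep_len(w_abs_mean, n))
}

state_row <- function(i_sol = 0, i_lab = 0, i_sec = 0, i_prim = 0,
                      o_lab = 0, o_sta = 0, x_occ = 0) {
  matrix(c(i_sol, i_lab, i_sec, i_prim, o_lab, o_sta, x_occ), 1, 7,
         dimnames = list(NULL, pool_names()))
}

const_climate <- function(n = 1, t_soil = 15, w_rel = 1, w_abs = 2) {
  list(t_soil = rep(t_soil, n), w_rel = rep(w_rel, n), w_abs = rep(w_abs, n))
}

tiny_world <- function(seed = 1, nx = 3, ny = 3, years = 1995:2006) {
  make_world(world_config(nx = nx, ny = ny, n_countries = 2, years = years),
             seed = seed)
}
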