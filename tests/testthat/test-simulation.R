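test_that("the integrator agrees with the matrix-exponential solution", {
  reg <- regimen_preset("450/900")
  traj <- simulate_regimen(tbl_params, reg, n_cycles = 1)
  check_t <- c(60, 240, 480, 720, 960, 1200, 1440)
  exact <- oracle_states(tbl_params, expand_regimen(reg, 1), check_t)
  got <- as.matrix(as.data.frame(traj)[match(check_t, traj$time_min),
                                       state_names]) / 1000
  expect_equal(unname(got), unname(exact), tolerance = 1e-6)
})

test_that("a zero-dose regimen stays identically zero", {
  traj <- simulate_regimen(tbl_params, regimen_preset("none"), n_cycles = 1)
  expect_true(all(as.matrix(as.data.frame(traj)[, state_names]) == 0))
})

test_that("plasma peaks at the end of the 4-h release window", {
  traj <- simulate_regimen(tbl_params, regimen_preset("single-900"),
                           t_end = 48 * 60)
  pk_t <- traj$time_min[which.max(traj$plasma)]
  expect_lt(abs(pk_t - 240), 5)
  # concentrations stay non-negative from a non-negative start
  expect_gte(min(as.matrix(as.data.frame(traj)[, state_names])), -1e-9)
})

test_that("without clearance every tissue relaxes to its partition ratio", {
  p0 <- params_with(kk = 0)
  traj <- simulate_regimen(p0, li_regimen(300, 0), t_end = 10 * 1440,
                           grid_dt = 10)
  last <- as.data.frame(traj)[nrow(traj), ]
  expect_equal(last$brain / last$plasma, 1.5, tolerance = 1e-2)
  expect_equal(last$uterus / last$plasma, 0.4, tolerance = 1e-2)
  expect_equal(last$fetus / last$plasma, 0.8, tolerance = 1e-2)
})

test_that("doubling every dose doubles the whole trajectory", {
  reg <- regimen_preset("450/900")
  dbl <- li_regimen(reg$doses_mg * 2, reg$offsets_min)
  t1 <- simulate_regimen(tbl_params, reg, n_cycles = 1)
  t2 <- simulate_regimen(tbl_params, dbl, n_cycles = 1)
  m1 <- as.matrix(as.data.frame(t1)[, state_names])
  m2 <- as.matrix(as.data.frame(t2)[, state_names])
  expect_equal(m2, 2 * m1, tolerance = 1e-6)
})

test_that("terminal-cycle detection converges and satisfies its definition", {
  cs <- find_terminal_cycle(tbl_params, regimen_preset("450/900"))
  expect_true(attr(cs, "converged"))
  expect_lt(attr(cs, "n_cycles_run"), 60)
  expect_true(all(cs$average <= cs$peak))

  # a further cycle changes the profile by less than the tolerance allows
  y_end <- attr(attr(cs, "trajectory"), "final_state")
  more <- simulate_regimen(tbl_params, regimen_preset("450/900"),
                           n_cycles = 1, init = y_end)
  prev_grid_peak <- max(attr(cs, "trajectory")$fetus)
  next_grid_peak <- max(more$fetus)
  expect_lt(abs(next_grid_peak - prev_grid_peak) / prev_grid_peak, 1e-5)

  # cycle budget of 1 cannot converge and says so rather than erroring
  cs1 <- find_terminal_cycle(tbl_params, regimen_preset("450/900"),
                             max_cycles = 1)
  expect_false(attr(cs1, "converged"))
  expect_identical(attr(cs1, "n_cycles_run"), 1L)
})

test_that("terminal averages obey the closed-form flow balances", {
  for (nm in c("450/900", "400/400/400")) {
    reg <- regimen_preset(nm)
    cs <- find_terminal_cycle(tbl_params, reg)
    avg <- stats::setNames(cs$average, cs$compartment)
    exact <- steady_state_average(tbl_params, reg)
    expect_equal(avg[state_names], exact[state_names], tolerance = 1e-2)
    # avg C_F / R_F = avg C_U / R_U = avg C_P at the terminal profile
    expect_equal(avg[["fetus"]] / 0.8, avg[["plasma"]], tolerance = 1e-2)
    expect_equal(avg[["uterus"]] / 0.4, avg[["plasma"]], tolerance = 1e-2)
  }
})

test_that("the closed-form average is linear in dose and errors without clearance", {
  reg <- regimen_preset("400/400/400")
  base <- steady_state_average(tbl_params, reg)
  dbl <- steady_state_average(tbl_params,
                              li_regimen(reg$doses_mg * 2, reg$offsets_min))
  expect_equal(dbl, 2 * base)
  expect_equal(base[["fetus"]] / base[["plasma"]], 0.8)
  # 32 mEq/day against the effective clearance of 19.68 mL/min
  expect_equal(base[["plasma"]],
               (32 / 1440) / (20 * 1240 / 1260) * 1000, tolerance = 1e-12)
  expect_error(steady_state_average(params_with(kk = 0), reg),
               "no periodic steady state")
})

test_that("cycle absorption balances renal elimination at the terminal profile", {
  reg <- regimen_preset("450/900")
  cs <- find_terminal_cycle(tbl_params, reg)
  avg <- stats::setNames(cs$average, cs$compartment) / 1000  # mEq/mL
  eliminated <- 20 * avg[["kidney"]] / 1 * 1440              # kk*avgC_K/R_K * T
  expect_equal(eliminated, cycle_dose_meq(reg, tbl_params$li_per_mg),
               tolerance = 1e-2)
})

test_that("plasma half-life after a single dose is about half a day", {
  hl <- estimate_half_life(tbl_params, regimen_preset("single-900"))
  # one-pool approximation: ln2 (V_P + sum V_i R_i) / CL_eff = 12.2 h
  one_pool <- log(2) * (5200 + 15554) / (20 * 1240 / 1260) / 60
  expect_lt(abs(hl - one_pool) / one_pool, 0.15)
  # doubling clearance shortens the half-life roughly proportionally
  hl2 <- estimate_half_life(params_with(kk = 40),
                            regimen_preset("single-900"))
  expect_lt(hl2, 0.65 * hl)
  expect_error(estimate_half_life(tbl_params, regimen_preset("450/900")),
               "exactly one")
})

test_that("reported peaks are insensitive to the output grid", {
  reg <- regimen_preset("450/900")
  cs1 <- find_terminal_cycle(tbl_params, reg, grid_dt = 1)
  cs2 <- find_terminal_cycle(tbl_params, reg, grid_dt = 0.5)
  expect_equal(cs1$peak, cs2$peak, tolerance = 1e-3)
})

test_that("splitting a fixed daily dose lowers the peaks monotonically", {
  splits <- list(li_regimen(c(600, 600)), li_regimen(rep(400, 3)),
                 li_regimen(rep(300, 4)))
  peaks <- vapply(splits, function(r) {
    cs <- find_terminal_cycle(tbl_params, r)
    cs$peak[cs$compartment == "fetus"]
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
  # equal daily dose means equal terminal averages regardless of splitting
  avgs <- vapply(splits, function(r) {
    cs <- find_terminal_cycle(tbl_params, r)
    cs$average[cs$compartment == "fetus"]
  }, numeric(1))
  expect_equal(max(avgs) / min(avgs), 1, tolerance = 1e-3)
})
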