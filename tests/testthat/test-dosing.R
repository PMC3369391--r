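lpm <- 8 / 300

test_that("regimen expansion places dose events on the cycle grid", {
  ev <- expand_regimen(regimen_preset("450/900"), n_cycles = 2)
  expect_equal(ev$start_min, c(0, 720, 1440, 2160))
  expect_equal(ev$mass_mg, c(450, 900, 450, 900))
  expect_equal(ev$duration_min, rep(240, 4))

  ev1 <- expand_regimen(li_regimen(900, 0), n_cycles = 1)
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$start_min, 0)
  expect_equal(ev1$mass_mg, 900)

  # n-dose presets default to even spacing across the 24-h cycle
  expect_equal(expand_regimen(regimen_preset("400/400/400"))$start_min,
               c(0, 480, 960))
  expect_equal(expand_regimen(regimen_preset("300/300/300/300"))$start_min,
               c(0, 360, 720, 1080))

  expect_error(expand_regimen(regimen_preset("300/300"), n_cycles = 0),
               ">= 1")
})

test_that("regimen invariants are enforced", {
  expect_error(li_regimen(numeric(0)), "at least one dose")
  expect_error(li_regimen(300, offsets_min = 1500), "\\[0, cycle_length_min\\)")
  expect_error(li_regimen(300, offsets_min = -5), "\\[0, cycle_length_min\\)")
  expect_error(li_regimen(300, 0, duration_min = 0), "duration")
  expect_error(li_regimen(-10, 0), ">= 0")
  expect_error(regimen_preset("nonsense"), "unknown regimen preset")
})

test_that("zero-order absorption rate is dose * conversion / duration", {
  ev <- data.frame(start_min = 0, mass_mg = 300, duration_min = 240)
  g <- absorption_profile(ev, lpm)
  expect_equal(absorption_rate(g, 100), 8 / 240)   # 8 mEq over 4 h
  expect_equal(absorption_rate(g, 240), 0)         # half-open window
  expect_equal(absorption_rate(g, -1), 0)

  g900 <- absorption_profile(data.frame(start_min = 0, mass_mg = 900,
                                        duration_min = 240), lpm)
  expect_equal(absorption_rate(g900, 10), 0.1)     # 24 mEq over 240 min

  # no events at all, and a zero-mass dose, both give G identically zero
  none <- absorption_profile(data.frame(start_min = numeric(),
                                        mass_mg = numeric(),
                                        duration_min = numeric()), lpm)
  expect_equal(absorption_rate(none, c(0, 100, 1000)), c(0, 0, 0))
  zero <- absorption_profile(expand_regimen(regimen_preset("none")), lpm)
  expect_equal(absorption_rate(zero, c(0, 100, 1000)), c(0, 0, 0))

  # overlapping windows sum
  ev2 <- data.frame(start_min = c(0, 120), mass_mg = c(300, 300),
                    duration_min = c(240, 240))
  g2 <- absorption_profile(ev2, lpm)
  expect_equal(absorption_rate(g2, 130), 2 * 8 / 240)
})

test_that("cycle dose totals the administered lithium", {
  expect_equal(cycle_dose_meq(regimen_preset("450/900"), lpm), 36)
  expect_equal(cycle_dose_meq(regimen_preset("300/300/300/300"), lpm), 32)
  expect_equal(cycle_dose_meq(regimen_preset("none"), lpm), 0)
})

test_that("G(t) integrates to the administered dose and scales linearly", {
  # offsets chosen away from the grid start so the trapezoid rule sees both
  # edges of every absorption window
  regs <- list(li_regimen(c(450, 900), c(60, 780)),
               li_regimen(c(300, 300, 500), c(30, 510, 990)),
               li_regimen(900, 120))
  for (reg in regs) {
    n <- 3L
    g <- absorption_profile(expand_regimen(reg, n), lpm)
    t <- seq(0, n * reg$cycle_length_min, by = 1)  # grid aligned on breakpoints
    y <- absorption_rate(g, t)
    integral <- sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
    expect_equal(integral, n * cycle_dose_meq(reg, lpm), tolerance = 1e-9)
  }

  reg <- regimen_preset("450/900")
  scaled <- li_regimen(reg$doses_mg * 2.5, reg$offsets_min)
  g1 <- absorption_profile(expand_regimen(reg), lpm)
  g2 <- absorption_profile(expand_regimen(scaled), lpm)
  t <- seq(0, 1440, by = 7)
  expect_equal(absorption_rate(g2, t), 2.5 * absorption_rate(g1, t))
})

test_that("regimen YAML round trip preserves the schedule", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  reg <- li_regimen(c(300, 300, 500), c(0, 480, 960), label = "meals")
  write_regimen(reg, tmp)
  back <- read_regimen(tmp)
  expect_identical(back, reg)
})
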