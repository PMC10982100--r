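p_1c <- pk_params(kel = 0.1, V = 2)
p_2c <- pk_params(kel = 0.1, V = 2, k12 = 0.2, k21 = 0.2)
p_tmdd <- pk_params(kel = 0.1, V = 2, kon = 0.25, koff = 0.01, ksyn = 0.5,
                    kdeg = 0.25, kint = 0.1)

test_that("mechanistic right-hand sides match hand-derived values", {
  iv <- dose_regimen("iv_bolus", d = 1)
  expect_equal(mechanistic_rhs("onecomp_iv", p_1c, iv, 0.5, 0), -0.05)

  # receptor turnover baseline ksyn/kdeg = 2 is stationary without ligand
  reg <- dose_regimen("iv_bolus", d = 50)
  expect_equal(mechanistic_rhs("tmdd_iv", p_tmdd, reg, c(0, 2, 0), 5),
               c(0, 0, 0))

  expect_error(mechanistic_rhs("nope", p_1c, iv, 0.5, 0))
  expect_error(mechanistic_rhs("twocomp_iv", p_2c, iv, 0.5, 0), "dimension 2")
})

test_that("zero transit compartments collapse to first-order absorption", {
  p0 <- pk_params(kel = 0.1, V = 2, ka = 0.2, ntr = 0L)
  po <- dose_regimen("oral", d = 5)
  set.seed(7)
  for (i in 1:20) {
    st <- stats::runif(2, 0, 5)
    d1 <- mechanistic_rhs("onecomp_po_transit", p0, po, st, 0)
    # plain first-order absorption written out directly
    d2 <- c(-0.2 * st[1], 0.2 * st[1] / 2 - 0.1 * st[2])
    expect_equal(d1, d2)
  }
})

test_that("one-compartment solution matches the closed form", {
  reg <- dose_regimen("iv_bolus", d = 1)
  tt <- seq(0, 50, by = 2.5)
  conc <- simulate_reference("onecomp_iv", p_1c, reg, tt)
  expect_equal(conc[1], 0.5)
  expect_lt(max(abs(conc - onecomp_closed_form(tt, 0.1, 2, 1))), 1e-6)
})

test_that("two-compartment solution agrees with a fixed-step RK4 oracle", {
  reg <- dose_regimen("iv_bolus", d = 1)
  tt <- seq(0, 50, by = 5)
  conc <- simulate_reference("twocomp_iv", p_2c, reg, tt)
  oracle <- rk4_oracle(function(y, t) mechanistic_rhs("twocomp_iv", p_2c, reg, y, t),
                       c(0.5, 0), tt, h = 1e-3)
  expect_lt(max(abs(conc - oracle[, 1])), 1e-4)
})

test_that("linear models are exactly dose-proportional", {
  tt <- seq(0, 50, by = 5)
  for (m in list(list("onecomp_iv", p_1c, "iv_bolus"),
                 list("twocomp_iv", p_2c, "iv_bolus"),
                 list("onecomp_po_transit",
                      pk_params(kel = 0.1, V = 2, ka = 0.2, ktr = 0.1, ntr = 4L),
                      "oral"))) {
    c1 <- simulate_reference(m[[1]], m[[2]], dose_regimen(m[[3]], d = 2), tt)
    c2 <- simulate_reference(m[[1]], m[[2]], dose_regimen(m[[3]], d = 4), tt)
    expect_equal(c2, 2 * c1, tolerance = 1e-6)
  }
  # infusion: doubling the rate doubles the curve
  ci1 <- simulate_reference("onecomp_infusion", p_1c,
                            dose_regimen("iv_infusion", kin = 1, tinf = 6), tt)
  ci2 <- simulate_reference("onecomp_infusion", p_1c,
                            dose_regimen("iv_infusion", kin = 2, tinf = 6), tt)
  expect_equal(ci2, 2 * ci1, tolerance = 1e-6)
})

test_that("transit chain conserves mass up to elimination", {
  p <- pk_params(kel = 0.1, V = 2, ka = 0.2, ktr = 0.1, ntr = 4L)
  po <- dose_regimen("oral", d = 5)
  set.seed(13)
  for (i in 1:10) {
    st <- stats::runif(6, 0, 3) # depot, 4 transits, central conc
    dv <- mechanistic_rhs("onecomp_po_transit", p, po, st, 0)
    # d/dt(depot + transits + central * V) = -kel * xC * V
    total_rate <- sum(dv[1:5]) + dv[6] * p$V
    expect_equal(total_rate, -p$kel * st[6] * p$V)
    expect_lte(total_rate, 0)
  }
})

test_that("the TMDD receptor stays at baseline when no ligand is present", {
  reg <- dose_regimen("iv_bolus", d = 0)
  rhs <- function(y, t) mechanistic_rhs("tmdd_iv", p_tmdd, reg, y, t)
  tt <- seq(0, 60, by = 5)
  traj <- pk_solve(rhs, c(0, 2, 0), tt)
  expect_lt(max(abs(traj[, 2] - 2)), 1e-7)
})

test_that("infusion concentration is continuous at tinf with the expected derivative drop", {
  reg <- dose_regimen("iv_infusion", kin = 10, tinf = 6)
  eps <- 1e-3
  tt <- c(0, 6 - eps, 6, 6 + eps)
  conc <- simulate_reference("onecomp_infusion", p_1c, reg, tt,
                             solver_config(breakpoints = 6))
  expect_lt(abs(conc[3] - conc[2]), 0.02)  # continuous
  slope_before <- (conc[3] - conc[2]) / eps
  slope_after <- (conc[4] - conc[3]) / eps
  expect_equal(slope_before - slope_after, reg$kin / p_1c$V, tolerance = 1e-2)
})

test_that("proportional error is reproducible, unbiased, and clipped", {
  conc <- c(0.5, 0.2, 0.05)
  expect_identical(add_proportional_error(conc, 0, seed = 1), conc)
  a <- add_proportional_error(conc, 0.1, seed = 42)
  b <- add_proportional_error(conc, 0.1, seed = 42)
  expect_identical(a, b)
  expect_error(add_proportional_error(conc, -0.1, seed = 1), "cv")

  draws <- add_proportional_error(rep(1, 10000), 0.1, seed = 7)
  se <- 0.1 / sqrt(10000)
  expect_lt(abs(mean(draws) - 1), 3 * se)
  expect_lt(abs(stats::sd(draws - 1) - 0.1), 0.005)
  big <- add_proportional_error(rep(0.01, 1000), 5, seed = 9)
  expect_true(all(big >= 0))
})

test_that("the scenario registry reproduces the stated study designs", {
  sc <- make_scenario("twocomp_iv", seed = 4)
  expect_setequal(unique(sc$data$dose), c(1, 10))
  expect_length(unique(sc$data$group_id), 2L)
  expect_length(sc$times, 5L)

  sc8 <- make_scenario("po_transit8", seed = 4)
  expect_length(unique(sc8$data$time), 10L)
  expect_setequal(unique(sc8$data$dose), c(5, 15))

  inf <- make_scenario("infusion", seed = 4)
  expect_setequal(unique(inf$data$kin), c(1, 10))
  expect_true(all(inf$data$tinf == 6))

  tm <- make_scenario("tmdd_iv", seed = 4)
  expect_setequal(unique(tm$data$dose), c(50, 200))
  expect_identical(tm$loss, "wmse")
  expect_equal(tm$tests[[1]]$d, 100)

  # zero-noise path is exactly the clean simulation, which tracks the
  # closed form to solver accuracy
  ov <- make_scenario("overfit_onecomp", seed = 4, cv = 0)
  clean <- simulate_reference("onecomp_iv", ov$oracle$params,
                              ov$train[[1]], ov$times)
  expect_identical(ov$data$conc, clean)
  expect_equal(ov$data$conc, onecomp_closed_form(ov$data$time, 0.1, 2, 1),
               tolerance = 1e-5)
  expect_identical(nrow(ov$data), 5L)

  expect_error(make_scenario("nope", seed = 1), "unknown scenario")
})

test_that("infusion regimens enforce d = kin * tinf", {
  r <- dose_regimen("iv_infusion", kin = 2, tinf = 3)
  expect_equal(r$d, 6)
  expect_error(dose_regimen("iv_infusion", d = 5, kin = 2, tinf = 3),
               "kin \\* tinf")
  expect_error(dose_regimen("iv_bolus", d = -1), ">= 0")
})
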