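test_that("pk_solve reproduces the exponential decay closed form", {
  traj <- pk_solve(function(y, t) -0.1 * y, 0.5, c(0, 10))
  expect_identical(traj[1, 1], 0.5)
  expect_lt(abs(traj[2, 1] - 0.5 * exp(-1)), 1e-6)
})

test_that("a zero right-hand side gives the identity flow", {
  y0 <- c(1.5, -2)
  traj <- pk_solve(function(y, t) c(0, 0), y0, seq(0, 20, by = 5))
  expect_true(all(apply(traj, 1, function(r) identical(r, y0))))
})

test_that("declared breakpoints give converged answers for discontinuous inputs", {
  p <- pk_params(kel = 0.1, V = 2)
  reg <- dose_regimen("iv_infusion", kin = 10, tinf = 6)
  rhs <- function(y, t) mechanistic_rhs("onecomp_infusion", p, reg, y, t)
  tt <- c(0, 3, 6, 12, 25, 50)
  sol <- pk_solve(rhs, 0, tt, solver_config(breakpoints = 6))
  # closed form at default tolerances (concentration scale ~ 20)
  truth <- infusion_closed_form(tt, 0.1, 2, 10, 6)
  expect_lt(max(abs(sol[, 1] - truth) / pmax(1, truth)), 1e-5)
  # tightening tolerances tenfold changes nothing material
  tight <- pk_solve(rhs, 0, tt, solver_config(rtol = 1e-7, atol = 1e-9,
                                              breakpoints = 6))
  expect_lt(max(abs(sol - tight)), 1e-4)
})

test_that("halving tolerances leaves scenario-model solutions within the coarser tolerance", {
  cases <- list(
    list("onecomp_iv", pk_params(kel = 0.1, V = 2), dose_regimen("iv_bolus", d = 1)),
    list("twocomp_iv", pk_params(kel = 0.1, V = 2, k12 = 0.2, k21 = 0.2),
         dose_regimen("iv_bolus", d = 10)),
    list("onecomp_po_transit",
         pk_params(kel = 0.1, V = 2, ka = 0.2, ktr = 0.1, ntr = 8L),
         dose_regimen("oral", d = 15)),
    list("tmdd_iv", pk_params(kel = 0.1, V = 2, kon = 0.25, koff = 0.01,
                              ksyn = 0.5, kdeg = 0.25, kint = 0.1),
         dose_regimen("iv_bolus", d = 200)))
  tt <- seq(0, 60, by = 6)
  for (cs in cases) {
    coarse <- simulate_reference(cs[[1]], cs[[2]], cs[[3]], tt,
                                 solver_config(rtol = 1e-6, atol = 1e-8))
    fine <- simulate_reference(cs[[1]], cs[[2]], cs[[3]], tt,
                               solver_config(rtol = 5e-7, atol = 5e-9))
    # global error accumulates a modest multiple of the local tolerance
    allowance <- 50 * (1e-8 + 1e-6 * pmax(abs(coarse), abs(fine)))
    expect_true(all(abs(coarse - fine) <= allowance), label = cs[[1]])
  }
})

test_that("the training-grid gradient passes a finite-difference check", {
  set.seed(91)
  m <- node_model("separated", n_hid = 3, V = 2)
  sc <- make_scenario("overfit_onecomp", seed = 3)
  lg <- node_loss_grad(m, sc$data, "mse", h_max = 1)
  th <- neuralpk:::pack_theta(m)
  for (i in sample(seq_along(th), 8)) {
    h <- 1e-6 * max(1, abs(th[i]))
    up <- th; up[i] <- th[i] + h
    dn <- th; dn[i] <- th[i] - h
    fd <- (node_loss_grad(neuralpk:::unpack_theta(m, up), sc$data, "mse", h_max = 1)$loss -
           node_loss_grad(neuralpk:::unpack_theta(m, dn), sc$data, "mse", h_max = 1)$loss) / (2 * h)
    expect_equal(lg$grad[i], fd, tolerance = 1e-4)
  }
})

test_that("derivative_along_trajectory recovers the elimination mechanism", {
  p1 <- pk_params(kel = 0.1, V = 2)
  reg <- dose_regimen("iv_bolus", d = 1)
  rhs1 <- function(y, t) mechanistic_rhs("onecomp_iv", p1, reg, y, t)
  tt <- seq(0, 50, length.out = 120)
  prof <- derivative_along_trajectory(rhs1, pk_solve(rhs1, 0.5, tt), tt)
  fitln <- stats::lm(deriv ~ conc, prof)
  expect_equal(unname(stats::coef(fitln)["conc"]), -0.1, tolerance = 1e-6)
  expect_lt(abs(unname(stats::coef(fitln)["(Intercept)"])), 1e-8)

  # two-compartment: distribution phase steeper than the terminal phase
  p2 <- pk_params(kel = 0.1, V = 2, k12 = 0.2, k21 = 0.2)
  rhs2 <- function(y, t) mechanistic_rhs("twocomp_iv", p2, reg, y, t)
  traj2 <- pk_solve(rhs2, c(0.5, 0), tt)
  prof2 <- derivative_along_trajectory(rhs2, traj2, tt, central = 1)
  ord <- order(prof2$conc)
  lo <- prof2[ord[seq_len(40)], ]          # terminal tercile
  hi <- prof2[ord[(80 + 1):120], ]         # distribution tercile
  s_lo <- stats::coef(stats::lm(deriv ~ conc, lo))["conc"]
  s_hi <- stats::coef(stats::lm(deriv ~ conc, hi))["conc"]
  expect_lt(s_hi, s_lo)  # more negative = steeper

  # zero rhs: all derivative samples vanish
  z <- derivative_along_trajectory(function(y, t) 0 * y,
                                   matrix(1, 5, 1), 1:5)
  expect_identical(z$deriv, rep(0, 5))

  expect_error(derivative_along_trajectory(rhs1, matrix(1, 4, 1), 1:5),
               "4 rows")
})
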