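# models with all networks zeroed expose the mechanistic skeleton
zero_model <- function(structure, n_hid = 2L, ...) {
  m <- node_model(structure, n_hid = n_hid, ...)
  for (nm in names(m$nets)) {
    m$nets[[nm]]$W2[] <- 0
    m$nets[[nm]]$b2[] <- 0
  }
  m
}

test_that("initial states follow the printed initial conditions", {
  sep <- node_model("separated", n_hid = 2, V = 2)
  expect_equal(initial_state(sep, dose_regimen("iv_bolus", d = 1)), 0.5)

  abs <- node_model("absorption", n_hid = 2)
  expect_identical(initial_state(abs, dose_regimen("oral", d = 7)), c(0, 0))

  ma <- node_model("mech_abs", n_hid = 2, V = 2, mech_params = list(ka = 0.2))
  expect_equal(initial_state(ma, dose_regimen("oral", d = 10)), c(5, 0))

  inf <- node_model("infusion", n_hid = 2, V = 2)
  expect_identical(initial_state(inf, dose_regimen("iv_infusion", kin = 1, tinf = 6)), 0)
})

test_that("route/structure mismatches are rejected before any computation", {
  sep <- node_model("separated", n_hid = 2, V = 2)
  expect_error(initial_state(sep, dose_regimen("oral", d = 1)),
               "requires a iv_bolus regimen")
  abs <- node_model("absorption", n_hid = 2)
  expect_error(initial_state(abs, dose_regimen("iv_bolus", d = 1)), "oral")
  expect_error(node_rhs(sep, c(1, 2), 0, dose_regimen("iv_bolus", d = 1)),
               "dimension 1")
})

test_that("zeroed networks reduce the right-hand sides to their mechanistic parts", {
  reg <- dose_regimen("iv_bolus", d = 1)
  sep <- zero_model("separated", V = 2)
  expect_identical(node_rhs(sep, 0.3, 2, reg), 0)

  # infusion: only the indicator input term survives
  infm <- zero_model("infusion", V = 2)
  rinf <- dose_regimen("iv_infusion", kin = 1, tinf = 6)
  expect_equal(node_rhs(infm, 0.4, 3, rinf), 0.5)
  expect_equal(node_rhs(infm, 0.4, 7, rinf), 0)

  # known elimination: dxC = -kel * xC
  me <- zero_model("mech_elim", mech_params = list(kel = 0.1))
  expect_equal(node_rhs(me, c(0, 4), 1, dose_regimen("oral", d = 5)), c(0, -0.4))
})

test_that("node_rhs equals the manual composition of its networks", {
  set.seed(61)
  nets <- list(C1 = random_mlp(4), C2 = random_mlp(4, restrict = TRUE))
  m <- node_model("separated", n_hid = 4, V = 2, nets = nets)
  reg <- dose_regimen("iv_bolus", d = 3)
  for (i in 1:20) {
    x <- stats::runif(1, 0, 2); t <- stats::runif(1, 0, 50)
    expect_equal(node_rhs(m, x, t, reg),
                 mlp_forward(nets$C1, x) + (3 / 2) * mlp_forward(nets$C2, t))
  }
  # basic structure: single two-input network
  cb <- mlp_spec(2, 3, 1, W1 = matrix(stats::runif(6, -1, 1), 3, 2),
                 b1 = stats::runif(3), W2 = matrix(stats::runif(3), 1, 3),
                 b2 = 0.2)
  mb <- node_model("basic", n_hid = 3, V = 2, nets = list(C = cb))
  for (i in 1:5) {
    x <- stats::runif(1); t <- stats::runif(1, 0, 10)
    expect_equal(node_rhs(mb, x, t, reg), mlp_forward(cb, c(x, t)))
  }
})

test_that("trainable parameter counts follow the layer shapes", {
  expect_identical(count_parameters(node_model("separated", n_hid = 20, V = 2)), 123L)
  expect_identical(count_parameters(node_model("mech_abs", n_hid = 20, V = 2,
                                               mech_params = list(ka = 0.2))), 123L)
  expect_identical(count_parameters(node_model("absorption", n_hid = 20)), 244L)
  expect_identical(count_parameters(node_model("basic", n_hid = 20, V = 2)), 82L)
  # degenerate: no hidden neurons leaves output biases and V
  expect_identical(count_parameters(node_model("separated", n_hid = 0, V = 2)), 3L)
})

test_that("time-dependence of the rhs vanishes beyond the time-net onset", {
  set.seed(71)
  nets <- list(C1 = random_mlp(4), C2 = random_mlp(4, restrict = TRUE))
  m <- node_model("separated", n_hid = 4, V = 2, nets = nets)
  reg <- dose_regimen("iv_bolus", d = 1)
  t0 <- constancy_onset(nets$C2)
  expect_identical(node_rhs(m, 0.25, t0 + 1, reg), node_rhs(m, 0.25, t0 + 500, reg))
})

test_that("mech_abs with zeroed nets accumulates the full dose into the central state", {
  m <- zero_model("mech_abs", V = 2, mech_params = list(ka = 0.2))
  reg <- dose_regimen("oral", d = 10)
  rhs <- function(state, t) node_rhs(m, state, t, reg)
  traj <- pk_solve(rhs, initial_state(m, reg), c(0, 100), solver_config())
  # xA(0) = d/V drains completely into xC (no elimination term left)
  expect_equal(traj[2, 2], 5, tolerance = 1e-5)
})

test_that("node checkpoints survive a JSON round trip behaviorally and bitwise", {
  set.seed(81)
  nets <- list(C1 = random_mlp(5), C2 = random_mlp(5, restrict = TRUE))
  m <- node_model("separated", n_hid = 5, V = 1.7, nets = nets)
  path <- tempfile(fileext = ".node.json")
  on.exit(unlink(path))
  write_node_json(m, path, metadata = list(seed = 99))
  back <- read_node_json(path)
  expect_identical(back$structure, m$structure)
  expect_identical(back$logV, m$logV)
  expect_identical(back$nets$C1$W1, m$nets$C1$W1)
  expect_identical(back$nets$C2$b1, m$nets$C2$b1)
  reg <- dose_regimen("iv_bolus", d = 2)
  for (i in 1:10) {
    x <- stats::runif(1, 0, 3); t <- stats::runif(1, 0, 40)
    expect_identical(node_rhs(back, x, t, reg), node_rhs(m, x, t, reg))
  }
  expect_identical(attr(back, "metadata")$seed, 99L)
})

test_that("hybrid structures require their mechanistic constants", {
  expect_error(node_model("mech_elim", n_hid = 2), "kel")
  expect_error(node_model("mech_abs", n_hid = 2, V = 1), "ka")
})
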