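test_that("mlp_forward matches hand-evaluated cases", {
  zero <- mlp_spec(1, 3, 1, W1 = matrix(0, 3, 1), b1 = rep(0, 3),
                   W2 = matrix(0, 1, 3), b2 = 0)
  expect_identical(mlp_forward(zero, 0.7), 0)
  expect_identical(mlp_forward(zero, -12), 0)

  # single ReLU neuron with unit weights is max(0, x)
  one <- mlp_spec(1, 1, 1, W1 = matrix(1), b1 = 0, W2 = matrix(1), b2 = 0)
  expect_equal(mlp_forward(one, -2), 0)
  expect_equal(mlp_forward(one, 3), 3)
})

test_that("matrix form agrees with the summation form on random specs", {
  set.seed(11)
  for (r in 1:100) {
    sp <- random_mlp(n_hid = 5L, restrict = r %% 2 == 0)
    x <- stats::runif(1, -5, 5)
    expect_equal(mlp_forward(sp, x), mlp_summation_oracle(sp, x),
                 tolerance = 1e-12)
  }
})

test_that("shape mismatches are rejected with the offending dimension named", {
  expect_error(mlp_spec(1, 3, 1, W1 = matrix(0, 2, 1), b1 = rep(0, 3),
                        W2 = matrix(0, 1, 3), b2 = 0), "W1 must be 3 x 1")
  expect_error(mlp_spec(1, 3, 1, W1 = matrix(0, 3, 1), b1 = rep(0, 2),
                        W2 = matrix(0, 1, 3), b2 = 0), "b1 must have length")
  expect_error(mlp_spec(1, 3, 1, W1 = matrix(0, 3, 1), b1 = rep(0, 3),
                        W2 = matrix(0, 1, 2), b2 = 0), "W2 must be 1 x 3")
  sp <- random_mlp(3)
  expect_error(mlp_forward(sp, c(1, 2)), "n_in = 1")
})

test_that("restricted_weight maps any weight to a nonpositive value", {
  expect_identical(restricted_weight(0), 0)
  expect_identical(restricted_weight(2), -4)
  expect_identical(restricted_weight(-3), -9)
  w <- stats::rnorm(50)
  expect_true(all(restricted_weight(w) <= 0))
})

test_that("restriction makes every effective input weight nonpositive", {
  set.seed(21)
  sp <- random_mlp(8, restrict = TRUE)
  expect_true(all(effective_W1(sp) <= 0))
})

test_that("constancy_onset gives the exact time the output settles at b2", {
  # all hidden biases nonpositive: constant from t = 0
  sp0 <- mlp_spec(1, 3, 1, W1 = matrix(c(1, 2, 0.5)), b1 = c(-1, 0, -2),
                  W2 = matrix(c(1, 1, 1), 1, 3), b2 = 0.3,
                  restrict_input_weights = TRUE)
  expect_identical(constancy_onset(sp0), 0)

  # single neuron, raw w = 1 (effective -1), b1 = 2: off for t >= 2
  sp1 <- mlp_spec(1, 1, 1, W1 = matrix(1), b1 = 2, W2 = matrix(1.5), b2 = -0.25,
                  restrict_input_weights = TRUE)
  expect_equal(constancy_onset(sp1), 2)
  expect_identical(mlp_forward(sp1, 2.5), -0.25)

  # zero effective weight with positive bias never switches off
  spInf <- mlp_spec(1, 2, 1, W1 = matrix(c(0, 1)), b1 = c(1, 1),
                    W2 = matrix(c(1, 1), 1, 2), b2 = 0,
                    restrict_input_weights = TRUE)
  expect_identical(constancy_onset(spInf), Inf)

  expect_error(constancy_onset(random_mlp(3)), "restricted")
})

test_that("restricted networks are exactly constant beyond their onset", {
  set.seed(31)
  for (r in 1:20) {
    sp <- random_mlp(6, restrict = TRUE)
    t0 <- constancy_onset(sp)
    expect_identical(mlp_forward(sp, t0 + 1), sp$b2)
    expect_identical(mlp_forward(sp, t0 + 100), sp$b2)
    expect_identical(mlp_forward(sp, t0 + 1), mlp_forward(sp, t0 + 100))
  }
})

test_that("1-in/1-out ReLU networks are piecewise linear with <= n_hid kinks", {
  set.seed(41)
  sp <- random_mlp(6)
  grid <- seq(-4, 4, length.out = 2001)
  y <- vapply(grid, function(x) mlp_forward(sp, x), numeric(1))
  d2 <- abs(diff(y, differences = 2))
  # each ReLU kink lies inside one grid cell and touches two second
  # differences; everywhere else the curvature is exactly zero
  expect_lte(sum(d2 > 1e-8), 2L * sp$n_hid)
  # and continuity: no jumps
  expect_lt(max(abs(diff(y))), 1)
})

test_that("JSON round trip of a spec is bit-faithful", {
  set.seed(51)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  for (restrict in c(TRUE, FALSE)) {
    sp <- random_mlp(7, restrict = restrict)
    write_mlp_json(sp, path)
    back <- read_mlp_json(path)
    expect_identical(back$W1, sp$W1)
    expect_identical(back$b1, sp$b1)
    expect_identical(back$W2, sp$W2)
    expect_identical(back$b2, sp$b2)
    expect_identical(back$restrict_input_weights, sp$restrict_input_weights)
  }
})

test_that("the activation registry accepts new entries and rejects unknown names", {
  register_activation("softplus_test", function(z) log1p(exp(z)),
                      function(z) 1 / (1 + exp(-z)))
  sp <- mlp_spec(1, 1, 1, W1 = matrix(1), b1 = 0, W2 = matrix(1), b2 = 0,
                 act_hidden = "softplus_test")
  expect_equal(mlp_forward(sp, 0), log(2))
  expect_error(mlp_spec(1, 1, 1, W1 = matrix(1), b1 = 0, W2 = matrix(1),
                        b2 = 0, act_hidden = "nope"), "unknown activation")
})
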