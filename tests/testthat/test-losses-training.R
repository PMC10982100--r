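test_that("loss formulas match hand evaluation", {
  expect_identical(mse(c(1, 2), c(2, 4)), 2.5)
  expect_identical(wmse(c(1, 2), c(2, 4)), 0.75)
  expect_identical(mse(c(1, 2), c(1, 2)), 0)
  expect_identical(wmse(c(1, 2), c(1, 2)), 0)
})

test_that("losses scale as their formulas dictate", {
  set.seed(101)
  obs <- stats::runif(12, 1, 3)
  pred <- obs + stats::runif(12, -0.5, 0.5)
  # doubling every residual quadruples the MSE
  expect_equal(mse(obs + 2 * (pred - obs), obs), 4 * mse(pred, obs))
  # joint scaling by c scales the WMSE by c
  expect_equal(wmse(3 * pred, 3 * obs), 3 * wmse(pred, obs))
})

test_that("losses validate their inputs", {
  expect_error(mse(1:3, 1:4), "3 predictions for 4")
  expect_error(wmse(c(1, 2), c(0, 1)), "positive")
  obs <- data.frame(group_id = "g1", time = c(1, 2), conc = c(2, 4))
  pred <- data.frame(group_id = "g1", time = 1, conc = 1)
  expect_error(mse(pred, obs), "no prediction")
  pred2 <- data.frame(group_id = "g1", time = c(1, 2), conc = c(1, 2))
  expect_identical(mse(pred2, obs), 2.5)
})

test_that("training is bit-reproducible for a fixed seed", {
  sc <- make_scenario("overfit_onecomp", seed = 5)
  f1 <- node_fit(sc, epochs = 400, seed = 5)
  f2 <- node_fit(sc, epochs = 400, seed = 5)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(coef(f1), coef(f2))
})

test_that("a clean single-group fit recovers the elimination mechanism", {
  sc <- make_scenario("overfit_onecomp", seed = 1, cv = 0)
  fit <- node_fit(sc, epochs = 20000, seed = 1)
  expect_lt(fit$final_loss, 1e-8)
  prof <- derivative_state_profile(fit)
  inr <- prof$conc >= min(sc$data$conc) & prof$conc <= max(sc$data$conc)
  slope <- stats::coef(stats::lm(deriv ~ conc, prof[inr, ]))[["conc"]]
  expect_lt(abs(slope - (-0.1)) / 0.1, 0.10)
})

test_that("the estimated volume is identifiable from clean two-rate infusion data", {
  sc <- make_scenario("infusion", seed = 1, cv = 0)
  fit <- node_fit(sc, epochs = 12000, seed = 1)
  expect_lt(abs(exp(fit$model$logV) - 2) / 2, 0.10)
})

test_that("pooled replicates pull the learned mechanism toward the truth", {
  profile_error <- function(fit) {
    prof <- derivative_state_profile(fit)
    mean(abs(prof$deriv - (-0.1 * prof$conc)))
  }
  single <- node_fit(make_scenario("overfit_onecomp", seed = 1),
                     epochs = 10000, seed = 1)
  pooled <- node_fit(make_scenario("overfit_onecomp", seed = 1, n_rep = 8),
                     epochs = 10000, seed = 1)
  expect_lt(profile_error(pooled) / profile_error(single), 0.5)
})

test_that("the loss history never ends above its start", {
  for (name in c("twocomp_iv", "po_plain")) {
    f <- node_fit(make_scenario(name, seed = 2), epochs = 600, seed = 2)
    h <- f$loss_history
    expect_lte(h[length(h)], h[1])
    expect_true(all(is.finite(h)))
    expect_identical(f$final_loss, min(h))
  }
})

test_that("fitted objects expose the standard modelling methods", {
  sc <- make_scenario("twocomp_iv", seed = 3)
  fit <- node_fit(sc, epochs = 500, seed = 3)
  expect_s3_class(fit, "node_fit")
  expect_output(print(fit), "structure 'separated'")
  expect_output(print(summary(fit)), "Residuals")
  cf <- coef(fit)
  expect_length(cf, 123L)
  expect_true("V" %in% names(cf))
  pred <- predict(fit)
  expect_identical(nrow(pred), 10L) # 2 groups x 5 times
  res <- residuals(fit)
  expect_length(res, nrow(sc$data))
  expect_true(all(is.finite(res)))
  new <- predict(fit, dose_regimen("iv_bolus", d = 5), times = c(1, 10, 25))
  expect_identical(nrow(new), 3L)
  sim <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(nrow(sim), 10L)
  sim2 <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(sim, sim2)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit, oracle = sc$oracle))
})

test_that("structure/data route mismatches and bad losses are rejected", {
  sc <- make_scenario("twocomp_iv", seed = 1)
  expect_error(node_fit(sc, structure = "infusion", epochs = 10),
               "requires iv_infusion")
  d <- sc$data
  d$conc[1] <- -d$conc[1]
  expect_error(suppressWarnings(node_fit(d, structure = "separated",
                                         loss = "wmse", epochs = 10)),
               "positive")
})
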