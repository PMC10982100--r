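#' @export
print.node_fit <- function(x, ...) {
  cat(sprintf("PK neural ODE fit (structure '%s', %d trainable parameters)\n",
              x$model$structure, count_parameters(x$model)))
  if (!is.null(x$scenario)) cat(sprintf("  scenario: %s\n", x$scenario))
  cat(sprintf("  data: %d observations in %d dose group(s)\n",
              nrow(x$data), length(unique(x$data$group_id))))
  cat(sprintf("  pooled %s after %d epochs: %.3e (best at epoch %d)\n",
              toupper(x$config$loss), length(x$loss_history), x$final_loss,
              x$best_epoch))
  if (!is.null(x$model$logV)) cat(sprintf("  estimated V: %.4g\n", exp(x$model$logV)))
  invisible(x)
}

#' @export
summary.node_fit <- function(object, ...) {
  res <- residuals(object)
  by_group <- tapply(res, object$data$group_id, function(r)
    c(n = length(r), rmse = sqrt(mean(r^2)), max_abs = max(abs(r))))
  out <- list(fit = object,
              n_par = count_parameters(object$model),
              V = node_V(object$model),
              residual_summary = do.call(rbind, by_group),
              loss = object$final_loss,
              loss_name = object$config$loss)
  class(out) <- "summary.node_fit"
  out
}

#' @export
print.summary.node_fit <- function(x, ...) {
  print(x$fit)
  cat("\nResiduals (observed - fitted) by dose group:\n")
  print(round(x$residual_summary, 5))
  invisible(x)
}

#' Trainable parameters of a fitted NODE
#'
#' @param object a \code{node_fit}.
#' @param ... unused.
#' @return named numeric vector: per network the weights
#'   \code{<net>.W1.*}, \code{<net>.b1.*}, \code{<net>.W2.*},
#'   \code{<net>.b2}, and the volume on its natural scale as \code{V}.
#' @export
coef.node_fit <- function(object, ...) {
  m <- object$model
  out <- unlist(lapply(names(m$nets), function(nm) {
    s <- m$nets[[nm]]
    v <- c(as.numeric(s$W1), s$b1, as.numeric(s$W2), s$b2)
    names(v) <- c(sprintf("%s.W1.%d", nm, seq_len(s$n_hid * s$n_in)),
                  sprintf("%s.b1.%d", nm, seq_len(s$n_hid)),
                  sprintf("%s.W2.%d", nm, seq_len(s$n_hid)),
                  sprintf("%s.b2", nm))
    v
  }))
  if (!is.null(m$logV)) out <- c(out, V = exp(m$logV))
  out
}

# dense solution of a fitted model for one regimen
node_predict_curve <- function(model, regimen, times, config = NULL) {
  check_route(model, regimen)
  if (is.null(config)) {
    bp <- if (model$structure == "infusion") regimen$tinf else numeric()
    config <- solver_config(breakpoints = bp)
  }
  y0 <- initial_state(model, regimen)
  tt <- times
  prepend <- tt[1] > 0
  if (prepend) tt <- c(0, tt)
  traj <- pk_solve(function(state, t) node_rhs(model, state, t, regimen),
                   y0, tt, config)
  conc <- traj[, node_structure_dim(model$structure)]
  if (prepend) conc <- conc[-1]
  conc
}

#' Predict concentrations from a fitted NODE
#'
#' Solves the fitted model for the requested regimen(s) with the adaptive
#' reference solver (tight tolerances, infusion stop declared as a
#' breakpoint) and returns central-compartment concentrations. Without
#' \code{newdata} the fitted values at the training design points are
#' returned.
#'
#' @param object a \code{node_fit}.
#' @param newdata optional: a \code{\link{dose_regimen}}, a list of them,
#'   or a data frame with regimen columns (\code{route, dose, kin, tinf}).
#' @param times evaluation times; defaults to the training times.
#' @param ... unused.
#' @return data frame with columns \code{group_id}, \code{time},
#'   \code{conc}.
#' @export
predict.node_fit <- function(object, newdata = NULL, times = NULL, ...) {
  model <- object$model
  if (is.null(newdata)) {
    regs <- dataset_regimens(object$data)
    gs <- unique(object$data$group_id)
    out <- lapply(seq_along(regs), function(i) {
      sub <- object$data[object$data$group_id == gs[i], ]
      tt <- sort(unique(sub$time))
      data.frame(group_id = gs[i], time = tt,
                 conc = node_predict_curve(model, regs[[i]], tt))
    })
    return(do.call(rbind, out))
  }
  if (inherits(newdata, "dose_regimen")) newdata <- list(newdata)
  if (is.data.frame(newdata)) newdata <- dataset_regimens(
    cbind(newdata, group_id = sprintf("r%d", seq_len(nrow(newdata)))))
  if (is.null(times)) times <- sort(unique(object$data$time))
  out <- lapply(seq_along(newdata), function(i) {
    reg <- newdata[[i]]
    data.frame(group_id = sprintf("r%d", i), time = times,
               conc = node_predict_curve(model, reg, times))
  })
  do.call(rbind, out)
}

#' Residuals of a fitted NODE
#'
#' Observed minus fitted concentration at every pooled observation.
#'
#' @param object a \code{node_fit}.
#' @param ... unused.
#' @return numeric vector aligned with the rows of \code{object$data}.
#' @export
residuals.node_fit <- function(object, ...) {
  fitted <- predict(object)
  key_obs <- paste(object$data$group_id, object$data$time)
  key_fit <- paste(fitted$group_id, fitted$time)
  object$data$conc - fitted$conc[match(key_obs, key_fit)]
}

#' Simulate noisy observations from a fitted NODE
#'
#' Solves the fitted model for a regimen and adds proportional residual
#' error, mirroring the generating noise model of the training data.
#'
#' @param object a \code{node_fit}.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param regimen a \code{\link{dose_regimen}}; defaults to the first
#'   training regimen.
#' @param times sampling times; defaults to the training times.
#' @param cv proportional error coefficient of variation.
#' @param ... unused.
#' @return data frame with columns \code{sim}, \code{time}, \code{conc}.
#' @export
simulate.node_fit <- function(object, nsim = 1, seed = NULL, regimen = NULL,
                              times = NULL, cv = 0.1, ...) {
  if (is.null(regimen)) regimen <- dataset_regimens(object$data)[[1]]
  if (is.null(times)) times <- sort(unique(object$data$time))
  if (is.null(seed)) seed <- object$seed
  clean <- pmax(node_predict_curve(object$model, regimen, times), 0)
  out <- lapply(seq_len(nsim), function(s)
    data.frame(sim = s, time = times,
               conc = add_proportional_error(clean, cv, seed + s - 1L)))
  do.call(rbind, out)
}

#' Plot a fitted NODE
#'
#' Two base-graphics panels: the pooled data with fitted concentration
#' curves per dose group, and the derivative-versus-state diagnostic of
#' the fitted model (optionally against the generating oracle).
#'
#' @param x a \code{node_fit}.
#' @param oracle optional \code{"pk_oracle"} (as found in
#'   \code{make_scenario()$oracle}) whose profile is overlaid.
#' @param log_y plot concentrations on a log scale.
#' @param ... passed to \code{plot}.
#' @export
plot.node_fit <- function(x, oracle = NULL, log_y = FALSE, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  regs <- dataset_regimens(x$data)
  gs <- unique(x$data$group_id)
  horizon <- max(x$data$time)
  tt <- seq(1e-3, horizon, length.out = 200)
  cols <- grDevices::hcl.colors(max(3, length(gs)), "Dark 3")
  ylim <- range(x$data$conc[x$data$conc > 0 | !log_y])
  plot(NA, xlim = c(0, horizon), ylim = ylim, xlab = "time",
       ylab = "concentration", log = if (log_y) "y" else "",
       main = "pooled fit", ...)
  for (i in seq_along(gs)) {
    sub <- x$data[x$data$group_id == gs[i], ]
    graphics::points(sub$time, sub$conc, col = cols[i], pch = 1)
    cc <- node_predict_curve(x$model, regs[[i]], tt)
    if (log_y) cc <- pmax(cc, min(ylim))
    graphics::lines(tt, cc, col = cols[i], lwd = 2)
  }
  prof <- do.call(rbind, lapply(seq_along(gs), function(i)
    derivative_state_profile(x, regimen = regs[[i]], n = 200)))
  plot(prof$conc, prof$deriv, type = "p", pch = 16, cex = 0.4,
       xlab = "concentration x_C", ylab = "dx_C/dt",
       main = "derivative vs state")
  if (!is.null(oracle)) {
    oprof <- do.call(rbind, lapply(seq_along(regs), function(i)
      derivative_state_profile(oracle, regimen = regs[[i]],
                               times = seq(1e-3, horizon, length.out = 200))))
    graphics::points(oprof$conc, oprof$deriv, col = "grey50", cex = 0.4)
    graphics::legend("bottomleft", legend = c("NODE", "oracle"),
                     col = c("black", "grey50"), pch = 16, bty = "n")
  }
  invisible(x)
}
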