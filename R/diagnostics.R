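#' Derivative-versus-state profile of a model
#'
#' Solves the model for one regimen on a dense time grid and pairs the
#' central concentration with its instantaneous derivative at every grid
#' point. The resulting (x_C, dx_C/dt) samples are the raw material of the
#' derivative-versus-state plot, which exposes the learned or true
#' elimination/distribution mechanism: a one-compartment model gives the
#' line \eqn{-k_{el} x_C}; a two-compartment model gives a steep
#' distribution-phase slope flattening into the terminal phase.
#'
#' @param x a \code{node_fit}, \code{\link{node_model}}, or
#'   \code{"pk_oracle"} (generating model + parameters, as in
#'   \code{make_scenario()$oracle}).
#' @param regimen a \code{\link{dose_regimen}}.
#' @param times evaluation times; default 200 points from just after 0 to
#'   \code{horizon}.
#' @param horizon end of the default grid.
#' @param n number of default grid points.
#' @param ... unused.
#' @return data frame of class \code{"derivative_state_profile"} with
#'   columns \code{conc}, \code{deriv}, \code{time}, plus attributes
#'   \code{source} and \code{dose_group}.
#' @export
derivative_state_profile <- function(x, ...) UseMethod("derivative_state_profile")

profile_from_rhs <- function(rhs, y0, times, central, config, source, group) {
  traj <- pk_solve(rhs, y0, times, config)
  prof <- derivative_along_trajectory(rhs, traj, times, central = central)
  attr(prof, "source") <- source
  attr(prof, "dose_group") <- group
  prof
}

#' @rdname derivative_state_profile
#' @export
derivative_state_profile.node_model <- function(x, regimen, times = NULL,
                                                horizon = 50, n = 200, ...) {
  check_route(x, regimen)
  if (is.null(times)) times <- seq(0, horizon, length.out = n)
  bp <- if (x$structure == "infusion") regimen$tinf else numeric()
  profile_from_rhs(function(state, t) node_rhs(x, state, t, regimen),
                   initial_state(x, regimen), times,
                   central = node_structure_dim(x$structure),
                   config = solver_config(breakpoints = bp),
                   source = "node", group = sprintf("d=%g", regimen$d))
}

#' @rdname derivative_state_profile
#' @export
derivative_state_profile.node_fit <- function(x, regimen = NULL, times = NULL,
                                              horizon = NULL, n = 200, ...) {
  if (is.null(regimen)) regimen <- dataset_regimens(x$data)[[1]]
  if (is.null(horizon)) horizon <- max(x$data$time)
  derivative_state_profile(x$model, regimen, times = times, horizon = horizon,
                           n = n)
}

#' @rdname derivative_state_profile
#' @export
derivative_state_profile.pk_oracle <- function(x, regimen, times = NULL,
                                               horizon = 50, n = 200, ...) {
  if (is.null(times)) times <- seq(0, horizon, length.out = n)
  bp <- if (x$model_id == "onecomp_infusion") regimen$tinf else numeric()
  profile_from_rhs(function(state, t)
    mechanistic_rhs(x$model_id, x$params, regimen, state, t),
    pk_initial_state(x$model_id, x$params, regimen), times,
    central = pk_central_index(x$model_id, x$params),
    config = solver_config(breakpoints = bp),
    source = "reference", group = sprintf("d=%g", regimen$d))
}

#' Compare two derivative-versus-state profiles
#'
#' Interpolates both derivative curves onto a common concentration grid
#' inside \code{conc_range} and summarizes their discrepancy. This
#' quantifies how well a trained NODE learned the mechanism: small
#' discrepancies over the trained concentration range, typically much
#' larger ones outside it.
#'
#' @param node_profile,reference_profile profiles from
#'   \code{\link{derivative_state_profile}}.
#' @param conc_range length-2 numeric; defaults to the overlap of the two
#'   profiles' concentration ranges.
#' @param n grid size.
#' @return list with \code{mean_abs} and \code{max_abs} derivative
#'   discrepancy, the \code{grid}, and both interpolated curves.
#' @export
compare_profiles <- function(node_profile, reference_profile, conc_range = NULL,
                             n = 100) {
  if (is.null(conc_range))
    conc_range <- c(max(min(node_profile$conc), min(reference_profile$conc)),
                    min(max(node_profile$conc), max(reference_profile$conc)))
  if (conc_range[1] >= conc_range[2])
    stop("profiles have no overlapping concentration range")
  grid <- seq(conc_range[1], conc_range[2], length.out = n)
  interp <- function(p) stats::approx(p$conc, p$deriv, xout = grid,
                                      ties = mean, rule = 2)$y
  dn <- interp(node_profile); dr <- interp(reference_profile)
  list(mean_abs = mean(abs(dn - dr)), max_abs = max(abs(dn - dr)),
       grid = grid, node = dn, reference = dr)
}

rel_rmse <- function(pred, truth, log10_scale = FALSE, floor = 1e-3) {
  if (log10_scale) {
    lp <- log10(pmax(pred, floor)); lt <- log10(pmax(truth, floor))
    sqrt(mean((lp - lt)^2))
  } else {
    sqrt(mean((pred - truth)^2)) / mean(truth)
  }
}

#' Quantify unseen-regimen simulation accuracy against the oracle
#'
#' For each test regimen, simulates both the fitted NODE and the
#' generating mechanistic model on a dense grid over the horizon and
#' reports the relative RMSE (RMSE divided by the oracle's mean
#' concentration), the maximum absolute error, and whether the NODE
#' produced negative concentrations. This operationalizes "the simulation
#' coincides with the original model": in-range regimens should stay
#' below a small threshold (default 0.15) while extrapolation beyond the
#' trained range typically fails it by a wide margin.
#'
#' With \code{log10_scale = TRUE} (used for target-mediated profiles that
#' span several orders of magnitude) the reported value is the RMSE of
#' \code{log10} concentrations, both curves floored at \code{floor}; the
#' comparison then starts at the first observed time point, since the
#' initial rapid-binding transient is not identifiable from sparse
#' samples.
#'
#' @param fit a \code{node_fit}, or a bare \code{\link{node_model}} (then
#'   \code{horizon} is required and \code{log10_scale} has no data-driven
#'   default start, so the window begins at \code{horizon/n}).
#' @param oracle a \code{"pk_oracle"}.
#' @param test_regimens list of \code{\link{dose_regimen}} objects.
#' @param horizon end of the comparison window; defaults to the last
#'   training time.
#' @param log10_scale compare log10 concentrations.
#' @param floor lower clip for the log comparison.
#' @param n dense grid size.
#' @param tol relative-RMSE threshold recorded in the report.
#' @return data frame of class \code{"simulation_report"}: one row per
#'   regimen with columns \code{regimen}, \code{dose}, \code{rel_rmse},
#'   \code{max_abs_err}, \code{negative}, \code{within_tol}.
#' @export
interpolation_report <- function(fit, oracle, test_regimens, horizon = NULL,
                                 log10_scale = FALSE, floor = 1e-3, n = 200,
                                 tol = 0.15) {
  stopifnot(inherits(fit, c("node_fit", "node_model")),
            inherits(oracle, "pk_oracle"))
  if (inherits(test_regimens, "dose_regimen")) test_regimens <- list(test_regimens)
  model <- if (inherits(fit, "node_fit")) fit$model else fit
  if (is.null(horizon)) {
    if (!inherits(fit, "node_fit"))
      stop("horizon is required when evaluating a bare node_model")
    horizon <- max(fit$data$time)
  }
  t0 <- if (log10_scale && inherits(fit, "node_fit")) min(fit$data$time)
        else horizon / n
  times <- seq(t0, horizon, length.out = n)
  rows <- lapply(test_regimens, function(reg) {
    pred <- node_predict_curve(model, reg, times)
    truth <- simulate_reference(oracle$model_id, oracle$params, reg, times)
    rr <- rel_rmse(pred, truth, log10_scale = log10_scale, floor = floor)
    data.frame(regimen = if (reg$route == "iv_infusion")
                 sprintf("kin=%g,tinf=%g", reg$kin, reg$tinf)
               else sprintf("d=%g", reg$d),
               dose = reg$d, rel_rmse = rr,
               max_abs_err = max(abs(pred - truth)),
               negative = any(pred < 0), within_tol = rr <= tol,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "tol") <- tol
  attr(out, "log10_scale") <- log10_scale
  class(out) <- c("simulation_report", "data.frame")
  out
}
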