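#' Training configuration
#'
#' Settings for full-batch gradient training of a NODE: loss, epoch budget,
#' Adam learning-rate schedule, training-grid resolution, and best-loss
#' tracking. The default schedule is a triangular cyclic learning rate
#' starting at 1e-3, oscillating between 1e-4 and 1e-3 with a 200-epoch
#' cycle; \code{schedule = "constant"} holds \code{base_lr} fixed.
#'
#' @param loss \code{"mse"} or \code{"wmse"}.
#' @param epochs number of full-batch epochs (> 0).
#' @param base_lr peak learning rate (default 1e-3).
#' @param lr_min cyclic floor (default 1e-4).
#' @param cycle cycle length in epochs.
#' @param schedule \code{"cyclic"} or \code{"constant"}.
#' @param seed integer seed for weight initialization.
#' @param h_max largest RK4 step of the training grid, in time units.
#' @param track_best return the parameters at the lowest loss seen rather
#'   than the final epoch's.
#' @return object of class \code{"training_config"}.
#' @export
training_config <- function(loss = c("mse", "wmse"), epochs = 3000L,
                            base_lr = 1e-3, lr_min = 1e-4, cycle = 200L,
                            schedule = c("cyclic", "constant"), seed = 1L,
                            h_max = 0.5, track_best = TRUE) {
  loss <- match.arg(loss); schedule <- match.arg(schedule)
  if (epochs <= 0) stop("epochs must be > 0")
  if (base_lr <= 0 || lr_min <= 0) stop("learning rates must be > 0")
  structure(list(loss = loss, epochs = as.integer(epochs), base_lr = base_lr,
                 lr_min = lr_min, cycle = as.integer(cycle), schedule = schedule,
                 seed = as.integer(seed), h_max = h_max,
                 track_best = isTRUE(track_best)),
            class = "training_config")
}

# heuristic volume initialization from the data: for bolus-type structures
# V ~ dose / peak concentration of each group; for an infusion, the early
# slope conc(t1)/t1 ~ kin/V
init_V_from_data <- function(structure, data) {
  gs <- unique(data$group_id)
  v <- vapply(gs, function(g) {
    sub <- data[data$group_id == g, ]
    if (structure == "infusion") {
      t1 <- min(sub$time)
      c1 <- mean(sub$conc[sub$time == t1])
      if (c1 <= 0) return(NA_real_)
      sub$kin[1] * t1 / c1
    } else {
      peak <- max(sub$conc)
      if (peak <= 0) return(NA_real_)
      sub$dose[1] / peak
    }
  }, numeric(1))
  v <- v[is.finite(v) & v > 0]
  if (!length(v)) 1 else min(max(stats::median(v), 1e-3), 1e6)
}

validate_pooled_data <- function(data) {
  need <- c("group_id", "route", "dose", "time", "replicate", "conc")
  if (!all(need %in% names(data)))
    stop("pooled data needs columns ", paste(need, collapse = ", "))
  if (!"kin" %in% names(data)) data$kin <- NA_real_
  if (!"tinf" %in% names(data)) data$tinf <- NA_real_
  if (any(data$dose < 0)) stop("doses must be >= 0")
  if (any(data$time < 0)) stop("times must be >= 0")
  if (any(data$conc < 0))
    warning("negative observed concentrations present (kept; observations may be noisy)")
  for (g in unique(data$group_id)) {
    sub <- data[data$group_id == g, ]
    if (length(unique(sub$route)) != 1L ||
        length(unique(sub$dose)) != 1L ||
        length(unique(paste(sub$kin, sub$tinf))) != 1L)
      stop(sprintf("group '%s' mixes regimens; one regimen per group", g))
  }
  data
}

#' Fit a PK neural ODE by pooled full-batch training
#'
#' The main fitting function. All replicates and dose groups are fitted
#' jointly (pooled training): each epoch solves the NODE once per dose
#' group from its group-specific initial condition, pools the loss over
#' every observation, and updates all network parameters (raw weights
#' under the \eqn{w' = -(w^2)} restriction) and \eqn{\log V} by Adam with
#' a cyclic learning rate. Gradients are backpropagated through every
#' Runge--Kutta stage of the training grid, so they are exact for the
#' discretized trajectories. Training is deterministic given the seed.
#'
#' If an epoch produces a non-finite loss (diverged trajectory), training
#' restarts once with both learning-rate bounds halved; a second failure
#' is an error carrying the loss history.
#'
#' @param data a pooled dataset: either the data frame format described in
#'   \code{\link{make_scenario}} or a \code{"pk_scenario"} object (whose
#'   recommended structure and loss become the defaults).
#' @param structure NODE structure name; see \code{\link{node_model}}.
#' @param n_hid hidden neurons per network.
#' @param loss \code{"mse"} or \code{"wmse"}.
#' @param epochs full-batch epoch budget.
#' @param seed integer seed (weight initialization).
#' @param mech_params fixed mechanistic constants for the hybrid
#'   structures (\code{kel} for \code{mech_elim}, \code{ka} for
#'   \code{mech_abs}).
#' @param V_init optional starting volume; by default a heuristic from the
#'   data (dose over peak concentration, or input rate over early slope).
#' @param control a \code{\link{training_config}}; \code{loss},
#'   \code{epochs} and \code{seed} arguments override its fields.
#' @return object of class \code{"node_fit"} with elements \code{model}
#'   (the trained \code{\link{node_model}}), \code{data},
#'   \code{loss_history}, \code{final_loss}, \code{best_epoch},
#'   \code{config}, \code{seed}. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{residuals}, \code{simulate},
#'   \code{plot}.
#' @export
node_fit <- function(data, structure = NULL, n_hid = 20L, loss = NULL,
                     epochs = NULL, seed = 1L, mech_params = list(),
                     V_init = NULL, control = training_config()) {
  scen <- NULL
  if (inherits(data, "pk_scenario")) {
    scen <- data
    if (is.null(structure)) structure <- scen$structure
    if (is.null(loss)) loss <- scen$loss
    if (is.null(epochs) && !is.null(scen$epochs)) epochs <- scen$epochs
    data <- scen$data
  }
  if (is.null(structure)) structure <- "separated"
  structure <- match.arg(structure, .node_structures)
  if (!is.null(loss)) control$loss <- match.arg(loss, c("mse", "wmse"))
  if (!is.null(epochs)) control$epochs <- as.integer(epochs)
  if (!is.null(seed)) control$seed <- as.integer(seed)
  data <- validate_pooled_data(data)

  want <- node_structure_route(structure)
  routes <- unique(data$route)
  if (!all(routes == want))
    stop(sprintf("structure '%s' requires %s dose groups but data has route(s): %s",
                 structure, want, paste(routes, collapse = ", ")))
  if (control$loss == "wmse" && any(data$conc <= 0))
    stop("wmse requires strictly positive observations")

  if (structure == "mech_elim" && is.null(mech_params$kel))
    stop("mech_elim requires mech_params$kel")
  if (structure == "mech_abs" && is.null(mech_params$ka))
    stop("mech_abs requires mech_params$ka")

  V0 <- if (node_has_V(structure)) {
    if (!is.null(V_init)) V_init else init_V_from_data(structure, data)
  } else NULL
  model0 <- withr_seed(control$seed,
                       node_model(structure, n_hid = n_hid,
                                  mech_params = mech_params, V = V0))
  groups <- engine_groups(model0, data, control$h_max)
  desc <- engine_desc(model0)
  theta0 <- pack_theta(model0)
  loss_type <- if (control$loss == "wmse") 1L else 0L

  run <- function(lr_min, lr_max) {
    node_engine_train(desc, theta0, groups,
                      list(epochs = control$epochs, lr_min = lr_min,
                           lr_max = lr_max, cycle = control$cycle,
                           cyclic = control$schedule == "cyclic",
                           track_best = control$track_best,
                           loss_type = loss_type))
  }
  res <- run(control$lr_min, control$base_lr)
  if (!isTRUE(res$ok)) {
    res2 <- run(control$lr_min / 2, control$base_lr / 2)
    if (!isTRUE(res2$ok)) {
      cond <- simpleError(sprintf(
        "training diverged (non-finite loss at epoch %d, and again at epoch %d after halving the learning rate)",
        res$diverged_at, res2$diverged_at))
      cond$loss_history <- res$loss_history
      stop(cond)
    }
    res <- res2
  }

  model <- unpack_theta(model0, res$theta)
  structure(list(model = model, data = data, scenario = scen$name,
                 loss_history = as.numeric(res$loss_history),
                 final_loss = res$final_loss,
                 best_epoch = res$best_epoch,
                 config = control, seed = control$seed,
                 call = match.call()),
            class = "node_fit")
}

#' Pooled loss and exact gradient of a NODE on its training grid
#'
#' Computes the pooled loss of \code{model} on \code{data} and its
#' gradient with respect to every trainable parameter (packed network
#' weights, then \eqn{\log V}), backpropagated through the RK4 training
#' discretization. Exposed so the gradient can be verified against finite
#' differences.
#'
#' @param model a \code{\link{node_model}}.
#' @param data pooled data frame.
#' @param loss \code{"mse"} or \code{"wmse"}.
#' @param h_max training-grid resolution.
#' @return list with \code{loss} (scalar) and \code{grad} (numeric vector
#'   of length \code{\link{count_parameters}(model)}).
#' @export
node_loss_grad <- function(model, data, loss = c("mse", "wmse"), h_max = 0.5) {
  loss <- match.arg(loss)
  data <- validate_pooled_data(data)
  groups <- engine_groups(model, data, h_max)
  out <- node_engine_loss_grad(engine_desc(model), pack_theta(model), groups,
                               if (loss == "wmse") 1L else 0L)
  if (!isTRUE(out$ok)) stop("non-finite state encountered during integration")
  list(loss = out$loss, grad = out$grad)
}

# solve a fitted/constructed NODE on the training-style RK4 grid
node_solve_grid <- function(model, regimen, times, h_max = 0.5) {
  g <- engine_group(model, regimen, times, rep(0, length(times)), h_max)
  Y <- node_engine_solve(engine_desc(model), pack_theta(model), g)
  Y[g$obs_node + 1L, , drop = FALSE]
}
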