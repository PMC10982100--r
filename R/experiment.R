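#' Experiment configuration
#'
#' A fully serializable description of one simulate-train-evaluate run: a
#' persisted configuration plus its seed reproduces the run bit-identically.
#'
#' @param scenario scenario name (see \code{\link{scenario_names}}).
#' @param seed integer seed used for data generation and initialization.
#' @param cv proportional residual error of the synthetic data.
#' @param structure NODE structure; defaults to the scenario's
#'   recommendation.
#' @param n_hid hidden neurons per network.
#' @param loss \code{"mse"} or \code{"wmse"}; defaults to the scenario's
#'   recommendation.
#' @param epochs training epoch budget.
#' @param mech_params fixed constants for hybrid structures.
#' @return object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(scenario, seed = 1L, cv = 0.10, structure = NULL,
                              n_hid = 20L, loss = NULL, epochs = 3000L,
                              mech_params = list()) {
  if (!scenario %in% scenario_names())
    stop(sprintf("unknown scenario '%s'", scenario))
  structure(list(scenario = scenario, seed = as.integer(seed), cv = cv,
                 structure = structure, n_hid = as.integer(n_hid), loss = loss,
                 epochs = as.integer(epochs), mech_params = mech_params),
            class = "experiment_config")
}

#' Run a simulate-train-evaluate experiment
#'
#' Generates the scenario's pooled dataset, trains the NODE, evaluates it
#' on the scenario's unseen test regimens against the mechanistic oracle,
#' and writes all artifacts (dataset CSV + sidecar, \code{*.node.json}
#' checkpoint, training log CSV, evaluation report JSON) to
#' \code{out_dir}. Structure/scenario route compatibility is validated
#' before any computation.
#'
#' @param cfg an \code{\link{experiment_config}}.
#' @param out_dir output directory (created if missing). \code{NULL}
#'   skips writing files.
#' @return invisibly, a list with the scenario, the \code{node_fit}, the
#'   \code{\link{interpolation_report}}, and the paths written.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  structure <- if (is.null(cfg$structure)) .scenarios[[cfg$scenario]]$structure
               else cfg$structure
  structure <- match.arg(structure, .node_structures)
  want <- node_structure_route(structure)
  have <- .scenarios[[cfg$scenario]]$train[[1]]$route
  if (want != have)
    stop(sprintf("structure '%s' (%s) is incompatible with scenario '%s' (%s)",
                 structure, want, cfg$scenario, have))

  t0 <- proc.time()[["elapsed"]]
  scen <- make_scenario(cfg$scenario, seed = cfg$seed, cv = cfg$cv)
  sim_s <- proc.time()[["elapsed"]] - t0
  mech <- cfg$mech_params
  if (structure == "mech_elim" && is.null(mech$kel))
    mech$kel <- scen$oracle$params$kel
  if (structure == "mech_abs" && is.null(mech$ka))
    mech$ka <- if (!is.na(scen$oracle$params$kabs)) scen$oracle$params$kabs
               else scen$oracle$params$ka

  t0 <- proc.time()[["elapsed"]]
  fit <- node_fit(scen, structure = structure, n_hid = cfg$n_hid,
                  loss = cfg$loss, epochs = cfg$epochs, seed = cfg$seed,
                  mech_params = mech)
  train_s <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  log10_scale <- fit$config$loss == "wmse"
  report <- interpolation_report(fit, scen$oracle, scen$tests,
                                 horizon = scen$horizon,
                                 log10_scale = log10_scale)
  eval_s <- proc.time()[["elapsed"]] - t0
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$data <- file.path(out_dir, "dataset.csv")
    write_pooled_csv(scen, paths$data)
    paths$model <- file.path(out_dir, "model.node.json")
    write_node_json(fit, paths$model,
                    metadata = list(scenario = cfg$scenario,
                                    package_version = as.character(
                                      utils::packageVersion("neuralpk")),
                                    train_seconds = round(train_s, 2)))
    paths$log <- file.path(out_dir, "training_log.csv")
    utils::write.csv(data.frame(epoch = seq_along(fit$loss_history),
                                loss = fit$loss_history),
                     paths$log, row.names = FALSE)
    paths$config <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(cfg), paths$config, digits = I(17),
                         auto_unbox = TRUE, null = "null")
    paths$report <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(scenario = cfg$scenario, seed = cfg$seed,
           structure = structure, loss = fit$config$loss,
           package_version = as.character(utils::packageVersion("neuralpk")),
           config_md5 = unname(tools::md5sum(paths$config)),
           wall_seconds = list(simulate = round(sim_s, 3),
                               train = round(train_s, 3),
                               evaluate = round(eval_s, 3)),
           train_groups = vapply(scen$train, function(r)
             if (r$route == "iv_infusion") sprintf("kin=%g,tinf=%g", r$kin, r$tinf)
             else sprintf("d=%g", r$d), character(1)),
           final_loss = fit$final_loss,
           tests = report[, c("regimen", "rel_rmse", "max_abs_err", "negative")]),
      paths$report, digits = I(17), auto_unbox = TRUE, dataframe = "rows")
  }
  invisible(list(scenario = scen, fit = fit, report = report, paths = paths,
                 train_seconds = train_s))
}
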