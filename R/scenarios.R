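#' Scenario registry for the synthetic study conditions
#'
#' Each scenario bundles a generating mechanistic model with its
#' parameters, the training dose groups, the sampling design, the
#' proportional-error level, and the unseen test regimens used for
#' interpolation checks, matching the single-dose experiments this
#' package reproduces.
#'
#' @return character vector of scenario names.
#' @export
scenario_names <- function() names(.scenarios)

# shared printed parameters: kel = 0.1, V = 2; ka = 0.2; ktr = 0.1;
# TMDD: kon = 0.25, koff = 0.01, ksyn = 0.5, kdeg = 0.25, kint = 0.1, kabs = 0.15
.base_lin <- function(...) pk_params(kel = 0.1, V = 2, ...)
.base_tmdd <- function(...) pk_params(kel = 0.1, V = 2, kon = 0.25, koff = 0.01,
                                      ksyn = 0.5, kdeg = 0.25, kint = 0.1, ...)

.iv <- function(d) dose_regimen("iv_bolus", d = d)
.po <- function(d) dose_regimen("oral", d = d)
.inf <- function(kin, tinf) dose_regimen("iv_infusion", kin = kin, tinf = tinf)

.scenarios <- list(
  overfit_onecomp = list(
    model_id = "onecomp_iv", params = .base_lin(),
    train = list(.iv(1)), tests = list(), n_times = 5L, horizon = 50,
    n_rep = 1L, structure = "separated", loss = "mse",
    spacing = "geometric", epochs = 10000L),
  interp_onecomp = list(
    model_id = "onecomp_iv", params = .base_lin(),
    train = list(.iv(1), .iv(50)),
    tests = list(.iv(5), .iv(10), .iv(20), .iv(35)),
    n_times = 5L, horizon = 50, n_rep = 8L, structure = "separated", loss = "mse",
    spacing = "geometric", epochs = 12000L),
  twocomp_iv = list(
    model_id = "twocomp_iv", params = .base_lin(k12 = 0.2, k21 = 0.2),
    train = list(.iv(1), .iv(10)), tests = list(.iv(5)),
    n_times = 5L, horizon = 50, n_rep = 8L, structure = "separated", loss = "mse",
    spacing = "geometric", epochs = 12000L),
  po_plain = list(
    model_id = "onecomp_po_transit", params = .base_lin(ka = 0.2, ntr = 0L),
    train = list(.po(5), .po(15)), tests = list(.po(10)),
    n_times = 7L, horizon = 50, n_rep = 8L, structure = "absorption", loss = "mse",
    spacing = "geometric", epochs = 12000L),
  po_transit4 = list(
    model_id = "onecomp_po_transit", params = .base_lin(ka = 0.2, ktr = 0.1, ntr = 4L),
    train = list(.po(5), .po(15)), tests = list(.po(10)),
    n_times = 10L, horizon = 120, n_rep = 8L, structure = "absorption", loss = "mse",
    spacing = "uniform", epochs = 15000L),
  po_transit8 = list(
    model_id = "onecomp_po_transit", params = .base_lin(ka = 0.2, ktr = 0.1, ntr = 8L),
    train = list(.po(5), .po(15)), tests = list(.po(10)),
    n_times = 10L, horizon = 180, n_rep = 8L, structure = "absorption", loss = "mse",
    spacing = "uniform", epochs = 20000L),
  infusion = list(
    model_id = "onecomp_infusion", params = .base_lin(),
    train = list(.inf(1, 6), .inf(10, 6)), tests = list(.inf(7, 4), .inf(5, 8)),
    n_times = 7L, horizon = 50, n_rep = 8L, structure = "infusion", loss = "mse",
    spacing = "geometric", epochs = 12000L),
  tmdd_iv = list(
    model_id = "tmdd_iv", params = .base_tmdd(),
    train = list(.iv(50), .iv(200)), tests = list(.iv(100)),
    n_times = 7L, horizon = 60, n_rep = 8L, structure = "separated", loss = "wmse",
    spacing = "uniform", epochs = 60000L),
  tmdd_po = list(
    model_id = "tmdd_po", params = .base_tmdd(kabs = 0.15),
    train = list(.po(50), .po(200)), tests = list(.po(100)),
    n_times = 7L, horizon = 60, n_rep = 8L, structure = "mech_abs", loss = "wmse",
    spacing = "uniform", epochs = 30000L)
)

#' Generate a pooled synthetic training dataset for a named scenario
#'
#' Simulates the scenario's mechanistic model at its sampling design for
#' each training regimen, replicates each time point \code{n_rep} times,
#' and adds proportional residual error. Returns the pooled dataset
#' together with the ground-truth oracle description and the unseen test
#' regimens.
#'
#' Sampling times span \code{[1, horizon]}: geometrically spaced for the
#' scenarios whose dynamics are fastest right after dosing (IV bolus,
#' plain oral, infusion), uniformly spaced for the delayed-absorption and
#' target-mediated scenarios, whose informative phases (absorption peak,
#' binding transition) sit mid-horizon where geometric spacing would leave
#' them unobserved. The noise level defaults to \code{cv = 0.10}; the
#' per-scenario replicate counts, spans, recommended structure/loss, and
#' training epoch budgets are part of the registry and recorded in the
#' result.
#'
#' @param name a name from \code{\link{scenario_names}}.
#' @param seed integer seed controlling the residual-error draws.
#' @param cv proportional residual error coefficient of variation.
#' @param n_rep optional override of the scenario's replicate count.
#' @return object of class \code{"pk_scenario"}: a list with elements
#'   \code{name}, \code{data} (the pooled data frame with columns
#'   \code{group_id, route, dose, kin, tinf, time, replicate, conc}),
#'   \code{oracle} (class \code{"pk_oracle"}: generating model + params),
#'   \code{train} and \code{tests} (lists of \code{\link{dose_regimen}}),
#'   \code{times}, \code{structure}, \code{loss}, \code{cv}, \code{seed}.
#' @export
make_scenario <- function(name, seed, cv = 0.10, n_rep = NULL) {
  if (!name %in% names(.scenarios))
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(scenario_names(), collapse = ", ")))
  sc <- .scenarios[[name]]
  if (is.null(n_rep)) n_rep <- sc$n_rep
  times <- if (sc$spacing == "uniform") seq(1, sc$horizon, length.out = sc$n_times)
           else geometric_times(sc$n_times, 1, sc$horizon)
  rows <- list()
  for (g in seq_along(sc$train)) {
    reg <- sc$train[[g]]
    clean <- simulate_reference(sc$model_id, sc$params, reg, times)
    conc <- add_proportional_error(rep(clean, each = n_rep), cv,
                                   seed = seed * 1000L + g)
    rows[[g]] <- data.frame(
      group_id = sprintf("g%d", g), route = reg$route, dose = reg$d,
      kin = reg$kin, tinf = reg$tinf,
      time = rep(times, each = n_rep),
      replicate = rep(seq_len(n_rep), times = length(times)),
      conc = conc, stringsAsFactors = FALSE)
  }
  data <- do.call(rbind, rows)
  oracle <- structure(list(model_id = sc$model_id, params = sc$params),
                      class = "pk_oracle")
  structure(list(name = name, data = data, oracle = oracle,
                 train = sc$train, tests = sc$tests, times = times,
                 horizon = sc$horizon, structure = sc$structure,
                 loss = sc$loss, epochs = sc$epochs, cv = cv, n_rep = n_rep,
                 seed = seed),
            class = "pk_scenario")
}

#' @export
print.pk_scenario <- function(x, ...) {
  cat(sprintf("<pk_scenario> %s: model %s, %d dose group(s) x %d time points x %d replicate(s), cv = %g\n",
              x$name, x$oracle$model_id, length(x$train), length(x$times),
              x$n_rep, x$cv))
  invisible(x)
}

#' @export
print.pk_oracle <- function(x, ...) {
  p <- unlist(unclass(x$params))
  p <- p[!is.na(p)]
  cat(sprintf("<pk_oracle> %s (%s)\n", x$model_id,
              paste(sprintf("%s = %g", names(p), p), collapse = ", ")))
  invisible(x)
}

# regimens of a pooled data frame, one per group, in group order
dataset_regimens <- function(data) {
  gs <- unique(data$group_id)
  lapply(gs, function(g) {
    r <- data[data$group_id == g, ][1, ]
    if (r$route == "iv_infusion") dose_regimen("iv_infusion", kin = r$kin, tinf = r$tinf)
    else dose_regimen(r$route, d = r$dose)
  })
}
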