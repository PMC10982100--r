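#' Mechanistic PK parameter set
#'
#' Container for the rate constants of the mechanistic compartment models
#' used to generate training data and to serve as ground-truth oracles.
#' Only the parameters a given model uses need to be supplied. Units are
#' arbitrary but must be mutually consistent (rates in 1/time, dose in
#' amount, V in volume; concentrations are amount/volume).
#'
#' @param kel elimination rate constant (1/time).
#' @param V volume of distribution.
#' @param k12,k21 central-peripheral transfer rates (1/time).
#' @param ka absorption rate constant (1/time).
#' @param ktr transit rate constant (1/time).
#' @param ntr nonnegative integer number of transit compartments.
#' @param kon,koff target binding / dissociation rates.
#' @param ksyn receptor synthesis rate (concentration/time).
#' @param kdeg receptor degradation rate (1/time).
#' @param kint drug-receptor complex internalization rate (1/time).
#' @param kabs absorption rate constant for extravascular TMDD (1/time).
#' @return object of class \code{"pk_params"}.
#' @export
pk_params <- function(kel = NA_real_, V = NA_real_, k12 = NA_real_, k21 = NA_real_,
                      ka = NA_real_, ktr = NA_real_, ntr = NA_integer_,
                      kon = NA_real_, koff = NA_real_, ksyn = NA_real_,
                      kdeg = NA_real_, kint = NA_real_, kabs = NA_real_) {
  p <- list(kel = kel, V = V, k12 = k12, k21 = k21, ka = ka, ktr = ktr,
            ntr = as.integer(ntr), kon = kon, koff = koff, ksyn = ksyn,
            kdeg = kdeg, kint = kint, kabs = kabs)
  rates <- unlist(p[setdiff(names(p), c("V", "ntr"))])
  if (any(!is.na(rates) & rates < 0)) stop("rate constants must be >= 0")
  if (!is.na(p$V) && p$V <= 0) stop("V must be > 0")
  if (!is.na(p$ntr) && p$ntr < 0L) stop("ntr must be >= 0")
  structure(p, class = "pk_params")
}

#' Single-dose administration description
#'
#' @param route one of \code{"iv_bolus"}, \code{"oral"}, \code{"iv_infusion"}.
#' @param d dose amount. For an infusion the total dose is
#'   \eqn{d = k_{in} t_{inf}} and is computed when omitted.
#' @param kin infusion rate (amount/time; infusion only).
#' @param tinf infusion duration (time; infusion only).
#' @return object of class \code{"dose_regimen"}.
#' @export
dose_regimen <- function(route = c("iv_bolus", "oral", "iv_infusion"),
                         d = NULL, kin = NULL, tinf = NULL) {
  route <- match.arg(route)
  if (route == "iv_infusion") {
    if (is.null(kin) || is.null(tinf))
      stop("iv_infusion requires kin and tinf")
    if (kin < 0 || tinf <= 0) stop("kin must be >= 0 and tinf > 0")
    if (is.null(d)) d <- kin * tinf
    if (abs(d - kin * tinf) > 1e-8 * max(1, d))
      stop("for an infusion the dose must equal kin * tinf")
  } else {
    if (is.null(d)) stop("d is required for ", route)
    kin <- NA_real_; tinf <- NA_real_
  }
  if (d < 0) stop("dose must be >= 0")
  structure(list(route = route, d = d, kin = kin, tinf = tinf),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  if (x$route == "iv_infusion")
    cat(sprintf("<dose_regimen> iv_infusion: kin = %g, tinf = %g (d = %g)\n",
                x$kin, x$tinf, x$d))
  else cat(sprintf("<dose_regimen> %s: d = %g\n", x$route, x$d))
  invisible(x)
}

.pk_models <- c("onecomp_iv", "twocomp_iv", "onecomp_po_transit",
                "onecomp_infusion", "tmdd_iv", "tmdd_po")

pk_model_dim <- function(model_id, params) {
  switch(model_id,
         onecomp_iv = 1L,
         twocomp_iv = 2L,
         onecomp_po_transit = 2L + params$ntr,
         onecomp_infusion = 1L,
         tmdd_iv = 3L,
         tmdd_po = 4L,
         stop(sprintf("unknown model_id '%s'", model_id)))
}

# index of the state matched to measured concentrations
pk_central_index <- function(model_id, params) {
  switch(model_id,
         onecomp_iv = 1L,
         twocomp_iv = 1L,
         onecomp_po_transit = 2L + params$ntr,
         onecomp_infusion = 1L,
         tmdd_iv = 1L,
         tmdd_po = 2L)
}

#' Right-hand side of a mechanistic compartment model
#'
#' Standard mass-action compartmental equations. States are concentrations
#' for the central (and peripheral/receptor/complex) compartments and
#' amounts for depot/transit compartments.
#'
#' \describe{
#'   \item{onecomp_iv}{\code{x}: central concentration; \eqn{x' = -k_{el} x}.}
#'   \item{twocomp_iv}{\code{(xc, xp)}: \eqn{x_c' = -k_{el} x_c - k_{12} x_c
#'     + k_{21} x_p}, \eqn{x_p' = k_{12} x_c - k_{21} x_p}.}
#'   \item{onecomp_po_transit}{\code{(depot, tr_1..tr_ntr, xc)} (amounts,
#'     then concentration): the depot feeds a chain of \code{ntr} transit
#'     compartments at rate \eqn{k_{tr}}; the last compartment is absorbed
#'     into the central compartment at rate \eqn{k_a}. \code{ntr = 0}
#'     collapses to plain first-order absorption at \eqn{k_a}.}
#'   \item{onecomp_infusion}{\eqn{x' = k_{in}/V \cdot 1(t \le t_{inf}) - k_{el} x}.}
#'   \item{tmdd_iv}{\code{(L, R, C)}: free ligand, free receptor, complex:
#'     \eqn{L' = -k_{el} L - k_{on} L R + k_{off} C},
#'     \eqn{R' = k_{syn} - k_{deg} R - k_{on} L R + k_{off} C},
#'     \eqn{C' = k_{on} L R - k_{off} C - k_{int} C}.}
#'   \item{tmdd_po}{\code{(A, L, R, C)} with depot amount \code{A}:
#'     \eqn{A' = -k_{abs} A} and \eqn{L'} gains \eqn{k_{abs} A / V}.}
#' }
#'
#' @param model_id one of \code{"onecomp_iv"}, \code{"twocomp_iv"},
#'   \code{"onecomp_po_transit"}, \code{"onecomp_infusion"},
#'   \code{"tmdd_iv"}, \code{"tmdd_po"}.
#' @param params a \code{\link{pk_params}}.
#' @param regimen a \code{\link{dose_regimen}}.
#' @param state numeric state vector of the model's dimension.
#' @param t time.
#' @return the state derivative vector.
#' @export
mechanistic_rhs <- function(model_id, params, regimen, state, t) {
  model_id <- match.arg(model_id, .pk_models)
  dm <- pk_model_dim(model_id, params)
  if (length(state) != dm)
    stop(sprintf("model '%s' has dimension %d but state has length %d",
                 model_id, dm, length(state)))
  p <- params
  switch(model_id,
    onecomp_iv = -p$kel * state,
    twocomp_iv = c(-p$kel * state[1] - p$k12 * state[1] + p$k21 * state[2],
                   p$k12 * state[1] - p$k21 * state[2]),
    onecomp_po_transit = {
      ntr <- p$ntr
      if (ntr == 0L) {
        c(-p$ka * state[1], p$ka * state[1] / p$V - p$kel * state[2])
      } else {
        depot <- state[1]; tr <- state[2:(1 + ntr)]; xc <- state[2 + ntr]
        dtr <- p$ktr * c(depot, tr[-ntr]) - c(p$ktr * tr[-ntr], p$ka * tr[ntr])
        c(-p$ktr * depot, dtr, p$ka * tr[ntr] / p$V - p$kel * xc)
      }
    },
    onecomp_infusion = {
      inp <- if (t <= regimen$tinf) regimen$kin / p$V else 0
      inp - p$kel * state
    },
    tmdd_iv = {
      L <- state[1]; R <- state[2]; C <- state[3]
      c(-p$kel * L - p$kon * L * R + p$koff * C,
        p$ksyn - p$kdeg * R - p$kon * L * R + p$koff * C,
        p$kon * L * R - p$koff * C - p$kint * C)
    },
    tmdd_po = {
      A <- state[1]; L <- state[2]; R <- state[3]; C <- state[4]
      c(-p$kabs * A,
        p$kabs * A / p$V - p$kel * L - p$kon * L * R + p$koff * C,
        p$ksyn - p$kdeg * R - p$kon * L * R + p$koff * C,
        p$kon * L * R - p$koff * C - p$kint * C)
    })
}

pk_initial_state <- function(model_id, params, regimen) {
  dm <- pk_model_dim(model_id, params)
  y0 <- numeric(dm)
  if (model_id %in% c("onecomp_iv", "twocomp_iv")) {
    if (regimen$route != "iv_bolus") stop(model_id, " requires an iv_bolus regimen")
    y0[1] <- regimen$d / params$V
  } else if (model_id == "onecomp_po_transit") {
    if (regimen$route != "oral") stop(model_id, " requires an oral regimen")
    y0[1] <- regimen$d
  } else if (model_id == "onecomp_infusion") {
    if (regimen$route != "iv_infusion") stop(model_id, " requires an iv_infusion regimen")
  } else if (model_id == "tmdd_iv") {
    if (regimen$route != "iv_bolus") stop(model_id, " requires an iv_bolus regimen")
    y0[1] <- regimen$d / params$V
    y0[2] <- params$ksyn / params$kdeg # receptor at turnover baseline
  } else if (model_id == "tmdd_po") {
    if (regimen$route != "oral") stop(model_id, " requires an oral regimen")
    y0[1] <- regimen$d
    y0[3] <- params$ksyn / params$kdeg
  }
  y0
}

#' Simulate central-compartment concentrations from a mechanistic model
#'
#' Integrates \code{\link{mechanistic_rhs}} from the route-appropriate
#' initial condition (IV bolus: central \code{d/V}; oral: depot \code{d};
#' infusion: all zero) and returns the central concentration at the
#' requested times. The infusion stop time is declared as a solver
#' breakpoint so the input discontinuity is never stepped over.
#'
#' @inheritParams mechanistic_rhs
#' @param times sorted nonnegative time vector.
#' @param config a \code{\link{solver_config}}.
#' @return numeric concentration vector, one value per requested time.
#' @export
simulate_reference <- function(model_id, params, regimen, times,
                               config = solver_config()) {
  model_id <- match.arg(model_id, .pk_models)
  if (is.unsorted(times) || any(times < 0)) stop("times must be sorted and >= 0")
  y0 <- pk_initial_state(model_id, params, regimen)
  if (model_id == "onecomp_infusion" && length(config$breakpoints) == 0L)
    config$breakpoints <- regimen$tinf
  rhs <- function(state, t) mechanistic_rhs(model_id, params, regimen, state, t)
  tt <- times
  prepend <- tt[1] > 0
  if (prepend) tt <- c(0, tt)
  traj <- tryCatch(pk_solve(rhs, y0, tt, config), error = function(e)
    stop(sprintf("solver failure for model '%s' (params: %s): %s", model_id,
                 paste(sprintf("%s=%g", names(unclass(params))[!is.na(unlist(params))],
                               unlist(params)[!is.na(unlist(params))]), collapse = ", "),
                 conditionMessage(e)), call. = FALSE))
  conc <- traj[, pk_central_index(model_id, params)]
  if (prepend) conc <- conc[-1]
  conc
}

#' Add proportional residual error
#'
#' Multiplicative observation noise \eqn{c_i (1 + cv\,\varepsilon_i)} with
#' independent standard-normal \eqn{\varepsilon_i}; results are clipped at
#' zero from below. The same seed always reproduces the same draws.
#'
#' @param conc nonnegative concentration vector.
#' @param cv nonnegative coefficient of variation.
#' @param seed integer seed.
#' @return noisy concentration vector of the same length.
#' @export
add_proportional_error <- function(conc, cv, seed) {
  if (cv < 0) stop("cv must be >= 0")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  out <- withr_seed(seed, conc * (1 + cv * stats::rnorm(length(conc))))
  pmax(out, 0)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Geometrically spaced sampling times
#'
#' @param n number of points.
#' @param t1 first time (> 0).
#' @param t2 last time.
#' @return increasing vector of length \code{n}.
#' @export
geometric_times <- function(n, t1 = 1, t2 = 50) {
  stopifnot(n >= 2, t1 > 0, t2 > t1)
  exp(seq(log(t1), log(t2), length.out = n))
}
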