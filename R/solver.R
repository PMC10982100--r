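#' Solver configuration
#'
#' Settings for the adaptive ODE solves used for data generation and model
#' evaluation. Right-hand-side discontinuities (e.g. the end of an
#' infusion) are declared as breakpoints: integration restarts at each one
#' so the discontinuity is never stepped over.
#'
#' @param method integration method passed to \code{deSolve::ode}
#'   (default \code{"lsoda"}, adaptive).
#' @param rtol,atol relative/absolute tolerances (both > 0). Defaults are
#'   tight (1e-6 / 1e-8) since these solves define reference data.
#' @param breakpoints sorted times at which the right-hand side is
#'   discontinuous.
#' @param max_steps maximum internal steps per solve segment.
#' @return object of class \code{"solver_config"}.
#' @export
solver_config <- function(method = "lsoda", rtol = 1e-6, atol = 1e-8,
                          breakpoints = numeric(), max_steps = 100000L) {
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0")
  structure(list(method = method, rtol = rtol, atol = atol,
                 breakpoints = sort(unique(breakpoints)),
                 max_steps = as.integer(max_steps)),
            class = "solver_config")
}

#' Solve an ODE on a fixed output grid
#'
#' Thin contract over \code{deSolve::ode}: integrates \code{rhs} from
#' \code{y0} over \code{times}, splitting the integration at each declared
#' breakpoint. The first output row equals \code{y0} exactly.
#'
#' @param rhs function \code{(state, t) -> derivative vector}.
#' @param y0 initial state at \code{times[1]}.
#' @param times sorted output times; \code{times[1]} is the initial time.
#' @param config a \code{\link{solver_config}}.
#' @return numeric matrix \code{length(times) x length(y0)} of states.
#' @export
pk_solve <- function(rhs, y0, times, config = solver_config()) {
  stopifnot(is.function(rhs), is.numeric(y0), length(times) >= 1)
  if (is.unsorted(times)) stop("times must be sorted")
  dm <- length(y0)
  out <- matrix(NA_real_, length(times), dm)
  out[1, ] <- y0
  if (length(times) == 1L) return(structure(out, times = times))
  bps <- config$breakpoints
  bps <- bps[bps > times[1] & bps < times[length(times)]]
  # segment boundaries: initial time, interior breakpoints, final time
  bounds <- sort(unique(c(times[1], bps, times[length(times)])))
  func <- function(t, y, parms) list(rhs(y, t))
  y <- y0
  for (s in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1L]
    inner <- times[times > t0 & times < t1]
    seg <- unique(c(t0, inner, t1))
    sol <- deSolve::ode(y = y, times = seg, func = func, parms = NULL,
                        method = config$method, rtol = config$rtol,
                        atol = config$atol, maxsteps = config$max_steps)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("integration failed near t = %g", seg[length(seg)]))
    sol <- unname(as.matrix(sol)[, -1, drop = FALSE])
    if (any(!is.finite(sol)))
      stop(sprintf("non-finite state encountered in [%g, %g]", t0, t1))
    idx <- match(times[times > t0 & times <= t1], seg)
    out[which(times > t0 & times <= t1), ] <- sol[idx, , drop = FALSE]
    y <- sol[nrow(sol), ]
  }
  structure(out, times = times)
}

#' Pair concentrations with their time derivatives along a trajectory
#'
#' Evaluates the right-hand side along a solved trajectory and returns the
#' paired (concentration, derivative) samples that make up the
#' derivative-versus-state diagnostic: the x-axis is the central
#' concentration, the y-axis its instantaneous derivative, so the plot
#' exposes the elimination/distribution mechanism a model encodes.
#'
#' @param rhs function \code{(state, t) -> derivative vector}.
#' @param trajectory matrix from \code{\link{pk_solve}} on the same times.
#' @param times time vector matching the trajectory rows.
#' @param central column index of the central (measured) state; defaults
#'   to the last column.
#' @return data frame of class \code{"derivative_state_profile"} with
#'   columns \code{conc}, \code{deriv}, \code{time}.
#' @export
derivative_along_trajectory <- function(rhs, trajectory, times,
                                        central = ncol(trajectory)) {
  trajectory <- as.matrix(trajectory)
  if (nrow(trajectory) != length(times))
    stop(sprintf("trajectory has %d rows but %d times were given",
                 nrow(trajectory), length(times)))
  deriv <- vapply(seq_along(times),
                  function(i) rhs(trajectory[i, ], times[i])[central],
                  numeric(1))
  structure(data.frame(conc = trajectory[, central], deriv = deriv, time = times),
            class = c("derivative_state_profile", "data.frame"))
}
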