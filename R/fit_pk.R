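#' Classical one-compartment IV refit
#'
#' Least-squares fit of the two-parameter one-compartment IV bolus model
#' \eqn{c(t) = (d/V) e^{-k_{el} t}} to pooled observations, used as the
#' conventional-model counterpart in the overfitting comparison: with few
#' noisy points its MSE plateaus near the residual-error variance, while a
#' flexible NODE can fit far below that floor. Optimization is on
#' \eqn{(\log k_{el}, \log V)} with data-driven starting values (terminal
#' log-slope and dose over peak), so the refit is deterministic.
#'
#' @param data pooled data frame with one IV bolus dose group per
#'   \code{group_id} (columns as in \code{\link{make_scenario}}).
#' @return list with \code{kel}, \code{V}, \code{mse}, and the fitted
#'   values \code{fitted} aligned with \code{data}.
#' @export
fit_onecomp_iv <- function(data) {
  data <- validate_pooled_data(data)
  if (!all(data$route == "iv_bolus")) stop("fit_onecomp_iv requires iv_bolus data")
  pos <- data$conc > 0
  sl <- stats::coef(stats::lm(log(conc) ~ time, data = data[pos, ]))
  kel0 <- max(1e-3, -sl[["time"]])
  V0 <- max(1e-3, stats::median(data$dose) / max(data$conc))
  obj <- function(p) {
    kel <- exp(p[1]); V <- exp(p[2])
    mean((data$dose / V * exp(-kel * data$time) - data$conc)^2)
  }
  opt <- stats::optim(c(log(kel0), log(V0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  kel <- exp(opt$par[1]); V <- exp(opt$par[2])
  list(kel = kel, V = V, mse = opt$value,
       fitted = data$dose / V * exp(-kel * data$time))
}
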