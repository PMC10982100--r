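align_pred_obs <- function(pred, obs) {
  if (is.data.frame(obs)) {
    if (!all(c("time", "conc") %in% names(obs)))
      stop("observed data frame needs columns time and conc")
    if (is.data.frame(pred)) {
      key_obs <- if ("group_id" %in% names(obs) && "group_id" %in% names(pred))
        paste(obs$group_id, obs$time) else as.character(obs$time)
      key_pred <- if ("group_id" %in% names(obs) && "group_id" %in% names(pred))
        paste(pred$group_id, pred$time) else as.character(pred$time)
      i <- match(key_obs, key_pred)
      if (anyNA(i)) {
        miss <- unique(key_obs[is.na(i)])
        stop(sprintf("no prediction for observation time(s): %s",
                     paste(utils::head(miss, 5), collapse = ", ")))
      }
      list(pred = pred$conc[i], obs = obs$conc)
    } else {
      if (length(pred) != nrow(obs))
        stop(sprintf("%d predictions for %d observations", length(pred), nrow(obs)))
      list(pred = as.numeric(pred), obs = obs$conc)
    }
  } else {
    if (length(pred) != length(obs))
      stop(sprintf("%d predictions for %d observations", length(pred), length(obs)))
    list(pred = as.numeric(pred), obs = as.numeric(obs))
  }
}

#' Mean squared error of pooled concentration predictions
#'
#' \deqn{MSE = \frac{1}{mn} \sum_{i=1}^m \sum_{j=1}^n (x_C(t_i) - x_{ji})^2,}
#' with \eqn{m} time points and \eqn{n} replicates per time point. With
#' unequal replicate counts the divisor is the total number of observation
#' points, which reduces to \eqn{mn} for a rectangular design.
#'
#' @param pred predicted concentrations: a numeric vector aligned with the
#'   observations, or a data frame with columns \code{time}, \code{conc}
#'   (and optionally \code{group_id}) matched to the observations by time.
#' @param obs observed concentrations: numeric vector or pooled data frame
#'   with columns \code{time}, \code{conc}.
#' @return nonnegative scalar.
#' @export
mse <- function(pred, obs) {
  a <- align_pred_obs(pred, obs)
  mean((a$pred - a$obs)^2)
}

#' Weighted mean squared error
#'
#' \deqn{WMSE = \frac{1}{mn} \sum_{i=1}^m \sum_{j=1}^n
#'   \frac{(x_C(t_i) - x_{ji})^2}{x_{ji}},}
#' down-weighting large observations so profiles spanning several orders
#' of magnitude are fitted across their whole range. All observations must
#' be positive.
#'
#' @inheritParams mse
#' @return nonnegative scalar.
#' @export
wmse <- function(pred, obs) {
  a <- align_pred_obs(pred, obs)
  if (any(a$obs <= 0))
    stop("wmse requires strictly positive observations (weights are 1/obs)")
  mean((a$pred - a$obs)^2 / a$obs)
}
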