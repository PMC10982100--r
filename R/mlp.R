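#' One-hidden-layer network specification
#'
#' Constructs the specification of a one-hidden-layer feed-forward network
#' \deqn{f(x) = \sigma^{(2)}(W^{(2)} \sigma^{(1)}(W^{(1)} x + b^{(1)}) + b^{(2)}),}
#' the building block of all neural-ODE right-hand sides in this package.
#' With ReLU hidden activation and identity output the network is a
#' continuous piecewise-linear function of its input.
#'
#' When \code{restrict_input_weights} is \code{TRUE} the stored input
#' weights are raw values \eqn{w} and evaluation uses the effective weight
#' \eqn{w' = -(w^2) \le 0}. For a time-input network this forces every
#' hidden ReLU to switch off at some finite time, so the network output
#' becomes constant (equal to \eqn{b^{(2)}}) for large \eqn{t}: the
#' time-dependence of the ODE right-hand side vanishes, as required for a
#' concentration that must not grow without bound after input processes
#' have finished.
#'
#' @param n_in,n_hid,n_out positive integers; input, hidden, and output
#'   dimensions. All uses in this package have \code{n_out = 1} and
#'   \code{n_in} 1 or 2.
#' @param W1 numeric matrix \code{n_hid x n_in}; input-to-hidden weights
#'   (raw weights when restricted).
#' @param b1 numeric vector of length \code{n_hid}; hidden biases.
#' @param W2 numeric matrix \code{n_out x n_hid}; hidden-to-output weights.
#' @param b2 numeric vector of length \code{n_out}; output biases.
#' @param act_hidden,act_out activation names; \code{"relu"} and
#'   \code{"identity"} are built in (see \code{\link{register_activation}}).
#' @param restrict_input_weights logical; apply \eqn{w' = -(w^2)} to the
#'   input weights at evaluation time.
#' @return An object of class \code{"mlp_spec"}.
#' @seealso \code{\link{mlp_forward}}, \code{\link{mlp_init}},
#'   \code{\link{constancy_onset}}
#' @export
mlp_spec <- function(n_in = 1L, n_hid, n_out = 1L, W1, b1, W2, b2,
                     act_hidden = "relu", act_out = "identity",
                     restrict_input_weights = FALSE) {
  n_in <- as.integer(n_in); n_hid <- as.integer(n_hid); n_out <- as.integer(n_out)
  if (n_in < 1L || n_hid < 0L || n_out < 1L)
    stop("dimensions must be positive (n_in, n_out >= 1; n_hid >= 0)")
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  b1 <- as.numeric(b1); b2 <- as.numeric(b2)
  if (!identical(dim(W1), c(n_hid, n_in)))
    stop(sprintf("W1 must be %d x %d (n_hid x n_in), got %d x %d",
                 n_hid, n_in, nrow(W1), ncol(W1)))
  if (length(b1) != n_hid)
    stop(sprintf("b1 must have length n_hid = %d, got %d", n_hid, length(b1)))
  if (!identical(dim(W2), c(n_out, n_hid)))
    stop(sprintf("W2 must be %d x %d (n_out x n_hid), got %d x %d",
                 n_out, n_hid, nrow(W2), ncol(W2)))
  if (length(b2) != n_out)
    stop(sprintf("b2 must have length n_out = %d, got %d", n_out, length(b2)))
  get_activation(act_hidden); get_activation(act_out) # fail early on unknown names
  structure(list(n_in = n_in, n_hid = n_hid, n_out = n_out,
                 W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 act_hidden = act_hidden, act_out = act_out,
                 restrict_input_weights = isTRUE(restrict_input_weights)),
            class = "mlp_spec")
}

# activation registry: each entry holds the function and its derivative
.act_registry <- new.env(parent = emptyenv())

#' Register an activation function
#'
#' Activations are looked up by name when a network is evaluated. Only
#' \code{"relu"} and \code{"identity"} are used by the built-in NODE
#' structures; the registry exists so alternative activations can be
#' plugged in without touching network evaluation.
#'
#' @param name character scalar.
#' @param fn vectorized function of a numeric vector.
#' @param grad vectorized derivative of \code{fn}.
#' @export
register_activation <- function(name, fn, grad) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn), is.function(grad))
  assign(name, list(fn = fn, grad = grad), envir = .act_registry)
  invisible(name)
}

get_activation <- function(name) {
  if (!exists(name, envir = .act_registry, inherits = FALSE))
    stop(sprintf("unknown activation '%s'", name))
  get(name, envir = .act_registry, inherits = FALSE)
}

register_activation("relu", function(z) pmax(0, z), function(z) as.numeric(z > 0))
register_activation("identity", function(z) z, function(z) rep(1, length(z)))

#' Weight restriction forcing non-positive input weights
#'
#' Maps a raw weight \eqn{w} to the effective weight \eqn{w' = -(w^2)}.
#' Applied elementwise to the input weights of time-input networks so that
#' every hidden ReLU argument eventually becomes negative and the network
#' output settles at its output bias.
#'
#' @param w numeric.
#' @return \code{-(w^2)}, always \eqn{\le 0}.
#' @export
restricted_weight <- function(w) -(w^2)

#' Effective input-weight matrix of a network
#'
#' @param spec an \code{\link{mlp_spec}}.
#' @return \code{W1} with the restriction applied when the spec requests it.
#' @export
effective_W1 <- function(spec) {
  if (spec$restrict_input_weights) restricted_weight(spec$W1) else spec$W1
}

#' Evaluate a one-hidden-layer network
#'
#' Matrix-form evaluation
#' \eqn{\sigma^{(2)}(W^{(2)} \sigma^{(1)}(W^{(1)}_{\mathrm{eff}} x + b^{(1)}) + b^{(2)})},
#' deterministic and continuous in \code{x}.
#'
#' @param spec an \code{\link{mlp_spec}}.
#' @param x numeric vector of length \code{n_in}.
#' @return numeric vector of length \code{n_out}.
#' @export
mlp_forward <- function(spec, x) {
  stopifnot(inherits(spec, "mlp_spec"))
  x <- as.numeric(x)
  if (length(x) != spec$n_in)
    stop(sprintf("input has length %d but n_in = %d", length(x), spec$n_in))
  if (any(!is.finite(x))) stop("input must be finite")
  s1 <- get_activation(spec$act_hidden)$fn
  s2 <- get_activation(spec$act_out)$fn
  h <- s1(drop(effective_W1(spec) %*% x) + spec$b1)
  as.numeric(s2(drop(spec$W2 %*% h) + spec$b2))
}

#' Random network initialization
#'
#' Hidden layer: standard uniform fan-in initialization, drawing weights
#' and biases from \eqn{U(-1/\sqrt{\mathrm{fan~in}}, 1/\sqrt{\mathrm{fan~in}})}.
#' Output layer: initialized at zero, so every freshly built network is
#' the zero function and a neural-ODE right-hand side starts as the
#' identity flow. Because inputs are fed in natural units (raw time, raw
#' concentration, which can span orders of magnitude across dose groups),
#' a random output layer would give initial vector fields whose magnitude
#' grows with the concentration scale and frequently produces explosive
#' early trajectories; the zero start is scale-free and removes that
#' failure mode without restricting what training can reach (the output
#' layer receives nonzero gradients from the first epoch). Draws come
#' from R's global RNG; fitting functions seed it and record the seed.
#'
#' @inheritParams mlp_spec
#' @return an \code{\link{mlp_spec}}.
#' @export
mlp_init <- function(n_in = 1L, n_hid = 20L, n_out = 1L,
                     restrict_input_weights = FALSE) {
  r1 <- 1 / sqrt(n_in)
  mlp_spec(n_in, n_hid, n_out,
           W1 = matrix(stats::runif(n_hid * n_in, -r1, r1), n_hid, n_in),
           b1 = stats::runif(n_hid, -r1, r1),
           W2 = matrix(0, n_out, n_hid),
           b2 = numeric(n_out),
           restrict_input_weights = restrict_input_weights)
}

#' Time after which a restricted time-network becomes constant
#'
#' For a restricted 1-input ReLU network every hidden argument
#' \eqn{w'_i t + b^{(1)}_i} is non-increasing in \eqn{t}, so there is a
#' smallest \eqn{t^* \ge 0} beyond which all ReLUs are off and the output
#' equals \eqn{b^{(2)}} exactly: \eqn{t^* = \max_i b^{(1)}_i / (-w'_i)}
#' over neurons with \eqn{b^{(1)}_i > 0}. Returns \code{Inf} when some
#' such neuron has zero effective weight (its ReLU never switches off).
#'
#' @param spec a restricted \code{\link{mlp_spec}} with \code{n_in = 1} and
#'   ReLU hidden activation.
#' @return nonnegative scalar (possibly \code{Inf}).
#' @export
constancy_onset <- function(spec) {
  stopifnot(inherits(spec, "mlp_spec"))
  if (!spec$restrict_input_weights)
    stop("constancy_onset is only defined for restricted (time-input) networks")
  if (spec$n_in != 1L || spec$act_hidden != "relu")
    stop("constancy_onset requires n_in = 1 and ReLU hidden activation")
  w <- drop(effective_W1(spec))
  pos <- spec$b1 > 0
  if (!any(pos)) return(0)
  if (any(pos & w == 0)) return(Inf)
  max(spec$b1[pos] / (-w[pos]))
}

#' @export
print.mlp_spec <- function(x, ...) {
  cat(sprintf("<mlp_spec> %d-%d-%d, %s/%s%s\n", x$n_in, x$n_hid, x$n_out,
              x$act_hidden, x$act_out,
              if (x$restrict_input_weights) ", restricted input weights" else ""))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

mlp_to_list <- function(spec) {
  list(n_in = spec$n_in, n_hid = spec$n_hid, n_out = spec$n_out,
       W1 = spec$W1, b1 = spec$b1, W2 = spec$W2, b2 = spec$b2,
       act_hidden = spec$act_hidden, act_out = spec$act_out,
       restrict_input_weights = spec$restrict_input_weights)
}

mlp_from_list <- function(x) {
  nh <- as.integer(x$n_hid); ni <- as.integer(x$n_in); no <- as.integer(x$n_out)
  mlp_spec(ni, nh, no,
           W1 = matrix(unlist(x$W1), nh, ni), b1 = unlist(x$b1),
           W2 = matrix(unlist(x$W2), no, nh), b2 = unlist(x$b2),
           act_hidden = x$act_hidden, act_out = x$act_out,
           restrict_input_weights = isTRUE(x$restrict_input_weights))
}

#' Read or write a network specification as JSON
#'
#' Numbers are serialized at full precision so a write/read round trip is
#' bit-faithful for finite doubles.
#'
#' @param spec an \code{\link{mlp_spec}}.
#' @param path file path.
#' @return \code{read_mlp_json} returns an \code{\link{mlp_spec}};
#'   \code{write_mlp_json} returns \code{path} invisibly.
#' @export
write_mlp_json <- function(spec, path) {
  jsonlite::write_json(mlp_to_list(spec), path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_mlp_json
#' @export
read_mlp_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nh <- as.integer(x$n_hid); ni <- as.integer(x$n_in); no <- as.integer(x$n_out)
  as_mat <- function(m, nr, nc) {
    if (is.matrix(m)) matrix(as.numeric(m), nr, nc)
    else matrix(as.numeric(m), nr, nc, byrow = (nr == 1L))
  }
  mlp_spec(ni, nh, no, W1 = as_mat(x$W1, nh, ni), b1 = as.numeric(x$b1),
           W2 = as_mat(x$W2, no, nh), b2 = as.numeric(x$b2),
           act_hidden = x$act_hidden, act_out = x$act_out,
           restrict_input_weights = isTRUE(x$restrict_input_weights))
}
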