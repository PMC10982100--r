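.node_structures <- c("basic", "separated", "absorption", "infusion",
                      "mech_elim", "mech_abs")

# net layout per structure: names, input kind (conc/time/conc+time), and
# whether the input weights are restricted (time-input nets must decay)
node_net_layout <- function(structure) {
  switch(structure,
    basic      = list(C  = list(n_in = 2L, restrict = FALSE)),
    separated  = list(C1 = list(n_in = 1L, restrict = FALSE),
                      C2 = list(n_in = 1L, restrict = TRUE)),
    absorption = list(A1 = list(n_in = 1L, restrict = TRUE),
                      A2 = list(n_in = 1L, restrict = FALSE),
                      C1 = list(n_in = 1L, restrict = FALSE),
                      C2 = list(n_in = 1L, restrict = TRUE)),
    infusion   = list(C1 = list(n_in = 1L, restrict = FALSE),
                      C2 = list(n_in = 1L, restrict = TRUE)),
    mech_elim  = list(A1 = list(n_in = 1L, restrict = TRUE),
                      A2 = list(n_in = 1L, restrict = FALSE)),
    mech_abs   = list(C1 = list(n_in = 1L, restrict = FALSE),
                      C2 = list(n_in = 1L, restrict = TRUE)),
    stop(sprintf("unknown structure '%s'", structure)))
}

node_structure_dim <- function(structure) {
  if (structure %in% c("absorption", "mech_elim", "mech_abs")) 2L else 1L
}

node_structure_route <- function(structure) {
  switch(structure,
    basic = "iv_bolus", separated = "iv_bolus",
    absorption = "oral", mech_elim = "oral", mech_abs = "oral",
    infusion = "iv_infusion")
}

node_has_V <- function(structure) {
  structure %in% c("basic", "separated", "infusion", "mech_abs")
}

#' Construct a PK neural-ODE model
#'
#' Builds one of the six PK-principled NODE structures. State dimension is
#' one (a central compartment \eqn{x_C}) or two (absorption compartment
#' \eqn{x_A} feeding \eqn{x_C}):
#' \describe{
#'   \item{basic}{\eqn{x_C' = f^{C}(x_C, t)}, \eqn{x_C(0) = d/V}; one
#'     two-input network.}
#'   \item{separated}{\eqn{x_C' = f^{C1}(x_C) + (d/V) f^{C2}(t)},
#'     \eqn{x_C(0) = d/V}; the recommended general structure, with the
#'     concentration- and time-dependence in separate one-input networks.}
#'   \item{absorption}{\eqn{x_A' = d f^{A1}(t) - f^{A2}(x_A)},
#'     \eqn{x_C' = f^{A2}(x_A) - f^{C1}(x_C) - d f^{C2}(t)}, both states
#'     starting at 0; no volume parameter (scaling is absorbed by
#'     \eqn{f^{A2}}).}
#'   \item{infusion}{\eqn{x_C' = (k_{in}/V) 1(t \le t_{inf}) + f^{C1}(x_C)
#'     + (d/V) f^{C2}(t)}, \eqn{x_C(0) = 0}; \eqn{V} must be estimated
#'     because the input rate enters explicitly.}
#'   \item{mech_elim}{known linear elimination \eqn{k_{el}}, learned
#'     absorption: \eqn{x_A' = d f^{A1}(t) - f^{A2}(x_A)},
#'     \eqn{x_C' = f^{A2}(x_A) - k_{el} x_C}.}
#'   \item{mech_abs}{known first-order absorption \eqn{k_a}, learned
#'     disposition: \eqn{x_A' = -k_a x_A}, \eqn{x_A(0) = d/V},
#'     \eqn{x_C' = k_a x_A - f^{C1}(x_C) - (d/V) f^{C2}(t)}.}
#' }
#' Every time-input network has its input weights restricted
#' (\eqn{w' = -(w^2)}) so its output is constant beyond a finite onset and
#' the right-hand side eventually loses its explicit time-dependence.
#' \eqn{V} is stored and optimized as \eqn{\log V} to enforce positivity.
#'
#' @param structure one of \code{"basic"}, \code{"separated"},
#'   \code{"absorption"}, \code{"infusion"}, \code{"mech_elim"},
#'   \code{"mech_abs"}.
#' @param n_hid hidden neurons per network (default 20, ample for the PK
#'   scenarios considered here).
#' @param mech_params named list of fixed mechanistic constants:
#'   \code{kel} for \code{mech_elim}, \code{ka} for \code{mech_abs}.
#' @param V volume of distribution, for structures whose equations contain
#'   \code{d/V} or \code{kin/V}.
#' @param nets optional named list of \code{\link{mlp_spec}} objects to use
#'   instead of fresh random initialization (names and restriction flags
#'   must match the structure's layout).
#' @return object of class \code{"node_model"}.
#' @export
node_model <- function(structure = .node_structures, n_hid = 20L,
                       mech_params = list(), V = NULL, nets = NULL) {
  structure <- match.arg(structure)
  layout <- node_net_layout(structure)
  if (is.null(nets)) {
    nets <- lapply(layout, function(l)
      mlp_init(n_in = l$n_in, n_hid = n_hid, restrict_input_weights = l$restrict))
    names(nets) <- names(layout)
  } else {
    if (!setequal(names(nets), names(layout)))
      stop(sprintf("structure '%s' requires nets named %s", structure,
                   paste(names(layout), collapse = ", ")))
    nets <- nets[names(layout)]
    for (nm in names(layout)) {
      if (!inherits(nets[[nm]], "mlp_spec")) stop("nets must be mlp_spec objects")
      if (nets[[nm]]$n_in != layout[[nm]]$n_in)
        stop(sprintf("net %s must have n_in = %d", nm, layout[[nm]]$n_in))
      if (!identical(nets[[nm]]$restrict_input_weights, layout[[nm]]$restrict))
        stop(sprintf("net %s must have restrict_input_weights = %s", nm,
                     layout[[nm]]$restrict))
    }
  }
  logV <- NULL
  if (node_has_V(structure)) {
    if (is.null(V)) V <- 1
    if (V <= 0) stop("V must be > 0")
    logV <- log(V)
  }
  if (structure == "mech_elim" && is.null(mech_params$kel))
    stop("mech_elim requires mech_params$kel")
  if (structure == "mech_abs" && is.null(mech_params$ka))
    stop("mech_abs requires mech_params$ka")
  structure(list(structure = structure, nets = nets, logV = logV,
                 mech_params = mech_params, n_hid = as.integer(n_hid)),
            class = "node_model")
}

node_V <- function(model) if (is.null(model$logV)) NA_real_ else exp(model$logV)

check_route <- function(model, regimen) {
  want <- node_structure_route(model$structure)
  if (regimen$route != want)
    stop(sprintf("structure '%s' requires a %s regimen but got %s",
                 model$structure, want, regimen$route))
}

#' Initial state of a NODE structure for a regimen
#'
#' Returns the structure's initial condition with the model's current
#' volume: \code{d/V} in the central compartment for IV bolus structures,
#' \code{d/V} in the absorption compartment for \code{mech_abs}, zero
#' otherwise. The regimen's route must match the structure.
#'
#' @param model a \code{\link{node_model}}.
#' @param regimen a \code{\link{dose_regimen}}.
#' @return numeric state vector (\eqn{x_A} first where present, then
#'   \eqn{x_C}).
#' @export
initial_state <- function(model, regimen) {
  stopifnot(inherits(model, "node_model"), inherits(regimen, "dose_regimen"))
  check_route(model, regimen)
  switch(model$structure,
         basic = ,
         separated = regimen$d / node_V(model),
         infusion = 0,
         absorption = ,
         mech_elim = c(0, 0),
         mech_abs = c(regimen$d / node_V(model), 0))
}

#' Right-hand side of a NODE structure
#'
#' Composes the structure's networks and mechanistic terms exactly as the
#' model equations state them (see \code{\link{node_model}} for the six
#' structures). Used by \code{\link{pk_solve}} for prediction; training
#' uses an equivalent compiled implementation.
#'
#' @param model a \code{\link{node_model}}.
#' @param state numeric state vector of the structure's dimension.
#' @param t time.
#' @param regimen a \code{\link{dose_regimen}}.
#' @return the state derivative vector.
#' @export
node_rhs <- function(model, state, t, regimen) {
  stopifnot(inherits(model, "node_model"))
  dm <- node_structure_dim(model$structure)
  if (length(state) != dm)
    stop(sprintf("structure '%s' has dimension %d but state has length %d",
                 model$structure, dm, length(state)))
  nets <- model$nets
  d <- regimen$d
  switch(model$structure,
    basic = mlp_forward(nets$C, c(state[1], t)),
    separated = mlp_forward(nets$C1, state[1]) +
      (d / node_V(model)) * mlp_forward(nets$C2, t),
    absorption = {
      a2 <- mlp_forward(nets$A2, state[1])
      c(d * mlp_forward(nets$A1, t) - a2,
        a2 - mlp_forward(nets$C1, state[2]) - d * mlp_forward(nets$C2, t))
    },
    infusion = {
      V <- node_V(model)
      (if (t <= regimen$tinf) regimen$kin / V else 0) +
        mlp_forward(nets$C1, state[1]) + (d / V) * mlp_forward(nets$C2, t)
    },
    mech_elim = {
      a2 <- mlp_forward(nets$A2, state[1])
      c(d * mlp_forward(nets$A1, t) - a2,
        a2 - model$mech_params$kel * state[2])
    },
    mech_abs = {
      V <- node_V(model)
      c(-model$mech_params$ka * state[1],
        model$mech_params$ka * state[1] - mlp_forward(nets$C1, state[2]) -
          (d / V) * mlp_forward(nets$C2, t))
    })
}

#' Number of trainable parameters in a NODE model
#'
#' Per network \code{n_hid * (n_in + n_out + 1) + n_out} weights and
#' biases, plus one for \eqn{\log V} where the volume is estimated; fixed
#' mechanistic constants are excluded.
#'
#' @param model a \code{\link{node_model}}.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  n <- sum(vapply(model$nets, function(s)
    s$n_hid * (s$n_in + s$n_out + 1L) + s$n_out, integer(1)))
  n + if (is.null(model$logV)) 0L else 1L
}

#' @export
print.node_model <- function(x, ...) {
  cat(sprintf("<node_model> structure '%s', %d net(s) with n_hid = %d, %d trainable parameters\n",
              x$structure, length(x$nets), x$n_hid, count_parameters(x)))
  if (!is.null(x$logV)) cat(sprintf("  V = %g\n", exp(x$logV)))
  if (length(x$mech_params))
    cat(sprintf("  fixed: %s\n", paste(sprintf("%s = %g", names(x$mech_params),
                                               unlist(x$mech_params)), collapse = ", ")))
  invisible(x)
}

# ---- engine interface ------------------------------------------------------

structure_code <- function(structure) {
  match(structure, .node_structures) - 1L # basic = 0 ... mech_abs = 5
}

engine_desc <- function(model) {
  list(structure = structure_code(model$structure),
       nets = lapply(unname(model$nets), function(s)
         list(n_in = s$n_in, n_hid = s$n_hid, restrict = s$restrict_input_weights)),
       has_v = !is.null(model$logV),
       kel = if (!is.null(model$mech_params$kel)) model$mech_params$kel else 0,
       ka = if (!is.null(model$mech_params$ka)) model$mech_params$ka else 0,
       dim = node_structure_dim(model$structure))
}

# pack nets + logV into the engine's flat parameter vector
# per net: W1 (column-major), b1, W2, b2; nets in layout order; logV last
pack_theta <- function(model) {
  th <- unlist(lapply(model$nets, function(s)
    c(as.numeric(s$W1), s$b1, as.numeric(s$W2), s$b2)), use.names = FALSE)
  if (!is.null(model$logV)) th <- c(th, model$logV)
  th
}

unpack_theta <- function(model, theta) {
  off <- 0L
  for (nm in names(model$nets)) {
    s <- model$nets[[nm]]
    n1 <- s$n_hid * s$n_in
    s$W1 <- matrix(theta[off + seq_len(n1)], s$n_hid, s$n_in); off <- off + n1
    s$b1 <- theta[off + seq_len(s$n_hid)]; off <- off + s$n_hid
    s$W2 <- matrix(theta[off + seq_len(s$n_hid)], s$n_out, s$n_hid); off <- off + s$n_hid
    s$b2 <- theta[off + 1L]; off <- off + 1L
    model$nets[[nm]] <- s
  }
  if (!is.null(model$logV)) { model$logV <- theta[off + 1L]; off <- off + 1L }
  stopifnot(off == length(theta))
  model
}

# integration grid for one group: all observation times, the infusion stop
# time, and a regular fill so no RK4 step exceeds h_max
engine_group <- function(model, regimen, obs_time, obs_conc, h_max) {
  anchors <- sort(unique(c(0, obs_time)))
  if (model$structure == "infusion") anchors <- sort(unique(c(anchors, regimen$tinf)))
  grid <- unlist(lapply(seq_len(length(anchors) - 1L), function(i) {
    a <- anchors[i]; b <- anchors[i + 1L]
    n <- max(1L, ceiling((b - a) / h_max))
    seq(a, b, length.out = n + 1L)[-1L]
  }))
  grid <- c(0, grid)
  list(d = regimen$d,
       kin = if (is.na(regimen$kin)) 0 else regimen$kin,
       tinf = if (is.na(regimen$tinf)) 0 else regimen$tinf,
       grid = grid,
       obs_node = match(obs_time, grid) - 1L, # 0-based for the engine
       obs_val = obs_conc)
}

engine_groups <- function(model, data, h_max) {
  gs <- unique(data$group_id)
  regs <- dataset_regimens(data)
  lapply(seq_along(gs), function(i) {
    sub <- data[data$group_id == gs[i], ]
    engine_group(model, regs[[i]], sub$time, sub$conc, h_max)
  })
}

# ---- checkpoint serialization ---------------------------------------------

node_to_list <- function(model, metadata = list()) {
  list(structure = model$structure,
       n_hid = model$n_hid,
       nets = lapply(model$nets, mlp_to_list),
       logV = model$logV,
       mech_params = model$mech_params,
       metadata = metadata)
}

#' Read or write a NODE model checkpoint as JSON
#'
#' Self-describing JSON (structure, network weights, \eqn{\log V}, fixed
#' mechanistic constants, free-form metadata); numbers are written at full
#' precision so round trips are bit-faithful for finite doubles.
#'
#' @param model a \code{\link{node_model}} (or \code{node_fit}; its model
#'   is saved).
#' @param path file path (conventionally \code{*.node.json}).
#' @param metadata optional list stored alongside the weights.
#' @return \code{read_node_json} returns a \code{\link{node_model}};
#'   \code{write_node_json} returns \code{path} invisibly.
#' @export
write_node_json <- function(model, path, metadata = list()) {
  if (inherits(model, "node_fit")) {
    metadata <- c(metadata, list(seed = model$seed,
                                 final_loss = model$final_loss,
                                 best_epoch = model$best_epoch))
    model <- model$model
  }
  stopifnot(inherits(model, "node_model"))
  jsonlite::write_json(node_to_list(model, metadata), path, digits = I(17),
                       auto_unbox = TRUE, matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_node_json
#' @export
read_node_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # restore matrix shapes lost in the JSON round trip
  nets <- lapply(names(x$nets), function(nm) {
    s <- x$nets[[nm]]
    mlp_spec(as.integer(s$n_in), as.integer(s$n_hid), as.integer(s$n_out),
             W1 = matrix(as.numeric(if (is.matrix(s$W1)) s$W1 else unlist(s$W1)),
                         as.integer(s$n_hid), as.integer(s$n_in)),
             b1 = as.numeric(unlist(s$b1)),
             W2 = matrix(as.numeric(unlist(s$W2)), as.integer(s$n_out),
                         as.integer(s$n_hid), byrow = TRUE),
             b2 = as.numeric(unlist(s$b2)),
             act_hidden = s$act_hidden, act_out = s$act_out,
             restrict_input_weights = isTRUE(s$restrict_input_weights))
  })
  names(nets) <- names(x$nets)
  mech <- as.list(x$mech_params)
  model <- node_model(x$structure, n_hid = as.integer(x$n_hid),
                      mech_params = mech,
                      V = if (is.null(x$logV)) NULL else exp(as.numeric(x$logV)),
                      nets = nets)
  attr(model, "metadata") <- x$metadata
  model
}
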