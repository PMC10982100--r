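# independent oracles used to freeze expected values

# summation-form evaluation of a 1-in/1-out ReLU/identity network,
# term by term
mlp_summation_oracle <- function(spec, x) {
  w1 <- if (spec$restrict_input_weights) -(spec$W1^2) else spec$W1
  out <- spec$b2
  for (i in seq_len(spec$n_hid))
    out <- out + spec$W2[1, i] * max(0, w1[i, 1] * x + spec$b1[i])
  out
}

# fixed-step classical RK4 integrator, independent of the package's solvers
rk4_oracle <- function(rhs, y0, times, h = 1e-3) {
  out <- matrix(NA_real_, length(times), length(y0))
  out[1, ] <- y <- y0
  for (k in seq_len(length(times) - 1L)) {
    t0 <- times[k]; t1 <- times[k + 1L]
    n <- max(1L, ceiling((t1 - t0) / h))
    hh <- (t1 - t0) / n
    t <- t0
    for (s in seq_len(n)) {
      k1 <- rhs(y, t)
      k2 <- rhs(y + hh / 2 * k1, t + hh / 2)
      k3 <- rhs(y + hh / 2 * k2, t + hh / 2)
      k4 <- rhs(y + hh * k3, t + hh)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    out[k + 1L, ] <- y
  }
  out
}

# closed-form one-compartment IV bolus concentration
onecomp_closed_form <- function(t, kel, V, d) (d / V) * exp(-kel * t)

# closed-form one-compartment constant-rate infusion concentration
infusion_closed_form <- function(t, kel, V, kin, tinf) {
  css <- kin / (V * kel)
  ifelse(t <= tinf,
         css * (1 - exp(-kel * t)),
         css * (1 - exp(-kel * tinf)) * exp(-kel * (t - tinf)))
}

random_mlp <- function(n_hid = 5L, n_in = 1L, restrict = FALSE) {
  mlp_spec(n_in, n_hid, 1L,
           W1 = matrix(stats::runif(n_hid * n_in, -1, 1), n_hid, n_in),
           b1 = stats::runif(n_hid, -1, 1),
           W2 = matrix(stats::runif(n_hid, -1, 1), 1, n_hid),
           b2 = stats::runif(1, -1, 1),
           restrict_input_weights = restrict)
}
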