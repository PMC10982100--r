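# neuralpk

Low-dimensional neural ordinary differential equations (NODEs) for
single-dose pharmacokinetics, for pharmacometricians and
scientific-ML practitioners who want to fit concentration–time data
without committing to a compartmental mechanism — and to know exactly
what such a model has and has not learned.

A NODE replaces the right-hand side of a PK model with a small
trainable network. `neuralpk` implements the PK-principled,
low-dimensional form in which the reduced one-dimensional system is
non-autonomous and the concentration- and time-dependence live in
separate one-hidden-layer ReLU networks:

    dx_C/dt = f_C1(x_C) + (d/V) · f_C2(t),   x_C(0) = d/V

with the time network's input weights restricted to w' = −(w²) ≤ 0 so
its output settles at a constant after a finite onset and the
time-dependence vanishes, as it must once absorption and distribution
are over. Variants add a learned absorption compartment, an explicit
zero-order infusion input `(k_in/V)·1(t ≤ t_inf)`, or hybrid
scientific-ML structures with a known elimination rate `k_el` or a
known absorption rate `k_a`. Training is pooled full-batch Adam with a
cyclic learning rate; gradients are backpropagated exactly through a
Runge–Kutta discretization by the compiled engine in `src/`.

The package also ships the mechanistic ground-truth models used to
generate data and judge the NODEs — one/two-compartment IV bolus, oral
absorption with 0/4/8 transit compartments, IV infusion, and
target-mediated drug disposition (TMDD) — plus the diagnostics that
make the evaluation quantitative: derivative-versus-state profiles,
unseen-dose simulation error against the oracle, and
interpolation/extrapolation reports.

## Worked example

Fit the general NODE to pooled two-compartment IV data (two dose
groups, 5 time points × 8 replicates each, 10% proportional error) and
simulate an unseen intermediate dose:

```r
library(neuralpk)

sc  <- make_scenario("twocomp_iv", seed = 1)   # doses 1 and 10, kel=0.1, V=2, k12=k21=0.2
fit <- node_fit(sc, seed = 1)                  # separated structure, n_hid = 20
fit
#> PK neural ODE fit (structure 'separated', 123 trainable parameters)
#>   scenario: twocomp_iv
#>   data: 80 observations in 2 dose group(s)
#>   pooled MSE after 12000 epochs: 1.821e-02 (best at epoch 12000)
#>   estimated V: 2.169

interpolation_report(fit, sc$oracle, sc$tests, horizon = sc$horizon)
#>   regimen dose   rel_rmse max_abs_err negative within_tol
#> 1     d=5    5 0.05936542   0.1275428    FALSE       TRUE
```

The pooled MSE (1.8e-02) sits at the data's noise floor, the estimated
volume of distribution is close to the generating value 2, and the
simulation for the unseen dose d = 5 deviates from the ground-truth
model by about 6% of its mean concentration — the NODE has learned the
two-compartment mechanism well enough to interpolate between its
training doses. `plot(fit, oracle = sc$oracle)` shows the fit and the
derivative-versus-state diagnostic; `summary()`, `coef()`,
`predict()`, `residuals()` and `simulate()` behave as for any fitted
R model.

The overfitting contrast from the same machinery: on a single-replicate
5-point dataset the 123-parameter NODE drives its training MSE to
~1e-25 (far below the noise floor), while the classical two-parameter
refit plateaus at 5.5e-4 — the noise variance:

```r
sc1 <- make_scenario("overfit_onecomp", seed = 1)
node_fit(sc1, seed = 1)$final_loss     # ~3.6e-25
fit_onecomp_iv(sc1$data)$mse           # ~5.5e-4
```

A command-line interface wrapping the same functions is installed at
`system.file("cli", "neuralpk.R", package = "neuralpk")` with
subcommands `simulate-data`, `train`, `predict`, `derivative-state`,
`evaluate`, and `run-experiment`.

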