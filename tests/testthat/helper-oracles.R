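# Shared oracles and fixture builders (everything generated in code).

# Independent stiff-ODE oracle for the depot + two-compartment system.
ode_oracle <- function(p, dose, route, times, events = NULL) {
  mc <- micro_constants(p)
  ka <- if (route == "iv") 0 else p$ka[[route]]
  f <- if (route == "iv") 1 else p$f[[route]]
  rhs <- function(t, y, parms) {
    dA0 <- -ka * y[1]
    dA1 <- ka * y[1] - (mc$k10 + mc$k12) * y[2] + mc$k21 * y[3]
    dA2 <- mc$k12 * y[2] - mc$k21 * y[3]
    list(c(dA0, dA1, dA2))
  }
  if (is.null(events)) {
    yini <- if (route == "iv") c(A0 = 0, A1 = dose, A2 = 0)
      else c(A0 = f * dose, A1 = 0, A2 = 0)
    out <- deSolve::ode(yini, c(0, times), rhs, NULL, method = "lsoda",
                        rtol = 1e-12, atol = 1e-14)
    return(out[-1, "A1"] / p$v1)
  }
  amt <- if (route == "iv") events$amount else f * events$amount
  evd <- data.frame(var = if (route == "iv") "A1" else "A0",
                    time = events$time, value = amt, method = "add")
  tt <- sort(unique(c(0, times, events$time)))
  out <- deSolve::ode(c(A0 = 0, A1 = 0, A2 = 0), tt, rhs, NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-14,
                      events = list(data = evd))
  out[match(times, out[, 1]), "A1"] / p$v1
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# log-spaced quadrature grid: resolves the fast distribution phase near
# t = 0 and reaches far into the terminal phase
auc_grid <- function(p, n = 20000) {
  c(0, 10^seq(-6, log10(100 * terminal_half_life(p)), length.out = n))
}

random_params <- function(with_oral = TRUE) {
  structural_params(
    cl = runif(1, 0.01, 1), v1 = runif(1, 0.1, 1.5),
    q = runif(1, 0.05, 2), v2 = runif(1, 0.05, 1.5),
    ka = if (with_oral) c(oral = runif(1, 0.2, 3)),
    f = if (with_oral) c(oral = runif(1, 0.3, 1)))
}

# The published SDZ model without random effects, for deterministic fits.
sdz_model_novar <- function(a = 0.02) {
  population_model("SDZ", fixed = c(cl = 0.12, v1 = 0.3, q = 0.32, v2 = 0.29),
                   ka = c(oral = 0.5), f = c(oral = 0.93), resid_a = a)
}
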