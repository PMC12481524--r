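test_that("micro-constants reproduce direct ratios and the Vieta identities", {
  p <- structural_params(cl = 0.12, v1 = 0.3, q = 0.32, v2 = 0.29)
  mc <- micro_constants(p)
  expect_equal(mc$k10, 0.40)
  expect_equal(mc$k12, 0.32 / 0.3)
  expect_equal(mc$k21, 0.32 / 0.29)
  expect_gt(mc$alpha, mc$beta)
  # Vieta identities for the disposition quadratic
  set.seed(41)
  for (r in 1:50) {
    mc <- micro_constants(random_params(FALSE))
    expect_equal(mc$alpha * mc$beta, mc$k10 * mc$k21, tolerance = 1e-12)
    expect_equal(mc$alpha + mc$beta, mc$k10 + mc$k12 + mc$k21,
                 tolerance = 1e-12)
  }
})

test_that("one-compartment collapse: q = 0 gives alpha = k10, beta = 0", {
  p <- structural_params(cl = 0.2, v1 = 0.5)
  mc <- micro_constants(p)
  expect_equal(mc$alpha, 0.4)
  expect_equal(mc$beta, 0)
  expect_equal(terminal_half_life(structural_params(cl = 0.693, v1 = 1)),
               1, tolerance = 1e-3)
})

test_that("invalid structural parameters are rejected", {
  expect_error(structural_params(cl = -1, v1 = 0.3), "positive")
  expect_error(structural_params(cl = 0.1, v1 = 0.3, q = 0.2, v2 = 0),
               "two-compartment")
  expect_error(structural_params(cl = 0.1, v1 = 0.3, f = c(oral = 1.2)),
               "0, 1")
  p <- structural_params(cl = 0.1, v1 = 0.3)
  expect_error(conc_iv_bolus(p, 10, c(-1, 0)), "negative")
})

test_that("IV bolus: C(0) = dose/V1 and AUC identity dose/CL", {
  set.seed(42)
  for (r in 1:25) {
    p <- random_params(FALSE)
    expect_equal(conc_iv_bolus(p, 7, 0), 7 / p$v1)
    tt <- auc_grid(p)
    expect_equal(trapz(tt, conc_iv_bolus(p, 7, tt)), auc_inf(p, 7),
                 tolerance = 1e-4)
  }
})

test_that("extravascular: C(0) = 0 and bioavailable AUC identity", {
  set.seed(43)
  for (r in 1:25) {
    p <- random_params()
    expect_equal(conc_extravascular(p, 20, "oral", 0), 0)
    tt <- auc_grid(p)
    expect_equal(trapz(tt, conc_extravascular(p, 20, "oral", tt)),
                 auc_inf(p, 20, "oral"), tolerance = 1e-4)
  }
})

test_that("closed forms agree with the stiff ODE oracle to 1e-8", {
  skip_if_not_installed("deSolve")
  set.seed(44)
  tt <- c(0.1, 1, 10)
  for (r in 1:100) {
    p <- random_params()
    expect_equal(conc_iv_bolus(p, 10, tt), ode_oracle(p, 10, "iv", tt),
                 tolerance = 1e-8)
    expect_equal(conc_extravascular(p, 10, "oral", tt),
                 ode_oracle(p, 10, "oral", tt), tolerance = 1e-8)
  }
})

test_that("absorption pole: ka equal to a disposition exponent is the
          analytic limit of nearby ka", {
  p0 <- structural_params(cl = 0.12, v1 = 0.3, q = 0.32, v2 = 0.29)
  mc <- micro_constants(p0)
  tt <- c(0.5, 2, 8, 24)
  for (lam in c(mc$alpha, mc$beta)) {
    at_pole <- structural_params(cl = 0.12, v1 = 0.3, q = 0.32, v2 = 0.29,
                                 ka = c(oral = lam), f = c(oral = 0.9))
    near <- structural_params(cl = 0.12, v1 = 0.3, q = 0.32, v2 = 0.29,
                              ka = c(oral = lam * (1 + 1e-5)),
                              f = c(oral = 0.9))
    expect_equal(conc_extravascular(at_pole, 10, "oral", tt),
                 conc_extravascular(near, 10, "oral", tt),
                 tolerance = 1e-3)
  }
  # one-compartment Bateman pole
  p1 <- structural_params(cl = 0.3, v1 = 1, ka = c(oral = 0.3),
                          f = c(oral = 1))
  expect_equal(conc_extravascular(p1, 10, "oral", 2), 10 * 0.3 * 2 * exp(-0.6),
               tolerance = 1e-10)
})

test_that("terminal log-linear slope recovers beta within 1%", {
  set.seed(45)
  for (r in 1:20) {
    p <- random_params(FALSE)
    mc <- micro_constants(p)
    th <- terminal_half_life(p)
    tt <- seq(5 * th, 8 * th, length.out = 30)
    sl <- coef(lm(log(conc_iv_bolus(p, 5, tt)) ~ tt))[[2]]
    expect_equal(-sl, mc$beta, tolerance = 0.01)
  }
})

test_that("two-compartment IV solution approaches the one-compartment
          limit as q tends to zero", {
  tt <- c(0.5, 2, 8)
  one <- structural_params(cl = 0.2, v1 = 0.5)
  for (q in c(1e-4, 1e-6, 1e-8)) {
    two <- structural_params(cl = 0.2, v1 = 0.5, q = q, v2 = 0.3)
    expect_equal(conc_iv_bolus(two, 10, tt), conc_iv_bolus(one, 10, tt),
                 tolerance = 10 * q)
  }
})

test_that("superposition is exact for multiple dosing", {
  skip_if_not_installed("deSolve")
  p <- structural_params(cl = 0.12, v1 = 0.3, q = 0.32, v2 = 0.29,
                         ka = c(oral = 0.5), f = c(oral = 0.93))
  ev <- data.frame(time = c(0, 12, 24), amount = 25, route = "oral")
  tt <- c(1, 6, 13, 20, 30, 48)
  expect_equal(superpose(p, ev, tt), ode_oracle(p, NA, "oral", tt, ev),
               tolerance = 1e-6)
  # single event equals the single-dose solution; simultaneous events add
  ev1 <- data.frame(time = 0, amount = 25, route = "oral")
  expect_equal(superpose(p, ev1, tt), conc_extravascular(p, 25, "oral", tt))
  ev2 <- data.frame(time = c(0, 0), amount = 25, route = "oral")
  expect_equal(superpose(p, ev2, tt),
               2 * conc_extravascular(p, 25, "oral", tt))
})

test_that("repeated daily dosing of a long half-life drug accumulates", {
  p <- typical_params(pig_population_models()$SDMX, 31.1)
  ev <- data.frame(time = seq(0, 96, by = 24), amount = 37.36,
                   route = "oral")
  troughs <- superpose(p, ev, c(24, 120))
  expect_gt(troughs[2], troughs[1])
  # growth consistent with the closed-form accumulation factor
  beta <- micro_constants(p)$beta
  expect_equal(troughs[2] / troughs[1], 1 / (1 - exp(-beta * 24)),
               tolerance = 0.05)
})

test_that("zero-order infusion tends to the bolus solution as duration
          shrinks and conserves AUC", {
  p <- structural_params(cl = 0.2, v1 = 0.5, q = 0.4, v2 = 0.6)
  tt <- c(0.5, 2, 8)
  expect_equal(conc_iv_bolus(p, 10, tt, tinf = 1e-6),
               conc_iv_bolus(p, 10, tt), tolerance = 1e-4)
  grid <- seq(0, 400, by = 0.01)
  expect_equal(trapz(grid, conc_iv_bolus(p, 10, grid, tinf = 0.5)),
               auc_inf(p, 10), tolerance = 1e-3)
})
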