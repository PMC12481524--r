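pops <- pig_population_models()

test_that("censored likelihood terms match their closed forms and a
          quadrature oracle", {
  p <- structural_params(cl = 0.12, v1 = 0.3, q = 0.32, v2 = 0.29)
  # one observed point exactly at the prediction, a = 1
  pred <- conc_iv_bolus(p, 12.5, 2)
  d <- data.frame(ID = 1, OCC = 1, TIME = c(0, 2), AMT = c(12.5, NA),
                  EVID = c(1L, 0L), ANALYTE = "SDZ",
                  DV = c(NA, pred), CENS = "none",
                  LLOQ = 0.1, LOD = 0.05, ROUTE = "iv", BW = 31.1)
  expect_equal(individual_loglik(d, p, a = 1), log(1 / sqrt(2 * pi)))
  # interval-censored row: normal mass between the log bounds
  a <- 0.3
  lod <- 0.05; loq <- 0.1
  tcen <- 30
  lpred <- log(conc_iv_bolus(p, 12.5, tcen))
  dc <- d
  dc$TIME[2] <- tcen
  dc$DV[2] <- loq
  dc$CENS[2] <- "interval"
  quad <- integrate(function(x) dnorm(x, lpred, a), log(lod), log(loq),
                    rel.tol = 1e-12)$value
  expect_equal(individual_loglik(dc, p, a), log(quad), tolerance = 1e-10)
  # left-censored row
  dl <- dc
  dl$CENS[2] <- "left"
  dl$DV[2] <- lod
  expect_equal(individual_loglik(dl, p, a),
               pnorm((log(lod) - lpred) / a, log.p = TRUE))
  # a censored row can never be more likely than the same density mass
  # spread over the interval
  expect_lte(individual_loglik(dc, p, a),
             log(dnorm(log(sqrt(lod * loq)), lpred, a) * log(loq / lod)) +
               1e-8)
})

test_that("likelihood flattens as the residual SD grows", {
  p <- structural_params(cl = 0.12, v1 = 0.3, q = 0.32, v2 = 0.29)
  d <- data.frame(ID = 1, OCC = 1, TIME = c(0, 1, 4, 12),
                  AMT = c(12.5, NA, NA, NA), EVID = c(1L, 0L, 0L, 0L),
                  ANALYTE = "SDZ", DV = c(NA, 30, 18, 5), CENS = "none",
                  LLOQ = 0.1, LOD = 0.05, ROUTE = "iv", BW = 31.1)
  p2 <- structural_params(cl = 0.2, v1 = 0.4, q = 0.32, v2 = 0.29)
  gap <- vapply(c(0.3, 3, 30), function(a)
    abs(individual_loglik(d, p, a) - individual_loglik(d, p2, a)),
    numeric(1))
  expect_true(all(diff(gap) < 0))
})

test_that("likelihood is invariant to a time-unit rescaling with
          correspondingly rescaled rate parameters", {
  p_h <- structural_params(cl = 0.12, v1 = 0.3, q = 0.32, v2 = 0.29,
                           ka = c(oral = 0.5), f = c(oral = 0.93))
  p_min <- structural_params(cl = 0.12 / 60, v1 = 0.3, q = 0.32 / 60,
                             v2 = 0.29, ka = c(oral = 0.5 / 60),
                             f = c(oral = 0.93))
  d_h <- data.frame(ID = 1, OCC = 1, TIME = c(0, 1, 6, 24),
                    AMT = c(25, NA, NA, NA), EVID = c(1L, 0L, 0L, 0L),
                    ANALYTE = "SDZ", DV = c(NA, 8, 12, 3), CENS = "none",
                    LLOQ = 0.1, LOD = 0.05, ROUTE = "oral", BW = 31.1)
  d_min <- d_h
  d_min$TIME <- d_h$TIME * 60
  expect_equal(individual_loglik(d_h, p_h, 0.3),
               individual_loglik(d_min, p_min, 0.3), tolerance = 1e-10)
})

test_that("deterministic curve fit: no-variability data recovers the
          fixed effects within about 1%", {
  pop0 <- sdz_model_novar(0.02)
  des <- study_design("TMP/SDZ", n_pigs = 6)
  d <- generate_study(des, list(SDZ = pop0, TMP = pops$TMP), seed = 7)
  fit <- fit_population(d, "SDZ", n_cpt = 2, variability = c(cl = "none"),
                        control = saem_control(n_explore = 200,
                                               n_smooth = 100),
                        seed = 2, compute_loglik = FALSE)
  co <- coef(fit)
  truth <- c(cl = 0.12, v1 = 0.3, q = 0.32, v2 = 0.29, ka_oral = 0.5,
             f_oral = 0.93)
  expect_equal(unname(co[names(truth)]), unname(truth), tolerance = 0.015)
  expect_equal(unname(co["a"]), 0.02, tolerance = 0.25)
})

test_that("BICc penalty matches its formula and is monotone in model
          size at equal likelihood", {
  d <- generate_study(study_design("TMP/SDZ", n_pigs = 4), pops, seed = 8)
  ctl <- saem_control(n_explore = 60, n_smooth = 30)
  fit <- suppressWarnings(fit_population(d, "SDZ", n_cpt = 2, control = ctl,
                                         seed = 9))
  # hand computation: random-effect block penalized by log(N), fixed
  # block (Q, F_oral, a) by log(n_obs)
  k_random <- 4 + 4  # mu of cl, v1, v2, ka + their 4 variances
  k_fixed <- 2 + 1   # Q and F_oral + residual a
  expect_equal(fit$bicc,
               -2 * fit$loglik + k_random * log(fit$n_subjects) +
                 k_fixed * log(fit$n_obs))
  # a nested model with one extra parameter at identical likelihood has
  # a strictly larger BICc
  fit_big <- fit
  fit_big$theta$estimate_beta_bw <- "cl"
  expect_equal(bicc(fit_big), fit$bicc + log(fit$n_subjects))
})

test_that("bootstrap over identical pigs yields zero standard errors", {
  pop0 <- sdz_model_novar(0.1)
  des <- study_design("TMP/SDZ", n_pigs = 1)
  d1 <- generate_study(des, list(SDZ = pop0, TMP = pops$TMP), seed = 10)
  d2 <- d1[d1$ID == 1, ]
  d2$ID <- 2
  d <- rbind(d1, d2)  # two byte-identical pigs
  bs <- bootstrap_se(d, "SDZ", n_runs = 2, seed = 11,
                     variability = c(cl = "none"),
                     control = saem_control(n_explore = 40, n_smooth = 20))
  expect_true(all(bs$se < 1e-10))
  expect_equal(attr(bs, "n_dropped"), 0)
})
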