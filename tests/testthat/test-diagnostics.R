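pops <- pig_population_models()

test_that("IWRES are standardized residuals around the individual
          prediction", {
  pop0 <- sdz_model_novar(0.3)
  des <- study_design("TMP/SDZ", n_pigs = 40)
  d <- generate_study(des, list(SDZ = pop0, TMP = pops$TMP), seed = 50)
  # with no variability the true EBEs are the typical parameters
  eb <- expand.grid(ID = 1:40, OCC = 1:2)
  eb <- cbind(eb, cl = 0.12, v1 = 0.3, q = 0.32, v2 = 0.29, ka = 0.5,
              f = 0.93)
  iw <- iwres(d, "SDZ", eb, a = 0.3)
  expect_equal(mean(iw$iwres), 0, tolerance = 0.05)
  expect_equal(sd(iw$iwres), 1, tolerance = 0.05)
  expect_gt(attr(iw, "n_censored_excluded"), 0)
  # doubling a halves the residuals
  iw2 <- iwres(d, "SDZ", eb, a = 0.6)
  expect_equal(iw2$iwres, iw$iwres / 2)
  # a DV equal to its prediction gives exactly zero
  row1 <- d[d$ANALYTE == "SDZ" & d$EVID == 0 & d$CENS == "none", ][1, ]
  d0 <- d
  i <- which(d0$ANALYTE == "SDZ" & d0$EVID == 0 & d0$CENS == "none")[1]
  d0$DV[i] <- d0$TRUE_CONC[i]
  iw0 <- iwres(d0, "SDZ", eb, a = 0.3)
  expect_equal(iw0$iwres[1], 0, tolerance = 1e-12)
})

test_that("PWRES under the true model are approximately standard normal", {
  d <- generate_study(study_design("TMP/SDZ", n_pigs = 12), pops, seed = 51)
  pw <- pwres(d, "SDZ", pops$SDZ, K = 1000, seed = 52)
  expect_equal(mean(pw$pwres), 0, tolerance = 0.1)
  expect_equal(var(pw$pwres), 1, tolerance = 0.1)
  expect_error(pwres(d, "SDZ", pops$SDZ, K = 50), "at least 100")
  # deterministic given the seed
  pw2 <- pwres(d, "SDZ", pops$SDZ, K = 1000, seed = 52)
  expect_identical(pw, pw2)
})

test_that("NPDE are calibrated under the true model and detect a
          twofold clearance misspecification", {
  d <- generate_study(study_design("TMP/SDZ", n_pigs = 12), pops, seed = 53)
  nn <- npde(d, "SDZ", pops$SDZ, K = 500, seed = 54)
  ks <- attr(nn, "ks")
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(nn$npde), 0, tolerance = 0.15)
  pop_bad <- pops$SDZ
  pop_bad$fixed["cl"] <- pop_bad$fixed["cl"] * 2
  nb <- npde(d, "SDZ", pop_bad, K = 500, seed = 54)
  expect_lt(attr(nb, "ks")$p.value, 1e-4)
  expect_gt(mean(nb$npde), 0.3)  # under-predicted concentrations
})

test_that("a lone observation at the median rank maps to an NPDE of
          about zero", {
  # one pig, one uncensored observation: its decorrelated rank among the
  # replicates is near K/2 under the true model
  pop0 <- sdz_model_novar(0.2)
  d <- data.frame(ID = 1, OCC = 1, TIME = c(0, 4), AMT = c(12.5, NA),
                  EVID = c(1L, 0L), ANALYTE = "SDZ",
                  DV = c(NA, conc_iv_bolus(typical_params(pop0, 31.1),
                                           12.5, 4)),
                  TRUE_CONC = NA, CENS = "none", LLOQ = 1e-6, LOD = 5e-7,
                  ROUTE = "iv", BW = 31.1, OUTLIER = FALSE)
  nn <- npde(d, "SDZ", pop0, K = 2000, seed = 55)
  expect_equal(nn$npde, 0, tolerance = 0.1)
})

test_that("pcVPC: identical typical predictions make the correction the
          identity, and output is seed-deterministic", {
  d <- generate_study(study_design("TMP/SDZ", n_pigs = 8), pops, seed = 56)
  v1 <- pcvpc(d, "SDZ", pops$SDZ, K = 150, n_bins = 5, seed = 57)
  v2 <- pcvpc(d, "SDZ", pops$SDZ, K = 150, n_bins = 5, seed = 57)
  expect_identical(v1, v2)
  # one shared sampling time and bodyweight: every row has the same
  # typical prediction, so prediction correction changes nothing
  n <- 10
  set.seed(58)
  pred <- conc_iv_bolus(typical_params(pops$SDZ, 31.1), 12.5, 2)
  dd <- data.frame(ID = rep(1:n, each = 2),
                   OCC = 1, TIME = rep(c(0, 2), n),
                   AMT = rep(c(12.5, NA), n), EVID = rep(c(1L, 0L), n),
                   ANALYTE = "SDZ",
                   DV = as.numeric(rbind(NA, pred * exp(rnorm(n, 0, 0.3)))),
                   TRUE_CONC = NA, CENS = "none", LLOQ = 1e-6, LOD = 5e-7,
                   ROUTE = "iv", BW = 31.1, OUTLIER = FALSE)
  v <- pcvpc(dd, "SDZ", pops$SDZ, K = 150, n_bins = 1, seed = 59)
  # percentiles are computed on the log scale, where the correction acts
  lobs <- log(dd$DV[dd$EVID == 0])
  expect_equal(log(v$observed[v$pct == 50]), median(lobs),
               tolerance = 1e-10)
  expect_equal(log(v$observed[v$pct == 10]),
               unname(quantile(lobs, 0.1)), tolerance = 1e-10)
})

test_that("pcVPC envelopes cover the empirical percentiles under the
          true model and break under misspecification", {
  d <- generate_study(study_design("TMP/SDZ", n_pigs = 12), pops, seed = 58)
  v <- pcvpc(d, "SDZ", pops$SDZ, K = 300, seed = 59)
  cover <- mean(v$observed >= v$env_lo & v$observed <= v$env_hi)
  expect_gte(cover, 0.8)
  pop_bad <- pops$SDZ
  pop_bad$fixed["cl"] <- pop_bad$fixed["cl"] * 2
  vb <- pcvpc(d, "SDZ", pop_bad, K = 300, seed = 59)
  expect_lt(mean(vb$observed >= vb$env_lo & vb$observed <= vb$env_hi),
            0.5)
})
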