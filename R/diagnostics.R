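# Simulation-based model evaluation: IWRES, PWRES, NPDE and
# prediction-corrected VPC. All residuals are computed on the log
# concentration scale, consistent with the log-additive constant error
# model.

# Collect one analyte's observation rows and their dosing context.
diag_prep <- function(dataset, analyte) {
  d <- dataset[dataset$ANALYTE == analyte, , drop = FALSE]
  if (!nrow(d)) stop("no rows for analyte '", analyte, "'", call. = FALSE)
  if ("OUTLIER" %in% names(d)) d <- filter_outliers(d)
  obs <- d[d$EVID == 0L, , drop = FALSE]
  obs$row <- seq_len(nrow(obs))
  occs <- list()
  for (id in unique(d$ID)) for (k in unique(d$OCC[d$ID == id])) {
    ev <- d[d$ID == id & d$OCC == k & d$EVID == 1L, ]
    ob <- obs[obs$ID == id & obs$OCC == k, ]
    if (!nrow(ev) || !nrow(ob)) next
    occs[[length(occs) + 1L]] <- list(
      id = id, occ = k, bw = ob$BW[1L], route = as.character(ev$ROUTE[1L]),
      events = data.frame(time = ev$TIME, amount = ev$AMT, route = ev$ROUTE),
      t_obs = ob$TIME, rows = ob$row)
  }
  list(obs = obs, occs = occs)
}

# K replicate datasets simulated under `pop` at the observed design:
# matrix of log concentrations (n_obs x K), plus per-row typical
# (fixed-effect) log predictions.
simulate_replicates <- function(prep, pop, K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(prep$obs)
  lsim <- matrix(NA_real_, n, K)
  ltyp <- numeric(n)
  for (occ in prep$occs) {
    tp <- typical_params(pop, occ$bw)
    ltyp[occ$rows] <- log(pmax(superpose(tp, occ$events, occ$t_obs), 1e-300))
  }
  for (r in seq_len(K)) {
    for (occ in prep$occs) {
      ind <- draw_individual(pop, occ$bw)
      conc <- superpose(ind$params_by_occasion[[1L]], occ$events, occ$t_obs)
      lsim[occ$rows, r] <- log(pmax(conc, 1e-300)) +
        stats::rnorm(length(occ$rows), 0, pop$resid_a)
    }
  }
  list(lsim = lsim, ltyp = ltyp)
}

#' Individual weighted residuals
#'
#' `(log DV - log individual prediction) / a` for uncensored observation
#' rows, using per pig-occasion empirical Bayes parameter estimates.
#' Censored rows are excluded; their count is reported in the
#' `n_censored_excluded` attribute.
#'
#' @param dataset a PK dataset.
#' @param analyte analyte name.
#' @param ebes empirical Bayes estimates, a data.frame with columns `ID`,
#'   `OCC`, `cl`, `v1`, `q`, `v2`, `ka`, `f` (as in `popfit$ebes`).
#' @param a residual SD on the log scale.
#' @return data.frame `ID`, `OCC`, `TIME`, `ROUTE`, `iwres`.
#' @export
iwres <- function(dataset, analyte, ebes, a) {
  prep <- diag_prep(dataset, analyte)
  obs <- prep$obs
  res <- rep(NA_real_, nrow(obs))
  for (occ in prep$occs) {
    e <- ebes[ebes$ID == occ$id & ebes$OCC == occ$occ, ]
    if (!nrow(e)) next
    conc <- .conc_events(e$cl[1], e$v1[1], e$q[1], e$v2[1],
                         if (is.na(e$ka[1])) 0 else e$ka[1], e$f[1],
                         occ$route, occ$events$time, occ$events$amount,
                         occ$t_obs)
    res[occ$rows] <- (log(obs$DV[occ$rows]) - log(pmax(conc, 1e-300))) / a
  }
  keep <- obs$CENS == "none" & !is.na(res)
  out <- data.frame(ID = obs$ID[keep], OCC = obs$OCC[keep],
                    TIME = obs$TIME[keep], ROUTE = obs$ROUTE[keep],
                    iwres = res[keep])
  attr(out, "n_censored_excluded") <- sum(obs$CENS != "none")
  out
}

#' Population weighted residuals (simulation-based)
#'
#' Per pig, centers the observed log concentrations on the mean of `K`
#' model-simulated replicates and decorrelates with the Cholesky factor
#' of the empirical between-replicate covariance (Monte-Carlo population
#' moments). Under a correct model the residuals are approximately
#' standard normal. Censored rows are excluded.
#'
#' @param dataset a PK dataset.
#' @param analyte analyte name.
#' @param pop the [population_model()] to evaluate.
#' @param K number of simulation replicates (>= 100).
#' @param seed integer seed.
#' @return data.frame `ID`, `OCC`, `TIME`, `ROUTE`, `pwres`.
#' @export
pwres <- function(dataset, analyte, pop, K = 500, seed = NULL) {
  if (K < 100) stop("'K' must be at least 100", call. = FALSE)
  dec <- decorrelated_residuals(dataset, analyte, pop, K, seed)
  out <- dec$obs_meta
  out$pwres <- dec$ystar
  out
}

#' Normalized prediction distribution errors
#'
#' Per pig, observed and simulated log-concentration vectors are
#' decorrelated with the empirical simulation covariance (Cholesky
#' square root); each observation's exceedance rank among its `K`
#' decorrelated replicates is mapped through the inverse standard normal
#' CDF with a `1/(2K)` continuity correction at the extremes. Under the
#' true model the NPDE are standard normal; a Kolmogorov-Smirnov test
#' against N(0,1) is reported.
#'
#' @inheritParams pwres
#' @param K number of simulation replicates (500 recommended).
#' @return data.frame `ID`, `OCC`, `TIME`, `ROUTE`, `npde`, with the
#'   KS test as attribute `"ks"`.
#' @export
npde <- function(dataset, analyte, pop, K = 500, seed = NULL) {
  dec <- decorrelated_residuals(dataset, analyte, pop, K, seed,
                                decorrelate_sims = TRUE)
  pde <- (dec$rank_count) / K
  pde[pde <= 0] <- 1 / (2 * K)
  pde[pde >= 1] <- 1 - 1 / (2 * K)
  out <- dec$obs_meta
  out$npde <- stats::qnorm(pde)
  attr(out, "ks") <- suppressWarnings(stats::ks.test(out$npde, "pnorm"))
  out
}

# Shared machinery: per-pig mean/covariance of simulated log
# concentrations, Cholesky decorrelation of observations (and,
# optionally, of each simulated replicate for NPDE ranks).
decorrelated_residuals <- function(dataset, analyte, pop, K, seed,
                                   decorrelate_sims = FALSE) {
  prep <- diag_prep(dataset, analyte)
  sims <- simulate_replicates(prep, pop, K, seed)
  obs <- prep$obs
  keep <- obs$CENS == "none"
  ystar <- rep(NA_real_, nrow(obs))
  rank_count <- rep(NA_real_, nrow(obs))
  for (id in unique(obs$ID)) {
    rows <- which(obs$ID == id & keep)
    if (!length(rows)) next
    S <- sims$lsim[rows, , drop = FALSE]
    m <- rowMeans(S)
    V <- stats::cov(t(S))
    L <- tryCatch(chol(V), error = function(e) {
      warning("singular simulation covariance for pig ", id,
              "; ridge-regularized", call. = FALSE)
      chol(V + diag(1e-6 * mean(diag(V)), nrow(V)))
    })
    y <- log(obs$DV[rows])
    ystar[rows] <- backsolve(L, y - m, transpose = TRUE)
    if (decorrelate_sims) {
      Sstar <- backsolve(L, S - m, transpose = TRUE)
      rank_count[rows] <- rowSums(Sstar < ystar[rows])
    }
  }
  sel <- keep & !is.na(ystar)
  list(obs_meta = data.frame(ID = obs$ID[sel], OCC = obs$OCC[sel],
                             TIME = obs$TIME[sel], ROUTE = obs$ROUTE[sel]),
       ystar = ystar[sel], rank_count = rank_count[sel])
}

#' Prediction-corrected visual predictive check
#'
#' Observations and simulations are corrected, on the log scale, by the
#' difference between the bin-median typical (fixed-effect) prediction
#' and each row's own typical prediction, then summarized as 10/50/90th
#' percentiles per time bin, stratified by route. Simulation envelopes
#' are the 5th and 95th percentiles, across `K` replicates, of each
#' replicate's bin percentiles. Censored observations are excluded from
#' the percentile computation. Time bins are quantile-based; empty or
#' singleton bins are merged with their neighbor.
#'
#' @inheritParams pwres
#' @param K number of simulation replicates.
#' @param n_bins number of time bins per route stratum.
#' @return data.frame with one row per (route, bin, percentile):
#'   `route`, `bin`, `t_lo`, `t_hi`, `t_mid`, `pct`, `observed`,
#'   `env_lo`, `env_hi`, `n` (concentration scale, ug/mL).
#' @export
pcvpc <- function(dataset, analyte, pop, K = 500, n_bins = 8, seed = NULL) {
  prep <- diag_prep(dataset, analyte)
  sims <- simulate_replicates(prep, pop, K, seed)
  obs <- prep$obs
  keep <- obs$CENS == "none"
  out <- list()
  pcts <- c(0.1, 0.5, 0.9)
  for (rt in unique(obs$ROUTE)) {
    sel <- which(keep & obs$ROUTE == rt)
    if (length(sel) < 4L) next
    tt <- obs$TIME[sel]
    br <- unique(stats::quantile(tt, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- if (length(br) < 2L) factor(rep("all", length(tt)))
      else cut(tt, br, include.lowest = TRUE)
    # merge singleton bins with their neighbor
    counts <- table(bin)
    while (any(counts < 2L) && length(levels(bin)) > 1L) {
      iz <- which(counts < 2L)[1L]
      lv <- levels(bin)
      merge_into <- if (iz == 1L) 2L else iz - 1L
      levels(bin)[iz] <- lv[merge_into]
      counts <- table(bin)
    }
    for (bl in levels(bin)) {
      rows <- sel[bin == bl]
      if (!length(rows)) next
      lcorr <- stats::median(sims$ltyp[rows]) - sims$ltyp[rows]
      yobs <- log(obs$DV[rows]) + lcorr
      emp <- stats::quantile(yobs, pcts, names = FALSE)
      simq <- apply(sims$lsim[rows, , drop = FALSE] + lcorr, 2,
                    stats::quantile, probs = pcts)
      env <- apply(simq, 1, stats::quantile, probs = c(0.05, 0.95))
      for (m in seq_along(pcts)) {
        out[[length(out) + 1L]] <- data.frame(
          route = rt, bin = bl,
          t_lo = min(obs$TIME[rows]), t_hi = max(obs$TIME[rows]),
          t_mid = stats::median(obs$TIME[rows]),
          pct = 100 * pcts[m], observed = exp(emp[m]),
          env_lo = exp(env[1L, m]), env_hi = exp(env[2L, m]),
          n = length(rows), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
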