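# Monte-Carlo herd simulation of free sulfonamide : trimethoprim plasma
# concentration ratios under label dosing.

scp_doses <- function(combination) {
  switch(combination,
         "TMP/SDZ" = c(S = 25, TMP = 5),
         "TMP/SMX" = c(S = 25, TMP = 5),
         "TMP/SDMX" = c(S = 37.36, TMP = 8),
         stop("unknown combination '", combination, "'", call. = FALSE))
}

study_bw_range <- function(combination) {
  switch(combination,
         "TMP/SDZ" = c(28, 46.8),
         "TMP/SMX" = c(28.3, 37.2),
         "TMP/SDMX" = c(23.8, 43.6),
         stop("unknown combination '", combination, "'", call. = FALSE))
}

# Vectorized multi-dose concentration for a matrix of sampled parameters
# (data.frame from the internal sampler), on a shared time grid.
# Rows where ka collides with a disposition exponent fall back to the
# scalar repeated-pole solution.
cohort_conc <- function(pars, route, dose, ev_times, grid) {
  n <- nrow(pars)
  Tn <- length(grid)
  k10 <- pars$cl / pars$v1
  two <- pars$q > 0 & pars$v2 > 0
  k12 <- ifelse(two, pars$q / pars$v1, 0)
  k21 <- ifelse(two, pars$q / pars$v2, 0)
  s <- k10 + k12 + k21
  alpha <- (s + sqrt(pmax(s^2 - 4 * k10 * k21, 0))) / 2
  beta <- ifelse(two, k10 * k21 / alpha, 0)
  if (route == "iv") {
    lam <- cbind(alpha, beta)
    co <- cbind(ifelse(two, (alpha - k21) / (pars$v1 * (alpha - beta)), 1 / pars$v1),
                ifelse(two, (k21 - beta) / (pars$v1 * (alpha - beta)), 0))
    amt <- rep(dose, n)
  } else {
    ka <- pars[[paste0("ka_", route)]]
    f <- pars[[paste0("f_", route)]]
    denom_a <- (ka - alpha) * (beta - alpha)
    denom_b <- (ka - beta) * (alpha - beta)
    denom_k <- (alpha - ka) * (beta - ka)
    bad <- abs(ka - alpha) < 1e-8 * pmax(ka, alpha) |
      (two & abs(ka - beta) < 1e-8 * pmax(ka, beta))
    denom_a[bad] <- denom_b[bad] <- denom_k[bad] <- 1  # handled row-wise below
    num <- function(x) ifelse(two, k21 - x, 1)
    lam <- cbind(alpha, ifelse(two, beta, 0), ka)
    co <- cbind(num(alpha) / denom_a,
                ifelse(two, num(beta) / denom_b, 0),
                num(ka) / denom_k) * (ka / pars$v1)
    # 1-cpt: poles are (k10, ka); reuse columns 1 and 3
    one <- !two
    if (any(one)) {
      co[one, 1L] <- ka[one] / (pars$v1[one] * (ka[one] - k10[one]))
      co[one, 3L] <- -co[one, 1L]
    }
    amt <- f * dose
  }
  conc <- matrix(0, n, Tn)
  for (te in ev_times) {
    rel <- grid - te
    on <- rel >= 0
    if (!any(on)) next
    add <- matrix(0, n, sum(on))
    for (j in seq_len(ncol(lam))) {
      lj <- lam[, j]
      nz <- lj > 0 | co[, j] != 0
      if (!any(nz)) next
      add <- add + co[, j] * exp(-outer(lj, rel[on]))
    }
    conc[, on] <- conc[, on] + amt * add
  }
  if (route != "iv" && any(bad)) {
    for (i in which(bad)) {
      conc[i, ] <- .conc_events(pars$cl[i], pars$v1[i], pars$q[i], pars$v2[i],
                                ka[i], f[i], route, ev_times,
                                rep(dose, length(ev_times)), grid)
    }
  }
  conc
}

# Pig-major random draws so that the first n pigs of a larger cohort are
# identical to a cohort of size n under the same seed.
cohort_draws <- function(pop_s, pop_t, bw_range, n) {
  d_of <- function(pop) length(pop$omega) + length(pop$gamma)
  d <- 1L + d_of(pop_s) + d_of(pop_t)
  Z <- matrix(stats::rnorm(d * n), nrow = d, ncol = n)
  bw <- bw_range[1] + (bw_range[2] - bw_range[1]) * stats::pnorm(Z[1L, ])
  off <- 1L
  take <- function(pop) {
    k <- d_of(pop)
    out <- if (k > 0) t(Z[off + seq_len(k), , drop = FALSE]) else
      matrix(0, n, 0)
    off <<- off + k
    out
  }
  list(bw = bw, z_s = take(pop_s), z_t = take(pop_t))
}

# Natural-scale parameter table from standard-normal draws.
realize_cohort <- function(pop, bw, Z) {
  n <- length(bw)
  lbw <- log(bw / pop$bw_ref)
  dev <- matrix(0, n, 6,
                dimnames = list(NULL, c("cl", "v1", "q", "v2", "ka", "f")))
  j <- 0L
  for (nm in names(pop$omega)) {
    j <- j + 1L
    dev[, nm] <- dev[, nm] + pop$omega[[nm]] * Z[, j]
  }
  L <- gamma_chol(pop)
  if (!is.null(L)) {
    G <- Z[, j + seq_len(ncol(L)), drop = FALSE] %*% t(L)
    for (m in seq_along(rownames(L)))
      dev[, rownames(L)[m]] <- dev[, rownames(L)[m]] + G[, m]
  }
  out <- data.frame(bw = bw)
  for (nm in c("cl", "v1", "q", "v2")) {
    h <- unname(pop$fixed[nm])
    out[[nm]] <- if (h > 0)
      exp(log(h) + beta_of(pop, nm) * lbw + dev[, nm]) else 0
  }
  for (rt in names(pop$ka))
    out[[paste0("ka_", rt)]] <-
      exp(log(pop$ka[[rt]]) + beta_of(pop, "ka") * lbw + dev[, "ka"])
  for (rt in names(pop$f)) {
    h <- pop$f[[rt]]
    out[[paste0("f_", rt)]] <-
      if (h >= 1) rep(1, n) else inv_logit(logit(h) + dev[, "f"])
  }
  out
}

#' Simulate a herd's total concentration trajectories
#'
#' Draws `n` virtual pigs (one bodyweight and one correlated parameter
#' realization per analyte each), and computes total plasma
#' concentrations of the sulfonamide and of TMP on a shared time grid
#' under the given regimen. Draws are pig-major, so with the same seed
#' the first `n` pigs of a larger cohort are identical to a cohort of
#' size `n`.
#'
#' @param combination `"TMP/SDZ"`, `"TMP/SMX"` or `"TMP/SDMX"`.
#' @param n number of pigs.
#' @param pop_models named list of population models (default the
#'   published pig models).
#' @param route administration route, default `"oral"`.
#' @param doses named vector `c(S = , TMP = )` in mg/kg; defaults to the
#'   maximum labeled (SCP) oral doses: 25 + 5 for SDZ and SMX,
#'   37.36 + 8 for SDMX.
#' @param n_doses,interval repeated-dosing regimen (default a single
#'   dose at time 0).
#' @param bw_range bodyweight sampling range (kg); defaults to the
#'   combination's study range.
#' @param grid time grid (h), default 0-24 h in steps of 0.1.
#' @param variability draw random effects (`TRUE`) or use typical values
#'   at each pig's bodyweight (`FALSE`).
#' @param seed integer seed.
#' @param chunk pigs per vectorized block (memory control).
#' @return a list with `time`, `conc` (list of two `n x length(grid)`
#'   matrices named by analyte), `bw`, `combination`, `sulfa`.
#' @export
simulate_cohort <- function(combination, n,
                            pop_models = pig_population_models(),
                            route = "oral", doses = NULL,
                            n_doses = 1L, interval = 24,
                            bw_range = NULL, grid = seq(0, 24, by = 0.1),
                            variability = TRUE, seed = NULL,
                            chunk = 5000L) {
  sulfa <- sub("TMP/", "", combination)
  pop_s <- pop_models[[sulfa]]
  pop_t <- pop_models[["TMP"]]
  if (is.null(pop_s) || is.null(pop_t))
    stop("population models required for ", sulfa, " and TMP", call. = FALSE)
  if (is.null(doses)) doses <- scp_doses(combination)
  if (is.null(bw_range)) bw_range <- study_bw_range(combination)
  if (!is.null(seed)) set.seed(seed)
  ev_times <- (seq_len(n_doses) - 1L) * interval
  conc_s <- matrix(NA_real_, n, length(grid))
  conc_t <- matrix(NA_real_, n, length(grid))
  bw_all <- numeric(n)
  done <- 0L
  while (done < n) {
    m <- min(chunk, n - done)
    idx <- done + seq_len(m)
    dr <- cohort_draws(pop_s, pop_t, bw_range, m)
    bw_all[idx] <- dr$bw
    if (variability) {
      ps <- realize_cohort(pop_s, dr$bw, dr$z_s)
      pt <- realize_cohort(pop_t, dr$bw, dr$z_t)
    } else {
      ps <- realize_cohort(pop_s, dr$bw, 0 * dr$z_s)
      pt <- realize_cohort(pop_t, dr$bw, 0 * dr$z_t)
    }
    conc_s[idx, ] <- cohort_conc(ps, route, doses[["S"]], ev_times, grid)
    conc_t[idx, ] <- cohort_conc(pt, route, doses[["TMP"]], ev_times, grid)
    done <- done + m
  }
  conc <- list(conc_s, conc_t)
  names(conc) <- c(sulfa, "TMP")
  list(time = grid, conc = conc, bw = bw_all,
       combination = combination, sulfa = sulfa)
}

#' Free sulfonamide : trimethoprim concentration ratio trajectories
#'
#' `R(t) = (C_S(t) * fu_S) / (C_TMP(t) * fu_TMP)`: the free-concentration
#' ratio in "1:R" orientation, so the historical 1:19 synergy target
#' corresponds to `R = 19`. Points where both concentrations are zero
#' are undefined (`NA`).
#'
#' @param sim a cohort from [simulate_cohort()].
#' @param fu_s,fu_tmp unbound fractions of the sulfonamide and TMP;
#'   default the measured pig values ([binding_table()]).
#' @return a list with `time` and `ratio` (`n x length(time)` matrix).
#' @export
ratio_trajectory <- function(sim, fu_s = NULL, fu_tmp = NULL) {
  if (is.null(fu_s)) fu_s <- fu_of(sim$sulfa)
  if (is.null(fu_tmp)) fu_tmp <- fu_of("TMP")
  if (fu_s < 0 || fu_tmp < 0) stop("unbound fractions must be >= 0",
                                   call. = FALSE)
  cs <- sim$conc[[sim$sulfa]] * fu_s
  ct <- sim$conc[["TMP"]] * fu_tmp
  R <- cs / ct
  # 0/0 (e.g. pre-absorption) is undefined; tolerance absorbs the
  # floating-point cancellation of the closed forms at t = 0
  R[abs(cs) < 1e-12 & abs(ct) < 1e-12] <- NA_real_
  list(time = sim$time, ratio = R)
}

#' Band-occupancy summaries of ratio trajectories
#'
#' For each pig, flags the grid points where the ratio lies inside
#' `band` within the time `window`, and summarizes: the proportion of
#' pigs with at least one in-band point (`fraction_ever_in_band`, the
#' headline metric), the proportion in band at every point
#' (`fraction_always_in_band`), each pig's fraction of time in band, and
#' the median per-pig in-band duration in hours (a pig's duration is
#' `(number of in-band points - 1) * dt`, i.e. the length of the covered
#' grid interval).
#'
#' @param traj a list with `time` and `ratio` from [ratio_trajectory()]
#'   (a single trajectory vector is also accepted together with `time`).
#' @param band ratio band, default `c(10, 50)` (the 1:10-1:50 interval).
#' @param window evaluation window in hours, default `c(0, 24)`.
#' @return a list with `fraction_ever_in_band`,
#'   `fraction_always_in_band`, `time_fraction_in_band` (per pig),
#'   `duration_in_band` (per pig, h), `median_duration_in_band` (h) and
#'   `n`.
#' @export
band_metrics <- function(traj, band = c(10, 50), window = c(0, 24)) {
  R <- traj$ratio
  if (is.null(dim(R))) R <- matrix(R, nrow = 1)
  if (nrow(R) == 0L) stop("empty cohort", call. = FALSE)
  tt <- traj$time
  sel <- tt >= window[1] & tt <= window[2]
  if (!any(sel)) stop("time grid does not cover the window", call. = FALSE)
  R <- R[, sel, drop = FALSE]
  dt <- stats::median(diff(tt[sel]))
  mask <- !is.na(R) & R >= band[1] & R <= band[2]
  pts <- unname(rowSums(mask))
  dur <- pmax(pts - 1, 0) * dt
  list(fraction_ever_in_band = mean(pts > 0),
       fraction_always_in_band = mean(pts == ncol(R)),
       time_fraction_in_band = pts / ncol(R),
       duration_in_band = dur,
       median_duration_in_band = stats::median(dur),
       n = nrow(R))
}

#' Herd ratio simulation with band metrics
#'
#' Convenience wrapper: simulates a cohort at the labeled oral doses,
#' converts to free concentrations and returns the 1:10-1:50 band
#' summaries over 0-24 h alongside the ratio percentiles over time.
#'
#' @inheritParams simulate_cohort
#' @param band ratio band.
#' @param window evaluation window (h).
#' @param probs percentiles of the ratio reported over time.
#' @return a list with `band` (from [band_metrics()]), `percentiles`
#'   (matrix, rows = probs), `time`, `combination`.
#' @export
herd_ratio_simulation <- function(combination, n = 50000,
                                  pop_models = pig_population_models(),
                                  band = c(10, 50), window = c(0, 24),
                                  grid = seq(0, 24, by = 0.1),
                                  probs = c(0.05, 0.5, 0.95),
                                  seed = NULL, chunk = 5000L) {
  sim <- simulate_cohort(combination, n, pop_models = pop_models,
                         grid = grid, seed = seed, chunk = chunk)
  traj <- ratio_trajectory(sim)
  pm <- apply(traj$ratio, 2, stats::quantile, probs = probs, na.rm = TRUE)
  list(band = band_metrics(traj, band, window),
       percentiles = pm, time = traj$time, combination = combination)
}

#' Multi-day accumulation simulation
#'
#' Simulates repeated dosing (e.g. every 24 h for 5 days), returning
#' per-day band metrics of the free ratio and the pre-dose trough
#' concentrations of both analytes, to quantify the plasma accumulation
#' of slowly eliminated sulfonamides (SDMX) and its effect on the ratio.
#'
#' @inheritParams simulate_cohort
#' @param n_days treatment duration in days (label maxima are 5 or 7).
#' @param interval dosing interval (h).
#' @param band,probs as in [herd_ratio_simulation()].
#' @return a list with `daily` (data.frame: day, ever/always in band,
#'   median duration, median troughs of sulfa and TMP at end of day) and
#'   `time`/`ratio_median`.
#' @export
accumulation_sim <- function(combination, n = 1000, n_days = 5,
                             interval = 24,
                             pop_models = pig_population_models(),
                             route = "oral", doses = NULL,
                             bw_range = NULL, band = c(10, 50),
                             variability = TRUE, seed = NULL,
                             chunk = 5000L) {
  grid <- seq(0, n_days * 24, by = 0.1)
  n_doses <- ceiling(n_days * 24 / interval)
  sim <- simulate_cohort(combination, n, pop_models = pop_models,
                         route = route, doses = doses, n_doses = n_doses,
                         interval = interval, bw_range = bw_range,
                         grid = grid, variability = variability,
                         seed = seed, chunk = chunk)
  traj <- ratio_trajectory(sim)
  daily <- list()
  for (day in seq_len(n_days)) {
    win <- c((day - 1) * 24, day * 24)
    bm <- band_metrics(traj, band, win)
    i_end <- which.min(abs(sim$time - day * 24))
    daily[[day]] <- data.frame(
      day = day,
      ever_in_band = bm$fraction_ever_in_band,
      always_in_band = bm$fraction_always_in_band,
      median_duration_in_band = bm$median_duration_in_band,
      trough_sulfa = stats::median(sim$conc[[sim$sulfa]][, i_end]),
      trough_tmp = stats::median(sim$conc[["TMP"]][, i_end]))
  }
  list(daily = do.call(rbind, daily), time = sim$time,
       ratio_median = apply(traj$ratio, 2, stats::median, na.rm = TRUE))
}
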