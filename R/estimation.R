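# Nonlinear mixed-effects estimation by SAEM with censored observations.
#
# Latent variables are the link-scale individual parameters phi_ik per
# pig-occasion (log for CL/V1/Q/V2/ka, logit for F) for parameters that
# carry a random effect, with prior mean mu + beta_bw * log(BW/bw_ref)
# and per-parameter variance. Parameters without a random effect are
# pure fixed effects, updated by a damped numeric step on the
# complete-data likelihood. Observations below the LOQ enter through the
# censored likelihood and are imputed from their truncated conditionals
# in the E-step, so the remaining M-step updates are closed-form
# sufficient-statistic averages.

#' SAEM algorithm settings
#'
#' @param n_explore number of exploration iterations (step size 1).
#' @param n_smooth number of smoothing iterations (step size `1/k`).
#' @param rw_sweeps random-walk Metropolis sweeps per iteration.
#' @param var_floor_rate simulated-annealing floor: during exploration a
#'   variance may shrink by at most this factor per iteration.
#' @param target_accept Metropolis target acceptance rate for step-size
#'   adaptation.
#' @param laplace_every refresh period (iterations) of the per-occasion
#'   Gaussian posterior approximation used as an independence proposal
#'   (it mixes along narrow posterior ridges where component-wise
#'   random walks stall).
#' @param fix_bfgs_every period (iterations) of the full BFGS refresh of
#'   the no-random-effect fixed effects (between refreshes they move by
#'   damped diagonal-Newton steps).
#' @param verbose print progress every 50 iterations.
#' @return a list of settings for [fit_population()].
#' @export
saem_control <- function(n_explore = 300, n_smooth = 100, rw_sweeps = 2,
                         var_floor_rate = 0.95, target_accept = 0.4,
                         laplace_every = 20, fix_bfgs_every = 20,
                         verbose = FALSE) {
  list(n_explore = n_explore, n_smooth = n_smooth, rw_sweeps = rw_sweeps,
       var_floor_rate = var_floor_rate, target_accept = target_accept,
       laplace_every = laplace_every, fix_bfgs_every = fix_bfgs_every,
       verbose = verbose)
}

# censoring codes
.cens_code <- function(cens) {
  match(cens, c("none", "interval", "left")) - 1L
}

# Per-row censored log-likelihood on the log-concentration scale.
.row_ll <- function(lpred, ldv, cens, l_lod, l_loq, a) {
  ll <- numeric(length(lpred))
  obs <- cens == 0L
  if (any(obs)) ll[obs] <- stats::dnorm(ldv[obs], lpred[obs], a, log = TRUE)
  iv <- cens == 1L
  if (any(iv)) {
    p2 <- stats::pnorm((l_loq[iv] - lpred[iv]) / a)
    p1 <- stats::pnorm((l_lod[iv] - lpred[iv]) / a)
    ll[iv] <- log(pmax(p2 - p1, 1e-300))
  }
  lf <- cens == 2L
  if (any(lf))
    ll[lf] <- stats::pnorm((l_lod[lf] - lpred[lf]) / a, log.p = TRUE)
  ll
}

#' Censored log-likelihood of one pig's data
#'
#' Sums, over the pig's observation rows, the normal log-density of
#' `log(DV)` around the log individual prediction (SD `a`) for observed
#' rows, the normal-CDF difference between the log LOQ and log LOD for
#' interval-censored rows, and the normal CDF at the log LOD for
#' left-censored rows. Rows with a non-positive prediction contribute
#' `-Inf`.
#'
#' @param data dataset rows for one pig and one analyte (dose events
#'   included), with the usual `TIME`, `DV`, `CENS`, `LLOQ`, `LOD`,
#'   `EVID`, `OCC`, `ROUTE` columns.
#' @param p a [structural_params()] object (the pig's individual
#'   parameters, shared across the supplied occasions).
#' @param a residual SD on the log scale.
#' @return the log-likelihood (scalar).
#' @export
individual_loglik <- function(data, p, a) {
  stopifnot(inherits(p, "structural_params"), a > 0)
  total <- 0
  for (k in unique(data$OCC)) {
    d <- data[data$OCC == k, ]
    ev <- d[d$EVID == 1L, ]
    ob <- d[d$EVID == 0L, ]
    if (!nrow(ob)) next
    pred <- superpose(p, data.frame(time = ev$TIME, amount = ev$AMT,
                                    route = ev$ROUTE), ob$TIME)
    lpred <- log(pmax(pred, 0))  # -Inf for non-positive predictions
    total <- total + sum(.row_ll(lpred, log(ob$DV), .cens_code(ob$CENS),
                                 log(ob$LOD), log(ob$LLOQ), a))
  }
  total
}

# ---- internal data preparation -------------------------------------------

prepare_fit_data <- function(dataset, analyte, bw_ref) {
  d <- dataset[dataset$ANALYTE == analyte, , drop = FALSE]
  if (!nrow(d)) stop("no rows for analyte '", analyte, "'", call. = FALSE)
  if (!"OUTLIER" %in% names(d)) d$OUTLIER <- FALSE
  n_out <- sum(d$OUTLIER & d$EVID == 0L)
  if (n_out > 0) {
    message("excluding ", n_out, " outlier-flagged observation(s)")
    d <- filter_outliers(d)
  }
  pigs <- list()
  for (id in unique(d$ID)) {
    di <- d[d$ID == id, ]
    occs <- list()
    for (k in sort(unique(di$OCC))) {
      dk <- di[di$OCC == k, ]
      ev <- dk[dk$EVID == 1L, ]
      ob <- dk[dk$EVID == 0L, ]
      if (!nrow(ob) || !nrow(ev)) next
      route <- as.character(ev$ROUTE[1L])
      cens <- .cens_code(ob$CENS)
      occs[[length(occs) + 1L]] <- list(
        occ = k, bw = ob$BW[1L], lbw = log(ob$BW[1L] / bw_ref),
        route = route, ev_time = ev$TIME, ev_amt = ev$AMT,
        t_obs = ob$TIME, ldv = log(ob$DV), cens = cens,
        l_lod = log(ob$LOD), l_loq = log(ob$LLOQ),
        n_obs = nrow(ob))
    }
    if (length(occs))
      pigs[[length(pigs) + 1L]] <- list(id = id, occs = occs)
  }
  pigs
}

# crude data-driven starting values
init_theta <- function(pigs, two_cpt) {
  cl0 <- v10 <- numeric(0)
  for (pig in pigs) for (occ in pig$occs) {
    keep <- is.finite(occ$ldv)
    t <- occ$t_obs[keep]; dv <- exp(occ$ldv[keep])
    if (length(t) < 3L) next
    dose <- sum(occ$ev_amt)
    auc <- sum(diff(t) * (utils::head(dv, -1) + utils::tail(dv, -1)) / 2)
    tail_n <- min(4L, length(t))
    sl <- stats::coef(stats::lm(utils::tail(occ$ldv[keep], tail_n) ~
                                  utils::tail(t, tail_n)))[2L]
    if (is.finite(sl) && sl < 0) auc <- auc + dv[length(dv)] / (-sl)
    if (auc > 0) {
      eff <- if (occ$route == "iv") 1 else 0.7
      cl0 <- c(cl0, eff * dose / auc)
    }
    if (occ$route == "iv" && dv[1L] > 0) v10 <- c(v10, dose / dv[1L])
  }
  cl <- if (length(cl0)) stats::median(cl0) else 0.2
  v1 <- if (length(v10)) stats::median(v10) else 0.5
  list(cl = log(cl), v1 = log(v1),
       q = if (two_cpt) log(cl) else NULL,
       v2 = if (two_cpt) log(v1) else NULL)
}

.rtrunc_z <- function(n, lo, hi) {
  plo <- stats::pnorm(lo)
  phi <- stats::pnorm(hi)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

# ---- the fitter ----------------------------------------------------------

#' Fit a population PK model by SAEM
#'
#' Estimates one analyte's population model (fixed effects, bodyweight
#' covariate exponents, random-effect SDs and residual error) from a
#' long-format dataset with possible left- and interval-censored
#' observations. The E-step runs Metropolis-within-Gibbs (random-walk
#' sweeps plus a Laplace-approximation independence kernel) over the
#' link-scale individual parameters of random-effect-carrying
#' parameters, and imputes censored log concentrations from their
#' truncated conditionals; random-effect fixed effects, covariate
#' exponents and variances are updated in closed form from
#' stochastically approximated sufficient statistics, while fixed
#' effects without random effects are updated by damped numeric steps on
#' the complete-data likelihood. Rows flagged `OUTLIER` are excluded
#' before fitting.
#'
#' @param dataset a long-format dataset (see [generate_study()] /
#'   [read_dataset()]).
#' @param analyte which analyte to fit.
#' @param n_cpt 1 or 2 compartments.
#' @param variability named character vector over
#'   `c("cl","v1","q","v2","ka","f")` with values `"iiv"`, `"iov"` or
#'   `"none"`; defaults to IOV on `cl`, `v1`, `v2` and IIV on `ka`
#'   (the placement supported by the pig data). Parameters set to (or
#'   left at) `"none"` are estimated as pure fixed effects.
#' @param estimate_beta_bw character vector of parameters whose
#'   bodyweight power exponent is estimated (e.g. `c("cl", "v1")`);
#'   must carry a random effect. `NULL` fixes all exponents at 0.
#' @param bw_ref reference bodyweight (kg).
#' @param control a [saem_control()] list.
#' @param seed integer seed.
#' @param compute_loglik compute the Laplace marginal log-likelihood and
#'   BICc after fitting (adds a per-pig mode search).
#' @return an object of class `popfit` with elements `estimates`
#'   (a [population_model()]), `theta`, `ebes`, `trace`, `loglik`,
#'   `bicc`, `converged`, `n_obs`, `n_subjects`.
#' @export
fit_population <- function(dataset, analyte, n_cpt = 2,
                           variability = NULL, estimate_beta_bw = NULL,
                           bw_ref = 31.1, control = saem_control(),
                           seed = NULL, compute_loglik = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  two_cpt <- n_cpt == 2L
  pigs <- prepare_fit_data(dataset, analyte, bw_ref)
  N <- length(pigs)
  if (N < 2L) stop("need at least two pigs", call. = FALSE)

  base_keys <- if (two_cpt) c("cl", "v1", "q", "v2") else c("cl", "v1")
  routes <- sort(unique(unlist(lapply(pigs, function(pg)
    vapply(pg$occs, function(o) o$route, character(1))))))
  ev_routes <- setdiff(routes, "iv")
  if (is.null(variability)) {
    variability <- c(cl = "iov", v1 = "iov", ka = "iiv")
    if (two_cpt) variability <- c(variability, v2 = "iov")
  }
  level_of <- function(key) {
    if (!key %in% names(variability)) return("none")
    variability[[key]]
  }
  keys <- c(base_keys, if (length(ev_routes)) c("ka", "f"))
  lat_keys <- keys[vapply(keys, function(k)
    level_of(k) %in% c("iiv", "iov"), logical(1))]
  none_keys <- setdiff(keys, lat_keys)
  bad_beta <- setdiff(estimate_beta_bw, lat_keys)
  if (length(bad_beta))
    stop("bodyweight exponents can only be estimated on parameters with ",
         "a random effect: ", paste(bad_beta, collapse = ", "),
         call. = FALSE)
  mu_names_of <- function(key) {
    if (key %in% c("ka", "f")) paste0(key, "_", ev_routes) else key
  }
  variant_of <- function(key, route) {
    if (key %in% c("ka", "f")) paste0(key, "_", route) else key
  }

  # per-occasion latent/fixed key split
  for (i in seq_len(N)) for (j in seq_along(pigs[[i]]$occs)) {
    occ <- pigs[[i]]$occs[[j]]
    kk <- base_keys
    if (occ$route != "iv") kk <- c(kk, "ka", "f")
    lat <- intersect(kk, lat_keys)
    fix <- intersect(kk, none_keys)
    pigs[[i]]$occs[[j]]$lat_keys <- lat
    pigs[[i]]$occs[[j]]$lat_mu <- vapply(lat, variant_of,
                                         character(1), route = occ$route)
    pigs[[i]]$occs[[j]]$fix_keys <- fix
    pigs[[i]]$occs[[j]]$fix_mu <- vapply(fix, variant_of,
                                         character(1), route = occ$route)
  }

  # design matrices per latent key
  occ_index <- X <- XtX <- list()
  for (key in lat_keys) {
    rows <- list()
    for (i in seq_len(N)) for (j in seq_along(pigs[[i]]$occs)) {
      occ <- pigs[[i]]$occs[[j]]
      if (key %in% occ$lat_keys) rows[[length(rows) + 1L]] <-
          c(i, j, occ$lbw, match(variant_of(key, occ$route),
                                 mu_names_of(key)))
    }
    M <- do.call(rbind, rows)
    occ_index[[key]] <- M
    nv <- length(mu_names_of(key))
    Xk <- matrix(0, nrow(M), nv)
    Xk[cbind(seq_len(nrow(M)), M[, 4L])] <- 1
    if (key %in% estimate_beta_bw) Xk <- cbind(Xk, M[, 3L])
    X[[key]] <- Xk
    XtX[[key]] <- crossprod(Xk)
  }

  # ---- initial values ----
  init <- init_theta(pigs, two_cpt)
  mu_all <- c(cl = init$cl, v1 = init$v1)
  if (two_cpt) mu_all <- c(mu_all, q = init$q, v2 = init$v2)
  for (rt in ev_routes) {
    mu_all[paste0("ka_", rt)] <- 0       # ka = 1 /h
    mu_all[paste0("f_", rt)] <- logit(0.7)
  }
  lat_mu_names <- unlist(lapply(lat_keys, mu_names_of))
  fix_mu_names <- unlist(lapply(none_keys, mu_names_of))
  mu <- mu_all[lat_mu_names]
  mufix <- mu_all[fix_mu_names]
  beta <- stats::setNames(rep(0, length(estimate_beta_bw)), estimate_beta_bw)
  vvar <- stats::setNames(rep(0.3^2, length(lat_keys)), lat_keys)
  a2 <- 0.3^2

  ctl <- control
  n_iter <- ctl$n_explore + ctl$n_smooth

  occ_lpred <- function(occ, phi) {
    lv <- function(key) {
      if (key %in% names(phi)) phi[[key]]
      else mufix[[variant_of(key, occ$route)]]
    }
    cl <- exp(lv("cl")); v1 <- exp(lv("v1"))
    q <- if (two_cpt) exp(lv("q")) else 0
    v2 <- if (two_cpt) exp(lv("v2")) else 0
    ka <- 0; f <- 1
    if (occ$route != "iv") {
      ka <- exp(lv("ka"))
      f <- inv_logit(lv("f"))
    }
    conc <- .conc_events(cl, v1, q, v2, ka, f, occ$route,
                         occ$ev_time, occ$ev_amt, occ$t_obs)
    log(pmax(conc, 1e-300))
  }

  prior_mean <- function(occ) {
    vapply(seq_along(occ$lat_keys), function(m) {
      key <- occ$lat_keys[m]
      b <- if (key %in% names(beta)) beta[[key]] else 0
      mu[[occ$lat_mu[m]]] + b * occ$lbw
    }, numeric(1))
  }

  for (i in seq_len(N)) for (j in seq_along(pigs[[i]]$occs)) {
    occ <- pigs[[i]]$occs[[j]]
    phi <- stats::setNames(mu[occ$lat_mu], occ$lat_keys)
    pigs[[i]]$occs[[j]]$phi <- phi
    pigs[[i]]$occs[[j]]$ycomp <- ifelse(occ$cens == 0L, occ$ldv, occ$l_lod)
  }

  rw <- stats::setNames(rep(0.2, length(lat_keys)), lat_keys)
  acc_n <- acc_y <- stats::setNames(rep(0, length(lat_keys)), lat_keys)

  s_xtphi <- lapply(lat_keys, function(k) rep(0, ncol(X[[k]])))
  names(s_xtphi) <- lat_keys
  s_phi2 <- stats::setNames(rep(0, length(lat_keys)), lat_keys)
  s_rss <- 0
  n_obs_tot <- sum(vapply(pigs, function(pg)
    sum(vapply(pg$occs, function(o) o$n_obs, numeric(1))), numeric(1)))
  first_stats <- TRUE

  # complete-data RSS as a function of the no-random-effect fixed effects
  fix_rss <- function(th) {
    mufix_save <- mufix
    mufix[names(th)] <<- th
    rss <- 0
    for (i in seq_len(N)) for (occ in pigs[[i]]$occs)
      rss <- rss + sum((occ$ycomp - occ_lpred(occ, occ$phi))^2)
    mufix <<- mufix_save
    rss
  }

  trace <- vector("list", n_iter)

  for (t_iter in seq_len(n_iter)) {
    explore <- t_iter <= ctl$n_explore
    rho <- if (explore) 1 else 1 / (t_iter - ctl$n_explore)
    a <- sqrt(a2)

    # ---- E-step ----
    for (i in seq_len(N)) {
      for (j in seq_along(pigs[[i]]$occs)) {
        occ <- pigs[[i]]$occs[[j]]
        phi <- occ$phi
        lpred <- occ_lpred(occ, phi)  # fresh: mufix may have moved
        y <- occ$ycomp
        dll <- -0.5 * sum((y - lpred)^2) / a2
        if (length(phi)) {
          pm <- prior_mean(occ)
          psd <- sqrt(vvar[occ$lat_keys])
          # Laplace independence kernel: joint proposal from a Gaussian
          # approximation of the occasion posterior
          if (is.null(pigs[[i]]$occs[[j]]$lap) ||
              t_iter %% ctl$laplace_every == 1L) {
            negpost <- function(z) {
              lp <- occ_lpred(occ, stats::setNames(z, occ$lat_keys))
              0.5 * sum((y - lp)^2) / a2 + 0.5 * sum(((z - pm) / psd)^2)
            }
            opt <- try(stats::optim(phi, negpost, method = "BFGS",
                                    control = list(maxit = 50)),
                       silent = TRUE)
            if (!inherits(opt, "try-error")) {
              H <- stats::optimHess(opt$par, negpost)
              R <- tryCatch(chol(H), error = function(e)
                diag(1 / psd, length(psd)))
              pigs[[i]]$occs[[j]]$lap <- list(m = opt$par, R = R)
            }
          }
          lap <- pigs[[i]]$occs[[j]]$lap
          if (!is.null(lap)) {
            prop <- stats::setNames(
              lap$m + backsolve(lap$R, stats::rnorm(length(phi))),
              occ$lat_keys)
            lpred_new <- occ_lpred(occ, prop)
            dll_new <- -0.5 * sum((y - lpred_new)^2) / a2
            dprior <- -0.5 * sum(((prop - pm) / psd)^2) +
              0.5 * sum(((phi - pm) / psd)^2)
            dq <- -0.5 * sum((lap$R %*% (prop - lap$m))^2) +
              0.5 * sum((lap$R %*% (phi - lap$m))^2)
            if (log(stats::runif(1)) < dll_new - dll + dprior - dq) {
              phi <- prop
              lpred <- lpred_new
              dll <- dll_new
            }
          }
          for (sweep in seq_len(ctl$rw_sweeps + 1L)) {
            indep <- sweep == 1L
            for (m in seq_along(phi)) {
              key <- occ$lat_keys[m]
              phi_new <- phi
              if (indep) {
                phi_new[m] <- stats::rnorm(1, pm[m], psd[m])
              } else {
                phi_new[m] <- phi[m] + rw[key] * stats::rnorm(1)
              }
              lpred_new <- occ_lpred(occ, phi_new)
              dll_new <- -0.5 * sum((y - lpred_new)^2) / a2
              dprior <- if (indep) 0 else
                (-0.5 * ((phi_new[m] - pm[m])^2 -
                           (phi[m] - pm[m])^2) / psd[m]^2)
              if (log(stats::runif(1)) < dll_new - dll + dprior) {
                phi <- phi_new
                lpred <- lpred_new
                dll <- dll_new
                if (!indep) acc_y[key] <- acc_y[key] + 1
              }
              if (!indep) acc_n[key] <- acc_n[key] + 1
            }
          }
        }
        # impute censored observations from the truncated conditional
        cen <- occ$cens > 0L
        if (any(cen)) {
          lo <- ifelse(occ$cens[cen] == 1L, occ$l_lod[cen], -Inf)
          hi <- ifelse(occ$cens[cen] == 1L, occ$l_loq[cen], occ$l_lod[cen])
          z <- .rtrunc_z(sum(cen), (lo - lpred[cen]) / a,
                         (hi - lpred[cen]) / a)
          y[cen] <- lpred[cen] + a * z
        }
        pigs[[i]]$occs[[j]]$phi <- phi
        pigs[[i]]$occs[[j]]$lpred <- lpred
        pigs[[i]]$occs[[j]]$ycomp <- y
      }
    }

    if (explore && t_iter %% 10L == 0L) {
      for (key in lat_keys) {
        if (acc_n[key] > 0) {
          rate <- acc_y[key] / acc_n[key]
          rw[key] <- rw[key] * exp(0.5 * (rate - ctl$target_accept))
          acc_y[key] <- acc_n[key] <- 0
        }
      }
    }

    # ---- sufficient statistics ----
    for (key in lat_keys) {
      M <- occ_index[[key]]
      phiv <- vapply(seq_len(nrow(M)), function(r)
        pigs[[M[r, 1L]]]$occs[[M[r, 2L]]]$phi[[key]], numeric(1))
      xt <- drop(crossprod(X[[key]], phiv))
      p2 <- sum(phiv^2)
      if (first_stats) {
        s_xtphi[[key]] <- xt
        s_phi2[key] <- p2
      } else {
        s_xtphi[[key]] <- s_xtphi[[key]] + rho * (xt - s_xtphi[[key]])
        s_phi2[key] <- s_phi2[key] + rho * (p2 - s_phi2[key])
      }
    }
    rss <- 0
    for (i in seq_len(N)) for (occ in pigs[[i]]$occs)
      rss <- rss + sum((occ$ycomp - occ$lpred)^2)
    if (first_stats) s_rss <- rss else s_rss <- s_rss + rho * (rss - s_rss)
    first_stats <- FALSE

    # ---- M-step: closed-form updates for random-effect parameters ----
    for (key in lat_keys) {
      A <- XtX[[key]]
      cvec <- s_xtphi[[key]]
      b <- solve(A, cvec)
      nv <- length(mu_names_of(key))
      mu[mu_names_of(key)] <- b[seq_len(nv)]
      if (key %in% names(beta)) beta[key] <- b[nv + 1L]
      Nk <- nrow(occ_index[[key]])
      vnew <- (s_phi2[key] - 2 * sum(b * cvec) + drop(t(b) %*% A %*% b)) / Nk
      vnew <- max(vnew, 1e-6)
      if (explore) vnew <- max(vnew, ctl$var_floor_rate * vvar[key])
      vvar[key] <- vnew
    }
    a2_new <- max(s_rss / n_obs_tot, 1e-8)
    if (explore) a2_new <- max(a2_new, ctl$var_floor_rate * a2)
    a2 <- a2_new

    # ---- damped numeric update of no-random-effect fixed effects ----
    if (length(mufix)) {
      if (t_iter %% ctl$fix_bfgs_every == 0L) {
        opt <- try(stats::optim(mufix, fix_rss, method = "BFGS",
                                control = list(maxit = 10)), silent = TRUE)
        if (!inherits(opt, "try-error"))
          mufix <- mufix + min(rho, 1) * (opt$par - mufix)
      } else {
        eps <- 1e-4
        f0 <- fix_rss(mufix)
        step <- numeric(length(mufix))
        for (m in seq_along(mufix)) {
          thp <- thm <- mufix
          thp[m] <- thp[m] + eps
          thm[m] <- thm[m] - eps
          fp <- fix_rss(thp)
          fm <- fix_rss(thm)
          g <- (fp - fm) / (2 * eps)
          h <- (fp - 2 * f0 + fm) / eps^2
          step[m] <- -g / max(h, abs(g) / 0.3, 1e-8)
        }
        step <- pmin(pmax(step, -0.3), 0.3)
        mufix <- mufix + min(rho, 1) * step
      }
    }

    nat <- c(exp(c(mu, mufix)[setdiff(c(lat_mu_names, fix_mu_names),
                                      grep("^f_", c(lat_mu_names, fix_mu_names),
                                           value = TRUE))])
             )
    fnames <- grep("^f_", c(lat_mu_names, fix_mu_names), value = TRUE)
    if (length(fnames))
      nat <- c(nat, stats::setNames(inv_logit(c(mu, mufix)[fnames]), fnames))
    trace[[t_iter]] <- c(nat,
                         if (length(beta))
                           stats::setNames(beta, paste0("beta_", names(beta))),
                         if (length(lat_keys))
                           stats::setNames(sqrt(vvar[lat_keys]),
                                           paste0("sd_", lat_keys)),
                         a = sqrt(a2))
    if (ctl$verbose && t_iter %% 50L == 0L)
      message("iter ", t_iter, ": ",
              paste(sprintf("%s=%.3g", names(trace[[t_iter]]),
                            trace[[t_iter]]), collapse = " "))
  }

  trace <- do.call(rbind, trace)

  # convergence heuristic: relative drift over the second half of the
  # smoothing phase
  half <- ctl$n_explore + ctl$n_smooth %/% 2L
  drift <- abs(trace[n_iter, ] - trace[half, ]) /
    pmax(abs(trace[n_iter, ]), 1e-8)
  converged <- max(drift) < 0.10
  if (!converged)
    warning("SAEM parameter drift over the final smoothing phase exceeds ",
            "10%; estimates may not have converged", call. = FALSE)

  # ---- assemble estimates ----
  mu_get <- function(nm) {
    if (nm %in% names(mu)) mu[[nm]] else mufix[[nm]]
  }
  fixed <- c(cl = exp(mu_get("cl")), v1 = exp(mu_get("v1")),
             q = if (two_cpt) exp(mu_get("q")) else 0,
             v2 = if (two_cpt) exp(mu_get("v2")) else 0)
  ka_est <- if (length(ev_routes))
    stats::setNames(vapply(paste0("ka_", ev_routes), function(nm)
      exp(mu_get(nm)), numeric(1)), ev_routes)
  f_est <- if (length(ev_routes))
    stats::setNames(vapply(paste0("f_", ev_routes), function(nm)
      inv_logit(mu_get(nm)), numeric(1)), ev_routes)
  omega <- gamma <- numeric(0)
  for (key in lat_keys) {
    if (level_of(key) == "iiv") omega[key] <- sqrt(vvar[key])
    if (level_of(key) == "iov") gamma[key] <- sqrt(vvar[key])
  }
  estimates <- population_model(
    analyte, fixed = fixed, ka = ka_est, f = f_est,
    beta_bw = if (length(beta)) beta,
    omega = if (length(omega)) omega,
    gamma = if (length(gamma)) gamma,
    resid_a = sqrt(a2), bw_ref = bw_ref)

  fit <- structure(list(
    estimates = estimates, analyte = analyte, n_cpt = n_cpt,
    theta = list(mu = mu, mufix = mufix, beta = beta, var = vvar, a2 = a2,
                 lat_keys = lat_keys, none_keys = none_keys,
                 ev_routes = ev_routes, two_cpt = two_cpt,
                 estimate_beta_bw = estimate_beta_bw, bw_ref = bw_ref,
                 variability = variability),
    pigs = pigs, trace = trace, converged = converged,
    n_obs = n_obs_tot, n_subjects = N,
    loglik = NA_real_, bicc = NA_real_, ebes = NULL),
    class = "popfit")

  if (compute_loglik) {
    ll <- laplace_loglik(fit)
    fit$loglik <- ll$loglik
    fit$ebes <- ll$ebes
    fit$bicc <- bicc(fit)
  }
  fit
}

#' @export
print.popfit <- function(x, ...) {
  cat(sprintf("<popfit> %s, %d-compartment, %d pigs, %d observations\n",
              x$analyte, x$n_cpt, x$n_subjects, x$n_obs))
  cat(sprintf("  converged: %s", x$converged))
  if (is.finite(x$loglik))
    cat(sprintf("; -2LL = %.1f; BICc = %.1f", -2 * x$loglik, x$bicc))
  cat("\n")
  print(x$estimates)
  invisible(x)
}

#' @export
coef.popfit <- function(object, ...) {
  est <- object$estimates
  out <- est$fixed
  for (rt in names(est$ka)) out[paste0("ka_", rt)] <- est$ka[[rt]]
  for (rt in names(est$f)) out[paste0("f_", rt)] <- est$f[[rt]]
  for (nm in names(est$beta_bw)) out[paste0("beta_", nm)] <- est$beta_bw[[nm]]
  for (nm in names(est$omega)) out[paste0("omega_", nm)] <- est$omega[[nm]]
  for (nm in names(est$gamma)) out[paste0("gamma_", nm)] <- est$gamma[[nm]]
  out["a"] <- est$resid_a
  out
}

# Laplace approximation of the marginal log-likelihood, maximizing each
# pig's joint latent vector (posterior mode = empirical Bayes estimate).
laplace_loglik <- function(fit) {
  th <- fit$theta
  two_cpt <- th$two_cpt
  a <- sqrt(th$a2)
  variant_of <- function(key, route) {
    if (key %in% c("ka", "f")) paste0(key, "_", route) else key
  }
  occ_lpred_fix <- function(occ, phi) {
    lv <- function(key) {
      if (key %in% names(phi)) phi[[key]]
      else th$mufix[[variant_of(key, occ$route)]]
    }
    cl <- exp(lv("cl")); v1 <- exp(lv("v1"))
    q <- if (two_cpt) exp(lv("q")) else 0
    v2 <- if (two_cpt) exp(lv("v2")) else 0
    ka <- 0; f <- 1
    if (occ$route != "iv") {
      ka <- exp(lv("ka"))
      f <- inv_logit(lv("f"))
    }
    conc <- .conc_events(cl, v1, q, v2, ka, f, occ$route,
                         occ$ev_time, occ$ev_amt, occ$t_obs)
    log(pmax(conc, 1e-300))
  }
  total <- 0
  ebes <- list()
  for (pig in fit$pigs) {
    z0 <- unlist(lapply(pig$occs, function(o) o$phi))
    pm <- unlist(lapply(pig$occs, function(o) {
      vapply(seq_along(o$lat_keys), function(m) {
        key <- o$lat_keys[m]
        b <- if (key %in% names(th$beta)) th$beta[[key]] else 0
        th$mu[[o$lat_mu[m]]] + b * o$lbw
      }, numeric(1))
    }))
    pv <- unlist(lapply(pig$occs, function(o) th$var[o$lat_keys]))
    d <- length(z0)
    data_ll <- function(z) {
      val <- 0
      off <- 0L
      for (o in pig$occs) {
        nk <- length(o$lat_keys)
        phi <- stats::setNames(z[off + seq_len(nk)], o$lat_keys)
        off <- off + nk
        lpred <- occ_lpred_fix(o, phi)
        val <- val + sum(.row_ll(lpred, o$ldv, o$cens, o$l_lod, o$l_loq, a))
      }
      val
    }
    if (d == 0L) {
      total <- total + data_ll(numeric(0))
      mode <- numeric(0)
    } else {
      negll <- function(z)
        0.5 * sum((z - pm)^2 / pv) + 0.5 * sum(log(2 * pi * pv)) - data_ll(z)
      opt <- stats::optim(z0, negll, method = "BFGS",
                          control = list(maxit = 200))
      H <- stats::optimHess(opt$par, negll)
      ld <- determinant(H, logarithm = TRUE)
      ldet <- if (ld$sign > 0) as.numeric(ld$modulus) else
        as.numeric(determinant(H + diag(1e-6, nrow(H)), TRUE)$modulus)
      total <- total + (-opt$value + d / 2 * log(2 * pi) - 0.5 * ldet)
      mode <- opt$par
    }
    off <- 0L
    for (o in pig$occs) {
      nk <- length(o$lat_keys)
      phi <- stats::setNames(mode[off + seq_len(nk)], o$lat_keys)
      off <- off + nk
      lv <- function(key, default = NA_real_) {
        if (key %in% names(phi)) phi[[key]]
        else if (variant_of(key, o$route) %in% names(th$mufix))
          th$mufix[[variant_of(key, o$route)]]
        else default
      }
      ebes[[length(ebes) + 1L]] <- data.frame(
        ID = pig$id, OCC = o$occ, ROUTE = o$route, BW = o$bw,
        cl = exp(lv("cl")), v1 = exp(lv("v1")),
        q = if (two_cpt) exp(lv("q")) else 0,
        v2 = if (two_cpt) exp(lv("v2")) else 0,
        ka = if (o$route != "iv") exp(lv("ka")) else NA_real_,
        f = if (o$route != "iv") inv_logit(lv("f")) else 1)
    }
  }
  list(loglik = total, ebes = do.call(rbind, ebes))
}

#' Corrected Bayesian information criterion for a population fit
#'
#' Hybrid small-sample BIC for mixed models: parameters tied to the
#' random-effect structure (fixed effects and covariate exponents of
#' parameters carrying a random effect, plus the variance components) are
#' penalized by `log(N_subjects)`, while purely fixed quantities (fixed
#' effects without variability, and the residual SD) are penalized by
#' `log(n_observations)`. Lower is better.
#'
#' @param fit a `popfit` object with its log-likelihood computed.
#' @return the criterion value.
#' @export
bicc <- function(fit) {
  stopifnot(inherits(fit, "popfit"))
  if (!is.finite(fit$loglik)) {
    ll <- laplace_loglik(fit)
    fit$loglik <- ll$loglik
  }
  k <- bicc_param_counts(fit)
  -2 * fit$loglik + k$k_random * log(fit$n_subjects) +
    k$k_fixed * log(fit$n_obs)
}

bicc_param_counts <- function(fit) {
  th <- fit$theta
  n_mu <- function(key) if (key %in% c("ka", "f"))
    length(th$ev_routes) else 1L
  k_random <- 0L
  k_fixed <- 1L  # residual a
  for (key in th$lat_keys)
    k_random <- k_random + n_mu(key) + sum(th$estimate_beta_bw == key) + 1L
  for (key in th$none_keys)
    k_fixed <- k_fixed + n_mu(key)
  list(k_random = k_random, k_fixed = k_fixed)
}

#' Bootstrap standard errors by case resampling of pigs
#'
#' Resamples pigs with replacement, refits each replicate and reports the
#' per-parameter SD and 2.5/97.5 percentile interval. Replicates whose
#' fit does not converge are dropped (their count is reported in the
#' `n_dropped` attribute).
#'
#' @param dataset the original dataset.
#' @param analyte analyte to fit.
#' @param n_runs number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param ... passed to [fit_population()] (e.g. `n_cpt`, `variability`,
#'   `estimate_beta_bw`, `control`).
#' @return data.frame with `parameter`, `se`, `lo`, `hi` and the replicate
#'   estimates as attribute `"replicates"`.
#' @export
bootstrap_se <- function(dataset, analyte, n_runs = 100, seed = NULL, ...) {
  if (n_runs < 2) stop("'n_runs' must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(dataset$ID[dataset$ANALYTE == analyte])
  # draw all resamples up front and refit every replicate from the same
  # RNG state: replicate-to-replicate variation then reflects the
  # resampled data only, not the fitting algorithm's Monte-Carlo noise
  takes <- lapply(seq_len(n_runs), function(r)
    sample(ids, length(ids), replace = TRUE))
  fit_seed <- sample.int(.Machine$integer.max, 1L)
  reps <- list()
  n_dropped <- 0L
  for (r in seq_len(n_runs)) {
    take <- takes[[r]]
    pieces <- lapply(seq_along(take), function(m) {
      d <- dataset[dataset$ID == take[m], , drop = FALSE]
      d$ID <- m
      d
    })
    boot_data <- do.call(rbind, pieces)
    est <- tryCatch({
      fit <- suppressWarnings(
        fit_population(boot_data, analyte, compute_loglik = FALSE,
                       seed = fit_seed, ...))
      if (!fit$converged) NULL else coef(fit)
    }, error = function(e) NULL)
    if (is.null(est)) n_dropped <- n_dropped + 1L else
      reps[[length(reps) + 1L]] <- est
  }
  if (!length(reps)) stop("all bootstrap replicates failed", call. = FALSE)
  mat <- do.call(rbind, reps)
  out <- data.frame(
    parameter = colnames(mat),
    se = apply(mat, 2, stats::sd),
    lo = apply(mat, 2, stats::quantile, 0.025),
    hi = apply(mat, 2, stats::quantile, 0.975),
    row.names = NULL)
  attr(out, "replicates") <- mat
  attr(out, "n_dropped") <- n_dropped
  out
}
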