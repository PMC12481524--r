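#' Population pharmacokinetic model (fixed effects + variability)
#'
#' Describes one analyte's population model: typical (median) structural
#' parameters, a bodyweight power covariate, inter-individual variability
#' (IIV, `omega`, one draw per pig) and inter-occasion variability
#' (IOV, `gamma`, one draw per pig-occasion) on the log scale
#' (logit scale for bioavailabilities), optional correlations between the
#' occasion-level random effects, and the constant residual error SD on
#' log-concentration.
#'
#' Parameter vocabulary: `cl`, `v1`, `q`, `v2` (disposition), `ka`
#' (absorption; the fixed effect is route-specific via `ka`, the random
#' effect is shared across routes) and `f` (bioavailability, logit link).
#'
#' @param analyte analyte label, e.g. `"SDZ"`.
#' @param fixed named numeric with entries `cl`, `v1`, `q`, `v2`
#'   (natural scale, per kg).
#' @param ka named numeric of absorption rate constants per route (1/h).
#' @param f named numeric of bioavailability fractions per route in (0, 1].
#' @param beta_bw named numeric of bodyweight power exponents (subset of
#'   `cl`, `v1`, `q`, `v2`, `ka`); parameters without an entry are not
#'   bodyweight-scaled.
#' @param omega named numeric of IIV standard deviations (log scale);
#'   only parameters listed get an `eta` draw.
#' @param gamma named numeric of IOV standard deviations (log scale);
#'   only parameters listed get a per-occasion `gamma` draw.
#' @param corr optional correlation matrix (dimnames = names of `gamma`)
#'   for the joint per-occasion draw; identity when `NULL`.
#' @param resid_a residual SD on the log-concentration scale, > 0.
#' @param bw_ref reference bodyweight (kg) of the covariate model,
#'   default 31.1.
#' @return an object of class `population_model`.
#' @export
population_model <- function(analyte, fixed, ka = NULL, f = NULL,
                             beta_bw = NULL, omega = NULL, gamma = NULL,
                             corr = NULL, resid_a, bw_ref = 31.1) {
  need <- c("cl", "v1", "q", "v2")
  if (!all(need %in% names(fixed)))
    stop("'fixed' must name cl, v1, q, v2", call. = FALSE)
  fixed <- fixed[need]
  if (any(fixed[c("cl", "v1")] <= 0) || any(fixed < 0))
    stop("fixed effects must be positive (q, v2 may be zero)", call. = FALSE)
  if (!is.null(omega) && any(omega < 0))
    stop("'omega' SDs must be non-negative", call. = FALSE)
  if (!is.null(gamma) && any(gamma < 0))
    stop("'gamma' SDs must be non-negative", call. = FALSE)
  ok_re <- c("cl", "v1", "q", "v2", "ka", "f")
  if (!all(names(omega) %in% ok_re) || !all(names(gamma) %in% ok_re))
    stop("random-effect names must be among ", paste(ok_re, collapse = ", "),
         call. = FALSE)
  if (!is.null(corr)) {
    gnames <- names(gamma)
    if (!is.matrix(corr) || !identical(rownames(corr), gnames) ||
        !identical(colnames(corr), gnames))
      stop("'corr' dimnames must equal names(gamma)", call. = FALSE)
    if (max(abs(corr - t(corr))) > 1e-10)
      stop("'corr' must be symmetric", call. = FALSE)
    if (any(abs(diag(corr) - 1) > 1e-10))
      stop("'corr' must have unit diagonal", call. = FALSE)
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop("'corr' must be positive semi-definite", call. = FALSE)
  }
  if (!is.numeric(resid_a) || resid_a <= 0)
    stop("'resid_a' must be positive", call. = FALSE)
  if (bw_ref <= 0) stop("'bw_ref' must be positive", call. = FALSE)
  if (!is.null(f) && (any(f <= 0) || any(f > 1)))
    stop("'f' must lie in (0, 1]", call. = FALSE)
  structure(list(analyte = analyte, fixed = fixed, ka = ka, f = f,
                 beta_bw = beta_bw, omega = omega, gamma = gamma,
                 corr = corr, resid_a = resid_a, bw_ref = bw_ref),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> %s (bw_ref = %g kg, a = %g)\n",
              x$analyte, x$bw_ref, x$resid_a))
  cat(sprintf("  CL %g, V1 %g, Q %g, V2 %g (L/h/kg, L/kg)\n",
              x$fixed["cl"], x$fixed["v1"], x$fixed["q"], x$fixed["v2"]))
  if (!is.null(x$ka))
    cat("  ka:", paste(sprintf("%s %g/h", names(x$ka), x$ka), collapse = ", "), "\n")
  if (!is.null(x$f))
    cat("  F:", paste(sprintf("%s %g", names(x$f), x$f), collapse = ", "), "\n")
  if (length(x$beta_bw))
    cat("  beta_bw:", paste(sprintf("%s %g", names(x$beta_bw), x$beta_bw),
                            collapse = ", "), "\n")
  if (length(x$omega))
    cat("  omega:", paste(sprintf("%s %g", names(x$omega), x$omega),
                          collapse = ", "), "\n")
  if (length(x$gamma))
    cat("  gamma:", paste(sprintf("%s %g", names(x$gamma), x$gamma),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Bodyweight power-covariate scaling
#'
#' Scales a typical parameter value by `(bw / bw_ref)^beta_bw`, i.e. the
#' power covariate model that is additive on the log scale.
#'
#' @param hpop typical value at the reference bodyweight.
#' @param beta_bw power exponent.
#' @param bw bodyweight (kg), > 0; vectorized.
#' @param bw_ref reference bodyweight (kg), default 31.1.
#' @return scaled parameter value(s).
#' @export
covariate_scale <- function(hpop, beta_bw, bw, bw_ref = 31.1) {
  if (any(bw <= 0)) stop("bodyweight must be positive", call. = FALSE)
  if (bw_ref <= 0) stop("'bw_ref' must be positive", call. = FALSE)
  hpop * (bw / bw_ref)^beta_bw
}

beta_of <- function(pop, param) {
  if (!param %in% names(pop$beta_bw)) return(0)
  pop$beta_bw[[param]]
}

#' Typical structural parameters for a given bodyweight
#'
#' Applies the bodyweight covariate to the fixed effects, with no random
#' effects: the median individual of that bodyweight. At `bw = bw_ref`
#' this returns the fixed effects verbatim.
#'
#' @param pop a [population_model()].
#' @param bw bodyweight (kg).
#' @return a [structural_params()] object.
#' @export
typical_params <- function(pop, bw) {
  stopifnot(inherits(pop, "population_model"))
  if (length(bw) != 1L || bw <= 0)
    stop("'bw' must be a single positive number", call. = FALSE)
  sc <- function(param, val) covariate_scale(val, beta_of(pop, param), bw, pop$bw_ref)
  ka <- if (!is.null(pop$ka)) {
    out <- sc("ka", pop$ka)
    names(out) <- names(pop$ka)
    out
  }
  structural_params(cl = sc("cl", unname(pop$fixed["cl"])),
                    v1 = sc("v1", unname(pop$fixed["v1"])),
                    q = sc("q", unname(pop$fixed["q"])),
                    v2 = sc("v2", unname(pop$fixed["v2"])),
                    ka = ka, f = pop$f)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Cholesky factor of the occasion-level random-effect covariance
gamma_chol <- function(pop) {
  gn <- names(pop$gamma)
  if (length(gn) == 0L) return(NULL)
  C <- if (is.null(pop$corr)) diag(length(gn)) else pop$corr
  D <- diag(pop$gamma, nrow = length(gn))
  S <- D %*% C %*% D
  # PSD-safe factor (corr may be semi-definite)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(gn))
  dimnames(L) <- list(gn, NULL)
  L
}

#' Draw one virtual pig (IIV + IOV realization)
#'
#' Draws `eta` once per pig for parameters with `omega > 0` and a joint
#' `gamma` vector independently per occasion for parameters with
#' `gamma > 0` (respecting `corr`), adds the bodyweight covariate on the
#' link scale, and inverts the link (`exp`, or inverse-logit for `f`).
#' Uses R's global RNG stream; seed with [set.seed()].
#'
#' @param pop a [population_model()].
#' @param bw_by_occasion bodyweight (kg) per occasion.
#' @return a list with `bw_by_occasion`, `eta`, `gamma_by_occasion` and
#'   `params_by_occasion` (a list of [structural_params()]).
#' @export
draw_individual <- function(pop, bw_by_occasion) {
  stopifnot(inherits(pop, "population_model"))
  n_occ <- length(bw_by_occasion)
  if (n_occ < 1L || any(bw_by_occasion <= 0))
    stop("bodyweights must be positive (one per occasion)", call. = FALSE)
  on <- names(pop$omega)
  eta <- if (length(on)) stats::setNames(stats::rnorm(length(on), 0, pop$omega), on)
  L <- gamma_chol(pop)
  gn <- names(pop$gamma)
  gam_occ <- vector("list", n_occ)
  params <- vector("list", n_occ)
  for (k in seq_len(n_occ)) {
    g <- if (!is.null(L)) stats::setNames(as.numeric(L %*% stats::rnorm(ncol(L))), gn)
    gam_occ[[k]] <- g
    params[[k]] <- realize_params(pop, bw_by_occasion[k], eta, g)
  }
  list(bw_by_occasion = bw_by_occasion, eta = eta,
       gamma_by_occasion = gam_occ, params_by_occasion = params)
}

# Assemble structural_params from link-scale deviations.
realize_params <- function(pop, bw, eta = NULL, gam = NULL) {
  dev <- function(param) {
    (if (!is.null(eta) && param %in% names(eta)) eta[[param]] else 0) +
      (if (!is.null(gam) && param %in% names(gam)) gam[[param]] else 0)
  }
  lbw <- log(bw / pop$bw_ref)
  val <- function(param, hpop) {
    exp(log(hpop) + beta_of(pop, param) * lbw + dev(param))
  }
  ka <- if (!is.null(pop$ka)) {
    out <- vapply(pop$ka, function(h) val("ka", h), numeric(1))
    names(out) <- names(pop$ka)
    out
  }
  f <- if (!is.null(pop$f)) {
    out <- vapply(pop$f, function(h) {
      if (h >= 1) 1 else inv_logit(logit(h) + dev("f"))
    }, numeric(1))
    names(out) <- names(pop$f)
    out
  }
  structural_params(cl = val("cl", unname(pop$fixed["cl"])),
                    v1 = val("v1", unname(pop$fixed["v1"])),
                    q = val("q", unname(pop$fixed["q"])),
                    v2 = val("v2", unname(pop$fixed["v2"])),
                    ka = ka, f = f)
}

#' Vectorized single-occasion parameter sampling
#'
#' Draws `n` pigs' parameters for one occasion (both IIV and IOV applied),
#' returning a data.frame with one row per pig: the workhorse behind the
#' Monte-Carlo herd simulations.
#'
#' @param pop a [population_model()].
#' @param bw bodyweight vector (kg), recycled to length `n`.
#' @param n number of pigs.
#' @return data.frame with columns `bw`, `cl`, `v1`, `q`, `v2` and
#'   `ka_<route>` / `f_<route>` where present.
#' @export
sample_parameters <- function(pop, bw, n) {
  stopifnot(inherits(pop, "population_model"))
  bw <- rep_len(bw, n)
  lbw <- log(bw / pop$bw_ref)
  dev <- matrix(0, n, 6,
                dimnames = list(NULL, c("cl", "v1", "q", "v2", "ka", "f")))
  for (nm in names(pop$omega))
    dev[, nm] <- dev[, nm] + stats::rnorm(n, 0, pop$omega[[nm]])
  L <- gamma_chol(pop)
  if (!is.null(L)) {
    Z <- matrix(stats::rnorm(n * ncol(L)), n, ncol(L))
    G <- Z %*% t(L)
    for (j in seq_along(rownames(L)))
      dev[, rownames(L)[j]] <- dev[, rownames(L)[j]] + G[, j]
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

#' Published population models for the four analytes
#'
#' Returns the fitted pig population models for sulfadiazine (SDZ),
#' sulfadimethoxine (SDMX), sulfamethoxazole (SMX) and trimethoprim (TMP):
#' median fixed effects, bodyweight covariate exponents (reference
#' 31.1 kg), IIV on `ka` where supported by the data, IOV on `CL`, `V1`,
#' `V2` where supported, and the constant log-scale residual error SD.
#' `Q` carries no random effect for any analyte, nor does `ka` for SMX.
#' Random-effect correlations are not published per analyte and default to
#' identity; supply `corr` on the returned objects to override.
#'
#' @return named list of [population_model()] objects.
#' @export
pig_population_models <- function() {
  list(
    SDZ = population_model(
      "SDZ",
      fixed = c(cl = 0.12, v1 = 0.30, q = 0.32, v2 = 0.29),
      ka = c(oral = 0.50, im = 1.30),
      f = c(oral = 0.93, im = 0.99),
      beta_bw = c(cl = 0.51, v1 = 1.1),
      omega = c(ka = 0.52),
      gamma = c(cl = 0.33, v1 = 0.12, v2 = 0.62),
      resid_a = 0.32),
    SDMX = population_model(
      "SDMX",
      fixed = c(cl = 0.015, v1 = 0.13, q = 0.20, v2 = 0.16),
      ka = c(oral = 0.60),
      f = c(oral = 0.68),
      omega = c(ka = 0.37),
      gamma = c(cl = 0.18, v1 = 0.40, v2 = 0.34),
      resid_a = 0.22),
    SMX = population_model(
      "SMX",
      fixed = c(cl = 0.21, v1 = 0.48, q = 0.83, v2 = 0.17),
      ka = c(oral = 1.82),
      f = c(oral = 0.64),
      gamma = c(v1 = 0.09, v2 = 0.40),
      resid_a = 0.18),
    TMP = population_model(
      "TMP",
      fixed = c(cl = 0.48, v1 = 0.92, q = 1.26, v2 = 0.86),
      ka = c(oral = 0.66, im = 1.14),
      f = c(oral = 0.58, im = 0.99),
      beta_bw = c(cl = 0.78, v1 = 1.33),
      omega = c(ka = 0.63),
      gamma = c(cl = 0.34, v1 = 0.44, v2 = 0.42),
      resid_a = 0.40)
  )
}
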