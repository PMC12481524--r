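#' Kinetic constants for a one- or two-compartment mammillary model
#'
#' Bundles the structural (fixed) pharmacokinetic constants of a single
#' analyte. All clearances and volumes are bodyweight-normalized
#' (L/h/kg and L/kg), so doses are expressed in mg/kg and concentrations
#' come out in mg/L = ug/mL. A model with `q = 0` or `v2 = 0` collapses to
#' one compartment.
#'
#' @param cl total body clearance (L/h/kg), > 0.
#' @param v1 central volume of distribution (L/kg), > 0.
#' @param q inter-compartment clearance (L/h/kg), >= 0; 0 means one
#'   compartment.
#' @param v2 peripheral volume of distribution (L/kg), >= 0; 0 means one
#'   compartment.
#' @param ka named numeric of first-order absorption rate constants (1/h)
#'   per extravascular route, e.g. `c(oral = 0.5, im = 1.3)`. May be `NULL`
#'   when only IV profiles are needed.
#' @param f named numeric of bioavailability fractions in (0, 1] per
#'   extravascular route. IV bioavailability is implicitly 1.
#' @return an object of class `structural_params`.
#' @export
structural_params <- function(cl, v1, q = 0, v2 = 0, ka = NULL, f = NULL) {
  for (nm in c("cl", "v1")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  }
  for (nm in c("q", "v2")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val < 0)
      stop("'", nm, "' must be a single non-negative number", call. = FALSE)
  }
  if (xor(q > 0, v2 > 0))
    stop("'q' and 'v2' must be both positive (two-compartment) or both zero",
         call. = FALSE)
  if (!is.null(ka)) {
    if (is.null(names(ka)) || any(!nzchar(names(ka))))
      stop("'ka' must be a named vector (route names)", call. = FALSE)
    if (any(!is.finite(ka)) || any(ka <= 0))
      stop("'ka' values must be positive and finite", call. = FALSE)
    if ("iv" %in% names(ka))
      stop("IV administration has no absorption rate constant", call. = FALSE)
  }
  if (!is.null(f)) {
    if (is.null(names(f)) || any(!nzchar(names(f))))
      stop("'f' must be a named vector (route names)", call. = FALSE)
    if (any(!is.finite(f)) || any(f <= 0) || any(f > 1))
      stop("'f' values must lie in (0, 1]", call. = FALSE)
  }
  structure(list(cl = cl, v1 = v1, q = q, v2 = v2,
                 ka = ka, f = f),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  ncpt <- if (x$q > 0) 2L else 1L
  cat(sprintf("<structural_params> %d-compartment\n", ncpt))
  cat(sprintf("  CL = %g L/h/kg, V1 = %g L/kg", x$cl, x$v1))
  if (ncpt == 2L) cat(sprintf(", Q = %g L/h/kg, V2 = %g L/kg", x$q, x$v2))
  cat("\n")
  if (!is.null(x$ka))
    cat("  ka:", paste(sprintf("%s = %g /h", names(x$ka), x$ka),
                       collapse = ", "), "\n")
  if (!is.null(x$f))
    cat("  F: ", paste(sprintf("%s = %g", names(x$f), x$f),
                       collapse = ", "), "\n")
  invisible(x)
}

is_two_cpt <- function(p) p$q > 0 && p$v2 > 0

#' First-order micro-constants and hybrid disposition exponents
#'
#' Computes the elimination and distribution micro-constants
#' `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2` and the hybrid exponents
#' `alpha >= beta`, the roots of
#' `s^2 - (k10 + k12 + k21) s + k10 k21 = 0`. For a one-compartment model
#' `k12 = k21 = 0`, `alpha = k10` and `beta = 0`.
#'
#' @param p a [structural_params()] object.
#' @return a list with `k10`, `k12`, `k21`, `alpha`, `beta`.
#' @export
micro_constants <- function(p) {
  stopifnot(inherits(p, "structural_params"))
  k10 <- p$cl / p$v1
  if (!is_two_cpt(p))
    return(list(k10 = k10, k12 = 0, k21 = 0, alpha = k10, beta = 0))
  k12 <- p$q / p$v1
  k21 <- p$q / p$v2
  s <- k10 + k12 + k21
  pr <- k10 * k21
  disc <- sqrt(max(s * s - 4 * pr, 0))
  alpha <- (s + disc) / 2
  beta <- pr / alpha  # Vieta: numerically stabler than (s - disc)/2
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

# Disposition exponents and unit-dose IV bolus coefficients, so that
# C_iv(t) = dose * sum(coef * exp(-lambda * t)). Raw-parameter version
# used in inner estimation loops.
.disp <- function(cl, v1, q, v2) {
  k10 <- cl / v1
  if (q <= 0 || v2 <= 0)
    return(list(lambda = k10, coef = 1 / v1, k21 = NA_real_))
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  pr <- k10 * k21
  alpha <- (s + sqrt(max(s * s - 4 * pr, 0))) / 2
  beta <- pr / alpha
  ab <- alpha - beta
  list(lambda = c(alpha, beta),
       coef = c((alpha - k21) / (v1 * ab), (k21 - beta) / (v1 * ab)),
       k21 = k21)
}

disposition <- function(p) {
  d <- .disp(p$cl, p$v1, p$q, p$v2)
  d$mc <- micro_constants(p)
  d
}

# Unit-(f*dose) concentration with first-order input; handles the
# repeated-pole limit when ka collides with a disposition exponent.
.ev_conc <- function(d, v1, ka, t) {
  lam <- d$lambda
  scale <- ka / v1
  two <- length(lam) == 2L
  poles <- c(lam, ka)
  hit <- which(abs(lam - ka) < 1e-8 * pmax(ka, lam))
  if (length(hit) == 0L) {
    out <- 0
    for (j in seq_along(poles)) {
      num <- if (two) d$k21 - poles[j] else 1
      out <- out + num / prod(poles[-j] - poles[j]) * exp(-poles[j] * t)
    }
    return(scale * out)
  }
  lamc <- lam[hit[1L]]
  if (!two) return(scale * t * exp(-lamc * t))
  mu <- lam[-hit[1L]]
  k21 <- d$k21
  shared <- (k21 - mu) / (mu - lamc)^2
  scale * (shared * (exp(-mu * t) - exp(-lamc * t)) +
             t * (k21 - lamc) / (mu - lamc) * exp(-lamc * t))
}

# Concentration for one dose event sequence, raw parameters; events may
# be a vector of times with a common amount per event.
.conc_events <- function(cl, v1, q, v2, ka, f, route, ev_time, ev_amt, t) {
  d <- .disp(cl, v1, q, v2)
  out <- numeric(length(t))
  iv <- identical(route, "iv")
  for (j in seq_along(ev_time)) {
    rel <- t - ev_time[j]
    on <- rel >= 0
    if (!any(on)) next
    if (iv) {
      add <- 0
      for (m in seq_along(d$lambda))
        add <- add + ev_amt[j] * d$coef[m] * exp(-d$lambda[m] * rel[on])
    } else {
      add <- f * ev_amt[j] * .ev_conc(d, v1, ka, rel[on])
    }
    out[on] <- out[on] + add
  }
  out
}

#' Plasma concentration after an IV dose
#'
#' Closed-form biexponential (two-compartment) or monoexponential
#' (one-compartment) disposition after an intravenous dose. The dose is
#' treated as an instantaneous bolus by default; a zero-order infusion of
#' duration `tinf` hours is available for slow injections.
#'
#' @param p a [structural_params()] object.
#' @param dose dose in mg/kg.
#' @param t vector of times (h), >= 0.
#' @param tinf zero-order infusion duration (h); 0 means bolus.
#' @return concentrations (ug/mL) at `t`.
#' @export
conc_iv_bolus <- function(p, dose, t, tinf = 0) {
  stopifnot(inherits(p, "structural_params"))
  if (!is.numeric(dose) || length(dose) != 1L || dose <= 0)
    stop("'dose' must be a single positive number", call. = FALSE)
  if (any(t < 0)) stop("negative times are not allowed", call. = FALSE)
  d <- disposition(p)
  if (tinf <= 0) {
    out <- rep(0, length(t))
    for (j in seq_along(d$lambda))
      out <- out + dose * d$coef[j] * exp(-d$lambda[j] * t)
    return(out)
  }
  # zero-order input at rate dose/tinf over [0, tinf]
  out <- rep(0, length(t))
  tin <- pmin(t, tinf)
  post <- pmax(t - tinf, 0)
  for (j in seq_along(d$lambda)) {
    lam <- d$lambda[j]
    out <- out + (dose / tinf) * d$coef[j] / lam *
      (1 - exp(-lam * tin)) * exp(-lam * post)
  }
  out
}

# Partial-fraction coefficients for first-order input: poles are the
# disposition exponents plus ka; numerator N(s) = (k21 - s) for 2-cpt,
# 1 for 1-cpt. Returns function of t giving unit-(f*dose) concentration.
extravascular_kernel <- function(p, ka) {
  d <- .disp(p$cl, p$v1, p$q, p$v2)
  v1 <- p$v1
  function(t) .ev_conc(d, v1, ka, t)
}

#' Plasma concentration after an extravascular dose
#'
#' Closed-form solution with first-order absorption (rate `ka`, amount
#' `f * dose`) into the central compartment: the Bateman equation for the
#' one-compartment model and its three-exponential analogue for the
#' two-compartment model. When `ka` coincides with a disposition exponent
#' the analytic repeated-pole limit (a `t * exp(-lambda t)` term) is used.
#'
#' @inheritParams conc_iv_bolus
#' @param route extravascular route name; must have `ka` and `f` entries
#'   in `p`.
#' @return concentrations (ug/mL) at `t`; `C(0) = 0`.
#' @export
conc_extravascular <- function(p, dose, route, t) {
  stopifnot(inherits(p, "structural_params"))
  if (any(t < 0)) stop("negative times are not allowed", call. = FALSE)
  ka <- p$ka[[route]]
  f <- p$f[[route]]
  if (is.null(ka) || is.na(ka))
    stop("no absorption rate constant for route '", route, "'", call. = FALSE)
  if (is.null(f) || is.na(f))
    stop("no bioavailability for route '", route, "'", call. = FALSE)
  kern <- extravascular_kernel(p, ka)
  f * dose * kern(t)
}

#' Concentration for an arbitrary route
#'
#' Dispatches to [conc_iv_bolus()] for `route = "iv"` and to
#' [conc_extravascular()] otherwise.
#' @inheritParams conc_extravascular
#' @export
conc_profile <- function(p, dose, route, t) {
  if (identical(route, "iv")) conc_iv_bolus(p, dose, t)
  else conc_extravascular(p, dose, route, t)
}

#' Superpose multiple dose events (linear pharmacokinetics)
#'
#' Sums single-dose solutions shifted to each dose event time. Linearity of
#' the kinetics makes this exact for any multiple-dosing regimen, e.g.
#' repeated oral dosing every 12 h for 5 days.
#'
#' @param p a [structural_params()] object.
#' @param events a data.frame with columns `time` (h), `amount` (mg/kg) and
#'   `route`.
#' @param times evaluation grid (h).
#' @return concentrations (ug/mL) at `times`.
#' @export
superpose <- function(p, events, times) {
  stopifnot(is.data.frame(events),
            all(c("time", "amount", "route") %in% names(events)))
  if (any(events$amount <= 0)) stop("dose amounts must be positive", call. = FALSE)
  if (any(events$time < 0)) stop("dose times must be non-negative", call. = FALSE)
  if (any(times < 0)) stop("negative times are not allowed", call. = FALSE)
  out <- rep(0, length(times))
  for (i in seq_len(nrow(events))) {
    rel <- times - events$time[i]
    on <- rel >= 0
    if (!any(on)) next
    out[on] <- out[on] +
      conc_profile(p, events$amount[i], as.character(events$route[i]), rel[on])
  }
  out
}

#' Terminal elimination half-life
#'
#' `ln(2) / beta` with `beta` the slow hybrid disposition exponent from
#' [micro_constants()] (equal to `ln(2) * V1 / CL` for a one-compartment
#' model). Route-independent for first-order absorption faster than
#' elimination.
#'
#' @param p a [structural_params()] object.
#' @return half-life in hours.
#' @export
terminal_half_life <- function(p) {
  mc <- micro_constants(p)
  lam <- if (is_two_cpt(p)) mc$beta else mc$k10
  log(2) / lam
}

#' Area under the concentration-time curve to infinity
#'
#' For linear kinetics `AUC(0-Inf) = F * dose / CL`, with `F = 1` for IV.
#'
#' @inheritParams conc_extravascular
#' @return AUC in h*ug/mL.
#' @export
auc_inf <- function(p, dose, route = "iv") {
  stopifnot(inherits(p, "structural_params"))
  if (dose <= 0) stop("'dose' must be positive", call. = FALSE)
  f <- if (identical(route, "iv")) 1 else p$f[[route]]
  if (is.null(f) || is.na(f))
    stop("no bioavailability for route '", route, "'", call. = FALSE)
  f * dose / p$cl
}
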