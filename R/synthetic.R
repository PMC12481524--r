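#' Cross-over study designs for the TMP/sulfonamide trials
#'
#' Builds the single-dose cross-over design used for each combination:
#' every pig receives the combination once IV and once by gavage (order
#' alternating between pigs, one route per occasion), at the licensed
#' doses. Rich sampling at 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12, 24, 32,
#' 48 and 56 h, with 5 and 15 min samples added after IV dosing; the
#' SDMX arm extends to 72, 80 and 96 h. Bodyweights are drawn uniformly
#' over the study range and re-drawn at each occasion (pigs are weighed
#' before each period).
#'
#' @param combination `"TMP/SDZ"`, `"TMP/SMX"` or `"TMP/SDMX"`.
#' @param n_pigs number of pigs; defaults to the trial sizes (10, 10, 14).
#' @param bw_range bodyweight sampling range (kg); defaults to the
#'   combination's observed range.
#' @param loq named limits of quantification (ug/mL) per analyte;
#'   defaults 0.1 (SDZ, SDMX), 0.02 (SMX), 0.01 (TMP).
#' @param lod named limits of detection; default `loq / 2`.
#' @param occasions optional list of occasions, each a list with `route`
#'   and optionally `n_doses` and `interval` (h) for repeated dosing;
#'   default the two-occasion IV/oral cross-over.
#' @return an object of class `study_design`.
#' @export
study_design <- function(combination = c("TMP/SDZ", "TMP/SMX", "TMP/SDMX"),
                         n_pigs = NULL, bw_range = NULL, loq = NULL,
                         lod = NULL, occasions = NULL) {
  combination <- match.arg(combination)
  sulfa <- sub("TMP/", "", combination)
  defaults <- list(
    "TMP/SDZ" = list(n = 10L, bw = c(28, 46.8)),
    "TMP/SMX" = list(n = 10L, bw = c(28.3, 37.2)),
    "TMP/SDMX" = list(n = 14L, bw = c(23.8, 43.6)))
  if (is.null(n_pigs)) n_pigs <- defaults[[combination]]$n
  if (is.null(bw_range)) bw_range <- defaults[[combination]]$bw
  default_loq <- c(SDZ = 0.1, SDMX = 0.1, SMX = 0.02, TMP = 0.01)
  analytes <- c(sulfa, "TMP")
  if (is.null(loq)) loq <- default_loq[analytes]
  if (is.null(lod)) lod <- loq / 2
  if (any(lod > loq)) stop("'lod' must not exceed 'loq'", call. = FALSE)
  base_times <- c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12, 24, 32, 48, 56)
  if (sulfa == "SDMX") base_times <- c(base_times, 72, 80, 96)
  times <- list(iv = c(5 / 60, 15 / 60, base_times),
                oral = base_times, im = base_times)
  doses <- switch(combination,
    "TMP/SDZ" = list(iv = c(SDZ = 12.5, TMP = 2.5),
                     oral = c(SDZ = 25, TMP = 5),
                     im = c(SDZ = 12.5, TMP = 2.5)),
    "TMP/SMX" = list(iv = c(SMX = 30, TMP = 6),
                     oral = c(SMX = 30, TMP = 6)),
    "TMP/SDMX" = list(iv = c(SDMX = 18.6, TMP = 4),
                      oral = c(SDMX = 37.36, TMP = 8)))
  if (is.null(occasions))
    occasions <- list(list(route = "iv"), list(route = "oral"))
  for (k in seq_along(occasions)) {
    occasions[[k]]$n_doses <- occasions[[k]]$n_doses %||% 1L
    occasions[[k]]$interval <- occasions[[k]]$interval %||% 24
  }
  structure(list(combination = combination, analytes = analytes,
                 sulfa = sulfa, n_pigs = as.integer(n_pigs),
                 bw_range = bw_range, loq = loq, lod = lod,
                 times = times, doses = doses, occasions = occasions),
            class = "study_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Censoring below the limits of quantification and detection
#'
#' Values at or above the LOQ are observed; values between the LOD and
#' the LOQ are interval-censored on `[lod, loq]`; values below the LOD
#' are left-censored at the LOD. The reported `dv` is the censoring bound
#' for censored rows.
#'
#' @param values concentrations (ug/mL).
#' @param lod limit of detection.
#' @param loq limit of quantification, `>= lod`.
#' @return data.frame with columns `dv` and
#'   `cens` (`"none"`, `"interval"`, `"left"`).
#' @export
apply_censoring <- function(values, lod, loq) {
  if (lod > loq) stop("'lod' must not exceed 'loq'", call. = FALSE)
  cens <- ifelse(values >= loq, "none",
                 ifelse(values >= lod, "interval", "left"))
  dv <- ifelse(cens == "none", values, ifelse(cens == "interval", loq, lod))
  data.frame(dv = dv, cens = cens, stringsAsFactors = FALSE)
}

#' Simulate a virtual cross-over PK study
#'
#' Generates a long-format dataset for all analytes of a combination:
#' per pig and occasion a parameter realization is drawn (IIV + IOV +
#' bodyweight covariate), true concentrations are computed at the design
#' sampling times, multiplied by `exp(eps)` with
#' `eps ~ N(0, a^2)` (the constant residual error on the log scale), and
#' censored at the analyte's LOQ/LOD. Dose events appear as `EVID = 1`
#' rows. The noiseless model output is kept in the `TRUE_CONC` column so
#' error-model recovery can be tested.
#'
#' @param design a [study_design()].
#' @param pop_models named list of [population_model()] objects covering
#'   `design$analytes` (e.g. [pig_population_models()]).
#' @param seed integer seed for reproducibility; `NULL` keeps the current
#'   RNG state.
#' @return a data.frame with columns `ID`, `OCC`, `TIME`, `AMT`, `EVID`,
#'   `ANALYTE`, `DV`, `TRUE_CONC`, `CENS`, `LLOQ`, `LOD`, `ROUTE`, `BW`,
#'   `OUTLIER`.
#' @export
generate_study <- function(design, pop_models, seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  missing <- setdiff(design$analytes, names(pop_models))
  if (length(missing))
    stop("no population model for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_len(design$n_pigs)) {
    n_occ <- length(design$occasions)
    bw <- stats::runif(n_occ, design$bw_range[1], design$bw_range[2])
    # alternate route order between pigs for the 2-occasion cross-over
    occ_order <- seq_len(n_occ)
    if (n_occ == 2L && i %% 2L == 0L) occ_order <- rev(occ_order)
    for (k in seq_len(n_occ)) {
      occ <- design$occasions[[occ_order[k]]]
      route <- occ$route
      ev_times <- (seq_len(occ$n_doses) - 1L) * occ$interval
      obs_times <- design$times[[route]]
      if (occ$n_doses > 1L)
        obs_times <- as.numeric(outer(obs_times[obs_times <= occ$interval],
                                      ev_times, `+`))
      for (an in design$analytes) {
        pop <- pop_models[[an]]
        ind <- draw_individual(pop, bw[k])
        p <- ind$params_by_occasion[[1L]]
        dose <- design$doses[[route]][[an]]
        events <- data.frame(time = ev_times, amount = dose, route = route)
        conc <- superpose(p, events, obs_times)
        dv_true <- conc
        dv <- conc * exp(stats::rnorm(length(conc), 0, pop$resid_a))
        cen <- apply_censoring(dv, design$lod[[an]], design$loq[[an]])
        rows[[length(rows) + 1L]] <- data.frame(
          ID = i, OCC = k,
          TIME = c(ev_times, obs_times),
          AMT = c(rep(dose, length(ev_times)), rep(NA_real_, length(obs_times))),
          EVID = c(rep(1L, length(ev_times)), rep(0L, length(obs_times))),
          ANALYTE = an,
          DV = c(rep(NA_real_, length(ev_times)), cen$dv),
          TRUE_CONC = c(rep(NA_real_, length(ev_times)), dv_true),
          CENS = c(rep("none", length(ev_times)), cen$cens),
          LLOQ = design$loq[[an]], LOD = design$lod[[an]],
          ROUTE = route, BW = bw[k], OUTLIER = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag and perturb a random fraction of observations as outliers
#'
#' Multiplies a binomially chosen fraction of observation rows by
#' `magnitude` and sets their `OUTLIER` flag, producing a stress fixture
#' for outlier-exclusion workflows.
#'
#' @param dataset a dataset from [generate_study()].
#' @param fraction expected fraction of observation rows to perturb,
#'   in `[0, 1)`.
#' @param magnitude multiplicative distortion applied to flagged rows.
#' @param seed optional integer seed.
#' @return the dataset with flagged rows perturbed.
#' @export
inject_outliers <- function(dataset, fraction, magnitude = 5, seed = NULL) {
  if (fraction < 0 || fraction >= 1)
    stop("'fraction' must lie in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (fraction == 0) return(dataset)
  obs <- which(dataset$EVID == 0L)
  hit <- obs[stats::runif(length(obs)) < fraction]
  dataset$DV[hit] <- dataset$DV[hit] * magnitude
  dataset$OUTLIER[hit] <- TRUE
  dataset
}

#' Multiple-dose design presets
#'
#' Named presets for repeated-dose regimens used to study accumulation:
#' `"de_smet_oral"` (oral bolus every 12 h for 5 days) and
#' `"de_smet_im"` (IM every 24 h for 5 days), both for the TMP/SDZ
#' combination at conventional doses.
#'
#' @param name preset name.
#' @return a [study_design()].
#' @export
preset_design <- function(name = c("de_smet_oral", "de_smet_im")) {
  name <- match.arg(name)
  if (name == "de_smet_oral")
    study_design("TMP/SDZ",
                 occasions = list(list(route = "oral", n_doses = 10L,
                                       interval = 12)))
  else
    study_design("TMP/SDZ",
                 occasions = list(list(route = "im", n_doses = 5L,
                                       interval = 24)))
}
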