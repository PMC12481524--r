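#' Write a PK dataset to CSV
#'
#' NONMEM-style long format: `EVID = 1` rows are dose events with `AMT`
#' in mg/kg, `EVID = 0` rows are observations with `DV` in ug/mL (the
#' censoring bound for censored rows), `CENS` in
#' `none`/`interval`/`left`, and per-row `LLOQ`, `LOD`, `ROUTE`, `BW`.
#'
#' @param dataset a dataset as produced by [generate_study()].
#' @param path output CSV path.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

pk_required_cols <- c("ID", "OCC", "TIME", "AMT", "EVID", "ANALYTE",
                      "DV", "CENS", "LLOQ", "ROUTE", "BW")

#' Read and validate a PK dataset
#'
#' Reads a long-format CSV and validates it: required columns present,
#' non-negative times, positive observed concentrations, censored rows
#' carrying their bounds, and every observation row having a matching
#' dose event for the same pig, occasion and analyte. Errors list the
#' offending column or rows.
#'
#' @param path CSV path.
#' @return the validated data.frame.
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(pk_required_cols, names(d))
  if (length(missing))
    stop("dataset is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"LOD" %in% names(d)) d$LOD <- d$LLOQ / 2
  if (!"OUTLIER" %in% names(d)) d$OUTLIER <- FALSE
  validate_dataset(d)
  d
}

validate_dataset <- function(d) {
  bad <- which(d$TIME < 0)
  if (length(bad))
    stop("negative TIME in row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  obs <- d$EVID == 0L
  bad <- which(obs & d$CENS == "none" & (!is.finite(d$DV) | d$DV <= 0))
  if (length(bad))
    stop("non-positive DV in uncensored row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(obs & d$CENS != "none" & (!is.finite(d$LLOQ) | !is.finite(d$LOD)))
  if (length(bad))
    stop("censored row(s) without LLOQ/LOD bounds: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  key <- function(rows) paste(d$ID[rows], d$OCC[rows], d$ANALYTE[rows])
  dosed <- unique(key(which(d$EVID == 1L)))
  orphan <- which(obs)[!key(which(obs)) %in% dosed]
  if (length(orphan))
    stop("observation row(s) without a matching dose event: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  invisible(d)
}

#' Drop rows flagged as outliers
#'
#' Removes observation rows whose `OUTLIER` flag is set (or listed in
#' `extra_rows`), mirroring the pre-modeling exclusion of aberrant
#' samples; dose events are always kept.
#'
#' @param dataset a PK dataset.
#' @param extra_rows optional integer row indices to drop additionally.
#' @return the filtered dataset.
#' @export
filter_outliers <- function(dataset, extra_rows = NULL) {
  drop <- dataset$OUTLIER & dataset$EVID == 0L
  if (!is.null(extra_rows)) drop[extra_rows] <- dataset$EVID[extra_rows] == 0L
  dataset[!drop, , drop = FALSE]
}

#' Drop late SMX observations
#'
#' Removes SMX observation rows after `cutoff` hours (assay instability
#' made late SMX samples unusable in the original trial); other analytes
#' are untouched.
#'
#' @param dataset a PK dataset.
#' @param cutoff time (h) after which SMX observations are dropped.
#' @return the filtered dataset.
#' @export
filter_smx_late <- function(dataset, cutoff = 12) {
  drop <- dataset$ANALYTE == "SMX" & dataset$EVID == 0L & dataset$TIME > cutoff
  dataset[!drop, , drop = FALSE]
}

#' Write population models to a parameter table CSV
#'
#' Serializes a list of [population_model()] objects to a long CSV with
#' columns `analyte`, `block` (`fixed`, `beta_bw`, `omega`, `gamma`,
#' `resid`, `meta`), `parameter`, `route` and `value`, mirroring the
#' published parameter-table layout (CL, V1, Q, V2, ka, F per route).
#'
#' @param pop_models named list of [population_model()] objects.
#' @param path output CSV path.
#' @export
write_population_table <- function(pop_models, path) {
  rows <- list()
  add <- function(analyte, block, parameter, route, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      analyte = analyte, block = block, parameter = parameter,
      route = route, value = value, stringsAsFactors = FALSE)
  for (an in names(pop_models)) {
    pop <- pop_models[[an]]
    for (nm in names(pop$fixed)) add(an, "fixed", nm, "", unname(pop$fixed[nm]))
    for (rt in names(pop$ka)) add(an, "fixed", "ka", rt, pop$ka[[rt]])
    for (rt in names(pop$f)) add(an, "fixed", "f", rt, pop$f[[rt]])
    for (nm in names(pop$beta_bw)) add(an, "beta_bw", nm, "", pop$beta_bw[[nm]])
    for (nm in names(pop$omega)) add(an, "omega", nm, "", pop$omega[[nm]])
    for (nm in names(pop$gamma)) add(an, "gamma", nm, "", pop$gamma[[nm]])
    add(an, "resid", "a", "", pop$resid_a)
    add(an, "meta", "bw_ref", "", pop$bw_ref)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read population models from a parameter table CSV
#'
#' Inverse of [write_population_table()]. Unknown parameter names, or
#' random-effect entries for parameters without a fixed effect, raise an
#' error.
#'
#' @param path CSV path.
#' @param corr optional named list of correlation matrices per analyte
#'   (see [read_correlation()]).
#' @return named list of [population_model()] objects.
#' @export
read_population_table <- function(path, corr = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "block", "parameter", "route", "value")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("parameter table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  d$route[is.na(d$route)] <- ""
  ok <- c("cl", "v1", "q", "v2", "ka", "f", "a", "bw_ref")
  bad <- setdiff(unique(d$parameter), ok)
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (an in unique(d$analyte)) {
    dd <- d[d$analyte == an, ]
    get_block <- function(block) {
      b <- dd[dd$block == block, ]
      stats::setNames(b$value, ifelse(b$route == "", b$parameter, b$route))
    }
    fx <- dd[dd$block == "fixed" & dd$route == "", ]
    fixed <- stats::setNames(fx$value, fx$parameter)
    ka_rows <- dd[dd$block == "fixed" & dd$parameter == "ka" & dd$route != "", ]
    f_rows <- dd[dd$block == "fixed" & dd$parameter == "f" & dd$route != "", ]
    ka <- if (nrow(ka_rows)) stats::setNames(ka_rows$value, ka_rows$route)
    f <- if (nrow(f_rows)) stats::setNames(f_rows$value, f_rows$route)
    omega <- get_block("omega")
    gamma <- get_block("gamma")
    have_fixed <- c(names(fixed), if (!is.null(ka)) "ka", if (!is.null(f)) "f")
    bad_re <- setdiff(c(names(omega), names(gamma)), have_fixed)
    if (length(bad_re))
      stop("random effect on parameter(s) without a fixed effect for ", an,
           ": ", paste(bad_re, collapse = ", "), call. = FALSE)
    a <- dd$value[dd$block == "resid"]
    if (length(a) != 1L)
      stop("exactly one residual error 'a' required for ", an, call. = FALSE)
    bw_ref <- dd$value[dd$block == "meta" & dd$parameter == "bw_ref"]
    out[[an]] <- population_model(
      an, fixed = fixed, ka = ka, f = f,
      beta_bw = if (length(get_block("beta_bw"))) get_block("beta_bw"),
      omega = if (length(omega)) omega,
      gamma = if (length(gamma)) gamma,
      corr = corr[[an]],
      resid_a = a,
      bw_ref = if (length(bw_ref)) bw_ref else 31.1)
  }
  out
}

#' Read a random-effect correlation matrix from CSV
#'
#' Square CSV with header and row names equal to the random-effect
#' parameter names; must be symmetric with unit diagonal.
#'
#' @param path CSV path.
#' @return a correlation matrix.
#' @export
read_correlation <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("correlation matrix must be square with matching dimnames",
         call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8)
    stop("correlation matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(m) - 1) > 1e-8))
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  m
}

#' Path to the shipped pig population parameter table
#'
#' The fitted parameter table for the four analytes shipped with the
#' package; `read_population_table(pig_parameter_file())` equals
#' [pig_population_models()].
#'
#' @return file path.
#' @export
pig_parameter_file <- function() {
  system.file("extdata", "popmodel_pigs.csv", package = "tmpsulfa",
              mustWork = TRUE)
}
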