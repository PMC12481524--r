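#' Percentage plasma protein binding
#'
#' `PB% = (total - free) / total * 100` from paired total and free
#' (ultrafiltrate) plasma concentrations.
#'
#' @param total total plasma concentration (ug/mL), > 0.
#' @param free free (unbound) plasma concentration (ug/mL), in `[0, total]`.
#' @return bound percentage in `[0, 100]`; vectorized.
#' @export
pb_percent <- function(total, free) {
  if (any(total <= 0)) stop("'total' must be positive", call. = FALSE)
  if (any(free < 0) || any(free > total))
    stop("'free' must lie in [0, total]", call. = FALSE)
  (total - free) / total * 100
}

#' Unbound fraction from bound percentage
#'
#' `fu = 1 - PB/100`; only the unbound fraction of a sulfonamide or
#' trimethoprim is microbiologically active.
#'
#' @param pb bound percentage in `[0, 100]`.
#' @return unbound fraction in `[0, 1]`; vectorized.
#' @export
fu_from_pb <- function(pb) {
  if (any(pb < 0) || any(pb > 100))
    stop("'pb' must lie in [0, 100]", call. = FALSE)
  1 - pb / 100
}

#' Convert total to free concentrations (linear binding)
#'
#' Multiplies a total-concentration series by the mean unbound fraction,
#' assuming binding is linear over the concentration range so a single
#' mean `fu` applies (no per-pig binding variability).
#'
#' @param total total concentrations (ug/mL).
#' @param fu unbound fraction in `[0, 1]`.
#' @return free concentrations.
#' @export
free_concentration <- function(total, fu) {
  if (length(fu) != 1L || fu < 0 || fu > 1)
    stop("'fu' must be a single fraction in [0, 1]", call. = FALSE)
  total * fu
}

#' Measured protein binding of the four analytes in pig plasma
#'
#' Mean in-vivo bound percentages (with their SDs) and the unbound
#' fractions used for the free-ratio simulations. The stored `fu` values
#' are the ones applied in the simulation workflow (for TMP the rounded
#' working value 0.489 is kept, alongside `1 - pb/100` computable from
#' `pb_mean`).
#'
#' @return data.frame with columns `analyte`, `pb_mean`, `pb_sd`, `fu`.
#' @export
binding_table <- function() {
  data.frame(
    analyte = c("SDZ", "SMX", "SDMX", "TMP"),
    pb_mean = c(29.2, 57.3, 94.1, 51.2),
    pb_sd = c(9.1, 7.9, 3.1, 9.7),
    fu = c(0.708, 0.427, 0.059, 0.489),
    stringsAsFactors = FALSE)
}

#' Look up the working unbound fraction of an analyte
#' @param analyte one of `"SDZ"`, `"SMX"`, `"SDMX"`, `"TMP"`.
#' @return the unbound fraction used in simulations.
#' @export
fu_of <- function(analyte) {
  tab <- binding_table()
  i <- match(analyte, tab$analyte)
  if (is.na(i)) stop("unknown analyte '", analyte, "'", call. = FALSE)
  tab$fu[i]
}
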