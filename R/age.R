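#' Age unit conversion factors
#'
#' Multiplicative factors taking a reported age value to years, per unit
#' code as used in the quarterly extracts: decades (`DEC`), years (`YR`),
#' months (`MON`), weeks (`WK`), days (`DY`) and hours (`HR`). The
#' calendar divisors (12, 52, 365, 8760) are the conventional ones.
#'
#' @return A tibble with columns `unit_code` and `to_years`.
#' @export
#' @examples
#' age_unit_factors()
age_unit_factors <- function() {
  tibble(
    unit_code = c("DEC", "YR", "MON", "WK", "DY", "HR"),
    to_years  = c(10, 1, 1 / 12, 1 / 52, 1 / 365, 1 / 8760)
  )
}

#' Normalize reported ages to years
#'
#' Converts a reported age value plus unit code to age in years. Unknown
#' unit codes, missing values, and results outside the plausibility bound
#' of 0--150 years all yield `NA`: an implausible age must not poison
#' downstream duplicate matching. The function is total and idempotent on
#' already-normalized values (unit `"YR"`).
#'
#' @param value Numeric vector (or character coercible to numeric) of
#'   reported age values.
#' @param unit_code Character vector of unit codes (`DEC`, `YR`, `MON`,
#'   `WK`, `DY`, `HR`); anything else maps to `NA`.
#' @return Numeric vector of ages in years, `NA` where undefined.
#' @export
#' @examples
#' normalize_age(c(25, 24, 3), c("YR", "MON", "DEC"))
normalize_age <- function(value, unit_code) {
  value <- suppressWarnings(as.numeric(blank_to_na(value)))
  unit_code <- toupper(trimws(as.character(unit_code)))
  units <- age_unit_factors()
  fac <- units$to_years[match(unit_code, units$unit_code)]
  out <- value * fac
  out[!is.na(out) & (out < 0 | out > 150)] <- NA_real_
  out
}
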