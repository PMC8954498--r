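#' Country alias lookup table
#'
#' A bundled alias table mapping reporter-country strings as they appear
#' in spontaneous-report extracts (ISO alpha-2 codes, full English names,
#' and common variants) to ISO 3166-1 alpha-2 codes. Matching elsewhere is
#' case-insensitive on the squished string.
#'
#' @return A tibble with columns `alias` (uppercase) and `code`.
#' @export
country_alias_table <- function() {
  base <- tibble::tribble(
    ~code, ~name,
    "US", "UNITED STATES OF AMERICA",
    "GB", "UNITED KINGDOM",
    "JP", "JAPAN",
    "CA", "CANADA",
    "FR", "FRANCE",
    "DE", "GERMANY",
    "IT", "ITALY",
    "BR", "BRAZIL",
    "ES", "SPAIN",
    "AU", "AUSTRALIA",
    "NL", "THE NETHERLANDS",
    "CN", "CHINA",
    "CH", "SWITZERLAND",
    "SE", "SWEDEN",
    "IN", "INDIA",
    "CO", "COLOMBIA",
    "TR", "TURKEY",
    "BE", "BELGIUM",
    "AR", "ARGENTINA",
    "PL", "POLAND",
    "MX", "MEXICO",
    "KR", "REPUBLIC OF KOREA",
    "DK", "DENMARK",
    "NO", "NORWAY",
    "FI", "FINLAND",
    "PT", "PORTUGAL",
    "IE", "IRELAND",
    "AT", "AUSTRIA",
    "GR", "GREECE",
    "ZA", "SOUTH AFRICA",
    "NZ", "NEW ZEALAND",
    "IL", "ISRAEL",
    "RU", "RUSSIAN FEDERATION",
    "SA", "SAUDI ARABIA",
    "MY", "MALAYSIA",
    "SG", "SINGAPORE",
    "TH", "THAILAND",
    "PH", "PHILIPPINES",
    "EG", "EGYPT",
    "JO", "JORDAN"
  )
  extra <- tibble::tribble(
    ~alias, ~code,
    "USA", "US",
    "UNITED STATES", "US",
    "U.S.A.", "US",
    "GREAT BRITAIN", "GB",
    "ENGLAND", "GB",
    "NETHERLANDS", "NL",
    "HOLLAND", "NL",
    "SOUTH KOREA", "KR",
    "KOREA, REPUBLIC OF", "KR",
    "RUSSIA", "RU",
    "TURKIYE", "TR"
  )
  dplyr::bind_rows(
    tibble(alias = base$code, code = base$code),
    tibble(alias = base$name, code = base$code),
    extra
  ) |>
    dplyr::distinct(.data$alias, .keep_all = TRUE)
}

#' Standardize reporter-country strings to ISO 3166 alpha-2 codes
#'
#' Case-insensitive lookup over [country_alias_table()]. Unmatched values
#' become `NA`; the tally of distinct unmatched strings is attached as the
#' `"unmatched"` attribute so a curation run can log them.
#'
#' @param raw Character vector of raw country entries (codes, full names,
#'   or arbitrary text).
#' @param aliases Alias table; defaults to the bundled one.
#' @return Character vector of alpha-2 codes (`NA` where unmatched), with
#'   attribute `unmatched`: a named integer tally of unmatched inputs.
#' @export
#' @examples
#' normalize_country(c("US", "United States of America", "XYZLAND"))
normalize_country <- function(raw, aliases = country_alias_table()) {
  key <- squish_upper(blank_to_na(raw))
  code <- aliases$code[match(key, aliases$alias)]
  unmatched <- key[!is.na(key) & is.na(code)]
  out <- code
  attr(out, "unmatched") <- if (length(unmatched)) {
    sort(table(unmatched), decreasing = TRUE)
  } else {
    table(character(0))
  }
  out
}
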