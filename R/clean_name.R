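# dosage-form / filler tokens removed by the deep clean
DOSAGE_FORM_STOPLIST <- c(
  "TABLET", "TABLETS", "CAPSULE", "CAPSULES", "SUPPOSITORY", "SUPPOSITORIES",
  "INJECTION", "INJECTABLE", "I.V.", "IV", "ORAL", "SOLUTION", "SUSPENSION",
  "SYRUP", "CREAM", "OINTMENT", "GEL", "DROPS", "PATCH", "SPRAY", "INHALER",
  "I.V", "UNIT DOSE", "UNIT-DOSE", "UNKNOWN", "NOS", "LONG-ACTING",
  "EXTENDED RELEASE"
)

minimal_clean_once <- function(x) {
  x <- toupper(x)
  x <- stringr::str_replace_all(x, "/\\d{3,}/", " ")      # trailing register codes
  x <- stringr::str_replace_all(x, "[;|]", " ")           # list separators
  x <- stringr::str_replace_all(x, "[?\"*#!]", "")        # stray symbols
  # unmatched parentheses: drop all paren characters
  unbal <- stringr::str_count(x, "\\(") != stringr::str_count(x, "\\)")
  x[unbal] <- stringr::str_replace_all(x[unbal], "[()]", " ")
  # strip junk characters hanging at either end
  x <- stringr::str_replace_all(x, "^[-/:;,.+ ]+|[-/:;,.+ ]+$", "")
  stringr::str_squish(x)
}

# separator runs dangling at either end (left behind by token removal);
# embedded single separators (combination names "X / Y", codes "CC-292")
# are kept
strip_separator_runs <- function(x) {
  for (i in 1:3) {
    x <- stringr::str_replace_all(x, "^[-/:;,. ]+|[-/:;,. ]+$", "")
    x <- stringr::str_replace_all(x, "\\s[-:;,.]+\\s", " ")
    x <- stringr::str_squish(x)
  }
  x
}

deep_clean_once <- function(x) {
  x <- minimal_clean_once(x)
  # parenthesized echo of the head: "X (X)" -> "X"
  x <- stringr::str_replace(x, "^(.+?)\\s*\\(\\s*\\1\\s*\\)", "\\1")
  # manufacturer tags delimited by carets
  x <- stringr::str_replace_all(x, "\\^[^^]*\\^", " ")
  x <- stringr::str_replace_all(x, "\\^", " ")
  # strength + unit tokens, e.g. "4MG", "0.5 ML", "10 MG/ML"
  x <- stringr::str_replace_all(
    x, "\\b\\d+(\\.\\d+)?\\s*(MG|MCG|UG|G|KG|ML|L|IU|MEQ|%)(/[A-Z0-9.]+)?\\b", " ")
  # dosage-form and filler tokens
  stop_re <- paste0("\\b(", paste(gsub("([.-])", "\\\\\\1", DOSAGE_FORM_STOPLIST),
                                  collapse = "|"), ")\\b")
  x <- stringr::str_replace_all(x, stop_re, " ")
  x <- stringr::str_replace_all(x, "\\(\\s*\\)", " ")     # now-empty parentheses
  x <- strip_separator_runs(x)
  stringr::str_squish(x)
}

#' Clean a verbatim drug-name string
#'
#' Two cleaning levels used by the mapping cascade. `minimal` uppercases,
#' trims and collapses whitespace, and strips stray symbols and embedded
#' register codes (e.g. `"/01483701/"`). `deep` additionally removes a
#' parenthesized echo of the name (`"X (X)"`), strength/unit tokens
#' (`"4MG"`), dosage-form tokens from a bundled stop-list (`TABLETS`,
#' `SUPPOSITORIES`, `I.V.`, ...), and caret-delimited manufacturer tags
#' (`"^SANDOZ^"`). Both levels are idempotent (applied to a fixpoint).
#'
#' @param verbatim Character vector of raw drug-name strings.
#' @param level `"minimal"` or `"deep"`.
#' @return Character vector of cleaned names.
#' @export
#' @examples
#' clean_name(" aspirin  ", "minimal")
#' clean_name("GALANTAMINE 4MG", "deep")
#' clean_name("LESCOL ^SANDOZ^", "deep")
clean_name <- function(verbatim, level = c("minimal", "deep")) {
  level <- match.arg(level)
  step <- if (level == "minimal") minimal_clean_once else deep_clean_once
  x <- as.character(verbatim)
  x[is.na(x)] <- ""
  for (i in 1:5) {
    nxt <- step(x)
    if (identical(nxt, x)) break
    x <- nxt
  }
  x
}
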