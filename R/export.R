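#' Phrases marking an unknown drug indication
#'
#' The verbatim phrases (in either wording variant) that mark an
#' indication entry as uninformative; such entries are treated as null.
#'
#' @return Character vector of phrases.
#' @export
unknown_indication_phrases <- function() UNKNOWN_INDICATION_PHRASES

#' Remove uninformative indication entries
#'
#' Rows whose indication term is an "unknown indication" phrase
#' (case-insensitive, whitespace-trimmed) are treated as null and
#' deleted.
#'
#' @param indi_table Combined indication tibble with a `pt` column.
#' @return The filtered tibble; attribute `n_removed` gives the count of
#'   rows deleted.
#' @export
clean_indications <- function(indi_table) {
  key <- squish_upper(indi_table$pt)
  drop <- !is.na(key) & key %in% squish_upper(UNKNOWN_INDICATION_PHRASES)
  out <- indi_table[!drop, ]
  attr(out, "n_removed") <- sum(drop)
  out
}

export_table_specs <- function() {
  list(
    DEMOGRAPHICS = "one row per deduplicated report: identifiers, dates, gender, age in years, ISO 3166 country code",
    DRUGS_STANDARDIZED = "one row per drug-ingredient entry: verbatim name, mapping method, matched atom, ingredient; constituents of a multi-ingredient product share the parent DRUG_ID",
    ADVERSE_REACTIONS = "adverse event preferred terms per report",
    DRUG_ADVERSE_REACTIONS_PAIRS = "distinct (report, ingredient, preferred term) triples",
    DRUG_ADVERSE_REACTIONS_COUNT = "distinct (ingredient, preferred term) pairs with report frequency",
    DRUG_INDICATIONS = "drug indications per report; unknown-indication entries deleted",
    CASE_OUTCOMES = "case outcome codes per report",
    THERAPY_DATES = "therapy start/end dates and duration per report drug",
    REPORT_SOURCES = "report source codes per report",
    CONTINGENCY_TABLE = "2x2 cell counts a, b, c, d per (ingredient, preferred term) pair",
    PROPORTIONATE_ANALYSIS = "PRR, ROR, Yates chi-squared, information component with interval bounds per pair"
  )
}

#' Export the curated dataset as eleven text tables
#'
#' Materializes the curated dataset as eleven tab-delimited UTF-8 text
#' files plus a machine-readable data dictionary and a manifest (row
#' counts, column lists, file checksums, pipeline stage counts). Nulls
#' are written as empty fields. The output directory must be writable
#' before anything is written; a partial export is never left behind on
#' a failed precondition.
#'
#' @param curated A `faers_curation` object from [curate_faers()].
#' @param outdir Output directory.
#' @return An `ExportManifest`-style list (invisibly a side effect of
#'   writing the files), with `tables` (name -> rows, columns, checksum)
#'   and `stages`.
#' @export
export_dataset <- function(curated, outdir) {
  stopifnot(inherits(curated, "faers_curation"))
  parent <- dirname(normalizePath(outdir, mustWork = FALSE))
  if (!dir.exists(outdir) && (!dir.exists(parent) || file.access(parent, 2) != 0)) {
    abort(paste0("output directory is not writable: ", outdir))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) abort(paste0("output directory is not writable: ", outdir))

  ds <- curated$dataset
  indi_clean <- clean_indications(ds$indi)
  ther <- ds$ther |>
    mutate(date_order_flag = !is.na(.data$start_dt) & !is.na(.data$end_dt) &
             nchar(.data$start_dt) == 8 & nchar(.data$end_dt) == 8 &
             .data$start_dt > .data$end_dt)

  tables <- list(
    DEMOGRAPHICS = ds$demo |>
      select(any_of(c("primaryid", "caseid", "caseversion", "i_f_code",
                      "event_dt", "fda_dt", "age_years", "gender",
                      "country_code", "period", "source"))),
    DRUGS_STANDARDIZED = curated$std_drugs |>
      select(any_of(c("drug_id", "primaryid", "drug_seq", "role_code",
                      "verbatim_name", "method", "matched_rxaui",
                      "ingredient_rxaui", "ingredient_name",
                      "exception_flag", "period"))),
    ADVERSE_REACTIONS = ds$reac,
    DRUG_ADVERSE_REACTIONS_PAIRS = curated$pairs,
    DRUG_ADVERSE_REACTIONS_COUNT = curated$contingency |>
      select(any_of(c("ingredient_rxaui", "ingredient_name", "pt", "a"))) |>
      rename(frequency = "a"),
    DRUG_INDICATIONS = indi_clean,
    CASE_OUTCOMES = ds$outc,
    THERAPY_DATES = ther,
    REPORT_SOURCES = ds$rpsr,
    CONTINGENCY_TABLE = curated$contingency,
    PROPORTIONATE_ANALYSIS = tidy(curated$signals)
  )

  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(outdir, paste0(nm, ".txt"))
    readr::write_tsv(tables[[nm]], p, na = "")
    paths[nm] <- p
  }

  dictionary <- purrr::imap(tables, function(tab, nm) {
    list(description = export_table_specs()[[nm]],
         columns = names(tab))
  })
  jsonlite::write_json(dictionary, file.path(outdir, "data_dictionary.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  manifest <- list(
    tables = purrr::imap(tables, function(tab, nm) {
      list(rows = nrow(tab), columns = names(tab),
           md5 = unname(tools::md5sum(paths[nm])))
    }),
    stages = curated$audit,
    indications_removed = attr(indi_clean, "n_removed"),
    config = curated$config
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
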