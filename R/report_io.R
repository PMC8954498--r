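#' Describe one quarterly extract
#'
#' Bundles the file paths of a single quarterly data extract. A quarter
#' must provide at least the demographic (`DEMO`), drug (`DRUG`) and
#' reaction (`REAC`) tables: every report carries at least one drug and
#' one reaction. `INDI`, `THER`, `OUTC`, `RPSR` and a deleted-case list
#' are optional.
#'
#' @param period Quarter label matching `YYYYQ[1-4]`, e.g. `"2012Q1"`.
#' @param files Named character vector/list of file paths; names from
#'   `DEMO`, `DRUG`, `REAC`, `INDI`, `THER`, `OUTC`, `RPSR`, `DELETED`
#'   (case-insensitive).
#' @return A `faers_quarter` object.
#' @export
faers_quarter <- function(period, files) {
  if (length(period) != 1L || !is_period(period)) {
    abort("`period` must be a single label matching YYYYQ[1-4], e.g. \"2004Q1\"")
  }
  files <- as.list(files)
  names(files) <- toupper(names(files))
  bad <- setdiff(names(files), c(TABLE_KINDS, "DELETED"))
  if (length(bad)) abort(paste0("unknown table kind(s): ", paste(bad, collapse = ", ")))
  for (kind in c("DEMO", "DRUG", "REAC")) {
    if (is.null(files[[kind]])) abort(paste0("quarter ", period, " is missing the mandatory ", kind, " file"))
  }
  structure(list(period = period, files = files), class = "faers_quarter")
}

TABLE_KINDS <- c("DEMO", "DRUG", "REAC", "INDI", "THER", "OUTC", "RPSR")

#' @export
print.faers_quarter <- function(x, ...) {
  cat("<faers_quarter> ", x$period, ": ",
      paste(names(x$files), collapse = " "), "\n", sep = "")
  invisible(x)
}

# canonical column names per table kind; keys are lowercased source headers
.col_map <- list(
  demo = c(isr = "primaryid", primaryid = "primaryid", case = "caseid",
           caseid = "caseid", caseversion = "caseversion",
           i_f_cod = "i_f_code", i_f_code = "i_f_code",
           event_dt = "event_dt", fda_dt = "fda_dt",
           age = "age", age_cod = "age_cod",
           sex = "gender", gndr_cod = "gender",
           reporter_country = "country", country = "country"),
  drug = c(isr = "primaryid", primaryid = "primaryid", drug_seq = "drug_seq",
           role_cod = "role_code", role_code = "role_code",
           drugname = "verbatim_name", verbatim_name = "verbatim_name",
           prod_ai = "prod_ai", nda_num = "nda_num"),
  reac = c(isr = "primaryid", primaryid = "primaryid", pt = "pt"),
  indi = c(isr = "primaryid", primaryid = "primaryid",
           indi_drug_seq = "indi_drug_seq", drug_seq = "indi_drug_seq",
           indi_pt = "pt", pt = "pt"),
  ther = c(isr = "primaryid", primaryid = "primaryid",
           dsg_drug_seq = "dsg_drug_seq", drug_seq = "dsg_drug_seq",
           start_dt = "start_dt", end_dt = "end_dt",
           dur = "dur", dur_cod = "dur_cod"),
  outc = c(isr = "primaryid", primaryid = "primaryid",
           outc_cod = "outc_code", outc_code = "outc_code"),
  rpsr = c(isr = "primaryid", primaryid = "primaryid",
           rpsr_cod = "rpsr_code", rpsr_code = "rpsr_code"),
  deleted = c(caseid = "caseid", case = "caseid")
)

# split "$"-delimited lines preserving trailing empty fields
split_dollar <- function(lines) {
  parts <- strsplit(paste0(lines, "\x01"), "$", fixed = TRUE)
  lapply(parts, function(p) {
    p[length(p)] <- sub("\x01$", "", p[length(p)])
    p
  })
}

# parse one "$"-delimited file with header; rows whose field count differs
# from the header are quarantined, never silently dropped
read_dollar_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) abort(paste0("file has no header line: ", path))
  header <- split_dollar(lines[1L])[[1L]]
  header <- tolower(trimws(header))
  body <- lines[-1L]
  parts <- split_dollar(body)
  nf <- lengths(parts)
  ok <- nf == length(header)
  good <- parts[ok]
  data <- if (length(good)) {
    mat <- do.call(rbind, good)
    df <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE), .name_repair = "minimal")
    names(df) <- header
    df |> mutate(across(everything(), blank_to_na))
  } else {
    as_tibble(setNames(rep(list(character(0)), length(header)), header))
  }
  rejects <- tibble(
    line = which(!ok) + 1L,   # physical line number in the file
    n_fields = nf[!ok],
    text = body[!ok]
  )
  list(data = data, rejects = rejects, n_lines = length(body))
}

rename_to_canonical <- function(df, kind) {
  map <- .col_map[[kind]]
  known <- names(df) %in% names(map)
  names(df)[known] <- unname(map[names(df)[known]])
  df
}

#' Parse one quarterly extract
#'
#' Reads every file of a quarterly extract ("$"-delimited ASCII with one
#' header line), harmonizes legacy and current column names onto one
#' canonical schema (the legacy `ISR` key is used verbatim as `primaryid`,
#' with the source system retained), and stamps every row with the quarter
#' label in a `period` column. No rows are filtered: malformed lines
#' (wrong field count) are quarantined with their physical line numbers,
#' and parsed + quarantined always equals the physical data lines.
#'
#' @param quarter A [faers_quarter()] object.
#' @return Named list of tibbles (lowercase table kinds present), with
#'   attributes `audit` (per-table line/parse/reject counts) and
#'   `rejects` (quarantined lines with table kind and line number).
#' @export
read_quarter <- function(quarter) {
  stopifnot(inherits(quarter, "faers_quarter"))
  out <- list()
  audit <- list()
  rejects <- list()
  for (kind in names(quarter$files)) {
    path <- quarter$files[[kind]]
    if (!file.exists(path)) abort(paste0(kind, " file not found: ", path))
    parsed <- read_dollar_file(path)
    lkind <- tolower(kind)
    df <- rename_to_canonical(parsed$data, lkind)
    legacy <- !("caseversion" %in% names(df)) && lkind == "demo"
    df$period <- rep(quarter$period, nrow(df))
    if (lkind == "demo") {
      df$source <- rep(if (legacy) "LAERS" else "FAERS", nrow(df))
    }
    out[[lkind]] <- df
    audit[[lkind]] <- list(n_lines = parsed$n_lines,
                           n_parsed = nrow(df),
                           n_rejected = nrow(parsed$rejects))
    if (nrow(parsed$rejects)) {
      rejects[[lkind]] <- parsed$rejects |> mutate(table = lkind, period = quarter$period)
    }
  }
  attr(out, "audit") <- audit
  attr(out, "rejects") <- if (length(rejects)) bind_rows(rejects) else
    tibble(line = integer(), n_fields = integer(), text = character(),
           table = character(), period = character())
  out
}

empty_table <- function(kind) {
  cols <- switch(kind,
    demo = c("primaryid", "caseid", "caseversion", "i_f_code", "event_dt",
             "fda_dt", "age", "age_cod", "gender", "country", "period", "source"),
    drug = c("primaryid", "drug_seq", "role_code", "verbatim_name",
             "prod_ai", "nda_num", "period"),
    reac = c("primaryid", "pt", "period"),
    indi = c("primaryid", "indi_drug_seq", "pt", "period"),
    ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt", "dur",
             "dur_cod", "period"),
    outc = c("primaryid", "outc_code", "period"),
    rpsr = c("primaryid", "rpsr_code", "period"),
    deleted = c("caseid", "period")
  )
  as_tibble(setNames(rep(list(character(0)), length(cols)), cols))
}

#' Merge parsed quarters into one combined dataset
#'
#' Unions the per-quarter tables into combined tables (the union of rows;
#' schema variants are reconciled by null-filling columns absent from a
#' source era). Legacy demographic rows get `caseversion` 0 and, lacking a
#' case identifier of their own era's semantics, fall back to `primaryid`
#' as `caseid` when none is present. Drug rows receive a globally unique
#' `drug_id` serial in ingest order. Ages are normalized to years and
#' reporter countries to ISO 3166 alpha-2 codes.
#'
#' @param quarters List of [faers_quarter()] objects (each period at most
#'   once; a duplicated period is an error).
#' @return A `faers_dataset`: list of combined tibbles `demo`, `drug`,
#'   `reac`, `indi`, `ther`, `outc`, `rpsr`, `deleted` plus an `audit`
#'   list (row counts per quarter/table, reject lines, unmatched-country
#'   tally).
#' @export
merge_quarters <- function(quarters) {
  if (inherits(quarters, "faers_quarter")) quarters <- list(quarters)
  periods <- vapply(quarters, function(q) q$period, character(1))
  if (anyDuplicated(periods)) {
    abort(paste0("duplicate period supplied: ",
                 paste(unique(periods[duplicated(periods)]), collapse = ", ")))
  }
  parsed <- lapply(quarters, read_quarter)
  kinds <- c(tolower(TABLE_KINDS), "deleted")
  tabs <- lapply(setNames(kinds, kinds), function(k) {
    got <- lapply(parsed, function(p) p[[k]])
    got <- got[!vapply(got, is.null, logical(1))]
    if (!length(got)) return(empty_table(k))
    bind_rows(empty_table(k), bind_rows(got))
  })

  tabs$demo <- tabs$demo |>
    mutate(
      caseversion = {
        cv <- suppressWarnings(as.integer(.data$caseversion))
        as.integer(ifelse(is.na(cv), 0L, cv))
      },
      caseid = ifelse(is.na(.data$caseid), .data$primaryid, .data$caseid),
      age_years = normalize_age(.data$age, .data$age_cod),
      gender = toupper(trimws(.data$gender))
    )
  cc <- normalize_country(tabs$demo$country)
  tabs$demo$country_code <- as.character(cc)
  tabs$drug <- tabs$drug |> mutate(drug_id = seq_len(dplyr::n()), .before = 1)

  audit <- list(
    quarters = periods,
    tables = lapply(parsed, attr, "audit") |> setNames(periods),
    rejects = bind_rows(lapply(parsed, attr, "rejects")),
    country_unmatched = {
      cu <- attr(cc, "unmatched")
      setNames(as.integer(cu), names(cu))
    }
  )
  new_faers_dataset(tabs, audit)
}

new_faers_dataset <- function(tabs, audit = list()) {
  structure(c(tabs, list(audit = audit)), class = "faers_dataset")
}

#' @export
print.faers_dataset <- function(x, ...) {
  cat("<faers_dataset>\n")
  for (k in intersect(c(tolower(TABLE_KINDS), "deleted"), names(x))) {
    cat(sprintf("  %-8s %8d rows\n", k, nrow(x[[k]])))
  }
  invisible(x)
}

#' Remove reports listed in deleted-case files
#'
#' Drops every report whose `caseid` appears in a deleted-case list (the
#' quarterly extracts ship such lists from 2019Q1 onward). Removal is a
#' set difference, hence idempotent; the count removed is recorded.
#'
#' @param x A `faers_dataset` or a demographic tibble with a `caseid`
#'   column.
#' @param deleted_caseids Character vector of case identifiers to remove;
#'   defaults to the dataset's own parsed deleted lists.
#' @return Object of the same type with matching reports removed from
#'   every table; attribute `n_deleted` gives the count of reports
#'   dropped.
#' @export
apply_deleted_cases <- function(x, deleted_caseids = NULL) {
  if (inherits(x, "faers_dataset")) {
    del <- deleted_caseids %||% x$deleted$caseid
    keep <- !(x$demo$caseid %in% del)
    n_del <- sum(!keep)
    ids <- x$demo$primaryid[keep]
    x$demo <- x$demo[keep, ]
    for (k in c("drug", "reac", "indi", "ther", "outc", "rpsr")) {
      x[[k]] <- x[[k]] |> filter(.data$primaryid %in% ids)
    }
    x$audit$deleted_cases_removed <- n_del
    attr(x, "n_deleted") <- n_del
    x
  } else {
    keep <- !(x$caseid %in% (deleted_caseids %||% character(0)))
    out <- x[keep, ]
    attr(out, "n_deleted") <- sum(!keep)
    out
  }
}

#' Write combined tables as tab-delimited text
#'
#' @param dataset A `faers_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named vector of file paths written.
#' @export
write_combined_tables <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kinds <- intersect(c(tolower(TABLE_KINDS), "deleted"), names(dataset))
  paths <- vapply(kinds, function(k) {
    p <- file.path(dir, paste0(toupper(k), "_combined.txt"))
    readr::write_tsv(dataset[[k]], p, na = "")
    p
  }, character(1))
  invisible(paths)
}

#' Read back a combined table written by [write_combined_tables()]
#'
#' @param path Path to a tab-delimited combined table.
#' @return A tibble with all columns as character except known numeric
#'   ones (`caseversion`, `age_years`, `drug_id`).
#' @export
read_combined_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = "", progress = FALSE)
  for (col in intersect(c("caseversion", "drug_id"), names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  if ("age_years" %in% names(df)) df$age_years <- as.numeric(df$age_years)
  df
}
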