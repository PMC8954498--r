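#' Run the full curation pipeline
#'
#' Orchestrates the whole curation in the fixed stage order: parse and
#' merge the quarterly extracts, standardize drug names to single
#' ingredients, deduplicate (latest version per case, deleted-case
#' lists, cross-source matching), build the drug--event contingency
#' table, compute the proportionate-analysis statistics, and optionally
#' export the eleven output tables. Drug mapping runs before
#' cross-source deduplication so that differently written forms of one
#' ingredient compare equal in the duplicate signature; the stage order
#' is recorded in the result. With `checkpoint_dir` set, each stage's
#' result is checkpointed and `resume = TRUE` skips completed stages.
#'
#' @param quarters A list of [faers_quarter()] objects, a single one, or
#'   an already-merged `faers_dataset`.
#' @param vocab A `faers_vocabulary`.
#' @param idd,overrides,nda_table Optional lookup tables for the mapping
#'   cascade.
#' @param null_policy,drug_level Passed to [deduplicate()].
#' @param manual_threshold Passed to [standardize_drugs()].
#' @param continuity,min_a Passed to [proportionate_analysis()].
#' @param outdir If non-`NULL`, export the eleven tables there.
#' @param checkpoint_dir If non-`NULL`, write per-stage checkpoints here.
#' @param resume Reuse existing checkpoints (default FALSE).
#' @return A `faers_curation` object: the deduplicated `dataset`,
#'   `std_drugs`, `mapping_report`, `dedup` result, `pairs`,
#'   `contingency`, `signals`, `audit`, `manifest` (when exported) and
#'   the `config` used.
#' @export
curate_faers <- function(quarters, vocab,
                         idd = NULL, overrides = NULL, nda_table = NULL,
                         null_policy = c("unknown", "match", "mismatch"),
                         drug_level = c("ingredient", "verbatim"),
                         manual_threshold = 200,
                         continuity = 0, min_a = 0,
                         outdir = NULL, checkpoint_dir = NULL, resume = FALSE) {
  null_policy <- match.arg(null_policy)
  drug_level <- match.arg(drug_level)
  config <- list(null_policy = null_policy, drug_level = drug_level,
                 manual_threshold = manual_threshold, continuity = continuity,
                 min_a = min_a,
                 stage_order = c("parse_merge", "map_drugs", "dedup",
                                 "contingency", "stats", "export"))

  ckpt <- function(name, compute) {
    if (is.null(checkpoint_dir)) return(compute())
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(checkpoint_dir, paste0(name, ".rds"))
    if (resume && file.exists(path)) return(readRDS(path))
    val <- compute()
    saveRDS(val, path)
    val
  }

  dataset <- if (inherits(quarters, "faers_dataset")) quarters else {
    ckpt("parse_merge", function() merge_quarters(quarters))
  }

  std <- ckpt("map_drugs", function() {
    standardize_drugs(dataset$drug, vocab, idd = idd, overrides = overrides,
                      nda_table = nda_table, manual_threshold = manual_threshold)
  })

  dd <- ckpt("dedup", function() {
    deduplicate(dataset, std$drugs, null_policy = null_policy,
                drug_level = drug_level)
  })

  pairs <- ckpt("contingency", function() {
    drug_event_pairs(dd$std_drugs, dd$dataset$reac)
  })
  contingency <- build_contingency(pairs)

  signals <- ckpt("stats", function() {
    proportionate_analysis(contingency, continuity = continuity, min_a = min_a)
  })

  audit <- list(
    parse = dataset$audit,
    mapping = std$report[c("n_rows", "n_mapped", "mapped_fraction")],
    dedup = dd$audit,
    n_pairs = nrow(contingency)
  )
  res <- structure(list(
    dataset = dd$dataset, std_drugs = dd$std_drugs,
    mapping_report = std$report, dedup = dd,
    pairs = pairs, contingency = contingency, signals = signals,
    audit = audit, config = config, manifest = NULL
  ), class = "faers_curation")

  if (!is.null(outdir)) {
    res$manifest <- export_dataset(res, outdir)
  }
  res
}

#' Distinct report--ingredient--event triples
#'
#' The pair universe the contingency table counts over: every
#' deduplicated report contributes each (mapped ingredient, reaction
#' preferred term) combination once.
#'
#' @param std_drugs Standardized drug tibble (mapped rows only are
#'   used).
#' @param reac Combined reaction tibble.
#' @return Tibble with `primaryid`, `ingredient_rxaui`,
#'   `ingredient_name`, `pt`.
#' @export
drug_event_pairs <- function(std_drugs, reac) {
  drugs <- std_drugs |>
    filter(!is.na(.data$ingredient_rxaui)) |>
    distinct(.data$primaryid, .data$ingredient_rxaui, .data$ingredient_name)
  events <- reac |>
    mutate(pt = stringr::str_squish(.data$pt)) |>
    filter(!is.na(.data$pt), .data$pt != "") |>
    distinct(.data$primaryid, .data$pt)
  inner_join(drugs, events, by = "primaryid", relationship = "many-to-many")
}

#' @export
print.faers_curation <- function(x, ...) {
  cat("<faers_curation>\n")
  cat("  reports:", x$audit$dedup$n_input, "->", x$audit$dedup$n_output, "\n")
  cat(sprintf("  drug rows mapped: %.1f%%\n", 100 * x$audit$mapping$mapped_fraction))
  cat("  drug-event pairs:", x$audit$n_pairs, "\n")
  invisible(x)
}

#' One-row summaries of pipeline objects
#'
#' `glance()` methods for the fitted pipeline objects, in the style of
#' model-summary one-liners: counts per curation stage for a
#' `faers_curation`, mapping totals for a `faers_drug_map`.
#'
#' @param x A `faers_curation` or `faers_drug_map`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.faers_curation <- function(x, ...) {
  a <- x$audit$dedup
  tibble(
    n_reports_raw = a$n_input,
    n_stage1_removed = a$stage1_removed,
    n_deleted_removed = a$deleted_removed,
    n_cross_removed = a$cross_removed,
    n_reports = a$n_output,
    mapped_fraction = x$audit$mapping$mapped_fraction,
    n_pairs = x$audit$n_pairs
  )
}

#' @export
tidy.faers_curation <- function(x, ...) tidy(x$signals)
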