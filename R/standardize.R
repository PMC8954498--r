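# vocabulary name index with the ambiguity tie-break baked in:
# prefer primary-source ingredient-level atoms, then primary-source atoms,
# then ingredient-level atoms of any source, then the lowest rxaui
vocab_name_index <- function(vocab) {
  cn <- vocab$concepts
  pri <- ifelse(cn$sab == "RXNORM" & cn$tty %in% INGREDIENT_TTYS, 1L,
         ifelse(cn$sab == "RXNORM", 2L,
         ifelse(cn$tty %in% INGREDIENT_TTYS, 3L, 4L)))
  tibble(name_key = cn$name_key, rxaui = cn$rxaui, priority = pri,
         rxaui_num = suppressWarnings(as.numeric(cn$rxaui))) |>
    arrange(.data$name_key, .data$priority, .data$rxaui_num, .data$rxaui) |>
    distinct(.data$name_key, .keep_all = TRUE)
}

#' Exact string match against the vocabulary
#'
#' Looks a (cleaned) name up in the vocabulary by exact match on the
#' case-folded, whitespace-collapsed string. When several atoms share a
#' name, primary-source ingredient-level atoms win, then primary-source
#' atoms, then ingredient-level atoms, then the lowest `rxaui`.
#'
#' @param name Character vector of names to look up.
#' @param vocab A `faers_vocabulary`.
#' @return Character vector of matched rxauis (`NA` where unmatched).
#' @export
exact_match <- function(name, vocab) {
  idx <- vocab_name_index(vocab)
  idx$rxaui[match(squish_upper(name), idx$name_key)]
}

#' Map drug entries via their new-drug-application number
#'
#' @param nda_num Character vector of application numbers (may be `NA`).
#' @param nda_table Tibble with columns `nda_num`, `rxaui`.
#' @return Character vector of rxauis (`NA` where no mapping).
#' @export
map_by_nda <- function(nda_num, nda_table) {
  if (is.null(nda_table) || nrow(nda_table) == 0L) {
    return(rep(NA_character_, length(nda_num)))
  }
  key <- trimws(as.character(nda_num))
  key[key == ""] <- NA_character_
  nda_table$rxaui[match(key, trimws(nda_table$nda_num))]
}

lookup_two_col <- function(name, table, key_col) {
  if (is.null(table) || nrow(table) == 0L) return(rep(NA_character_, length(name)))
  table$rxaui[match(squish_upper(name), squish_upper(table[[key_col]]))]
}

#' Map verbatim drug names through the standardization cascade
#'
#' Applies the lookup cascade in fixed order, first hit wins:
#' application-number mapping (`NDA`), exact vocabulary match on the
#' minimally cleaned name (`EXACT`), trade-name dictionary (`IDD`),
#' manual override table (`MANUAL`), then exact vocabulary match
#' (`CLEANED_EXACT`) and trade-name dictionary (`CLEANED_IDD`) on the
#' deeply cleaned name; otherwise `UNMAPPED`. The cascade is exact-lookup
#' only — no fuzzy matching — so adding rows to the dictionary or
#' override tables can only map more names, never fewer.
#'
#' @param verbatim_name Character vector of raw drug-name strings.
#' @param nda_num Character vector of application numbers, same length
#'   (or `NULL`).
#' @param vocab A `faers_vocabulary`.
#' @param idd Trade-name dictionary tibble (`trade_name`, `rxaui`) or `NULL`.
#' @param overrides Manual override tibble (`verbatim_name`, `rxaui`) or `NULL`.
#' @param nda_table Application-number tibble (`nda_num`, `rxaui`) or `NULL`.
#' @return Tibble with columns `verbatim_name`, `matched_rxaui`, `method`.
#' @export
cascade_map <- function(verbatim_name, nda_num = NULL, vocab,
                        idd = NULL, overrides = NULL, nda_table = NULL) {
  n <- length(verbatim_name)
  if (is.null(nda_num)) nda_num <- rep(NA_character_, n)
  rxaui <- rep(NA_character_, n)
  method <- rep("UNMAPPED", n)

  take <- function(cand, tag) {
    hit <- is.na(rxaui) & !is.na(cand)
    rxaui[hit] <<- cand[hit]
    method[hit] <<- tag
  }

  minimal <- clean_name(verbatim_name, "minimal")
  take(map_by_nda(nda_num, nda_table), "NDA")
  take(exact_match(minimal, vocab), "EXACT")
  take(lookup_two_col(minimal, idd, "trade_name"), "IDD")
  take(lookup_two_col(minimal, overrides, "verbatim_name"), "MANUAL")
  deep <- clean_name(verbatim_name, "deep")
  take(exact_match(deep, vocab), "CLEANED_EXACT")
  take(lookup_two_col(deep, idd, "trade_name"), "CLEANED_IDD")

  tibble(verbatim_name = verbatim_name, matched_rxaui = rxaui, method = method)
}

# ingredient closure for a set of atoms, memoized per distinct rxaui
ingredient_closure <- function(rxauis, vocab, max_hops = 5) {
  u <- unique(rxauis[!is.na(rxauis)])
  res <- lapply(u, normalize_to_ingredients, vocab = vocab, max_hops = max_hops)
  names(res) <- u
  res
}

#' Standardize a combined drug table to single active ingredients
#'
#' Runs the full cascade over every drug row, resolves each matched atom
#' to ingredient-level entries (one output row per constituent of a
#' multi-ingredient product, all sharing the parent `drug_id`), and
#' reports per-method counts, the mapped fraction, frequent unmapped
#' names for manual curation, and rows whose reported active-ingredient
#' field disagrees with the verbatim mapping (the verbatim mapping wins;
#' the conflict is only logged).
#'
#' @param drug_table Combined drug tibble with columns `drug_id`,
#'   `primaryid`, `drug_seq`, `verbatim_name`, optionally `prod_ai`,
#'   `nda_num`, `role_code`, `period`.
#' @param vocab A `faers_vocabulary`.
#' @param idd,overrides,nda_table Lookup tables as in [cascade_map()].
#' @param manual_threshold Unmapped names with frequency above this go on
#'   the manual-curation candidate list (default 200).
#' @param max_hops Relation-walk bound for ingredient resolution.
#' @return A list of class `faers_drug_map`: `drugs` (the standardized
#'   table, one row per drug-ingredient, `UNMAPPED` rows retained with
#'   `NA` ingredient) and `report` (method counts, mapped fraction,
#'   manual candidates, conflicts).
#' @export
standardize_drugs <- function(drug_table, vocab, idd = NULL, overrides = NULL,
                              nda_table = NULL, manual_threshold = 200,
                              max_hops = 5) {
  stopifnot(all(c("drug_id", "primaryid", "verbatim_name") %in% names(drug_table)))
  nda_num <- if ("nda_num" %in% names(drug_table)) drug_table$nda_num else NULL
  mapped <- cascade_map(drug_table$verbatim_name, nda_num, vocab,
                        idd = idd, overrides = overrides, nda_table = nda_table)
  base <- drug_table |>
    mutate(matched_rxaui = mapped$matched_rxaui, method = mapped$method)

  clo <- ingredient_closure(base$matched_rxaui, vocab, max_hops = max_hops)
  ing_list <- lapply(base$matched_rxaui, function(r) {
    if (is.na(r)) character(0) else clo[[r]]$ingredients
  })
  flags <- vapply(base$matched_rxaui, function(r) {
    if (is.na(r)) "none" else clo[[r]]$exception_flag
  }, character(1), USE.NAMES = FALSE)
  n_ing <- lengths(ing_list)
  # unresolved relation walks degrade to UNMAPPED-equivalent
  unresolved <- flags == "unresolved"
  base$method[unresolved] <- "UNMAPPED"
  base$matched_rxaui[unresolved] <- NA_character_
  n_ing[unresolved] <- 0L
  flags[unresolved] <- "none"

  reps <- pmax(n_ing, 1L)
  out <- base[rep(seq_len(nrow(base)), reps), ]
  out$ingredient_rxaui <- unlist(lapply(seq_along(ing_list), function(i) {
    if (n_ing[i] == 0L) NA_character_ else ing_list[[i]]
  }))
  out$exception_flag <- rep(flags, reps)
  out$ingredient_name <- vocab$concepts$name[
    match(out$ingredient_rxaui, vocab$concepts$rxaui)]
  out <- as_tibble(out)

  # reported active-ingredient field used only as a validator
  conflicts <- tibble(drug_id = integer(), prod_ai = character(),
                      mapped_ingredients = character())
  if ("prod_ai" %in% names(out)) {
    chk <- out |>
      filter(!is.na(.data$prod_ai), !is.na(.data$ingredient_name)) |>
      group_by(.data$drug_id, .data$prod_ai) |>
      summarise(mapped_ingredients = paste(sort(unique(.data$ingredient_name)),
                                           collapse = " / "),
                agree = any(squish_upper(.data$prod_ai) ==
                              squish_upper(.data$ingredient_name)),
                .groups = "drop") |>
      filter(!.data$agree)
    conflicts <- chk |> select(-"agree")
  }

  per_method <- base |> count(.data$method, name = "n_rows")
  n_total <- nrow(base)
  n_mapped <- sum(base$method != "UNMAPPED")
  unmapped_freq <- base |>
    filter(.data$method == "UNMAPPED") |>
    count(.data$verbatim_name, sort = TRUE, name = "n_rows")
  report <- list(
    per_method = per_method,
    n_rows = n_total,
    n_mapped = n_mapped,
    mapped_fraction = if (n_total) n_mapped / n_total else NA_real_,
    manual_candidates = unmapped_freq |> filter(.data$n_rows > manual_threshold),
    unmapped_names = unmapped_freq,
    prod_ai_conflicts = conflicts
  )
  structure(list(drugs = out, report = report), class = "faers_drug_map")
}

#' @export
print.faers_drug_map <- function(x, ...) {
  cat("<faers_drug_map> ", x$report$n_rows, " drug rows, ",
      sprintf("%.1f%% mapped\n", 100 * x$report$mapped_fraction), sep = "")
  print(x$report$per_method)
  invisible(x)
}

#' @rdname glance.faers_curation
#' @export
glance.faers_drug_map <- function(x, ...) {
  tibble(
    n_rows = x$report$n_rows,
    n_mapped = x$report$n_mapped,
    mapped_fraction = x$report$mapped_fraction,
    n_manual_candidates = nrow(x$report$manual_candidates),
    n_prod_ai_conflicts = nrow(x$report$prod_ai_conflicts)
  )
}
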