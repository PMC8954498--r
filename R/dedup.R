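#' Retain the latest report version per case
#'
#' Stage one of deduplication: a case accumulates follow-up report
#' versions under one case identifier; only the most recent is kept.
#' "Most recent" is the maximum `caseversion`, ties broken by maximum
#' `fda_dt` (receipt date), then maximum `primaryid` (numeric value).
#' Rows with a missing `caseid` pass through untouched.
#'
#' @param demo Demographic tibble with `primaryid`, `caseid`,
#'   `caseversion`, `fda_dt`.
#' @return Tibble with exactly one row per non-missing `caseid`;
#'   attribute `n_removed` gives the number of superseded versions
#'   dropped.
#' @export
keep_latest_version <- function(demo) {
  no_case <- demo |> filter(is.na(.data$caseid))
  with_case <- demo |> filter(!is.na(.data$caseid))
  kept <- with_case |>
    mutate(.pid_num = suppressWarnings(as.numeric(.data$primaryid))) |>
    arrange(.data$caseid, desc(.data$caseversion), desc(.data$fda_dt),
            desc(.data$.pid_num), desc(.data$primaryid)) |>
    distinct(.data$caseid, .keep_all = TRUE) |>
    select(-".pid_num")
  out <- bind_rows(kept, no_case)
  attr(out, "n_removed") <- nrow(demo) - nrow(out)
  out
}

sig_set_key <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  paste(sort(unique(x)), collapse = "\x1f")
}

#' Build eight-field case signatures for cross-source matching
#'
#' For every report, assembles the matching key used by cross-source
#' deduplication: two hard keys (the set of administered drugs and the
#' set of adverse-reaction preferred terms) and six soft keys (gender,
#' age in whole years, reporting country, event date, the set of therapy
#' start dates, and the set of indication terms). Text keys are trimmed
#' and case-folded; sets are order-insensitive and deduplicated. Drugs
#' are compared at standardized single-ingredient level by default (so
#' differently written forms of one ingredient match); rows the cascade
#' could not map contribute their cleaned verbatim string so they still
#' discriminate. A report's start-date key is missing exactly when no
#' non-null start date exists for its `primaryid`. Reports lacking drug
#' or reaction rows cannot satisfy the hard keys and are flagged
#' incomplete (excluded from cross-matching).
#'
#' @param demo Demographic tibble (post stage-1 dedup).
#' @param std_drugs Standardized drug tibble from [standardize_drugs()]
#'   (or a raw drug table when `drug_level = "verbatim"`).
#' @param reac,indi,ther The corresponding combined tables.
#' @param drug_level `"ingredient"` (default) or `"verbatim"`.
#' @return Tibble with one row per report: `primaryid`, `fda_dt`,
#'   `drugs_key`, `reactions_key`, the six soft keys, and `complete`.
#' @export
build_signatures <- function(demo, std_drugs, reac, indi, ther,
                             drug_level = c("ingredient", "verbatim")) {
  drug_level <- match.arg(drug_level)
  if (drug_level == "ingredient") {
    tok <- ifelse(!is.na(std_drugs$ingredient_rxaui),
                  std_drugs$ingredient_rxaui,
                  paste0("V:", clean_name(std_drugs$verbatim_name, "minimal")))
  } else {
    tok <- clean_name(std_drugs$verbatim_name, "minimal")
  }
  drug_keys <- tibble(primaryid = std_drugs$primaryid, tok = tok) |>
    group_by(.data$primaryid) |>
    summarise(drugs_key = sig_set_key(.data$tok), .groups = "drop")
  reac_keys <- reac |>
    mutate(pt_n = squish_upper(.data$pt)) |>
    group_by(.data$primaryid) |>
    summarise(reactions_key = sig_set_key(.data$pt_n), .groups = "drop")
  start_keys <- ther |>
    group_by(.data$primaryid) |>
    summarise(start_key = sig_set_key(.data$start_dt), .groups = "drop")
  indi_keys <- indi |>
    mutate(pt_n = squish_upper(.data$pt)) |>
    # an "unknown indication" phrase carries no information; treat as null
    filter(!.data$pt_n %in% squish_upper(UNKNOWN_INDICATION_PHRASES) |
             is.na(.data$pt_n)) |>
    group_by(.data$primaryid) |>
    summarise(indi_key = sig_set_key(.data$pt_n), .groups = "drop")

  demo |>
    transmute(
      primaryid = .data$primaryid,
      fda_dt = .data$fda_dt,
      gender = ifelse(.data$gender %in% c("F", "M"), .data$gender, NA_character_),
      age_r = round(.data$age_years),
      country_code = .data$country_code,
      event_dt = blank_to_na(.data$event_dt)
    ) |>
    left_join(drug_keys, by = "primaryid") |>
    left_join(reac_keys, by = "primaryid") |>
    left_join(start_keys, by = "primaryid") |>
    left_join(indi_keys, by = "primaryid") |>
    mutate(complete = !is.na(.data$drugs_key) & !is.na(.data$reactions_key))
}

soft_cmp <- function(a, b, null_policy) {
  if (is.na(a) || is.na(b)) {
    switch(null_policy, unknown = "unknown", match = "match", mismatch = "mismatch")
  } else if (identical(a, b)) "match" else "mismatch"
}

#' Decide whether two case signatures are duplicates
#'
#' Two reports are duplicates when their drug sets and reaction sets are
#' equal (hard keys) and at most one of the six soft keys mismatches. A
#' soft key missing on either side is, under the default `"unknown"`
#' policy, neither a match nor the one allowed mismatch — it is tallied
#' separately; missingness degrades a criterion, it should not trigger
#' it. Ages match when equal after rounding to whole years; partial
#' dates compare by exact string equality only.
#'
#' @param s1,s2 Single-row signatures from [build_signatures()].
#' @param null_policy `"unknown"` (default), `"match"`, or `"mismatch"`:
#'   how a soft key that is missing on either side is scored.
#' @return List: `duplicate` (logical), `soft_mismatches`, `unknowns`,
#'   `hard_match`.
#' @export
is_duplicate_pair <- function(s1, s2, null_policy = c("unknown", "match", "mismatch")) {
  null_policy <- match.arg(null_policy)
  hard <- identical(s1$drugs_key, s2$drugs_key) &&
    identical(s1$reactions_key, s2$reactions_key) &&
    !is.na(s1$drugs_key) && !is.na(s1$reactions_key)
  soft_fields <- c("gender", "age_r", "country_code", "event_dt",
                   "start_key", "indi_key")
  verdicts <- vapply(soft_fields, function(f) {
    soft_cmp(s1[[f]], s2[[f]], null_policy)
  }, character(1))
  mism <- sum(verdicts == "mismatch")
  unk <- sum(verdicts == "unknown")
  list(duplicate = hard && mism <= 1L,
       soft_mismatches = mism, unknowns = unk, hard_match = hard)
}

# iterative union-find with path halving
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# soft-key mismatch counts for all pairs within one block (matrix form);
# returns two-column matrix of indices (into the block) that form edges
block_edges <- function(block, null_policy) {
  soft_fields <- c("gender", "age_r", "country_code", "event_dt",
                   "start_key", "indi_key")
  m <- nrow(block)
  cols <- lapply(soft_fields, function(f) as.character(block[[f]]))
  idx <- which(upper.tri(matrix(TRUE, m, m)), arr.ind = TRUE)
  mism <- integer(nrow(idx))
  for (col in cols) {
    a <- col[idx[, 1]]
    b <- col[idx[, 2]]
    if (null_policy == "mismatch") {
      mm <- is.na(a) != is.na(b) | (!is.na(a) & !is.na(b) & a != b)
    } else {
      mm <- !is.na(a) & !is.na(b) & a != b
    }
    mism <- mism + mm
  }
  idx[mism <= 1L, , drop = FALSE]
}

#' Find cross-source duplicate groups
#'
#' Restricts candidate pairs to blocks sharing both hard keys (drug set
#' and reaction set must be equal for any duplicate, so blocking loses
#' nothing), scores every pair in a block with the allow-one-mismatch
#' rule, and closes the resulting edges into disjoint groups by
#' union-find (the pairwise relation is not transitive; closure is the
#' conservative choice that yields disjoint groups). Within each group
#' the retained report is the one with maximum `fda_dt`, then maximum
#' `primaryid`.
#'
#' @param signatures Output of [build_signatures()].
#' @inheritParams is_duplicate_pair
#' @return Tibble with one row per report in a multi-member group:
#'   `group_id`, `primaryid`, `retained` (logical), `retained_primaryid`.
#' @export
find_cross_duplicates <- function(signatures, null_policy = c("unknown", "match", "mismatch")) {
  null_policy <- match.arg(null_policy)
  sig <- signatures |> filter(.data$complete)
  if (nrow(sig) == 0L) {
    return(tibble(group_id = integer(), primaryid = character(),
                  retained = logical(), retained_primaryid = character()))
  }
  sig$block <- paste(sig$drugs_key, sig$reactions_key, sep = "\x1e")
  parent <- uf_new(nrow(sig))
  blocks <- split(seq_len(nrow(sig)), sig$block)
  for (rows in blocks) {
    if (length(rows) < 2L) next
    ed <- block_edges(sig[rows, ], null_policy)
    if (nrow(ed) == 0L) next
    for (k in seq_len(nrow(ed))) {
      i <- rows[ed[k, 1]]
      j <- rows[ed[k, 2]]
      ri <- uf_find(parent, i)
      rj <- uf_find(parent, j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(nrow(sig)), function(i) uf_find(parent, i), integer(1))
  sig$root <- root
  groups <- sig |>
    group_by(.data$root) |>
    filter(dplyr::n() > 1L) |>
    mutate(
      retained_primaryid = {
        top_dt <- .data$fda_dt == suppressWarnings(max(.data$fda_dt, na.rm = TRUE)) &
          !is.na(.data$fda_dt)
        if (!any(top_dt)) top_dt <- rep(TRUE, length(top_dt))
        max_id(.data$primaryid[top_dt])
      }
    ) |>
    ungroup()
  if (nrow(groups) == 0L) {
    return(tibble(group_id = integer(), primaryid = character(),
                  retained = logical(), retained_primaryid = character()))
  }
  groups |>
    mutate(group_id = match(.data$root, unique(.data$root)),
           retained = .data$primaryid == .data$retained_primaryid) |>
    select("group_id", "primaryid", "retained", "retained_primaryid") |>
    arrange(.data$group_id, desc(.data$retained), .data$primaryid)
}

#' Deduplicate a combined dataset end to end
#'
#' Applies both deduplication stages to a combined dataset: latest
#' version per case identifier, removal of reports on the deleted-case
#' lists, then cross-source duplicate collapse on the eight-field
#' signature. Non-retained reports are removed from every table by
#' `primaryid`. The audit records counts removed per stage.
#'
#' @param dataset A `faers_dataset` from [merge_quarters()].
#' @param std_drugs Standardized drug tibble (from
#'   [standardize_drugs()]`$drugs`); required for ingredient-level
#'   matching.
#' @inheritParams is_duplicate_pair
#' @inheritParams build_signatures
#' @param apply_deleted Apply the dataset's deleted-case lists (default
#'   TRUE).
#' @return List of class `faers_dedup`: `dataset` (deduplicated; the
#'   standardized drug table filtered alongside as `std_drugs`), `groups`
#'   (cross-duplicate groups), `audit` (per-stage counts).
#' @export
deduplicate <- function(dataset, std_drugs,
                        null_policy = c("unknown", "match", "mismatch"),
                        drug_level = c("ingredient", "verbatim"),
                        apply_deleted = TRUE) {
  null_policy <- match.arg(null_policy)
  drug_level <- match.arg(drug_level)
  n0 <- nrow(dataset$demo)

  demo1 <- keep_latest_version(dataset$demo)
  n_stage1 <- attr(demo1, "n_removed")
  dataset$demo <- demo1

  n_deleted <- 0L
  if (apply_deleted && nrow(dataset$deleted) > 0L) {
    dataset <- apply_deleted_cases(dataset)
    n_deleted <- attr(dataset, "n_deleted")
  }
  ids1 <- dataset$demo$primaryid
  std_drugs <- std_drugs |> filter(.data$primaryid %in% ids1)

  sigs <- build_signatures(dataset$demo, std_drugs, dataset$reac,
                           dataset$indi, dataset$ther, drug_level = drug_level)
  groups <- find_cross_duplicates(sigs, null_policy = null_policy)
  drop_ids <- groups$primaryid[!groups$retained]
  keep <- !(dataset$demo$primaryid %in% drop_ids)
  dataset$demo <- dataset$demo[keep, ]
  ids <- dataset$demo$primaryid
  for (k in c("drug", "reac", "indi", "ther", "outc", "rpsr")) {
    dataset[[k]] <- dataset[[k]] |> filter(.data$primaryid %in% ids)
  }
  std_drugs <- std_drugs |> filter(.data$primaryid %in% ids)

  audit <- list(
    n_input = n0,
    stage1_removed = n_stage1,
    deleted_removed = n_deleted,
    cross_removed = length(drop_ids),
    n_output = nrow(dataset$demo),
    n_groups = if (nrow(groups)) max(groups$group_id) else 0L,
    incomplete_signatures = sum(!sigs$complete)
  )
  structure(list(dataset = dataset, std_drugs = std_drugs,
                 groups = groups, audit = audit),
            class = "faers_dedup")
}

#' @export
print.faers_dedup <- function(x, ...) {
  a <- x$audit
  cat("<faers_dedup> ", a$n_input, " reports in -> ", a$n_output, " out\n",
      "  stage 1 (latest version): -", a$stage1_removed, "\n",
      "  deleted-case lists:       -", a$deleted_removed, "\n",
      "  cross-source duplicates:  -", a$cross_removed,
      " (", a$n_groups, " groups)\n", sep = "")
  invisible(x)
}
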