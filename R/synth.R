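# invented term pools (ordinary clinical words; no licensed terminology list)
reaction_pt_pool <- function() {
  c("Headache", "Nausea", "Dizziness", "Rash", "Pruritus", "Vomiting",
    "Diarrhoea", "Fatigue", "Pyrexia", "Insomnia", "Anxiety", "Tremor",
    "Dyspnoea", "Cough", "Hypotension", "Hypertension aggravated",
    "Tachycardia", "Bradycardia", "Oedema peripheral", "Arthralgia",
    "Myalgia", "Back pain", "Abdominal pain", "Constipation", "Dry mouth",
    "Somnolence", "Confusion", "Syncope", "Palpitations", "Chest pain",
    "Alopecia", "Urticaria", "Blurred vision", "Tinnitus", "Epistaxis",
    "Weight decreased", "Weight increased", "Appetite decreased",
    "Hepatic enzyme increased", "Renal impairment")
}

indication_pt_pool <- function() {
  c("Hypertension", "Diabetes mellitus", "Depression", "Asthma",
    "Rheumatoid arthritis", "Epilepsy", "Migraine", "Osteoporosis",
    "Hyperlipidaemia", "Atrial fibrillation", "Gastrooesophageal reflux",
    "Psoriasis", "Chronic pain", "Anaemia", "Insomnia disorder")
}

UNKNOWN_INDICATION_PHRASES <- c(
  "Product used for unknown indication",
  "Product used for the unknown indication",
  "Drug use for unknown indication",
  "Drug use for the unknown indication"
)

#' Configuration for the synthetic extract generator
#'
#' Defines the study conditions a synthetic run emulates. The default
#' marginal missingness rates are the ones characteristic of the real
#' reporting database: about 11% of gender entries null with 54% female,
#' about 65% of reports from the US with 7% missing country, 46% missing
#' event date, 40% missing age, 42% of reports without any therapy start
#' date, and 12% without an informative indication. Missingness is
#' independent per field.
#'
#' @param n_cases Number of base case reports (>= 1).
#' @param seed Integer seed; the same seed and config give byte-identical
#'   output files.
#' @param quarters Character vector of period labels (`YYYYQn`); quarters
#'   before 2013 are written in the legacy-era file layout.
#' @param rates Named list overriding any of the default marginal rates
#'   (`gender_null`, `female`, `us_share`, `country_null`,
#'   `event_dt_null`, `age_null`, `start_dt_null`, `indication_null`).
#' @param duplicate_rate Fraction of base cases re-emitted as
#'   cross-source duplicates (new report and case identifiers, same
#'   drugs and reactions).
#' @param perturb_one_field If TRUE (default) a duplicate has one
#'   randomly chosen soft field perturbed with probability 0.8 (else it
#'   is an exact copy); duplicates never differ in more than one soft
#'   field and never in drugs or reactions.
#' @param corruption_weights Named weights over the drug-name corruption
#'   operators (see [corrupt_drug_name()]).
#' @param planted_signals List of planted drug--event associations. Each
#'   element is a list with `ingredient` (a vocabulary ingredient name)
#'   and `pt`, plus either exact cell targets `a`, `b`, `c`, `d`
#'   (requiring `a+b+c+d == n_cases` per signal) or probabilistic
#'   targets `p_drug`, `p_event_base` and `or_target` (cases assigned
#'   independently so the true odds ratio equals `or_target`).
#' @param deleted_rate Fraction of base cases whose `caseid` is placed on
#'   a deleted-case list.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_cases = 1000, seed = 42, quarters = "2020Q1",
                         rates = list(), duplicate_rate = 0,
                         perturb_one_field = TRUE,
                         corruption_weights = NULL,
                         planted_signals = list(),
                         deleted_rate = 0) {
  defaults <- list(gender_null = 0.11, female = 0.54, us_share = 0.65,
                   country_null = 0.07, event_dt_null = 0.46,
                   age_null = 0.40, start_dt_null = 0.42,
                   indication_null = 0.12)
  rates <- utils::modifyList(defaults, rates)
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) abort("all rates must lie in [0, 1]")
  if (n_cases < 1) abort("n_cases must be >= 1")
  if (duplicate_rate < 0 || duplicate_rate > 1) abort("duplicate_rate must lie in [0, 1]")
  if (duplicate_rate > 0 && n_cases < 2) abort("duplicate_rate > 0 requires n_cases >= 2")
  if (!all(is_period(quarters))) abort("quarters must match YYYYQ[1-4]")
  w_def <- c(identity = 0.30, case = 0.10, strength = 0.12, form = 0.12,
             echo = 0.08, trade = 0.12, code = 0.06, typo = 0.10)
  if (!is.null(corruption_weights)) {
    w_def[names(corruption_weights)] <- corruption_weights
  }
  for (s in planted_signals) {
    if (!is.null(s$a)) {
      tot <- s$a + s$b + s$c + s$d
      if (any(c(s$a, s$b, s$c, s$d) < 0) || s$a > n_cases) {
        abort("infeasible planted cell target")
      }
      if (tot != n_cases) {
        abort("planted cell targets must satisfy a+b+c+d == n_cases")
      }
    }
  }
  if (length(planted_signals)) {
    used <- sum(vapply(planted_signals, function(s) {
      if (!is.null(s$a)) s$a + s$b + s$c else 0
    }, numeric(1)))
    if (used > n_cases) abort("planted cell targets exceed n_cases")
  }
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 quarters = quarters, rates = rates,
                 duplicate_rate = duplicate_rate,
                 perturb_one_field = isTRUE(perturb_one_field),
                 corruption_weights = w_def,
                 planted_signals = planted_signals,
                 deleted_rate = deleted_rate),
            class = "synth_config")
}

#' Corrupt an ingredient name into a messy verbatim string
#'
#' Applies one corruption operator of the styles seen in real verbatim
#' drug-name entries: case change, appended strength (`"4MG"`), appended
#' dosage form (`"TABLETS"`), parenthesized echo (`"X (X)"`),
#' substitution by a foreign trade name from the dictionary, an appended
#' register code (`"/01483701/"`), or a single-character typo. All
#' operators except `typo` are recoverable by the mapping cascade.
#'
#' @param name Ingredient (or product) name to corrupt.
#' @param operator Operator name; if `NULL`, one is sampled using
#'   `weights`.
#' @param idd Trade-name dictionary used by the `trade` operator.
#' @param true_rxaui The atom the name stands for (needed by `trade` to
#'   pick a trade name of the same entity).
#' @param weights Named sampling weights (see [synth_config()]).
#' @return List: `verbatim`, `operator` (the operator actually applied),
#'   `coverable` (whether the cascade can recover the ingredient).
#' @export
corrupt_drug_name <- function(name, operator = NULL, idd = mini_idd(),
                              true_rxaui = NA_character_, weights = NULL) {
  ops <- c("identity", "case", "strength", "form", "echo", "trade", "code", "typo")
  if (is.null(operator)) {
    w <- c(identity = 0.30, case = 0.10, strength = 0.12, form = 0.12,
           echo = 0.08, trade = 0.12, code = 0.06, typo = 0.10)
    if (!is.null(weights)) w[names(weights)] <- weights
    operator <- sample(ops, 1L, prob = w[ops])
  }
  operator <- match.arg(operator, ops)
  if (operator == "trade") {
    cand <- idd$trade_name[idd$rxaui == true_rxaui]
    if (!length(cand)) operator <- "identity" else {
      return(list(verbatim = cand[sample.int(length(cand), 1L)],
                  operator = "trade", coverable = TRUE))
    }
  }
  verbatim <- switch(operator,
    identity = name,
    case = {
      x <- tolower(name)
      substr(x, 1, 1) <- toupper(substr(x, 1, 1))
      x
    },
    strength = paste0(name, " ", sample(c("4MG", "10MG", "25 MG", "100MG", "0.5 ML"), 1L)),
    form = paste0(name, " ", sample(c("TABLETS", "CAPSULES", "I.V.", "ORAL SOLUTION",
                                      "TABLETS/SUPPOSITORIES"), 1L)),
    echo = paste0(name, " (", name, ")"),
    code = paste0(name, " /0", sample(1000000:9999999, 1L), "/"),
    typo = {
      pos <- sample.int(nchar(name), 1L)
      letter <- sample(setdiff(LETTERS, substr(name, pos, pos)), 1L)
      paste0(substr(name, 1, pos - 1L), letter,
             substr(name, pos + 1L, nchar(name)))
    }
  )
  list(verbatim = verbatim, operator = operator, coverable = operator != "typo")
}

rand_date <- function(n, from = as.Date("2004-01-01"), to = as.Date("2021-09-30")) {
  d <- from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
  format(d, "%Y%m%d")
}

quarter_fda_dt <- function(period) {
  y <- as.integer(substr(period, 1, 4))
  q <- as.integer(substr(period, 6, 6))
  sprintf("%04d%02d%02d", y, 3L * q - 2L + sample(0:2, length(period), replace = TRUE),
          sample(1:28, length(period), replace = TRUE))
}

# ---- generation -----------------------------------------------------------

#' Generate synthetic reports with a ground-truth ledger
#'
#' Produces an in-memory synthetic reporting dataset under the study
#' conditions of a [synth_config()]: case demographics with the
#' configured marginal missingness, drug mentions whose verbatim strings
#' are corrupted ingredient names with known truth, reactions,
#' indications, therapy dates, outcomes and report sources, optional
#' planted drug--event signals, and optional cross-source duplicates that
#' differ from their source case in at most one soft field and never in
#' drugs or reactions. Distinct cases are constructed to violate the
#' duplicate definition (hard-key difference or >= 3 soft-field
#' differences whenever hard keys collide), so ground-truth recall and
#' false-merge rates are well defined.
#'
#' @param config A [synth_config()].
#' @param vocab,idd,nda_table Vocabulary and lookup tables (defaults:
#'   the bundled miniature ones).
#' @return List of class `synth_reports`: `tables` (canonical combined
#'   tables), `ledger` (`duplicate_groups`, `name_map`, `signals`,
#'   `deleted_caseids`), `config`.
#' @export
generate_reports <- function(config, vocab = mini_vocabulary(),
                             idd = mini_idd(), nda_table = mini_nda_table()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_reports_impl(config, vocab, idd, nda_table))
}

generate_reports_impl <- function(config, vocab, idd, nda_table) {
  n <- config$n_cases
  r <- config$rates
  cn <- vocab$concepts
  ings <- cn |> filter(.data$tty == "IN", .data$sab == "RXNORM")
  combos <- cn |> filter(.data$tty == "MIN")
  pts <- reaction_pt_pool()
  indis <- indication_pt_pool()
  countries <- country_alias_table() |> distinct(.data$code)
  other_codes <- setdiff(countries$code, "US")

  planted <- config$planted_signals
  planted_x <- vapply(planted, function(s) s$ingredient, character(1)) |> unique()
  planted_y <- vapply(planted, function(s) s$pt, character(1)) |> unique()
  bg_ing <- ings |> filter(!.data$name %in% planted_x)
  bg_pts <- setdiff(pts, planted_y)
  x_aui <- setNames(ings$rxaui[match(planted_x, ings$name)], planted_x)
  if (length(planted_x) && anyNA(x_aui)) abort("planted ingredient not in vocabulary")

  # --- membership: drug/event assignment per case --------------------------
  drug_sets <- vector("list", n)    # character vectors of atom rxauis (truth)
  event_sets <- vector("list", n)
  cell_mode <- length(planted) && !is.null(planted[[1]]$a)
  if (cell_mode) {
    cursor <- 0L
    for (s in planted) {
      xa <- x_aui[[s$ingredient]]
      slices <- list(
        A = list(k = s$a, drug = "X", event = "Y"),
        B = list(k = s$b, drug = "other", event = "Y"),
        C = list(k = s$c, drug = "X", event = "other")
      )
      for (sl in slices) {
        if (sl$k == 0L) next
        idx <- cursor + seq_len(sl$k)
        cursor <- cursor + sl$k
        for (i in idx) {
          drug_sets[[i]] <- if (sl$drug == "X") xa else
            bg_ing$rxaui[sample.int(nrow(bg_ing), 1L)]
          event_sets[[i]] <- if (sl$event == "Y") s$pt else
            bg_pts[sample.int(length(bg_pts), 1L)]
        }
      }
    }
    if (cursor < n) {
      for (i in (cursor + 1L):n) {
        drug_sets[[i]] <- bg_ing$rxaui[sample.int(nrow(bg_ing), 1L)]
        event_sets[[i]] <- bg_pts[sample.int(length(bg_pts), 1L)]
      }
    }
  } else {
    # probabilistic planted signals (at most a handful) + background
    hit_x <- matrix(FALSE, n, length(planted))
    hit_y <- matrix(FALSE, n, length(planted))
    for (k in seq_along(planted)) {
      s <- planted[[k]]
      q0 <- s$p_event_base
      odds1 <- s$or_target * q0 / (1 - q0)
      q1 <- odds1 / (1 + odds1)
      hit_x[, k] <- runif(n) < s$p_drug
      hit_y[, k] <- runif(n) < ifelse(hit_x[, k], q1, q0)
    }
    for (i in seq_len(n)) {
      dx <- character(0)
      ev <- character(0)
      for (k in seq_along(planted)) {
        if (hit_x[i, k]) dx <- c(dx, x_aui[[planted[[k]]$ingredient]])
        if (hit_y[i, k]) ev <- c(ev, planted[[k]]$pt)
      }
      n_bg_d <- if (length(dx)) sample(0:1, 1L, prob = c(0.5, 0.5)) else
        sample(1:2, 1L, prob = c(0.7, 0.3))
      n_bg_e <- if (length(ev)) sample(0:1, 1L, prob = c(0.5, 0.5)) else 1L
      if (!length(planted)) {
        n_bg_d <- sample(1:3, 1L, prob = c(0.5, 0.3, 0.2))
        n_bg_e <- sample(1:2, 1L, prob = c(0.7, 0.3))
      }
      if (n_bg_d > 0L) {
        # occasional multi-ingredient product in a background slot
        if (!length(dx) && nrow(combos) && runif(1) < 0.05) {
          dx <- c(dx, combos$rxaui[sample.int(nrow(combos), 1L)])
          n_bg_d <- n_bg_d - 1L
        }
        if (n_bg_d > 0L) {
          dx <- c(dx, bg_ing$rxaui[sample.int(nrow(bg_ing), n_bg_d)])
        }
      }
      if (n_bg_e > 0L) ev <- c(ev, sample(bg_pts, n_bg_e))
      drug_sets[[i]] <- unique(dx)
      event_sets[[i]] <- unique(ev)
    }
  }

  # --- demographics --------------------------------------------------------
  period <- config$quarters[(seq_len(n) - 1L) %% length(config$quarters) + 1L]
  u_g <- runif(n)
  gender <- ifelse(u_g < r$gender_null, NA_character_,
            ifelse(u_g < r$gender_null + r$female, "F", "M"))
  u_c <- runif(n)
  country <- ifelse(u_c < r$country_null, NA_character_,
             ifelse(u_c < r$country_null + r$us_share,
                    sample(c("US", "UNITED STATES OF AMERICA"), n, replace = TRUE),
                    sample(other_codes, n, replace = TRUE)))
  event_dt <- ifelse(runif(n) < r$event_dt_null, NA_character_, rand_date(n))
  has_age <- runif(n) >= r$age_null
  age_cod <- sample(c("YR", "MON", "DEC", "WK", "DY"), n, replace = TRUE,
                    prob = c(0.70, 0.15, 0.10, 0.03, 0.02))
  age_val <- dplyr::case_when(
    age_cod == "YR" ~ sample(1:95, n, replace = TRUE) * 1,
    age_cod == "MON" ~ sample(1:24, n, replace = TRUE) * 1,
    age_cod == "DEC" ~ sample(1:9, n, replace = TRUE) * 1,
    age_cod == "WK" ~ sample(1:50, n, replace = TRUE) * 1,
    TRUE ~ sample(1:360, n, replace = TRUE) * 1
  )
  age_val[!has_age] <- NA_real_
  age_cod[!has_age] <- NA_character_
  has_start <- runif(n) >= r$start_dt_null
  start_dt <- ifelse(has_start, rand_date(n), NA_character_)
  u_i <- runif(n)
  indi_state <- ifelse(u_i < r$indication_null * 0.6, "absent",
                ifelse(u_i < r$indication_null, "unknown", "present"))
  indi_pt <- ifelse(indi_state == "present", sample(indis, n, replace = TRUE),
             ifelse(indi_state == "unknown",
                    sample(UNKNOWN_INDICATION_PHRASES, n, replace = TRUE),
                    NA_character_))
  fda_dt <- quarter_fda_dt(period)

  cases <- tibble(
    idx = seq_len(n),
    primaryid = as.character(100000L + seq_len(n)),
    caseid = as.character(500000L + seq_len(n)),
    caseversion = 1L, period = period, fda_dt = fda_dt,
    event_dt = event_dt, gender = gender, country = country,
    age_val = age_val, age_cod = age_cod,
    start_dt = start_dt, indi_state = indi_state, indi_pt = indi_pt
  )

  # --- repair: force distinct cases apart when hard keys collide -----------
  # any two distinct base cases sharing both hard keys (ingredient set,
  # event set) must differ in >= 3 soft fields, so that a duplicate
  # (<= 1 perturbed field) can never bridge two different true cases.
  # The repair of choice adds one background drug to the later member,
  # which moves it to another block without touching any soft field (and
  # cannot change a planted cell: the added drug is never a planted
  # ingredient, and cell membership depends only on the planted drug and
  # event being present). Soft-field repair remains as a fallback for the
  # rare pair that keeps colliding.
  fresh <- new.env()
  fresh$ctr <- 0L
  fresh_date <- function() {
    fresh$ctr <- fresh$ctr + 1L
    format(as.Date("1960-01-01") + fresh$ctr, "%Y%m%d")
  }
  soft_mismatches <- function(i, j) {
    cmp <- function(a, b) !is.na(a) && !is.na(b) && a != b
    age_i <- round(normalize_age(cases$age_val[i], cases$age_cod[i]))
    age_j <- round(normalize_age(cases$age_val[j], cases$age_cod[j]))
    code <- function(k) {
      cc <- cases$country[k]
      if (!is.na(cc) && cc == "UNITED STATES OF AMERICA") "US" else cc
    }
    sum(cmp(cases$gender[i], cases$gender[j]),
        cmp(age_i, age_j),
        cmp(code(i), code(j)),
        cmp(cases$event_dt[i], cases$event_dt[j]),
        cmp(cases$start_dt[i], cases$start_dt[j]),
        cmp(if (cases$indi_state[i] == "present") cases$indi_pt[i] else NA_character_,
            if (cases$indi_state[j] == "present") cases$indi_pt[j] else NA_character_))
  }
  # hard key at the level deduplication actually compares: the ingredient
  # closure of the atoms (a combo product equals its constituents)
  clo_all <- ingredient_closure(unique(unlist(drug_sets)), vocab)
  case_key <- function(i) {
    ingr <- unique(unlist(lapply(drug_sets[[i]], function(x) {
      y <- clo_all[[x]]$ingredients
      if (length(y)) y else x
    })))
    paste(paste(sort(ingr), collapse = "|"),
          paste(sort(event_sets[[i]]), collapse = "|"), sep = "#")
  }
  extra_ctr <- 0L
  for (round in 1:10) {
    hard_key <- vapply(seq_len(n), case_key, character(1))
    blocks <- Filter(function(r) length(r) > 1L, split(seq_len(n), hard_key))
    offenders <- integer(0)
    for (rows in blocks) {
      moved <- logical(length(rows))
      for (ii in seq_along(rows)[-1L]) {
        if (moved[ii]) next
        for (jj in seq_len(ii - 1L)) {
          if (moved[jj]) next
          if (soft_mismatches(rows[ii], rows[jj]) <= 2L) {
            offenders <- c(offenders, rows[ii])
            moved[ii] <- TRUE
            break
          }
        }
      }
    }
    if (!length(offenders)) break
    if (round < 10L) {
      for (i in offenders) {
        pool <- setdiff(bg_ing$rxaui, drug_sets[[i]])
        extra_ctr <- extra_ctr + 1L
        drug_sets[[i]] <- c(drug_sets[[i]],
                            pool[(extra_ctr %% length(pool)) + 1L])
      }
    } else {
      # fallback: pin three soft fields to fresh distinctive values
      for (i in offenders) {
        cases$event_dt[i] <- fresh_date()
        cases$age_val[i] <- 20 + (i %% 120)
        cases$age_cod[i] <- "YR"
        cases$indi_state[i] <- "present"
        cases$indi_pt[i] <- paste0("Synthetic indication ", i)
      }
    }
  }

  # --- duplicates ----------------------------------------------------------
  n_dup <- floor(config$duplicate_rate * n)
  dup_src <- if (n_dup > 0L) sort(sample.int(n, n_dup)) else integer(0)
  dup_rows <- NULL
  if (n_dup > 0L) {
    dup_rows <- cases[dup_src, ]
    dup_rows$idx <- n + seq_len(n_dup)
    dup_rows$primaryid <- as.character(100000L + n + seq_len(n_dup))
    dup_rows$caseid <- as.character(500000L + n + seq_len(n_dup))
    if (config$perturb_one_field) {
      do_perturb <- runif(n_dup) < 0.8
      field <- sample(c("gender", "age", "country", "event_dt", "start_dt",
                        "indication"), n_dup, replace = TRUE)
      for (k in seq_len(n_dup)) {
        if (!do_perturb[k]) next
        switch(field[k],
          gender = {
            dup_rows$gender[k] <- if (identical(dup_rows$gender[k], "F")) "M" else "F"
          },
          age = {
            base <- if (is.na(dup_rows$age_val[k]) || !identical(dup_rows$age_cod[k], "YR"))
              30 else dup_rows$age_val[k]
            dup_rows$age_val[k] <- ((base + 5) %% 120) + 1
            dup_rows$age_cod[k] <- "YR"
          },
          country = {
            cur <- dup_rows$country[k]
            pool <- setdiff(other_codes, cur)
            dup_rows$country[k] <- pool[sample.int(length(pool), 1L)]
          },
          event_dt = { dup_rows$event_dt[k] <- fresh_date() },
          start_dt = { dup_rows$start_dt[k] <- fresh_date() },
          indication = {
            dup_rows$indi_state[k] <- "present"
            dup_rows$indi_pt[k] <- paste0("Synthetic indication dup ", k)
          })
      }
    }
    drug_sets <- c(drug_sets, drug_sets[dup_src])
    event_sets <- c(event_sets, event_sets[dup_src])
    cases <- bind_rows(cases, dup_rows)
  }
  n_all <- nrow(cases)
  group_id <- seq_len(n)
  group_id <- c(group_id, group_id[dup_src])

  # --- drug rows with corrupted verbatim names (vectorized) ----------------
  n_per <- lengths(drug_sets[seq_len(n)])
  case_i <- rep(seq_len(n), n_per)
  seq_in_case <- unlist(lapply(n_per, seq_len))
  aui <- unlist(drug_sets[seq_len(n)])
  atom_name <- cn$name[match(aui, cn$rxaui)]
  atom_tty <- cn$tty[match(aui, cn$rxaui)]
  m <- length(aui)

  # operator per row; exact cell targets need every drug recoverable (an
  # unmapped drug would drop its report from the pair universe); combo and
  # planted-signal names also stay typo-free so their truth is recoverable
  ops <- c("identity", "case", "strength", "form", "echo", "trade", "code", "typo")
  w_full <- config$corruption_weights[ops]
  w_safe <- w_full
  w_safe["typo"] <- 0
  safe <- cell_mode | atom_tty == "MIN" |
    (length(x_aui) > 0L & aui %in% x_aui)
  op <- character(m)
  if (any(safe)) op[safe] <- sample(ops, sum(safe), replace = TRUE, prob = w_safe)
  if (any(!safe)) op[!safe] <- sample(ops, sum(!safe), replace = TRUE, prob = w_full)
  # trade substitution only where the dictionary covers the atom
  has_trade <- aui %in% idd$rxaui
  op[op == "trade" & !has_trade] <- "identity"

  verbatim <- atom_name
  k <- op == "case"
  if (any(k)) {
    low <- tolower(atom_name[k])
    verbatim[k] <- paste0(toupper(substr(low, 1, 1)), substr(low, 2, nchar(low)))
  }
  k <- op == "strength"
  if (any(k)) verbatim[k] <- paste0(atom_name[k], " ",
    sample(c("4MG", "10MG", "25 MG", "100MG", "0.5 ML"), sum(k), replace = TRUE))
  k <- op == "form"
  if (any(k)) verbatim[k] <- paste0(atom_name[k], " ",
    sample(c("TABLETS", "CAPSULES", "I.V.", "ORAL SOLUTION",
             "TABLETS/SUPPOSITORIES"), sum(k), replace = TRUE))
  k <- op == "echo"
  if (any(k)) verbatim[k] <- paste0(atom_name[k], " (", atom_name[k], ")")
  k <- op == "trade"
  if (any(k)) {
    verbatim[k] <- idd$trade_name[match(aui[k], idd$rxaui)]
  }
  k <- op == "code"
  if (any(k)) verbatim[k] <- paste0(atom_name[k], " /0",
    sample(1000000:9999999, sum(k), replace = TRUE), "/")
  k <- op == "typo"
  if (any(k)) {
    nm <- atom_name[k]
    pos <- 1L + floor(runif(sum(k)) * nchar(nm))
    repl <- sample(LETTERS, sum(k), replace = TRUE)
    cur <- substr(nm, pos, pos)
    repl[repl == cur] <- "Q"
    repl[repl == cur] <- "X"   # name letter might itself be Q
    verbatim[k] <- paste0(substr(nm, 1, pos - 1L), repl,
                          substr(nm, pos + 1L, nchar(nm)))
  }

  # a slice of rows carries an application number (recoverable regardless
  # of how mangled the string is)
  ing_idx <- match(aui, ings$rxaui)
  nda_num_row <- rep(NA_character_, m)
  nda_ok <- !is.na(ing_idx) & ing_idx <= nrow(nda_table) & runif(m) < 0.10
  nda_num_row[nda_ok] <- nda_table$nda_num[ing_idx[nda_ok]]

  clo <- ingredient_closure(aui, vocab)
  truth_str <- vapply(aui, function(x)
    paste(sort(clo[[x]]$ingredients), collapse = "|"), character(1),
    USE.NAMES = FALSE)

  drug_tab <- tibble(
    primaryid = cases$primaryid[case_i],
    drug_seq = as.character(seq_in_case),
    role_code = sample(c("PS", "SS", "C"), m, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)),
    verbatim_name = verbatim,
    prod_ai = atom_name,
    nda_num = nda_num_row,
    period = cases$period[case_i]
  )
  name_map <- tibble(
    primaryid = cases$primaryid[case_i],
    drug_seq = as.character(seq_in_case),
    verbatim_name = verbatim,
    true_rxaui = aui,
    true_ingredients = truth_str,
    operator = op,
    coverable = op != "typo" | !is.na(nda_num_row)
  )
  # duplicates copy their source case's drug rows verbatim
  if (n_dup > 0L) {
    src_ids <- cases$primaryid[dup_src]
    dup_ids <- cases$primaryid[n + seq_len(n_dup)]
    id_map <- setNames(dup_ids, src_ids)            # sources are unique
    period_map <- setNames(cases$period[n + seq_len(n_dup)], src_ids)
    cp <- drug_tab |> filter(.data$primaryid %in% src_ids)
    cp$period <- unname(period_map[cp$primaryid])
    cp$primaryid <- unname(id_map[cp$primaryid])
    cp_map <- name_map |> filter(.data$primaryid %in% src_ids)
    cp_map$primaryid <- unname(id_map[cp_map$primaryid])
    drug_tab <- bind_rows(drug_tab, cp)
    name_map <- bind_rows(name_map, cp_map)
  }

  # --- remaining tables ----------------------------------------------------
  reac_tab <- tibble(
    primaryid = rep(cases$primaryid, lengths(event_sets)),
    pt = unlist(event_sets),
    period = rep(cases$period, lengths(event_sets))
  )
  ther_src <- drug_tab |>
    left_join(cases |> select("primaryid", "start_dt"), by = "primaryid")
  # half of the start-date-missing cases emit rows with a null date, the
  # other half emit no therapy rows at all (both count as missing)
  emit_null_row <- cases$primaryid[is.na(cases$start_dt) &
                                     (cases$idx %% 2L == 0L)]
  ther_tab <- ther_src |>
    filter(!is.na(.data$start_dt) | .data$primaryid %in% emit_null_row) |>
    transmute(primaryid = .data$primaryid, dsg_drug_seq = .data$drug_seq,
              start_dt = .data$start_dt,
              end_dt = NA_character_, dur = NA_character_,
              dur_cod = NA_character_, period = .data$period)
  indi_cases <- cases |> filter(.data$indi_state != "absent")
  indi_tab <- drug_tab |>
    filter(.data$primaryid %in% indi_cases$primaryid) |>
    left_join(indi_cases |> select("primaryid", "indi_pt"), by = "primaryid") |>
    transmute(primaryid = .data$primaryid, indi_drug_seq = .data$drug_seq,
              pt = .data$indi_pt, period = .data$period)
  has_outc <- runif(n_all) < 0.7
  outc_tab <- tibble(
    primaryid = cases$primaryid[has_outc],
    outc_code = sample(c("DE", "LT", "HO", "DS", "CA", "RI", "OT"),
                       sum(has_outc), replace = TRUE),
    period = cases$period[has_outc]
  )
  has_rpsr <- runif(n_all) < 0.6
  rpsr_tab <- tibble(
    primaryid = cases$primaryid[has_rpsr],
    rpsr_code = sample(c("FGN", "DST", "CSM", "HP", "UF", "OTH"),
                       sum(has_rpsr), replace = TRUE),
    period = cases$period[has_rpsr]
  )

  deleted_ids <- character(0)
  if (config$deleted_rate > 0) {
    k <- floor(config$deleted_rate * n)
    deleted_ids <- cases$caseid[sample.int(n, k)]
  }

  demo_tab <- cases |>
    transmute(primaryid = .data$primaryid, caseid = .data$caseid,
              caseversion = .data$caseversion, i_f_code = "I",
              event_dt = .data$event_dt, fda_dt = .data$fda_dt,
              age = ifelse(is.na(.data$age_val), NA_character_,
                           format(.data$age_val, trim = TRUE)),
              age_cod = .data$age_cod, gender = .data$gender,
              country = .data$country, period = .data$period)

  signals_ledger <- if (length(planted)) {
    bind_rows(lapply(planted, function(s) {
      tibble(ingredient = s$ingredient, ingredient_rxaui = x_aui[[s$ingredient]],
             pt = s$pt,
             a = s$a %||% NA_integer_, b = s$b %||% NA_integer_,
             c = s$c %||% NA_integer_, d = s$d %||% NA_integer_,
             or_target = s$or_target %||% NA_real_)
    }))
  } else {
    tibble(ingredient = character(), ingredient_rxaui = character(),
           pt = character(), a = integer(), b = integer(), c = integer(),
           d = integer(), or_target = numeric())
  }

  structure(list(
    tables = list(demo = demo_tab, drug = drug_tab, reac = reac_tab,
                  indi = indi_tab, ther = ther_tab, outc = outc_tab,
                  rpsr = rpsr_tab,
                  deleted = tibble(caseid = deleted_ids,
                                   period = rep(tail(config$quarters, 1L),
                                                length(deleted_ids)))),
    ledger = list(
      duplicate_groups = tibble(primaryid = cases$primaryid, group_id = group_id),
      name_map = name_map,
      signals = signals_ledger,
      deleted_caseids = deleted_ids
    ),
    config = config
  ), class = "synth_reports")
}

#' @export
print.synth_reports <- function(x, ...) {
  cat("<synth_reports> ", nrow(x$tables$demo), " reports (",
      dplyr::n_distinct(x$ledger$duplicate_groups$group_id),
      " true cases), ", nrow(x$tables$drug), " drug rows\n", sep = "")
  invisible(x)
}

#' Convert synthetic reports to a combined dataset in memory
#'
#' Builds the same `faers_dataset` that writing the extracts to disk and
#' re-reading them through [merge_quarters()] would produce, without the
#' file round trip.
#'
#' @param reports A `synth_reports` object.
#' @return A `faers_dataset`.
#' @export
as_faers_dataset <- function(reports) {
  stopifnot(inherits(reports, "synth_reports"))
  t <- reports$tables
  legacy_p <- function(p) as.integer(substr(p, 1, 4)) < 2013
  demo <- t$demo |>
    mutate(age_years = normalize_age(.data$age, .data$age_cod),
           country_code = as.character(normalize_country(.data$country)),
           source = ifelse(legacy_p(.data$period), "LAERS", "FAERS"),
           # the legacy extract layout carries no case version
           caseversion = ifelse(legacy_p(.data$period), 0L, .data$caseversion))
  drug <- t$drug |>
    mutate(prod_ai = ifelse(legacy_p(.data$period), NA_character_, .data$prod_ai)) |>
    mutate(drug_id = seq_len(dplyr::n()), .before = 1)
  new_faers_dataset(list(demo = demo, drug = drug, reac = t$reac,
                         indi = t$indi, ther = t$ther, outc = t$outc,
                         rpsr = t$rpsr, deleted = t$deleted),
                    audit = list(synthetic = TRUE))
}

fmt_field <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

write_dollar_file <- function(df, path) {
  lines <- c(paste(names(df), collapse = "$"),
             do.call(paste, c(lapply(df, fmt_field), sep = "$")))
  writeLines(lines, path, useBytes = TRUE)
}

#' Write synthetic reports as quarterly extract files
#'
#' Emits the exact quarterly-extract layout the parser consumes:
#' "$"-delimited ASCII with one header line per file, one file per table
#' kind per quarter. Quarters before 2013 use the legacy layout (`ISR`
#' key, no case version); deleted-case lists attach to quarters from
#' 2019Q1 onward.
#'
#' @param reports A `synth_reports` object.
#' @param dir Output directory.
#' @return List of [faers_quarter()] objects pointing at the files.
#' @export
write_extracts <- function(reports, dir) {
  stopifnot(inherits(reports, "synth_reports"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t <- reports$tables
  quarters <- list()
  for (p in unique(t$demo$period)) {
    legacy <- as.integer(substr(p, 1, 4)) < 2013
    files <- list()
    demo <- t$demo |> filter(.data$period == p)
    ids <- demo$primaryid
    d <- if (legacy) {
      tibble(ISR = demo$primaryid, CASE = demo$caseid,
             i_f_cod = demo$i_f_code, event_dt = demo$event_dt,
             fda_dt = demo$fda_dt, age = demo$age, age_cod = demo$age_cod,
             gndr_cod = demo$gender, reporter_country = demo$country)
    } else {
      tibble(primaryid = demo$primaryid, caseid = demo$caseid,
             caseversion = demo$caseversion, i_f_cod = demo$i_f_code,
             event_dt = demo$event_dt, fda_dt = demo$fda_dt,
             age = demo$age, age_cod = demo$age_cod, sex = demo$gender,
             reporter_country = demo$country)
    }
    files$DEMO <- file.path(dir, paste0("DEMO_", p, ".txt"))
    write_dollar_file(d, files$DEMO)

    drug <- t$drug |> filter(.data$primaryid %in% ids)
    dr <- if (legacy) {
      tibble(ISR = drug$primaryid, drug_seq = drug$drug_seq,
             role_cod = drug$role_code, drugname = drug$verbatim_name,
             nda_num = drug$nda_num)
    } else {
      tibble(primaryid = drug$primaryid, drug_seq = drug$drug_seq,
             role_cod = drug$role_code, drugname = drug$verbatim_name,
             prod_ai = drug$prod_ai, nda_num = drug$nda_num)
    }
    files$DRUG <- file.path(dir, paste0("DRUG_", p, ".txt"))
    write_dollar_file(dr, files$DRUG)

    key <- if (legacy) "ISR" else "primaryid"
    emit <- function(tab, cols, kind) {
      sel <- tab |> filter(.data$primaryid %in% ids)
      out <- setNames(sel[c("primaryid", cols)], c(key, cols))
      path <- file.path(dir, paste0(kind, "_", p, ".txt"))
      write_dollar_file(out, path)
      path
    }
    files$REAC <- emit(t$reac, "pt", "REAC")
    files$INDI <- emit(t$indi |> rename(indi_pt = "pt"),
                       c("indi_drug_seq", "indi_pt"), "INDI")
    files$THER <- emit(t$ther, c("dsg_drug_seq", "start_dt", "end_dt",
                                 "dur", "dur_cod"), "THER")
    files$OUTC <- emit(t$outc |> rename(outc_cod = "outc_code"), "outc_cod", "OUTC")
    files$RPSR <- emit(t$rpsr |> rename(rpsr_cod = "rpsr_code"), "rpsr_cod", "RPSR")

    del <- t$deleted |> filter(.data$period == p)
    if (nrow(del) && !legacy && p >= "2019Q1") {
      files$DELETED <- file.path(dir, paste0("DELETED_", p, ".txt"))
      write_dollar_file(del |> select(caseid = "caseid"), files$DELETED)
    }
    quarters[[p]] <- faers_quarter(p, files)
  }
  unname(quarters)
}

#' Generate quarterly extract files with known ground truth
#'
#' Convenience wrapper: [generate_reports()] then [write_extracts()].
#'
#' @inheritParams generate_reports
#' @param dir Output directory for the extract files.
#' @return List: `quarters` (list of [faers_quarter()]), `ledger`,
#'   `reports` (the in-memory `synth_reports`).
#' @export
generate_extracts <- function(config, dir, vocab = mini_vocabulary(),
                              idd = mini_idd(), nda_table = mini_nda_table()) {
  reports <- generate_reports(config, vocab = vocab, idd = idd,
                              nda_table = nda_table)
  quarters <- write_extracts(reports, dir)
  list(quarters = quarters, ledger = reports$ledger, reports = reports)
}
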