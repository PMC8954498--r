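vocab <- mini_vocabulary()

test_that("name cleaning handles the documented corruption styles and is idempotent", {
  expect_equal(clean_name(" aspirin  ", "minimal"), "ASPIRIN")
  expect_equal(clean_name("GALANTAMINE 4MG", "deep"), "GALANTAMINE")
  expect_equal(clean_name("LESCOL ^SANDOZ^", "deep"), "LESCOL")
  expect_equal(clean_name("LOXOPROFEN SODIUM (LOXOPROFEN SODIUM)", "deep"),
               "LOXOPROFEN SODIUM")
  expect_equal(clean_name("PHENERGAN TABLETS/SUPPOSITORIES", "deep"), "PHENERGAN")
  expect_equal(clean_name("LOSEC I.V.", "deep"), "LOSEC")
  expect_equal(clean_name("CALCIUM & VITAMIN D /01483701/", "minimal"),
               "CALCIUM & VITAMIN D")
  expect_equal(clean_name("VALSARTAN-TABLET-UNIT DOSE: UNKNOWN", "deep"), "VALSARTAN")
  expect_equal(clean_name("ACETAMINOPHEN (LONG-ACTING)()", "deep"), "ACETAMINOPHEN")
  # combination names keep their embedded separator
  expect_equal(clean_name("METOPRAZINE / NORFLOXETINE 10MG", "deep"),
               "METOPRAZINE / NORFLOXETINE")
  # idempotence at both levels over a messy sample
  messy <- c(" aspirin ", "GALANTAMINE 4MG", "LESCOL ^SANDOZ^", "FT?2102",
             "CLOPIDOGREL/ASPIRIN) -", "X (X)", "A  B   C", "")
  for (lvl in c("minimal", "deep")) {
    once <- clean_name(messy, lvl)
    expect_identical(clean_name(once, lvl), once)
  }
})

test_that("exact matching is case/whitespace-insensitive with the documented tie-break", {
  expect_equal(exact_match("alprazovir", vocab), "1001")
  expect_true(is.na(exact_match("RIBAVARIN-LIKE TYPO", vocab)))
  # ambiguity: same name as a brand atom and an ingredient atom ->
  # the primary-source ingredient-level atom wins
  amb <- faers_vocabulary(tibble::tibble(
    rxaui = c("9", "5"), rxcui = c("C9", "C5"),
    name = c("DUPLEXIN", "DUPLEXIN"),
    tty = c("BN", "IN"), sab = c("RXNORM", "RXNORM")
  ))
  expect_equal(exact_match("DUPLEXIN", amb), "5")
  # tie within the same class -> lowest numeric rxaui
  amb2 <- faers_vocabulary(tibble::tibble(
    rxaui = c("12", "3"), rxcui = c("C12", "C3"),
    name = c("DUPLEXIN", "DUPLEXIN"), tty = c("IN", "IN"),
    sab = c("RXNORM", "RXNORM")
  ))
  expect_equal(exact_match("DUPLEXIN", amb2), "3")
})

test_that("the cascade tries stages in order and records the winning one", {
  idd <- mini_idd()
  nda <- mini_nda_table()
  overrides <- tibble::tibble(verbatim_name = "MY SPECIAL BLEND",
                              rxaui = "1005")
  res <- cascade_map(
    c("ALPRAZOVIR",                  # exact at minimal clean
      idd$trade_name[1],             # trade dictionary
      "MY SPECIAL BLEND",            # manual override
      "BECLOTIDINE 4MG",             # deep clean then exact
      "BLOOD THINNER",               # nothing
      "whatever name"),              # application number wins over everything
    nda_num = c(NA, NA, NA, NA, NA, nda$nda_num[1]),
    vocab, idd = idd, overrides = overrides, nda_table = nda)
  expect_equal(res$method,
               c("EXACT", "IDD", "MANUAL", "CLEANED_EXACT", "UNMAPPED", "NDA"))
  expect_equal(res$matched_rxaui[5], NA_character_)
  expect_equal(res$matched_rxaui[6], nda$rxaui[1])
})

test_that("cascade is monotone in its lookup resources", {
  names <- c("ALPRAZOVIR", mini_idd()$trade_name[1:5], "BLOOD THINNER",
             "BECLOTIDINE TABLETS")
  bare <- cascade_map(names, NULL, vocab)
  full <- cascade_map(names, NULL, vocab, idd = mini_idd(),
                      overrides = tibble::tibble(verbatim_name = "BLOOD THINNER",
                                                 rxaui = "1001"))
  was_mapped <- bare$method != "UNMAPPED"
  expect_true(all(full$method[was_mapped] != "UNMAPPED"))
  expect_true(sum(full$method != "UNMAPPED") >= sum(was_mapped))
})

test_that("ingredient normalization splits combos, keeps vaccines, flags exceptions", {
  expect_equal(normalize_to_ingredients("1001", vocab),
               list(ingredients = "1001", exception_flag = "none"))
  combo <- normalize_to_ingredients("1401", vocab)
  expect_equal(combo$ingredients, c("1001", "1002"))
  expect_equal(combo$exception_flag, "none")
  vac <- normalize_to_ingredients("1101", vocab)
  expect_equal(vac, list(ingredients = "1101", exception_flag = "vaccine"))
  expect_equal(normalize_to_ingredients("1201", vocab)$exception_flag,
               "nonRxNorm-ingredient")
  expect_equal(normalize_to_ingredients("1301", vocab)$exception_flag,
               "granularity")
  # brand resolves through its tradename relation
  expect_equal(normalize_to_ingredients("1501", vocab)$ingredients, "1001")
  # cyclic relations terminate at the hop bound as unresolved
  cyc <- faers_vocabulary(
    tibble::tibble(rxaui = c("1", "2"), rxcui = c("C1", "C2"),
                   name = c("A", "B"), tty = c("BN", "BN"),
                   sab = c("RXNORM", "RXNORM")),
    tibble::tibble(rxaui_from = c("1", "2"), rel = "tradename_of",
                   rxaui_to = c("2", "1")))
  expect_equal(normalize_to_ingredients("1", cyc)$exception_flag, "unresolved")
})

test_that("standardizing a drug table conserves drug ids and provenance", {
  drug <- tibble::tibble(
    drug_id = 1:4, primaryid = as.character(1:4), drug_seq = "1",
    verbatim_name = c("ALPRAZOVIR", "KETOPROLOL AND LAMOTRIGABINE",
                      "BLOOD THINNER", "MENINGOVAX B VACCINE"),
    prod_ai = NA_character_, nda_num = NA_character_
  )
  std <- standardize_drugs(drug, vocab)
  # combo split: two rows sharing the parent drug_id
  combo_rows <- std$drugs[std$drugs$drug_id == 2L, ]
  expect_equal(nrow(combo_rows), 2L)
  expect_setequal(combo_rows$ingredient_rxaui, c("1011", "1012"))
  # drug_id conservation and one method tag per input row
  expect_setequal(unique(std$drugs$drug_id), drug$drug_id)
  expect_true(all(std$drugs$method %in%
    c("NDA", "EXACT", "IDD", "MANUAL", "CLEANED_EXACT", "CLEANED_IDD", "UNMAPPED")))
  # unmapped rows retained, not deleted
  expect_true(any(std$drugs$method == "UNMAPPED" & is.na(std$drugs$ingredient_rxaui)))
  expect_equal(std$report$n_mapped, 3L)
  expect_equal(std$drugs$exception_flag[std$drugs$drug_id == 4L], "vaccine")
})

test_that("a contradicting reported active ingredient loses to the verbatim mapping", {
  drug <- tibble::tibble(
    drug_id = 1:2, primaryid = c("1", "2"), drug_seq = "1",
    verbatim_name = c("ALPRAZOVIR", "BECLOTIDINE"),
    prod_ai = c("ALPRAZOVIR", "CARVEDOPA"),   # second one disagrees
    nda_num = NA_character_
  )
  std <- standardize_drugs(drug, vocab)
  expect_equal(std$drugs$ingredient_name[std$drugs$drug_id == 2L], "BECLOTIDINE")
  expect_equal(std$report$prod_ai_conflicts$drug_id, 2L)
})

test_that("frequent unmapped names are listed for manual curation", {
  drug <- tibble::tibble(
    drug_id = 1:7, primaryid = as.character(1:7), drug_seq = "1",
    verbatim_name = c(rep("MYSTERY TONIC", 5), "ALPRAZOVIR", "ODD ONE"),
    prod_ai = NA_character_, nda_num = NA_character_
  )
  std <- standardize_drugs(drug, vocab, manual_threshold = 3)
  expect_equal(std$report$manual_candidates$verbatim_name, "MYSTERY TONIC")
  expect_equal(std$report$manual_candidates$n_rows, 5L)
})

test_that("an RRF-format vocabulary reads into the same structure", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "C100|ENG|||||Y|501||||RXNORM|IN|100|ZEPHRANOL|0|N||",
    "C101|ENG|||||Y|502||||RXNORM|BN|101|ZEPHRA|0|N||"
  ), file.path(dir, "RXNCONSO.RRF"))
  writeLines(c(
    "C101|502|AUI|RO|C100|501|AUI|tradename_of|||RXNORM|||||||"
  ), file.path(dir, "RXNREL.RRF"))
  v <- read_rrf_vocabulary(dir)
  expect_s3_class(v, "faers_vocabulary")
  expect_equal(exact_match("zephranol", v), "501")
  expect_equal(normalize_to_ingredients("502", v)$ingredients, "501")
})

test_that("corrupted synthetic names recover their true ingredient through the cascade", {
  cfg <- synth_config(n_cases = 300, seed = 17)
  rep <- generate_reports(cfg)
  ds <- as_faers_dataset(rep)
  std <- standardize_drugs(ds$drug, vocab, idd = mini_idd(),
                           nda_table = mini_nda_table())
  got <- std$drugs |>
    dplyr::group_by(primaryid, drug_seq) |>
    dplyr::summarise(
      got = paste(sort(unique(ingredient_rxaui[!is.na(ingredient_rxaui)])),
                  collapse = "|"),
      .groups = "drop")
  chk <- dplyr::left_join(rep$ledger$name_map, got, by = c("primaryid", "drug_seq"))
  cov <- chk[chk$coverable, ]
  expect_gt(nrow(cov), 100)
  expect_equal(sum(cov$got == cov$true_ingredients), nrow(cov))
  # names beyond the cascade's reach (typos without an application number)
  # are expected to stay unmapped
  ncov <- chk[!chk$coverable, ]
  expect_true(all(ncov$got == ""))
})
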