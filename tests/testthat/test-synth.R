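test_that("the generator is deterministic: same seed gives byte-identical files", {
  cfg <- synth_config(n_cases = 120, seed = 7, duplicate_rate = 0.2,
                      quarters = c("2010Q1", "2020Q3"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_extracts(cfg, d1)
  generate_extracts(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_equal(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(n_cases = 1, duplicate_rate = 0.5), "n_cases >= 2")
  expect_error(synth_config(rates = list(gender_null = 1.2)), "rates")
  expect_error(synth_config(quarters = "2020-Q1"), "YYYYQ")
  expect_error(synth_config(n_cases = 100, planted_signals = list(
    list(ingredient = "ALPRAZOVIR", pt = "Headache",
         a = 200, b = 0, c = 0, d = -100))), "infeasible")
  expect_error(synth_config(n_cases = 100, planted_signals = list(
    list(ingredient = "ALPRAZOVIR", pt = "Headache",
         a = 10, b = 10, c = 10, d = 10))), "a\\+b\\+c\\+d")
})

test_that("every generated drug mention is resolvable through the ledger", {
  cfg <- synth_config(n_cases = 250, seed = 19, duplicate_rate = 0.1)
  rep <- generate_reports(cfg)
  nm <- rep$ledger$name_map
  drug <- rep$tables$drug
  joined <- dplyr::left_join(drug, nm, by = c("primaryid", "drug_seq"))
  expect_equal(nrow(joined), nrow(drug))
  expect_true(all(!is.na(joined$true_ingredients)))
  expect_true(all(joined$verbatim_name.x == joined$verbatim_name.y))
  # every report belongs to exactly one duplicate group
  lg <- rep$ledger$duplicate_groups
  expect_setequal(lg$primaryid, rep$tables$demo$primaryid)
  expect_equal(anyDuplicated(lg$primaryid), 0L)
})

test_that("planted duplicates satisfy the matching rule by construction", {
  cfg <- synth_config(n_cases = 300, seed = 29, duplicate_rate = 0.3)
  rep <- generate_reports(cfg)
  ds <- as_faers_dataset(rep)
  std <- standardize_drugs(ds$drug, mini_vocabulary(), idd = mini_idd(),
                           nda_table = mini_nda_table())
  sigs <- build_signatures(ds$demo, std$drugs, ds$reac, ds$indi, ds$ther)
  lg <- rep$ledger$duplicate_groups
  multi <- split(lg$primaryid, lg$group_id)
  multi <- Filter(function(g) length(g) > 1, multi)
  expect_gt(length(multi), 50)
  for (g in multi) {
    s1 <- sigs[sigs$primaryid == g[1], ]
    s2 <- sigs[sigs$primaryid == g[2], ]
    v <- is_duplicate_pair(s1, s2)
    expect_true(v$hard_match)
    expect_lte(v$soft_mismatches, 1L)
  }
})

test_that("distinct cases sharing hard keys differ in at least three soft fields", {
  cfg <- synth_config(n_cases = 500, seed = 37)
  rep <- generate_reports(cfg)
  ds <- as_faers_dataset(rep)
  std <- standardize_drugs(ds$drug, mini_vocabulary(), idd = mini_idd(),
                           nda_table = mini_nda_table())
  sigs <- build_signatures(ds$demo, std$drugs, ds$reac, ds$indi, ds$ther)
  blocks <- split(seq_len(nrow(sigs)),
                  paste(sigs$drugs_key, sigs$reactions_key))
  softs <- c("gender", "age_r", "country_code", "event_dt", "start_key", "indi_key")
  for (rows in Filter(function(r) length(r) > 1, blocks)) {
    for (i in rows) for (j in rows) {
      if (i >= j) next
      mism <- sum(vapply(softs, function(f) {
        x <- sigs[[f]][i]; y <- sigs[[f]][j]
        !is.na(x) && !is.na(y) && x != y
      }, logical(1)))
      expect_gte(mism, 3L)
    }
  }
})

test_that("corruption operators produce the documented styles", {
  idd <- mini_idd()
  withr::with_seed(3, {
    expect_equal(corrupt_drug_name("ALPRAZOVIR", "identity")$verbatim, "ALPRAZOVIR")
    s <- corrupt_drug_name("ALPRAZOVIR", "strength")
    expect_match(s$verbatim, "^ALPRAZOVIR \\d")
    e <- corrupt_drug_name("LOXOPROFEN", "echo")
    expect_equal(e$verbatim, "LOXOPROFEN (LOXOPROFEN)")
    tr <- corrupt_drug_name("ALPRAZOVIR", "trade", idd = idd, true_rxaui = "1001")
    expect_equal(tr$verbatim, idd$trade_name[idd$rxaui == "1001"])
    ty <- corrupt_drug_name("ALPRAZOVIR", "typo")
    expect_false(ty$coverable)
    expect_equal(nchar(ty$verbatim), nchar("ALPRAZOVIR"))
    expect_false(ty$verbatim == "ALPRAZOVIR")
    cd <- corrupt_drug_name("ALPRAZOVIR", "code")
    expect_match(cd$verbatim, "/0\\d+/$")
    # trade without dictionary coverage degrades to identity
    fb <- corrupt_drug_name("ZIPRASIDIL", "trade", idd = idd, true_rxaui = "1046")
    expect_equal(fb$operator, "identity")
  })
})

test_that("deleted-case lists are emitted and honoured end to end", {
  cfg <- synth_config(n_cases = 200, seed = 43, deleted_rate = 0.1,
                      quarters = "2020Q1")
  gen <- generate_extracts(cfg, withr::local_tempdir())
  expect_length(gen$ledger$deleted_caseids, 20L)
  ds <- merge_quarters(gen$quarters)
  expect_equal(nrow(ds$deleted), 20L)
  out <- apply_deleted_cases(ds)
  expect_equal(nrow(out$demo), 180L)
})
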