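test_that("stage one keeps the most recent version per case identifier", {
  demo <- demo_fixture(
    primaryid = c("1", "2", "3", "4"),
    caseid = c("123", "123", "123", "777"),
    caseversion = c(1L, 2L, 3L, 1L)
  )
  out <- keep_latest_version(demo)
  expect_setequal(out$primaryid, c("3", "4"))
  # single-version cases pass through unchanged
  single <- demo_fixture("9", caseid = "55")
  expect_equal(keep_latest_version(single)$primaryid, "9")
  # version tie broken by receipt date
  tie <- demo_fixture(c("10", "11"), caseid = "88", caseversion = 1L,
                      fda_dt = c("20200101", "20200301"))
  expect_equal(keep_latest_version(tie)$primaryid, "11")
  # full tie broken by numeric primaryid
  tie2 <- demo_fixture(c("9", "10"), caseid = "89")
  expect_equal(keep_latest_version(tie2)$primaryid, "10")
  # rows without a case identifier pass through untouched
  nocase <- demo_fixture(c("20", "21"), caseid = NA_character_)
  expect_equal(nrow(keep_latest_version(nocase)), 2L)
})

test_that("signatures use set semantics and case-folding", {
  demo <- demo_fixture("1")
  std <- std_drugs_fixture("1", list(c("B", "A", "A")))
  reac <- reac_fixture("1", list(c("Rash", "rash ", "Nausea")))
  indi <- tibble::tibble(primaryid = "1", indi_drug_seq = "1",
                         pt = c("X", "x "))
  ther <- tibble::tibble(primaryid = rep("1", 3), dsg_drug_seq = as.character(1:3),
                         start_dt = rep(NA_character_, 3))
  sig <- build_signatures(demo, std, reac, indi, ther)
  expect_equal(sig$drugs_key, "A\x1fB")
  expect_equal(sig$reactions_key, "NAUSEA\x1fRASH")
  expect_equal(sig$indi_key, "X")
  # therapy rows all null start date => start date missing
  expect_true(is.na(sig$start_key))
  expect_true(sig$complete)
})

test_that("reports lacking drug or reaction rows are flagged incomplete", {
  demo <- demo_fixture(c("1", "2"))
  std <- std_drugs_fixture("1", list("A"))
  sig <- build_signatures(demo, std, reac_fixture("1", list("PT1")),
                          empty_indi(), empty_ther())
  expect_equal(sig$complete, c(TRUE, FALSE))
})

make_sig <- function(...) {
  defaults <- list(primaryid = "1", fda_dt = "20200101", gender = "F",
                   age_r = 30, country_code = "US", event_dt = "20190101",
                   drugs_key = "A|B", reactions_key = "R1", start_key = "20180101",
                   indi_key = "I1", complete = TRUE)
  tibble::as_tibble(utils::modifyList(defaults, list(...)))
}

test_that("the allow-one-mismatch rule: hard keys exact, at most one soft mismatch", {
  s <- make_sig()
  expect_true(is_duplicate_pair(s, s)$duplicate)
  # one soft mismatch still duplicates
  expect_true(is_duplicate_pair(s, make_sig(gender = "M"))$duplicate)
  # two soft mismatches do not
  r <- is_duplicate_pair(s, make_sig(gender = "M", age_r = 31))
  expect_false(r$duplicate)
  expect_equal(r$soft_mismatches, 2L)
  # hard-key differences always block, even with all soft keys equal
  expect_false(is_duplicate_pair(s, make_sig(drugs_key = "A"))$duplicate)
  expect_false(is_duplicate_pair(s, make_sig(reactions_key = "R2"))$duplicate)
})

test_that("a null soft key is a non-consuming unknown under the default policy", {
  s <- make_sig()
  # null gender + one real mismatch: the null must not consume the allowance
  r <- is_duplicate_pair(make_sig(gender = NA), make_sig(age_r = 31))
  expect_true(r$duplicate)
  expect_equal(r$soft_mismatches, 1L)
  expect_equal(r$unknowns, 1L)
  # under the mismatch policy the same pair fails
  r2 <- is_duplicate_pair(make_sig(gender = NA), make_sig(age_r = 31),
                          null_policy = "mismatch")
  expect_false(r2$duplicate)
})

test_that("cross-duplicate groups close transitively and retain the latest report", {
  # three mutually matching reports -> one group of three
  sigs <- dplyr::bind_rows(
    make_sig(primaryid = "1", fda_dt = "20200101"),
    make_sig(primaryid = "2", fda_dt = "20200301", gender = "M"),
    make_sig(primaryid = "3", fda_dt = "20200201", gender = NA)
  )
  g <- find_cross_duplicates(sigs)
  expect_equal(nrow(g), 3L)
  expect_equal(dplyr::n_distinct(g$group_id), 1L)
  expect_equal(unique(g$retained_primaryid), "2")
  # all-distinct reports -> no groups
  distinct_sigs <- dplyr::bind_rows(lapply(1:50, function(i) {
    make_sig(primaryid = as.character(i), drugs_key = paste0("D", i))
  }))
  expect_equal(nrow(find_cross_duplicates(distinct_sigs)), 0L)
})

test_that("blocked search equals the exhaustive pairwise oracle", {
  # 400 synthetic reports incl. duplicates; oracle compares all pairs with
  # its own field comparison and closes edges through igraph components
  cfg <- synth_config(n_cases = 400, seed = 23, duplicate_rate = 0.25)
  rep <- generate_reports(cfg)
  ds <- as_faers_dataset(rep)
  std <- standardize_drugs(ds$drug, mini_vocabulary(), idd = mini_idd(),
                           nda_table = mini_nda_table())
  sigs <- build_signatures(ds$demo, std$drugs, ds$reac, ds$indi, ds$ther)
  got <- find_cross_duplicates(sigs)

  sc <- sigs[sigs$complete, ]
  m <- nrow(sc)
  pr <- t(combn(m, 2))
  softs <- c("gender", "age_r", "country_code", "event_dt", "start_key", "indi_key")
  mism <- rep(0L, nrow(pr))
  for (f in softs) {
    x <- as.character(sc[[f]])[pr[, 1]]
    y <- as.character(sc[[f]])[pr[, 2]]
    mism <- mism + (!is.na(x) & !is.na(y) & x != y)
  }
  hard <- sc$drugs_key[pr[, 1]] == sc$drugs_key[pr[, 2]] &
    sc$reactions_key[pr[, 1]] == sc$reactions_key[pr[, 2]]
  edges <- pr[hard & mism <= 1L, , drop = FALSE]
  gr <- igraph::graph_from_edgelist(cbind(edges[, 1], edges[, 2]), directed = FALSE)
  gr <- igraph::add_vertices(gr, m - igraph::vcount(gr))
  comp <- igraph::components(gr)$membership
  oracle_groups <- split(sc$primaryid, comp)
  oracle_groups <- Filter(function(g) length(g) > 1, oracle_groups)
  got_groups <- split(got$primaryid, got$group_id)
  canon <- function(gs) sort(unname(vapply(gs, function(g) paste(sort(g), collapse = ","),
                                           character(1))))
  expect_equal(canon(got_groups), canon(oracle_groups))
})

test_that("deduplication recovers planted ground truth and is a fixpoint", {
  cfg <- synth_config(n_cases = 800, seed = 31, duplicate_rate = 0.2)
  rep <- generate_reports(cfg)
  ds <- as_faers_dataset(rep)
  std <- standardize_drugs(ds$drug, mini_vocabulary(), idd = mini_idd(),
                           nda_table = mini_nda_table())
  dd <- deduplicate(ds, std$drugs)
  lg <- rep$ledger$duplicate_groups
  # unique-case count equals ledger group count
  expect_equal(nrow(dd$dataset$demo), dplyr::n_distinct(lg$group_id))
  # recall: every true multi-member group detected as one group
  truth <- lg |> dplyr::group_by(group_id) |> dplyr::filter(dplyr::n() > 1) |>
    dplyr::ungroup()
  tr <- dplyr::left_join(truth,
                         dplyr::select(dd$groups, primaryid, det = group_id),
                         by = "primaryid")
  recall <- tr |> dplyr::group_by(group_id) |>
    dplyr::summarise(ok = dplyr::n_distinct(det) == 1 && !any(is.na(det)))
  expect_true(all(recall$ok))
  # false merges: no detected group mixes two true cases
  mix <- dplyr::left_join(dd$groups, lg, by = "primaryid") |>
    dplyr::group_by(group_id.x) |>
    dplyr::summarise(n_true = dplyr::n_distinct(group_id.y))
  expect_true(all(mix$n_true == 1L))
  # referential integrity after removal
  for (k in c("drug", "reac", "indi", "ther", "outc", "rpsr")) {
    expect_true(all(dd$dataset[[k]]$primaryid %in% dd$dataset$demo$primaryid))
  }
  # monotonicity and fixpoint
  expect_lte(nrow(dd$dataset$demo), nrow(ds$demo))
  dd2 <- deduplicate(dd$dataset, dd$std_drugs)
  expect_equal(dd2$audit$cross_removed, 0L)
  expect_equal(dd2$audit$stage1_removed, 0L)
  expect_equal(nrow(dd2$dataset$demo), nrow(dd$dataset$demo))
})

test_that("with no duplicates the dataset passes through unchanged", {
  cfg <- synth_config(n_cases = 200, seed = 41, duplicate_rate = 0)
  rep <- generate_reports(cfg)
  ds <- as_faers_dataset(rep)
  std <- standardize_drugs(ds$drug, mini_vocabulary(), idd = mini_idd(),
                           nda_table = mini_nda_table())
  dd <- deduplicate(ds, std$drugs)
  expect_equal(nrow(dd$dataset$demo), 200L)
  expect_equal(dd$audit$cross_removed, 0L)
})
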