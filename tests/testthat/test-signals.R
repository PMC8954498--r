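test_that("contingency cells enumerate distinct reports", {
  # four reports, one drug and one event each: {X,Y},{X,!Y},{!X,Y},{!X,!Y}
  pairs <- tibble::tibble(
    primaryid = c("1", "2", "3", "4"),
    ingredient_rxaui = c("X", "X", "Z", "Z"),
    pt = c("Y", "W", "Y", "W")
  )
  cells <- build_contingency(pairs)
  xy <- cells[cells$ingredient_rxaui == "X" & cells$pt == "Y", ]
  expect_equal(unlist(xy[c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_true(all(cells$n_reports == 4L))
  # a report listing the same drug-event pair twice contributes once
  rep2 <- dplyr::bind_rows(pairs, pairs[1, ])
  expect_equal(build_contingency(rep2), cells)
  # empty input -> empty table
  expect_equal(nrow(build_contingency(pairs[0, ])), 0L)
})

test_that("marginals are conserved across the table", {
  withr::with_seed(5, {
    pairs <- tibble::tibble(
      primaryid = as.character(sample(1:200, 600, replace = TRUE)),
      ingredient_rxaui = as.character(sample(1:12, 600, replace = TRUE)),
      pt = sample(LETTERS[1:8], 600, replace = TRUE)
    ) |> dplyr::distinct()
  })
  cells <- build_contingency(pairs)
  # within one drug, a + c is constant (= reports with that drug)
  per_drug <- cells |> dplyr::group_by(ingredient_rxaui) |>
    dplyr::summarise(n_ac = dplyr::n_distinct(a + c))
  expect_true(all(per_drug$n_ac == 1L))
  per_event <- cells |> dplyr::group_by(pt) |>
    dplyr::summarise(n_ab = dplyr::n_distinct(a + b))
  expect_true(all(per_event$n_ab == 1L))
  expect_equal(dplyr::n_distinct(cells$n_reports), 1L)
})

test_that("the worked cell reproduces the hand-derived statistics", {
  p <- prr(25, 75, 50, 1000)
  expect_equal(p$prr, 4.777778, tolerance = 1e-6)
  r <- ror(25, 75, 50, 1000)
  expect_equal(r$ror, 6.666667, tolerance = 1e-6)
  expect_equal(r$ror_lo, 3.9069, tolerance = 1e-4)
  expect_equal(r$ror_hi, 11.3758, tolerance = 1e-4)
  expect_equal(chi2_yates(25, 75, 50, 1000), 58.06706, tolerance = 1e-6)
  i <- ic(25, 75, 50, 1000)
  expect_equal(i$a_exp, 6.521739, tolerance = 1e-6)
  expect_equal(i$ic, 1.860597, tolerance = 1e-6)
  expect_equal(i$ic025, 1.191568, tolerance = 1e-6)
  expect_equal(i$ic975, 2.331985, tolerance = 1e-6)
})

test_that("a proportional table is exactly null under every measure", {
  expect_equal(prr(10, 90, 90, 810)$prr, 1)
  expect_equal(ror(10, 90, 90, 810)$ror, 1)
  expect_equal(chi2_yates(10, 90, 90, 810), 0)
  expect_equal(ic(10, 90, 90, 810)$ic, 0)
  expect_equal(ic(10, 90, 90, 810)$a_exp, 10)
})

test_that("zero cells yield null ratio statistics with a reason, IC stays finite", {
  p <- prr(0, 90, 90, 810)
  expect_true(is.na(p$prr))
  expect_equal(p$prr_reason, "zero-cell")
  r <- ror(5, 0, 90, 810)
  expect_true(is.na(r$ror))
  expect_equal(r$ror_reason, "zero-cell")
  i <- ic(0, 90, 90, 810)
  expect_true(is.finite(i$ic))
  expect_lt(i$ic, 0)
  # opt-in continuity gives finite ratio estimates instead
  pc <- prr(0, 90, 90, 810, continuity = 0.5)
  expect_true(is.finite(pc$prr))
})

test_that("the chi-squared statistic is symmetric under swapping the diagonal", {
  cells <- random_cells(200, seed = 7)
  expect_equal(chi2_yates(cells$a, cells$b, cells$c, cells$d),
               chi2_yates(cells$d, cells$c, cells$b, cells$a))
})

test_that("sign concordance holds across all measures on random cells", {
  cells <- random_cells(2000, seed = 11)
  p <- prr(cells$a, cells$b, cells$c, cells$d)
  r <- ror(cells$a, cells$b, cells$c, cells$d)
  i <- ic(cells$a, cells$b, cells$c, cells$d)
  dir_or <- sign(cells$a * cells$d - cells$b * cells$c)
  expect_true(all(sign(r$ror - 1) == dir_or))
  expect_true(all(sign(p$prr - 1) == dir_or | (p$prr == 1 & dir_or == 0)))
  # IC shrinks toward zero but never crosses: its sign agrees unless the
  # cell is exactly proportional
  nz <- dir_or != 0
  expect_true(all(sign(i$ic)[nz] == dir_or[nz]))
})

test_that("interval bounds bracket the point estimates for all cells", {
  cells <- random_cells(2000, seed = 13)
  p <- prr(cells$a, cells$b, cells$c, cells$d)
  r <- ror(cells$a, cells$b, cells$c, cells$d)
  i <- ic(cells$a, cells$b, cells$c, cells$d)
  expect_true(all(p$prr_lo <= p$prr & p$prr <= p$prr_hi))
  expect_true(all(r$ror_lo <= r$ror & r$ror <= r$ror_hi))
  expect_true(all(i$ic025 <= i$ic & i$ic <= i$ic975))
  # including the a = 0 boundary
  i0 <- ic(0, sample(1:50, 50, replace = TRUE), sample(1:50, 50, replace = TRUE),
           sample(1:500, 50, replace = TRUE))
  expect_true(all(i0$ic025 <= i0$ic & i0$ic <= i0$ic975))
})

test_that("the batch analysis equals per-cell calls row-wise", {
  cells <- build_contingency(tibble::tibble(
    primaryid = as.character(c(1, 1, 2, 3, 4, 5)),
    ingredient_rxaui = c("X", "Z", "X", "Z", "X", "Z"),
    pt = c("Y", "Y", "W", "Y", "Y", "W")
  ))
  sig <- proportionate_analysis(cells)
  expect_equal(nrow(sig), nrow(cells))
  for (k in seq_len(nrow(cells))) {
    expect_equal(sig$ror[k], ror(cells$a[k], cells$b[k], cells$c[k], cells$d[k])$ror)
    expect_equal(sig$ic[k], ic(cells$a[k], cells$b[k], cells$c[k], cells$d[k])$ic)
  }
  # tidy/glance/autoplot interfaces
  expect_s3_class(tidy(sig), "tbl_df")
  g <- glance(sig)
  expect_equal(g$n_pairs, nrow(cells))
  expect_s3_class(autoplot(sig), "ggplot")
})
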