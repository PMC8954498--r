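#' Build the drug--event contingency table
#'
#' For every observed (ingredient, preferred term) pair, counts distinct
#' reports: `a` reports mentioning both the drug and the event, `b`
#' reports of all other drugs with the event, `c` reports of the drug
#' with all other events, `d` reports of neither. The counting unit is
#' the report (`primaryid`), never the mention: a case listing a drug or
#' an event repeatedly contributes once. `N = a+b+c+d` is the number of
#' distinct reports in the pair universe and is identical across cells.
#'
#' @param pairs Tibble of (report, drug, event) triples with columns
#'   `primaryid`, `ingredient_rxaui`, `pt` (extra columns such as
#'   `ingredient_name` are carried through).
#' @return Tibble with one row per observed pair: identifiers, `a`, `b`,
#'   `c`, `d`, `n_reports`.
#' @export
build_contingency <- function(pairs) {
  need <- c("primaryid", "ingredient_rxaui", "pt")
  stopifnot(all(need %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    return(tibble(ingredient_rxaui = character(), pt = character(),
                  a = integer(), b = integer(), c = integer(), d = integer(),
                  n_reports = integer()))
  }
  keep_cols <- intersect(c("ingredient_rxaui", "ingredient_name", "pt"), names(pairs))
  pairs <- pairs |>
    filter(!is.na(.data$ingredient_rxaui), !is.na(.data$pt)) |>
    distinct(.data$primaryid, .data$ingredient_rxaui, .data$pt, .keep_all = TRUE)
  n_total <- dplyr::n_distinct(pairs$primaryid)
  drug_margin <- pairs |>
    distinct(.data$primaryid, .data$ingredient_rxaui) |>
    count(.data$ingredient_rxaui, name = "n_drug")
  event_margin <- pairs |>
    distinct(.data$primaryid, .data$pt) |>
    count(.data$pt, name = "n_event")
  cells <- pairs |>
    group_by(across(all_of(keep_cols))) |>
    summarise(a = dplyr::n_distinct(.data$primaryid), .groups = "drop") |>
    left_join(drug_margin, by = "ingredient_rxaui") |>
    left_join(event_margin, by = "pt") |>
    mutate(
      b = .data$n_event - .data$a,
      c = .data$n_drug - .data$a,
      d = n_total - .data$a - .data$b - .data$c,
      n_reports = n_total
    ) |>
    select(-"n_drug", -"n_event") |>
    arrange(.data$ingredient_rxaui, .data$pt)
  cells
}

ci_z <- function(level = 0.95) stats::qnorm(1 - (1 - level) / 2)

#' Proportional reporting ratio
#'
#' `PRR = [a/(a+c)] / [b/(b+d)]` with 95% interval
#' `exp(ln PRR +/- 1.96 * sqrt(1/a - 1/(a+c) + 1/b - 1/(b+d)))`. Cells
#' where the ratio or its log variance is undefined (`a = 0`, `b = 0`,
#' or a zero denominator) return `NA` with reason `"zero-cell"`; an
#' optional continuity constant added to all four cells makes the
#' estimate finite instead.
#'
#' @param a,b,c,d Integer vectors of cell counts (recycled to a common
#'   length).
#' @param continuity Constant added to all four cells before computing
#'   the ratio statistics (default 0; 0.5 gives Haldane-corrected
#'   estimates).
#' @return Tibble with `prr`, `prr_lo`, `prr_hi`, `prr_reason`.
#' @export
#' @examples
#' prr(25, 75, 50, 1000)
prr <- function(a, b, c, d, continuity = 0) {
  aa <- a + continuity; bb <- b + continuity
  cc <- c + continuity; dd <- d + continuity
  ok <- aa > 0 & bb > 0 & (bb + dd) > 0 & (aa + cc) > 0
  point <- ifelse(ok, (aa / (aa + cc)) / (bb / (bb + dd)), NA_real_)
  se <- ifelse(ok, sqrt(1 / aa - 1 / (aa + cc) + 1 / bb - 1 / (bb + dd)), NA_real_)
  z <- ci_z()
  tibble(
    prr = point,
    prr_lo = exp(log(point) - z * se),
    prr_hi = exp(log(point) + z * se),
    prr_reason = ifelse(ok, NA_character_, "zero-cell")
  )
}

#' Reporting odds ratio
#'
#' `ROR = ad/(bc)` with 95% interval
#' `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell
#' returns `NA` with reason `"zero-cell"` unless a continuity constant
#' is supplied.
#'
#' @inheritParams prr
#' @return Tibble with `ror`, `ror_lo`, `ror_hi`, `ror_reason`.
#' @export
#' @examples
#' ror(25, 75, 50, 1000)
ror <- function(a, b, c, d, continuity = 0) {
  aa <- a + continuity; bb <- b + continuity
  cc <- c + continuity; dd <- d + continuity
  ok <- aa > 0 & bb > 0 & cc > 0 & dd > 0
  point <- ifelse(ok, (aa * dd) / (bb * cc), NA_real_)
  se <- ifelse(ok, sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd), NA_real_)
  z <- ci_z()
  tibble(
    ror = point,
    ror_lo = exp(log(point) - z * se),
    ror_hi = exp(log(point) + z * se),
    ror_reason = ifelse(ok, NA_character_, "zero-cell")
  )
}

#' Yates-corrected chi-squared statistic for a 2x2 cell
#'
#' `N * (max(0, |ad - bc| - N/2))^2 / [(a+c)(a+b)(b+d)(c+d)]`. The
#' continuity correction is clamped at zero, so an exactly proportional
#' table scores 0 rather than a spurious positive value (this matches
#' the behaviour of standard continuity-corrected chi-squared routines).
#' A zero marginal makes the statistic undefined (`NA`).
#'
#' @inheritParams prr
#' @return Numeric vector of statistics.
#' @export
#' @examples
#' chi2_yates(25, 75, 50, 1000)
chi2_yates <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  denom <- (a + c) * (a + b) * (b + d) * (c + d)
  ok <- denom > 0
  dev <- pmax(0, abs(a * d - b * c) - n / 2)
  ifelse(ok, n * dev^2 / denom, NA_real_)
}

#' Information component with closed-form credibility bounds
#'
#' Shrinkage observed/expected measure on the base-2 log scale:
#' `IC = log2((a + 0.5) / (aexp + 0.5))` with expectation
#' `aexp = (a+b)(a+c)/N`, and bounds
#' `IC025 = IC - 3.3 (a+0.5)^-1/2 - 2 (a+0.5)^-3/2`,
#' `IC975 = IC + 2.4 (a+0.5)^-1/2 - 0.5 (a+0.5)^-3/2`. The shrinkage
#' makes the measure total: it is finite even for `a = 0`.
#'
#' @inheritParams prr
#' @return Tibble with `a_exp`, `ic`, `ic025`, `ic975`.
#' @export
#' @examples
#' ic(25, 75, 50, 1000)
ic <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  a_exp <- (a + b) * (a + c) / n
  point <- log2((a + 0.5) / (a_exp + 0.5))
  s <- (a + 0.5)^(-1 / 2)
  s3 <- (a + 0.5)^(-3 / 2)
  tibble(
    a_exp = a_exp,
    ic = point,
    ic025 = point - 3.3 * s - 2 * s3,
    ic975 = point + 2.4 * s - 0.5 * s3
  )
}

#' Compute the full proportionate-analysis table
#'
#' One row per contingency cell with all disproportionality statistics:
#' PRR, ROR (points and 95% intervals), the Yates-corrected chi-squared
#' statistic, and the information component with its credibility bounds.
#' Undefined ratio statistics carry a reason code rather than a value.
#'
#' @param cells Contingency tibble from [build_contingency()] (columns
#'   `a`, `b`, `c`, `d` required; identifier columns carried through).
#' @param continuity Continuity constant for the ratio statistics
#'   (default 0).
#' @param min_a Keep only cells with `a >= min_a` (default 0, keep all).
#' @return A `faers_signals` tibble.
#' @export
proportionate_analysis <- function(cells, continuity = 0, min_a = 0) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(cells)))
  cells <- cells |> filter(.data$a >= min_a)
  out <- bind_cols(
    as_tibble(cells),
    prr(cells$a, cells$b, cells$c, cells$d, continuity = continuity),
    ror(cells$a, cells$b, cells$c, cells$d, continuity = continuity),
    tibble(chi2_yates = chi2_yates(cells$a, cells$b, cells$c, cells$d)),
    ic(cells$a, cells$b, cells$c, cells$d)
  )
  class(out) <- c("faers_signals", class(out))
  out
}

#' @export
tidy.faers_signals <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "faers_signals")
  as_tibble(out)
}

#' Summarise a proportionate-analysis table
#'
#' @param x A `faers_signals` tibble.
#' @param ... Unused.
#' @return One-row tibble: number of pairs, number of reports in the
#'   universe, and counts of pairs flagged by the conventional
#'   thresholds (`IC025 > 0`; `ROR` lower bound > 1).
#' @export
glance.faers_signals <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_reports = if (nrow(x)) x$n_reports[1] else 0L,
    n_ic025_positive = sum(x$ic025 > 0, na.rm = TRUE),
    n_ror_lo_gt1 = sum(x$ror_lo > 1, na.rm = TRUE)
  )
}

#' Plot a proportionate-analysis table
#'
#' Scatter of the information component against the log-2 reporting odds
#' ratio, one point per drug--event pair, with pairs above the
#' conventional signal threshold (`IC025 > 0`) highlighted.
#'
#' @param object A `faers_signals` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.faers_signals <- function(object, ...) {
  df <- tidy(object) |>
    filter(!is.na(.data$ror)) |>
    mutate(signal = .data$ic025 > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$ror), y = .data$ic,
                                   colour = .data$signal)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 name = "IC025 > 0") +
    ggplot2::labs(x = "log2 reporting odds ratio", y = "information component") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.faers_signals
#' @param signals A `faers_signals` tibble.
#' @export
plot_signals <- function(signals, ...) autoplot(signals, ...)
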