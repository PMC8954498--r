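---
title: "Curating spontaneous adverse event reports: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating spontaneous adverse event reports: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersforge)
library(dplyr)
```

## The problem

Public quarterly extracts of a spontaneous adverse event reporting system
are messy in two specific ways. First, drug names are free text: the same
active ingredient appears as a generic name, a domestic or foreign trade
name, with appended strengths, dosage forms or manufacturer tags, or with
typographical errors, so no aggregate count of a drug is trustworthy until
names are standardized to a single-ingredient vocabulary entity. Second,
the same clinical case enters the database several times — as follow-up
versions under one case identifier, and as independent submissions from
different sources (patient, clinician, manufacturer) under different case
identifiers — so report counts overstate case counts until the duplicates
are collapsed.

`faersforge` implements the curation pipeline that addresses both, plus
the disproportionality statistics computed on the curated result, plus a
synthetic-extract generator with a ground-truth ledger so that every stage
is testable without downloading the real database.

## Pipeline stages and their order

1. **Parse and merge.** Each quarter ships "$"-delimited ASCII files
   (DEMO, DRUG, REAC, INDI, THER, OUTC, RPSR, and from 2019Q1 a
   deleted-case list). The legacy era keys reports by `ISR`, the current
   era by `primaryid`; the legacy key is used verbatim as `primaryid`
   (the two fields play the same role; re-keying would only obscure
   provenance) and a `source` flag is retained. Every row is stamped with
   its quarter in a `period` column. Rows with the wrong field count are
   quarantined with their physical line numbers — parsed plus quarantined
   always equals the physical data lines, which is the row-conservation
   audit the tests enforce. Ages are normalized to years with the
   conventional calendar factors (decades ×10, months ÷12, weeks ÷52,
   days ÷365, hours ÷8760); results outside 0–150 years become missing
   rather than poisoning duplicate matching. Reporter countries are
   mapped to ISO 3166 alpha-2 codes through a bundled alias table, with a
   tally of unmatched strings kept for curation.

2. **Drug standardization.** The mapping cascade tries, in order:
   the report's new-drug-application number against an application
   register already mapped to the vocabulary; exact string match of the
   minimally cleaned name against the vocabulary; the multinational
   trade-name dictionary; a manual override table; then exact match and
   trade-name lookup again on the deeply cleaned name. The first hit
   wins and its stage is recorded as the row's provenance. Matched atoms
   are then resolved through vocabulary relations to ingredient-level
   atoms; a multi-ingredient product becomes one row per constituent,
   all sharing the parent `drug_id`, so combination products remain
   traceable. Exceptions follow the curation conventions: vaccines stay
   unsplit, atoms kept for finer granularity stay as-is, and ingredients
   maintained only in a non-primary source are flagged as such.

   The cascade is exact-lookup only. Fuzzy matching would silently remap
   names the curator never reviewed; instead, unmapped names above a
   frequency threshold (default 200) are listed for manual curation into
   the override table. The reported active-ingredient field (`prod_ai`,
   present from 2014Q3) is used only as a validator: when it contradicts
   the verbatim mapping, the verbatim mapping wins and the conflict is
   logged, because the verbatim name is what the cascade is defined over
   and `prod_ai` is absent for half the database's history.

3. **Deduplication.** Stage one keeps the most recent report per case
   identifier: maximum `caseversion`, ties broken by receipt date, then
   by numeric `primaryid`. Reports on deleted-case lists are removed.
   Stage two collapses cross-source duplicates using an eight-field
   signature: the set of standardized ingredients and the set of
   reaction preferred terms are *hard* keys that must match exactly;
   gender, age (whole years), country, event date, the set of therapy
   start dates, and the set of indication terms are *soft* keys of which
   at most one may mismatch. A report's start date is considered missing
   exactly when no non-null start date exists for its `primaryid`.

   Three decisions here were genuinely open:

   * **Null semantics.** Whether a soft field missing on one side is a
     match or a mismatch is not determined by the matching rule itself.
     We score it as a non-consuming *unknown* — neither a match nor the
     one allowed mismatch — because missingness degrades a criterion's
     evidential value rather than providing evidence either way. A
     `null_policy` switch (`unknown`/`match`/`mismatch`) exposes the
     alternatives.
   * **Drug comparison level.** Drugs are compared as standardized
     single-ingredient sets (mapping runs before cross-dedup), so
     "ASPIRIN" and "aspirin 81mg" entries compare equal. Rows the
     cascade leaves unmapped contribute their cleaned verbatim string to
     the hard key so they still discriminate cases. A `drug_level`
     switch allows verbatim-level comparison.
   * **Group closure.** The pairwise duplicate relation is not
     transitive, so pairwise edges are closed into disjoint groups by
     union–find; within a group the report with the latest receipt date
     (then highest id) is retained. Candidate pairs are restricted to
     blocks sharing both hard keys, which loses nothing because hard-key
     equality is necessary for any duplicate — the tests assert blocked
     search equals an exhaustive pairwise oracle.

   Partial dates (`YYYY`, `YYYYMM`) compare by exact string equality
   only; prefix matching would over-merge silently, and no imputation is
   attempted.

4. **Contingency table and statistics.** For every observed
   (ingredient, preferred term) pair, cell `a` counts distinct reports
   mentioning both, `b` reports of other drugs with the event, `c`
   reports of the drug with other events, and `d` the remainder; the
   counting unit is the report, never the mention, and
   `N = a + b + c + d` is constant across cells. The proportionate
   analysis computes, from the standard closed forms:

   * proportional reporting ratio `PRR = [a/(a+c)] / [b/(b+d)]` with
     95% interval `exp(ln PRR ± z·sqrt(1/a − 1/(a+c) + 1/b − 1/(b+d)))`;
   * reporting odds ratio `ROR = ad/(bc)` with
     `exp(ln ROR ± z·sqrt(1/a + 1/b + 1/c + 1/d))`;
   * Yates-corrected chi-squared
     `N·(max(0, |ad − bc| − N/2))² / [(a+c)(a+b)(b+d)(c+d)]`;
   * information component `IC = log2((a+0.5)/(aexp+0.5))` with
     `aexp = (a+b)(a+c)/N` and the closed-form credibility bounds
     `IC025 = IC − 3.3(a+0.5)^{−1/2} − 2(a+0.5)^{−3/2}`,
     `IC975 = IC + 2.4(a+0.5)^{−1/2} − 0.5(a+0.5)^{−3/2}`.

   Numerical choices: `z` is the exact 97.5% normal quantile (1.959964),
   not the rounded 1.96. The Yates correction is clamped at zero so an
   exactly proportional table scores 0 — the unclamped textbook
   expression would give spuriously positive values when
   `|ad − bc| < N/2`; the clamp matches the behaviour of standard
   continuity-corrected routines (`stats::chisq.test`), which the tests
   use as an independent reference. Ratio statistics on cells with a
   zero entry return `NA` with reason code `"zero-cell"` rather than
   silently applying a continuity correction; a `continuity = 0.5`
   opt-in gives Haldane-corrected finite estimates. The information
   component is total (finite even at `a = 0`) by its shrinkage
   construction. Logs are natural for the interval exponentials and
   base-2 for the information component.

5. **Export.** Eleven tab-delimited UTF-8 tables (demographics,
   standardized drugs, reactions, report–drug–event pairs, pair counts,
   indications with unknown-indication phrases deleted, outcomes,
   therapy dates, report sources, contingency table, proportionate
   analysis) plus a machine-readable data dictionary and a manifest with
   row counts, column lists and file checksums. Nulls are written as
   empty fields; therapy rows whose fully specified start date exceeds
   the end date are flagged, not dropped.

Mapping runs before cross-source deduplication: the duplicate signature
needs ingredient-level drug sets, and running the stages the other way
would make the hard key depend on unstandardized strings. The stage order
is recorded in each run's configuration.

## The synthetic generator: what it emulates and what it does not

`synth_config()` defines the study conditions; its defaults are the
documented marginal properties of the real database: 11% of gender
entries null with 54% female overall, 65% of reports from the US with 7%
missing country, 46% missing event date, 40% missing age, 42% of reports
without any therapy start date, and 12% without an informative
indication. Missingness is independent per field (the joint overlap of
event and start dates observed in the real data is not modelled).
Verbatim drug names are produced by corrupting vocabulary ingredient
names with the operator styles seen in real entries — case changes,
appended strengths and dosage forms, parenthesized echo, foreign trade
names, appended register codes, single-character typos — and the ledger
records the truth for every mention. Typos are deliberately outside the
exact cascade's reach and are asserted to stay unmapped.

Duplicates are re-emitted copies of base cases with fresh report and
case identifiers, identical drugs and reactions, and at most one
perturbed soft field. Distinct base cases that would collide on both
hard keys with fewer than three soft-field differences are pushed apart
during generation — preferentially by adding one background drug, which
moves the case to a different hard key without disturbing the
missingness margins or any planted cell, with a soft-field rewrite as a
last-resort fallback. The planted truth is therefore structurally
unambiguous: a single perturbed field can never bridge two different
true cases, which is what makes "100% recall, 0% false merges" a
well-defined target rather than a statistical hope.

Planted drug–event signals come in two forms: exact cell targets
(`a, b, c, d` summing to the case count; every drug kept recoverable so
no report drops from the pair universe), realized exactly when no
duplicates are injected; and probabilistic targets (drug exposure and
conditional event probabilities chosen so the true odds ratio equals a
target), used for interval-calibration studies.

What passing these tests shows — and what it does not: ground-truth
recovery on this generator demonstrates that the matching rule, the
cascade, and the counting are implemented correctly under the stated
conditions. It does not certify performance on the real database, where
name corruption is more diverse than the operator menu, missingness is
correlated, and true duplicates can differ in more than one soft field
(such duplicates are outside the rule's definition and are intentionally
not planted).

## Problem sizes

The test suite and the acceptance script use 10,000-case runs for
ground-truth recovery and missingness calibration, a 500-case run for
the blocked-versus-exhaustive equivalence check, 10⁴ random cells for
formula-level oracle equivalence, and 400 seeded 600-case replicates for
interval coverage — sizes chosen so each property is measured with
comfortable statistical resolution while a full run of everything stays
a desk-scale job. Full-scale curation of the real 2004–2021 extracts
(11.6M deduplicated reports in the published dataset) is supported by the
same code paths but is not part of any test: the published mapped
fraction (97.1%) additionally depends on a specific vocabulary release,
so it is treated as indicative, not reproducible.

## Known limitations

* The cascade never fuzzy-matches; recall on typo-heavy real data is
  bounded by the override table a curator maintains.
* Partial dates compare only by string equality; two reports recording
  the same event at different date precision count as an unknown, not a
  match.
* The union–find closure makes group membership order-independent but
  can chain A–B–C when A and C would not match pairwise; this is the
  price of disjoint groups and is shared by any transitive-closure
  deduplication.
* Multiple planted signals realize their `a`, `b`, `c` cells exactly;
  the `d` cell of each is the complement of the others' slices, so only
  a single planted signal can pin all four cells simultaneously.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_cases = 1000, seed = 42, duplicate_rate = 0.15,
                    quarters = c("2019Q4", "2020Q1"))
gen <- generate_extracts(cfg, "extracts")
cur <- curate_faers(gen$quarters, vocab = mini_vocabulary(),
                    idd = mini_idd(), nda_table = mini_nda_table(),
                    outdir = "curated")
glance(cur)        # stage counts, mapped fraction, pair count
tidy(cur) |>       # the proportionate-analysis table
  arrange(desc(ic025)) |> head()
autoplot(cur$signals)
```
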