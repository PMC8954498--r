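# shared fixture builders (everything constructed in code)

write_quarter_fixture <- function(dir, period = "2012Q1", legacy = FALSE,
                                  demo_lines = NULL, drug_lines = NULL,
                                  reac_lines = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(demo_lines)) {
    demo_lines <- if (legacy) c(
      "ISR$CASE$i_f_cod$event_dt$fda_dt$age$age_cod$gndr_cod$reporter_country",
      "7001$8001$I$20110101$20110301$44$YR$F$US",
      "7002$8002$I$$20110302$$$M$FRANCE",
      "7003$8003$I$20110215$20110315$3$DEC$$GERMANY"
    ) else c(
      "primaryid$caseid$caseversion$i_f_cod$event_dt$fda_dt$age$age_cod$sex$reporter_country",
      "1001$2001$1$I$20120101$20120301$44$YR$F$US",
      "1002$2002$1$I$$20120302$$$M$FRANCE",
      "1003$2003$2$F$20120215$20120315$3$DEC$$GERMANY"
    )
  }
  if (is.null(drug_lines)) {
    key <- if (legacy) "ISR" else "primaryid"
    hdr <- if (legacy) "ISR$drug_seq$role_cod$drugname$nda_num" else
      "primaryid$drug_seq$role_cod$drugname$prod_ai$nda_num"
    ids <- if (legacy) c("7001", "7002", "7003") else c("1001", "1002", "1003")
    body <- if (legacy) paste0(ids, "$1$PS$ALPRAZOVIR$") else
      paste0(ids, "$1$PS$ALPRAZOVIR$ALPRAZOVIR$")
    drug_lines <- c(hdr, body)
  }
  if (is.null(reac_lines)) {
    key <- if (legacy) "ISR" else "primaryid"
    ids <- if (legacy) c("7001", "7002", "7003") else c("1001", "1002", "1003")
    reac_lines <- c(paste0(key, "$pt"), paste0(ids, "$Headache"))
  }
  paths <- list(
    DEMO = file.path(dir, paste0("DEMO_", period, ".txt")),
    DRUG = file.path(dir, paste0("DRUG_", period, ".txt")),
    REAC = file.path(dir, paste0("REAC_", period, ".txt"))
  )
  writeLines(demo_lines, paths$DEMO)
  writeLines(drug_lines, paths$DRUG)
  writeLines(reac_lines, paths$REAC)
  faers_quarter(period, paths)
}

# minimal standardized-drug tibble for dedup tests: one row per
# (primaryid, ingredient token)
std_drugs_fixture <- function(primaryid, ingredients) {
  tibble::tibble(
    primaryid = rep(primaryid, lengths(ingredients)),
    verbatim_name = unlist(ingredients),
    ingredient_rxaui = unlist(ingredients)
  )
}

demo_fixture <- function(primaryid, caseid = primaryid, caseversion = 1L,
                         fda_dt = "20200101", gender = "F", age_years = 40,
                         country_code = "US", event_dt = "20190101") {
  n <- length(primaryid)
  tibble::tibble(
    primaryid = primaryid,
    caseid = rep_len(caseid, n),
    caseversion = rep_len(as.integer(caseversion), n),
    fda_dt = rep_len(fda_dt, n),
    gender = rep_len(gender, n),
    age_years = rep_len(age_years, n),
    country_code = rep_len(country_code, n),
    event_dt = rep_len(event_dt, n)
  )
}

empty_reac <- function() tibble::tibble(primaryid = character(), pt = character())
empty_indi <- function() tibble::tibble(primaryid = character(),
                                        indi_drug_seq = character(),
                                        pt = character())
empty_ther <- function() tibble::tibble(primaryid = character(),
                                        dsg_drug_seq = character(),
                                        start_dt = character())

reac_fixture <- function(primaryid, pts) {
  tibble::tibble(primaryid = rep(primaryid, lengths(pts)), pt = unlist(pts))
}
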