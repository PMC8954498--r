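#' Construct a drug vocabulary
#'
#' A vocabulary is the pluggable nomenclature the standardization cascade
#' maps against: a table of atoms (string-level entries, each with a
#' unique `rxaui`, a concept `rxcui`, a term type and a source
#' vocabulary) plus a relation table linking atoms (e.g. a brand to its
#' ingredient, a multi-ingredient product to its constituents). Both an
#' RRF-format reader ([read_rrf_vocabulary()]) and the bundled
#' [mini_vocabulary()] produce this same structure.
#'
#' @param concepts Tibble with columns `rxaui`, `rxcui`, `name`, `tty`
#'   (term type: `IN`/`PIN` ingredient level, `MIN` multi-ingredient,
#'   `BN` brand, `SCD` clinical drug, `VAC` vaccine class), `sab`
#'   (source vocabulary, `"RXNORM"` for the primary source), and
#'   optionally `flag` (`"granularity"` for atoms kept because another
#'   source expresses the components more precisely).
#' @param relations Tibble with columns `rxaui_from`, `rel` (one of
#'   `has_ingredient`, `consists_of`, `tradename_of`), `rxaui_to`.
#' @return A `faers_vocabulary` object.
#' @export
faers_vocabulary <- function(concepts, relations = NULL) {
  concepts <- as_tibble(concepts)
  req <- c("rxaui", "rxcui", "name", "tty", "sab")
  miss <- setdiff(req, names(concepts))
  if (length(miss)) abort(paste0("concepts is missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(concepts$rxaui)) abort("rxaui values must be unique")
  if (!"flag" %in% names(concepts)) concepts$flag <- NA_character_
  relations <- if (is.null(relations)) {
    tibble(rxaui_from = character(), rel = character(), rxaui_to = character())
  } else {
    as_tibble(relations)
  }
  concepts$name_key <- squish_upper(concepts$name)
  structure(list(concepts = concepts, relations = relations),
            class = "faers_vocabulary")
}

#' @export
print.faers_vocabulary <- function(x, ...) {
  cat("<faers_vocabulary> ", nrow(x$concepts), " atoms, ",
      nrow(x$relations), " relations\n", sep = "")
  invisible(x)
}

INGREDIENT_TTYS <- c("IN", "PIN")

#' Read an RRF-format vocabulary directory
#'
#' Reads pipe-delimited concept (`RXNCONSO.RRF`) and relationship
#' (`RXNREL.RRF`) files in the standard column layout and returns a
#' [faers_vocabulary()]. Only the columns the cascade needs are kept;
#' relationship rows without a named relation attribute are dropped.
#'
#' @param dir Directory containing `RXNCONSO.RRF` and (optionally)
#'   `RXNREL.RRF`.
#' @return A `faers_vocabulary`.
#' @export
read_rrf_vocabulary <- function(dir) {
  conso_path <- file.path(dir, "RXNCONSO.RRF")
  if (!file.exists(conso_path)) abort(paste0("RXNCONSO.RRF not found in ", dir))
  conso_cols <- c("RXCUI", "LAT", "TS", "LUI", "STT", "SUI", "ISPREF", "RXAUI",
                  "SAUI", "SCUI", "SDUI", "SAB", "TTY", "CODE", "STR", "SRL",
                  "SUPPRESS", "CVF", "X")
  conso <- readr::read_delim(conso_path, delim = "|", col_names = conso_cols,
                             col_types = readr::cols(.default = readr::col_character()),
                             na = character(), progress = FALSE)
  concepts <- tibble(
    rxaui = conso$RXAUI, rxcui = conso$RXCUI, name = conso$STR,
    tty = conso$TTY, sab = conso$SAB
  )
  rel_path <- file.path(dir, "RXNREL.RRF")
  relations <- NULL
  if (file.exists(rel_path)) {
    rel_cols <- c("RXCUI1", "RXAUI1", "STYPE1", "REL", "RXCUI2", "RXAUI2",
                  "STYPE2", "RELA", "RUI", "SRUI", "SAB", "SL", "RG", "DIR",
                  "SUPPRESS", "CVF", "X")
    rr <- readr::read_delim(rel_path, delim = "|", col_names = rel_cols,
                            col_types = readr::cols(.default = readr::col_character()),
                            na = character(), progress = FALSE)
    rr <- rr |> filter(.data$RELA != "")
    relations <- tibble(rxaui_from = rr$RXAUI1, rel = rr$RELA,
                        rxaui_to = rr$RXAUI2)
  }
  faers_vocabulary(concepts, relations)
}

# invented ingredient inventory shared by the mini vocabulary and the
# synthetic generator
mini_ingredient_names <- function() {
  c("ALPRAZOVIR", "BECLOTIDINE", "CARVEDOPA", "DEXTROFLOXACIN", "ELVATINIB",
    "FLUMAZEPRIL", "GALANTOPRIL", "HALOPERIDINE", "IBUTRAMINE", "JOSAMIVIR",
    "KETOPROLOL", "LAMOTRIGABINE", "METOPRAZINE", "NORFLOXETINE", "OLANZAPRIDE",
    "PAROXICAM", "QUETIAFLOZIN", "RIVASTATINE", "SERTRACLINE", "TOLTERANIB",
    "ULIPRAZOLE", "VENLAFLOXIN", "WARFECOXIB", "XYLOMETAZINE", "YOHIMBUTEROL",
    "ZALEPHRINE", "ACEBUTERONE", "BRIVARACINE", "CLOBAZAPINE", "DULOXEPRAM",
    "ESCITALIPINE", "FAMOTIGLINE", "GEMFIBROTIN", "HYDRALAZOPRIL", "INDOMETHACOL",
    "LEVOCETIMIDE", "MEMANTIGREL", "NALTREXIDONE", "OXCARBAZINE", "PIOGLITAVIR",
    "RALOXIFLUNE", "SITAGLIPTONE", "TAMSULOPRIM", "URSODIACIN", "VERAPARIBE",
    "ZIPRASIDIL", "AMLODIMUNE", "BENAZEPINE", "CILOSTAMIDE", "DONEPEZANE")
}

mini_brand_names <- function() {
  c("ALPRAZIN", "BECLOMAX", "CARVEX", "DEXTRONORM", "ELVAPRA",
    "FLUMAZEN", "GALANTEX", "HALOPEX", "IBUTRIN", "JOSAVEX")
}

#' Bundled miniature vocabulary
#'
#' A small invented vocabulary (all names are fictitious) large enough to
#' exercise every mapping branch: 50 single ingredients, two ingredients
#' maintained only in a non-primary source, one precise-granularity atom,
#' two vaccine-class atoms, four multi-ingredient products with
#' constituent relations, and ten brands with tradename relations.
#'
#' @return A `faers_vocabulary`.
#' @export
mini_vocabulary <- function() {
  ing <- mini_ingredient_names()
  ing_aui <- as.character(1000L + seq_along(ing))
  concepts <- tibble(
    rxaui = ing_aui, rxcui = paste0("C", ing_aui), name = ing,
    tty = "IN", sab = "RXNORM", flag = NA_character_
  )
  vac <- tibble(
    rxaui = c("1101", "1102"), rxcui = c("C1101", "C1102"),
    name = c("MENINGOVAX B VACCINE", "INFLUVAX QUADRIVALENT VACCINE"),
    tty = "VAC", sab = "RXNORM", flag = NA_character_
  )
  nonrx <- tibble(
    rxaui = c("1201", "1202"), rxcui = c("C1201", "C1202"),
    name = c("HERBALOSIDE EXTRACT", "POLYVITAMINUM COMPLEX"),
    tty = "IN", sab = "MMSL", flag = NA_character_
  )
  gran <- tibble(
    rxaui = "1301", rxcui = "C1301",
    name = "INSULIN GLARVINE RECOMBINANT",
    tty = "PIN", sab = "MMSL", flag = "granularity"
  )
  combos <- tibble(
    rxaui = c("1401", "1402", "1403", "1404"),
    rxcui = paste0("C", c("1401", "1402", "1403", "1404")),
    name = c("ALPRAZOVIR / BECLOTIDINE",
             "CARVEDOPA AND DEXTROFLOXACIN",
             "KETOPROLOL AND LAMOTRIGABINE",
             "METOPRAZINE / NORFLOXETINE"),
    tty = "MIN", sab = "RXNORM", flag = NA_character_
  )
  brands <- tibble(
    rxaui = as.character(1500L + seq_along(mini_brand_names())),
    rxcui = paste0("C", 1500L + seq_along(mini_brand_names())),
    name = mini_brand_names(),
    tty = "BN", sab = "RXNORM", flag = NA_character_
  )
  combo_parts <- list(c("1001", "1002"), c("1003", "1004"),
                      c("1011", "1012"), c("1013", "1014"))
  relations <- bind_rows(
    tibble(rxaui_from = rep(combos$rxaui, lengths(combo_parts)),
           rel = "has_ingredient",
           rxaui_to = unlist(combo_parts)),
    tibble(rxaui_from = brands$rxaui,
           rel = "tradename_of",
           rxaui_to = ing_aui[seq_along(mini_brand_names())])
  )
  faers_vocabulary(bind_rows(concepts, vac, nonrx, gran, combos, brands),
                   relations)
}

#' Bundled miniature multinational trade-name dictionary
#'
#' Maps 30 invented foreign trade names directly to atoms of the
#' bundled vocabulary, playing the role of an international drug
#' dictionary in the mapping cascade.
#'
#' @return Tibble with columns `trade_name`, `rxaui`.
#' @export
mini_idd <- function() {
  ing <- mini_ingredient_names()
  suffixes <- c("OLIA", "FORTE", "DIX", "AXOL", "PRA", "ZEN", "TEX", "PEX",
                "TRIN", "VEX", "ORAL", "MITE", "PLEX", "NEO", "SANO",
                "DUO", "VITA", "LUX", "MED", "PHARM", "GEN", "NOVA", "ULTRA",
                "EURO", "ASIA", "ANDES", "NORD", "SUD", "ALPHA", "OMEGA")
  tibble(
    trade_name = paste0(substr(ing[1:30], 1, 6), suffixes),
    rxaui = as.character(1000L + 1:30)
  )
}

#' Bundled miniature new-drug-application table
#'
#' Maps invented application numbers to brand atoms of the bundled
#' vocabulary, standing in for an approved-drugs register already mapped
#' to the vocabulary.
#'
#' @return Tibble with columns `nda_num`, `rxaui`.
#' @export
mini_nda_table <- function() {
  brands <- as.character(1500L + seq_along(mini_brand_names()))
  tibble(nda_num = as.character(200001L + seq_along(brands) * 7L),
         rxaui = brands)
}

#' Resolve an atom to single active ingredients
#'
#' Walks the vocabulary relation graph from a matched atom down to
#' ingredient-level atoms (term types `IN`/`PIN`). A multi-ingredient
#' atom resolves to one entry per constituent. Exceptions follow the
#' curation conventions: vaccine-class atoms are kept unsplit
#' (`exception_flag = "vaccine"`); atoms flagged for precise granularity
#' are kept as-is (`"granularity"`); ingredient atoms maintained only in
#' a non-primary source resolve to themselves with flag
#' `"nonRxNorm-ingredient"`. A walk that exceeds `max_hops` (cycle
#' guard) resolves to nothing.
#'
#' @param rxaui Atom identifier (scalar).
#' @param vocab A `faers_vocabulary`.
#' @param max_hops Bound on relation hops (default 5).
#' @return List with `ingredients` (character vector of ingredient
#'   rxauis, possibly empty) and `exception_flag` (one of `"none"`,
#'   `"granularity"`, `"vaccine"`, `"nonRxNorm-ingredient"`,
#'   `"unresolved"`).
#' @export
normalize_to_ingredients <- function(rxaui, vocab, max_hops = 5) {
  cn <- vocab$concepts
  row <- cn[cn$rxaui == rxaui, ]
  if (nrow(row) == 0L) abort(paste0("unknown rxaui: ", rxaui))
  if (row$tty == "VAC") {
    return(list(ingredients = rxaui, exception_flag = "vaccine"))
  }
  if (!is.na(row$flag) && row$flag == "granularity") {
    return(list(ingredients = rxaui, exception_flag = "granularity"))
  }
  if (row$tty %in% INGREDIENT_TTYS) {
    flag <- if (row$sab != "RXNORM") "nonRxNorm-ingredient" else "none"
    return(list(ingredients = rxaui, exception_flag = flag))
  }
  # breadth-first walk over outgoing relations
  frontier <- rxaui
  seen <- rxaui
  found <- character(0)
  for (hop in seq_len(max_hops)) {
    nxt <- vocab$relations$rxaui_to[vocab$relations$rxaui_from %in% frontier]
    nxt <- setdiff(unique(nxt), seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    tty_next <- cn$tty[match(nxt, cn$rxaui)]
    found <- c(found, nxt[tty_next %in% INGREDIENT_TTYS])
    frontier <- nxt
    if (length(found)) break
  }
  found <- unique(found)
  if (!length(found)) {
    return(list(ingredients = character(0), exception_flag = "unresolved"))
  }
  list(ingredients = sort(found), exception_flag = "none")
}
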