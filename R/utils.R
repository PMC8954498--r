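# shared internal helpers

# empty strings and literal NA markers become real NA
blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (trimws(x) == "" | trimws(x) == "NA")] <- NA_character_
  x
}

squish_upper <- function(x) toupper(stringr::str_squish(x))

is_period <- function(x) grepl("^\\d{4}Q[1-4]$", x)

# numeric-aware maximum of id strings (primaryids are digit strings of
# varying width; lexicographic comparison would misorder them)
max_id <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  n <- suppressWarnings(as.numeric(x))
  if (anyNA(n)) x[order(x, decreasing = TRUE)][1L] else x[which.max(n)]
}

stopifnot_scalar_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE", name))
  }
}

# deterministic sub-seed derivation (keeps results < 2^31 and reproducible)
derive_seed <- function(seed, k) {
  (as.integer(seed) * 48271L + as.integer(k)) %% 2147480009L
}
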