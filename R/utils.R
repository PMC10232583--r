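# internal helpers

# round-half-up to whole percent; base round() is round-half-even, which
# would report 92.5% as 92 rather than the conventional 93
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

pct <- function(num, den) {
  if (den == 0) return(NA_real_)
  round_half_up(100 * num / den)
}

is_missing_cell <- function(x) {
  is.na(x) | (is.character(x) & trimws(as.character(x)) == "")
}

# normalise a raw character cell vector: trimmed, "" -> NA
as_cells <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  x
}

# parse numerics, collecting a note for values that are non-missing but
# unparseable
parse_numeric <- function(x) {
  cells <- as_cells(x)
  out <- suppressWarnings(as.numeric(cells))
  bad <- !is.na(cells) & is.na(out)
  notes <- character()
  if (any(bad)) {
    notes <- sprintf("unparseable numeric value (n=%d): %s", sum(bad),
                     paste(unique(cells[bad])[1:min(3, length(unique(cells[bad])))],
                           collapse = ", "))
  }
  structure(out, notes = notes)
}

notes_of <- function(x) attr(x, "notes") %||% character()

# deterministic 32-bit sub-seed for a cohort, derived from the master seed;
# keyed by cohort_id so adding a cohort never shifts another's stream
cohort_seed <- function(seed, cohort_id) {
  h <- 0
  for (k in utf8ToInt(cohort_id)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(seed) %% 1000003) * 1009 + h) %% 2147483646L + 1L
}
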