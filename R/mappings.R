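rule_kinds <- c(
  # simple calibration
  "identity", "unit_convert", "date_truncate", "text_lookup",
  "alcohol_units",
  # algorithmic transformation
  "recode", "date_presence", "score_threshold", "proxy_condition",
  "any_positive", "smoking_two_field", "quantile", "apoe",
  # standardisation
  "zscore",
  # structural marker: variable legally not collectable in this cohort
  "not_collected"
)

#' Load and validate a per-cohort mapping file
#'
#' A mapping file holds one rule per harmonised variable for one cohort:
#' codebook recodes (native labels to target codes), binary inference rules
#' (diagnosis dates, symptom-score thresholds, proxy conditions), simple
#' calibrations (identity, unit conversion, date truncation, text lookup),
#' within-cohort income quantiles, and z-score standardisation directives.
#'
#' Validation checks that every rule targets a known schema variable, that
#' no variable has two rules, that recode/lookup targets lie inside the
#' target codebook, and that unit conversions have a finite nonzero factor.
#'
#' @param path Path to a mapping JSON file (see
#'   `csurv_file("mappings_airwave.json")` etc. for the packaged ones).
#' @param schema A `csurv_schema` the rules must conform to.
#' @return A `csurv_ruleset`: list with `cohort_id`, `display_name`,
#'   `currency`, `date_dialect` and `rules` (a named list of rule objects).
#' @export
#' @examples
#' sch <- load_schema()
#' rs <- load_mappings(csurv_file("mappings_genscot.json"), sch)
#' length(rs$rules)
load_mappings <- function(path, schema) {
  stopifnot(inherits(schema, "csurv_schema"))
  doc <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) {
      abort(sprintf("cannot parse mapping file '%s': %s", path,
                    conditionMessage(e)),
            class = "csurv_parse_error")
    }
  )
  vars <- schema$variables

  entries_to_named <- function(entries, value_as = as.integer) {
    setNames(vapply(entries, function(e) value_as(e$code %||% e$midpoint),
                    value_as(1)),
             vapply(entries, function(e) as.character(e$label), ""))
  }

  rules <- list()
  for (r in doc$rules) {
    vid <- as.character(r$variable_id)
    if (!vid %in% vars$variable_id) {
      abort(sprintf("mapping rule for unknown variable '%s'", vid),
            class = "csurv_unknown_variable_error")
    }
    if (!is.null(rules[[vid]])) {
      abort(sprintf("duplicate rule for (%s, %s)", doc$cohort_id, vid),
            class = "csurv_duplicate_rule_error")
    }
    kind <- as.character(r$kind)
    if (!kind %in% rule_kinds) {
      abort(sprintf("unknown rule kind '%s' for variable '%s'", kind, vid),
            class = "csurv_unknown_rule_kind_error")
    }
    rule <- r
    rule$kind <- kind
    spec_row <- vars[vars$variable_id == vid, ]
    cbk <- spec_row$codebook[[1]]
    if (kind == "recode") {
      rule$map <- entries_to_named(r$map)
      if (anyDuplicated(names(rule$map))) {
        abort(sprintf("duplicate source labels in recode table for '%s'",
                      vid),
              class = "csurv_duplicate_label_error")
      }
      if (!is.null(cbk) && !all(rule$map %in% cbk$code)) {
        bad <- setdiff(rule$map, cbk$code)
        abort(sprintf("recode target code(s) %s for '%s' not in codebook",
                      paste(bad, collapse = ", "), vid),
              class = "csurv_codebook_violation_error")
      }
      rule$unmapped_policy <- r$unmapped_policy %||% "missing"
    }
    if (kind == "text_lookup") {
      rule$lookup <- entries_to_named(r$lookup)
      if (!is.null(cbk) && !all(rule$lookup %in% cbk$code)) {
        abort(sprintf("lookup target outside codebook for '%s'", vid),
              class = "csurv_codebook_violation_error")
      }
    }
    if (kind == "quantile" && !is.null(r$bands)) {
      rule$bands <- entries_to_named(r$bands, as.numeric)
    }
    if (kind == "unit_convert") {
      f <- as.numeric(r$factor)
      if (!is.finite(f) || f == 0) {
        abort(sprintf("unit_convert factor for '%s' must be finite and nonzero",
                      vid),
              class = "csurv_invalid_rule_error")
      }
      rule$factor <- f
      rule$offset <- as.numeric(r$offset %||% 0)
    }
    if (kind == "score_threshold") {
      rule$threshold <- as.numeric(r$threshold)
      rule$direction <- match.arg(as.character(r$direction %||% "ge"),
                                  c("ge", "le"))
    }
    if (kind == "any_positive") {
      rule$sources <- vapply(r$sources, as.character, "")
    }
    rules[[vid]] <- rule
  }

  structure(
    list(
      cohort_id = as.character(doc$cohort_id),
      display_name = as.character(doc$display_name %||% doc$cohort_id),
      currency = as.character(doc$currency %||% NA_character_),
      date_dialect = as.character(doc$date_dialect %||% "ymd"),
      rules = rules
    ),
    class = "csurv_ruleset"
  )
}

#' Load the packaged mapping files for all four cohorts
#'
#' @param schema A `csurv_schema`; defaults to the packaged core schema.
#' @return Named list of `csurv_ruleset` objects
#'   (airwave, elsa, genscot, memento).
#' @export
load_all_mappings <- function(schema = load_schema()) {
  ids <- c("airwave", "elsa", "genscot", "memento")
  setNames(lapply(ids, function(cid)
    load_mappings(csurv_file(paste0("mappings_", cid, ".json")), schema)),
    ids)
}

#' @export
print.csurv_ruleset <- function(x, ...) {
  cat(sprintf("<csurv_ruleset> %s (%s): %d rules\n", x$cohort_id,
              x$display_name, length(x$rules)))
  kinds <- table(vapply(x$rules, `[[`, "", "kind"))
  cat("  ", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Apply a categorical recode table
#'
#' Maps native source labels to harmonised target codes.  Unmapped labels
#' never raise: they become missing (or a designated "other" code, when the
#' rule says so) and are reported in the `notes` attribute of the result.
#'
#' @param values Character vector of source labels.
#' @param rule A recode rule from [load_mappings()] (kind `"recode"`), or a
#'   bare named integer vector of `label -> code` entries.
#' @return Integer vector of target codes with a `notes` attribute
#'   describing unmapped labels.
#' @export
#' @examples
#' sch <- load_schema()
#' rs <- load_mappings(csurv_file("mappings_genscot.json"), sch)
#' apply_recode(c("Highers", "No qualification", "astronaut school"),
#'              rs$rules$educational_level)
apply_recode <- function(values, rule) {
  map <- if (is.list(rule)) rule$map else rule
  policy <- if (is.list(rule)) rule$unmapped_policy %||% "missing" else
    "missing"
  other_code <- if (is.list(rule)) rule$other_code else NULL
  cells <- as_cells(values)
  idx <- match(cells, names(map))
  out <- unname(as.integer(map[idx]))
  unmapped <- !is.na(cells) & is.na(idx)
  notes <- character()
  if (any(unmapped)) {
    labs <- sort(unique(cells[unmapped]))
    notes <- sprintf("unmapped label (n=%d): %s", sum(unmapped),
                     paste(head(labs, 5), collapse = ", "))
    if (identical(policy, "other_code") && !is.null(other_code)) {
      out[unmapped] <- as.integer(other_code)
    }
  }
  structure(out, notes = notes)
}

#' Infer a yes/no variable from indirect evidence
#'
#' Implements the three inference patterns used for medical history items:
#' `date_presence` (a recorded diagnosis date implies presence),
#' `score_threshold` (a symptom rating score at or beyond a cut-off), and
#' `proxy_condition` (a proxy field equal to its trigger label, e.g.
#' self-reported heart disease standing in for angina and MI).
#'
#' @param x Character vector: the source field values.
#' @param rule An inference rule (kind `date_presence`, `score_threshold`
#'   or `proxy_condition`).
#' @return Integer vector of 0/1/`NA` with a `notes` attribute.
#' @export
#' @examples
#' infer_binary(c("2009-03-02", ""),
#'              list(kind = "date_presence", dialect = "ymd"))
infer_binary <- function(x, rule) {
  kind <- rule$kind
  if (kind == "date_presence") {
    dates <- truncate_date(x, dialect = rule$dialect %||% "ymd",
                           quiet = TRUE)
    out <- as.integer(!is.na(dates))
    return(structure(out, notes = character()))
  }
  if (kind == "score_threshold") {
    num <- parse_numeric(x)
    notes <- notes_of(num)
    notes <- sub("unparseable numeric value", "unparseable score value",
                 notes)
    out <- if (rule$direction == "le") {
      as.integer(num <= rule$threshold)
    } else {
      as.integer(num >= rule$threshold)
    }
    return(structure(out, notes = notes))
  }
  if (kind == "proxy_condition") {
    cells <- as_cells(x)
    out <- as.integer(cells == rule$trigger)
    return(structure(out, notes = character()))
  }
  abort(sprintf("not an inference rule kind: '%s'", kind),
        class = "csurv_invalid_rule_error")
}

#' Truncate dates to ISO calendar dates
#'
#' Normalises date and datetime text to `yyyy-mm-dd` (Gregorian calendar),
#' discarding any time of day.  Two input dialects are supported: `"ymd"`
#' (`yyyy-mm-dd`, optionally followed by a time) and `"dmy"`
#' (`dd/mm/yyyy`).  Partial dates (year or year-month only) and
#' calendar-invalid dates are rejected to missing with a note, not imputed.
#'
#' @param x Character vector of date or datetime text.
#' @param dialect Input dialect, `"ymd"` or `"dmy"`.
#' @param quiet Suppress note collection (used by [infer_binary()], where a
#'   blank field is meaningful absence rather than a data problem).
#' @return Character vector of `yyyy-mm-dd` strings (or `NA`) with a
#'   `notes` attribute.
#' @export
#' @examples
#' truncate_date("2001-05-17T13:45:00")
#' truncate_date("17/05/2001", dialect = "dmy")
#' truncate_date("2001")  # partial -> NA
truncate_date <- function(x, dialect = c("ymd", "dmy"), quiet = FALSE) {
  dialect <- match.arg(dialect)
  cells <- as_cells(x)
  # strip a time-of-day suffix ("T13:45:00" or " 13:45:00")
  stripped <- sub("[T ][0-9]{2}:[0-9]{2}(:[0-9]{2})?$", "", cells)
  fmt <- if (dialect == "ymd") "%Y-%m-%d" else "%d/%m/%Y"
  pat <- if (dialect == "ymd") "^[0-9]{4}-[0-9]{2}-[0-9]{2}$" else
    "^[0-9]{2}/[0-9]{2}/[0-9]{4}$"
  ok_shape <- !is.na(stripped) & grepl(pat, stripped)
  parsed <- rep(as.Date(NA), length(cells))
  parsed[ok_shape] <- as.Date(stripped[ok_shape], format = fmt)
  out <- ifelse(is.na(parsed), NA_character_, format(parsed, "%Y-%m-%d"))
  notes <- character()
  if (!quiet) {
    partial <- !is.na(stripped) & grepl("^[0-9]{4}(-[0-9]{2})?$", stripped)
    if (any(partial)) {
      notes <- c(notes, sprintf("partial date (n=%d)", sum(partial)))
    }
    bad <- !is.na(stripped) & is.na(out) & !partial
    if (any(bad)) {
      notes <- c(notes, sprintf("unparseable date (n=%d): %s", sum(bad),
                                paste(head(unique(stripped[bad]), 3),
                                      collapse = ", ")))
    }
  }
  structure(out, notes = notes)
}

# pair of alleles (sorted) -> target code
apoe_codes <- c("2/2" = 1L, "2/3" = 2L, "2/4" = 3L, "3/3" = 4L,
                "3/4" = 5L, "4/4" = 6L)

#' Encode APOE genotype labels
#'
#' Normalises free-form APOE genotype labels (`"3/4"`, `"e3/e4"`,
#' `"E4E3"`, ...) to the 6-level harmonised coding over unordered allele
#' pairs: 1 = 2/2, 2 = 2/3, 3 = 2/4, 4 = 3/3, 5 = 3/4, 6 = 4/4.  Order of
#' alleles is irrelevant; anything that does not resolve to exactly two
#' alleles from \{2, 3, 4\} becomes missing with a note.
#'
#' @param x Character vector of genotype labels.
#' @return Integer vector of codes 1-6 with a `notes` attribute.
#' @export
#' @examples
#' encode_apoe(c("3/4", "4/3", "e2/e2"))  # 5, 5, 1
encode_apoe <- function(x) {
  cells <- as_cells(x)
  digits <- gsub("[^0-9]", "", ifelse(is.na(cells), "", cells))
  ok <- !is.na(cells) & nchar(digits) == 2 &
    grepl("^[234]{2}$", digits)
  pair <- ifelse(ok, paste(
    pmin(substr(digits, 1, 1), substr(digits, 2, 2)),
    pmax(substr(digits, 1, 1), substr(digits, 2, 2)), sep = "/"),
    NA_character_)
  out <- unname(apoe_codes[pair])
  bad <- !is.na(cells) & !ok
  notes <- if (any(bad)) {
    sprintf("invalid APOE genotype (n=%d): %s", sum(bad),
            paste(head(unique(cells[bad]), 3), collapse = ", "))
  } else character()
  structure(out, notes = notes)
}

#' Within-cohort income quantiles
#'
#' Assigns each participant an income quantile code 1-4, computed within
#' the cohort on non-missing values.  Boundaries are the order statistics
#' at ranks `ceiling(n/4)`, `ceiling(n/2)` and `ceiling(3n/4)`; ties go to
#' the lower quantile.  Banded incomes are first resolved to band
#' midpoints via `bands` (a named numeric vector `label -> midpoint`; the
#' packaged fixtures value an open-ended top band at 1.5 times its lower
#' bound).
#'
#' @param values Numeric incomes, or character band labels when `bands` is
#'   supplied (numeric text is also accepted).
#' @param bands Optional named numeric `label -> midpoint` map.
#' @return Integer vector of codes 1-4 with a `notes` attribute.  Fewer
#'   than 4 non-missing values yields all-missing plus a note.
#' @export
#' @examples
#' table(income_quantiles(1:100))
income_quantiles <- function(values, bands = NULL) {
  notes <- character()
  if (!is.null(bands)) {
    cells <- as_cells(values)
    idx <- match(cells, names(bands))
    x <- unname(as.numeric(bands[idx]))
    unmapped <- !is.na(cells) & is.na(idx)
    if (any(unmapped)) {
      notes <- c(notes, sprintf("unmapped income band (n=%d): %s",
                                sum(unmapped),
                                paste(head(unique(cells[unmapped]), 3),
                                      collapse = ", ")))
    }
  } else {
    x <- parse_numeric(values)
    notes <- c(notes, notes_of(x))
    x <- as.numeric(x)
  }
  n_ok <- sum(!is.na(x))
  if (n_ok < 4) {
    return(structure(rep(NA_integer_, length(x)),
                     notes = c(notes, "insufficient data for quantiles")))
  }
  s <- sort(x)
  q <- s[ceiling(n_ok * c(1, 2, 3) / 4)]
  code <- 1L + (x > q[1]) + (x > q[2]) + (x > q[3])
  structure(as.integer(code), notes = notes)
}
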