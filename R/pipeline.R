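# which rule kinds are compatible with which applied strategy
kind_strategy <- list(
  SC = c("identity", "unit_convert", "date_truncate", "text_lookup",
         "alcohol_units", "recode", "quantile", "apoe", "not_collected"),
  AT = c("recode", "date_presence", "score_threshold", "proxy_condition",
         "any_positive", "smoking_two_field", "quantile", "identity",
         "not_collected"),
  S = "zscore"
)

rule_sources <- function(rule) {
  if (rule$kind == "any_positive") return(rule$sources)
  if (rule$kind == "smoking_two_field") {
    return(c(rule$ever_field, rule$current_field))
  }
  if (rule$kind == "alcohol_units") {
    return(c(rule$source, rule$flag_field))
  }
  if (rule$kind == "not_collected") return(character())
  rule$source
}

#' Harmonise one variable of one cohort
#'
#' Dispatches a mapping rule against the raw table: calibration (identity,
#' unit conversion, date truncation, text lookup), categorical recode,
#' binary inference, income quantiles, or z-score standardisation.  A rule
#' whose kind is incompatible with the variable's strategy is a
#' configuration error raised before any data is touched; a missing source
#' field yields an all-missing column with a warning, not an error.
#'
#' @param raw A data frame of raw cohort data (character cells; empty
#'   string = missing).
#' @param spec One row of a schema's `variables` tibble.
#' @param rule The mapping rule for this (cohort, variable).
#' @return List with `values` (the harmonised column) and `provenance`
#'   (a one-row tibble: variable_id, rule_kind, n_mapped, n_missing,
#'   warnings) plus `transform` (standardisation details or `NULL`).
#' @export
harmonise_variable <- function(raw, spec, rule) {
  stopifnot(nrow(spec) == 1)
  strategy <- spec$applied_strategy
  if (!rule$kind %in% kind_strategy[[strategy]]) {
    abort(sprintf(
      "rule kind '%s' is incompatible with strategy '%s' for variable '%s'",
      rule$kind, strategy, spec$variable_id),
      class = "csurv_config_error")
  }

  n <- nrow(raw)
  notes <- character()
  transform <- NULL

  srcs <- rule_sources(rule)
  srcs <- srcs[!vapply(srcs, is.null, TRUE)]
  missing_src <- setdiff(unlist(srcs), names(raw))
  # a flag field is auxiliary; only required sources block the rule
  required <- if (rule$kind == "alcohol_units") rule$source else
    unlist(srcs)
  if (rule$kind != "not_collected" &&
      length(intersect(required, missing_src)) > 0) {
    values <- if (spec$type %in% c("categorical")) rep(NA_integer_, n) else
      if (spec$type == "quantitative" && rule$kind != "alcohol_units")
        rep(NA_real_, n) else rep(NA_character_, n)
    prov <- tibble(
      variable_id = spec$variable_id, rule_kind = rule$kind,
      n_mapped = 0L, n_missing = n,
      warnings = list(sprintf("source field(s) not found: %s",
                              paste(missing_src, collapse = ", "))))
    return(list(values = values, provenance = prov, transform = NULL))
  }

  values <- switch(
    rule$kind,
    identity = {
      if (identical(rule$value_type, "numeric")) {
        v <- parse_numeric(raw[[rule$source]])
        notes <- c(notes, notes_of(v))
        as.numeric(v)
      } else {
        as_cells(raw[[rule$source]])
      }
    },
    unit_convert = {
      v <- parse_numeric(raw[[rule$source]])
      notes <- c(notes, notes_of(v))
      as.numeric(v) * rule$factor + rule$offset
    },
    date_truncate = {
      v <- truncate_date(raw[[rule$source]], dialect = rule$dialect)
      notes <- c(notes, notes_of(v))
      as.character(v)
    },
    text_lookup = {
      cells <- as_cells(raw[[rule$source]])
      idx <- match(tolower(cells), tolower(names(rule$lookup)))
      out <- unname(as.integer(rule$lookup[idx]))
      unmatched <- !is.na(cells) & is.na(idx)
      if (any(unmatched)) {
        notes <- c(notes, sprintf("unmatched text (n=%d)", sum(unmatched)))
      }
      out
    },
    recode = {
      v <- apply_recode(raw[[rule$source]], rule)
      notes <- c(notes, notes_of(v))
      as.integer(v)
    },
    date_presence = ,
    score_threshold = ,
    proxy_condition = {
      v <- infer_binary(raw[[rule$source]], rule)
      notes <- c(notes, notes_of(v))
      as.integer(v)
    },
    any_positive = {
      cols <- lapply(rule$sources, function(s) {
        v <- parse_numeric(raw[[s]])
        notes <<- c(notes, notes_of(v))
        as.numeric(v)
      })
      mat <- do.call(cbind, cols)
      any_pos <- apply(mat, 1, function(r) any(!is.na(r) & r > 0))
      any_obs <- apply(mat, 1, function(r) any(!is.na(r)))
      out <- ifelse(any_pos, 1L, ifelse(any_obs, 0L, NA_integer_))
      as.integer(out)
    },
    smoking_two_field = {
      ever <- as_cells(raw[[rule$ever_field]])
      cur <- as_cells(raw[[rule$current_field]])
      out <- rep(NA_integer_, n)
      out[!is.na(ever) & ever == rule$no] <- 0L
      # ever-smokers: current field resolves past vs current; when it is
      # missing the documented convention is "past"
      is_ever <- !is.na(ever) & ever == rule$yes
      out[is_ever] <- ifelse(!is.na(cur[is_ever]) &
                               cur[is_ever] == rule$yes, 2L, 1L)
      out
    },
    alcohol_units = {
      v <- parse_numeric(raw[[rule$source]])
      notes <- c(notes, notes_of(v))
      out <- ifelse(is.na(v), NA_character_,
                    format(as.numeric(v), trim = TRUE, digits = 10))
      if (!is.null(rule$flag_field) && rule$flag_field %in% names(raw)) {
        flag <- as_cells(raw[[rule$flag_field]])
        hit <- is.na(v) & !is.na(flag) & flag == rule$flag_trigger
        if (any(hit)) {
          out[hit] <- "other"
          notes <- c(notes, sprintf(
            "consumption present but not quantifiable (n=%d): coded 'other'",
            sum(hit)))
        }
      }
      out
    },
    quantile = {
      v <- income_quantiles(raw[[rule$source]], bands = rule$bands)
      notes <- c(notes, notes_of(v))
      as.integer(v)
    },
    apoe = {
      v <- encode_apoe(raw[[rule$source]])
      notes <- c(notes, notes_of(v))
      as.integer(v)
    },
    zscore = {
      v <- parse_numeric(raw[[rule$source]])
      notes <- c(notes, notes_of(v))
      x <- as.numeric(v)
      if (sum(!is.na(x)) < 3 || (sum(!is.na(x)) > 0 &&
                                 sd(x, na.rm = TRUE) == 0)) {
        notes <- c(notes, "cannot standardise: too few or constant scores")
        rep(NA_real_, n)
      } else {
        res <- zscore_standardise(x,
                                  skew_threshold = rule$skew_threshold %||% 1)
        transform <- list(transform_applied = res$transform_applied,
                          skewness = res$skewness, shift = res$shift)
        if (res$transform_applied == "log_e") {
          notes <- c(notes, sprintf(
            "log_e normalisation applied before z-scoring (skew=%.2f)",
            res$skewness))
        }
        res$z_values
      }
    },
    not_collected = {
      notes <- c(notes, rule$reason %||% "not collected")
      NULL
    }
  )

  n_missing <- if (is.null(values)) n else sum(is.na(values))
  prov <- tibble(
    variable_id = spec$variable_id, rule_kind = rule$kind,
    n_mapped = n - n_missing, n_missing = n_missing,
    warnings = list(notes))
  list(values = values, provenance = prov, transform = transform)
}

#' Harmonise a raw cohort table
#'
#' Runs every mapping rule of a cohort's rule set against its raw table,
#' producing a schema-conformant harmonised table and a provenance log.
#' The output holds exactly the variables that have a rule and a source in
#' this cohort (variables a cohort does not collect are omitted, not
#' emitted as all-missing); `not_collected` marker rules contribute a
#' provenance entry only.  Row count is always preserved and the run is
#' deterministic.
#'
#' @param raw Raw cohort table (data frame of character cells, one row per
#'   participant).
#' @param schema A `csurv_schema`.
#' @param ruleset A `csurv_ruleset` for this cohort.
#' @return A `csurv_harmonised` tibble, with attributes `cohort_id`,
#'   `provenance` (tibble, one row per processed variable), and
#'   `transforms` (standardisation details per z-scored variable).
#' @export
#' @examples
#' sch <- load_schema()
#' maps <- load_all_mappings(sch)
#' raw <- generate_cohort("genscot", n = 50, seed = 1)
#' h <- harmonise_cohort(raw, sch, maps$genscot)
#' ncol(h)
harmonise_cohort <- function(raw, schema, ruleset) {
  stopifnot(inherits(schema, "csurv_schema"),
            inherits(ruleset, "csurv_ruleset"))
  raw_cohort <- attr(raw, "cohort_id")
  if (!is.null(raw_cohort) && !identical(raw_cohort, ruleset$cohort_id)) {
    abort(sprintf("rule set is for '%s' but raw table is for '%s'",
                  ruleset$cohort_id, raw_cohort),
          class = "csurv_config_error")
  }
  if (anyDuplicated(names(raw))) {
    abort("raw table has duplicate column names",
          class = "csurv_invalid_input_error")
  }
  vars <- schema$variables
  # process in schema (row_number) order
  ids <- vars$variable_id[vars$variable_id %in% names(ruleset$rules)]

  cols <- list()
  prov <- list()
  transforms <- list()
  for (vid in ids) {
    spec <- vars[vars$variable_id == vid, ]
    res <- harmonise_variable(raw, spec, ruleset$rules[[vid]])
    if (!is.null(res$values)) cols[[vid]] <- res$values
    prov[[vid]] <- res$provenance
    if (!is.null(res$transform)) transforms[[vid]] <- res$transform
  }
  out <- if (length(cols)) as_tibble(cols) else tibble(.rows = nrow(raw))
  attr(out, "cohort_id") <- ruleset$cohort_id
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  attr(out, "transforms") <- transforms
  class(out) <- c("csurv_harmonised", class(out))
  out
}

#' Provenance log of a harmonised table
#'
#' @param x A `csurv_harmonised` table.
#' @return Tibble with one row per processed (cohort, variable):
#'   `variable_id`, `rule_kind`, `n_mapped`, `n_missing`, `warnings`.
#' @export
provenance <- function(x) attr(x, "provenance")

#' Write a harmonised table with its data dictionary sidecar
#'
#' Writes the table as CSV (missing cells as empty fields) plus a JSON
#' sidecar data dictionary (`<path minus .csv>.dict.json`) describing each
#' column: type, units, codebook and any standardisation transform.
#' Reading the pair back with [read_harmonised()] reproduces the table.
#'
#' @param table A `csurv_harmonised` table.
#' @param path Output CSV path.
#' @param schema The schema the table conforms to.
#' @return Invisibly, a list with the `csv` and `dict` paths.
#' @export
write_harmonised <- function(table, path, schema) {
  stopifnot(inherits(schema, "csurv_schema"))
  readr::write_csv(as_tibble(as.data.frame(table)), path, na = "")
  vars <- schema$variables
  transforms <- attr(table, "transforms") %||% list()
  columns <- lapply(names(table), function(vid) {
    spec <- vars[vars$variable_id == vid, ]
    cbk <- spec$codebook[[1]]
    list(
      variable_id = vid,
      display_name = spec$display_name,
      type = spec$type,
      units = if (is.na(spec$units)) NULL else spec$units,
      codebook = if (is.null(cbk)) NULL else
        lapply(seq_len(nrow(cbk)), function(j)
          list(code = cbk$code[j], label = cbk$label[j])),
      transform = transforms[[vid]]
    )
  })
  dict_path <- paste0(sub("\\.csv$", "", path), ".dict.json")
  jsonlite::write_json(
    list(cohort_id = attr(table, "cohort_id"), n_rows = nrow(table),
         columns = columns),
    dict_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(csv = path, dict = dict_path))
}

#' Read a harmonised table written by [write_harmonised()]
#'
#' @param path CSV path (the sidecar is located next to it).
#' @param schema The schema used when writing.
#' @return A `csurv_harmonised` tibble (without provenance, which is not
#'   serialised).
#' @export
read_harmonised <- function(path, schema) {
  stopifnot(inherits(schema, "csurv_schema"))
  dict_path <- paste0(sub("\\.csv$", "", path), ".dict.json")
  dict <- jsonlite::read_json(dict_path)
  vars <- schema$variables
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  col_for <- function(vid) {
    spec <- vars[vars$variable_id == vid, ]
    if (nrow(spec) == 0) return(readr::col_character())
    if (spec$type == "categorical") return(readr::col_integer())
    if (spec$type == "quantitative") {
      # alcohol consumption admits the sentinel category "other"
      if (identical(spec$units, "units/week")) return(readr::col_character())
      return(readr::col_double())
    }
    if (spec$type == "text" && !is.null(spec$codebook[[1]])) {
      return(readr::col_integer())
    }
    readr::col_character()
  }
  types <- do.call(readr::cols, setNames(lapply(header, col_for), header))
  out <- readr::read_csv(path, col_types = types, na = "",
                         show_col_types = FALSE)
  attr(out, "cohort_id") <- dict$cohort_id
  class(out) <- c("csurv_harmonised", class(out))
  out
}

#' @export
print.csurv_harmonised <- function(x, ...) {
  cat(sprintf("<csurv_harmonised> cohort '%s': %d participants x %d variables\n",
              attr(x, "cohort_id") %||% "?", nrow(x), ncol(x)))
  NextMethod()
}

#' Check harmonised values against the schema codebooks
#'
#' Verifies the closure invariant: every non-missing cell of a categorical
#' (or coded-text) column is a member of that variable's codebook.
#'
#' @param table A `csurv_harmonised` table.
#' @param schema The schema.
#' @return `TRUE` invisibly, or an error naming the offending column.
#' @export
check_codebook_closure <- function(table, schema) {
  vars <- schema$variables
  for (vid in names(table)) {
    spec <- vars[vars$variable_id == vid, ]
    cbk <- spec$codebook[[1]]
    if (is.null(cbk)) next
    vals <- table[[vid]]
    bad <- !is.na(vals) & !(vals %in% cbk$code)
    if (any(bad)) {
      abort(sprintf("codebook closure violated for '%s': values %s",
                    vid, paste(unique(vals[bad]), collapse = ", ")),
            class = "csurv_closure_error")
    }
  }
  invisible(TRUE)
}
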