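#' Path to a packaged fixture file
#'
#' Convenience accessor for the files shipped under `inst/extdata`: the
#' C-Surv core schema (`csurv_core_124.json`), the per-cohort mapping files
#' (`mappings_airwave.json`, ...) and the presence-matrix fixture
#' (`presence_matrix.csv`).
#'
#' @param name File name; with no argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' csurv_file()
#' csurv_file("csurv_core_124.json")
csurv_file <- function(name = NULL) {
  if (is.null(name)) {
    return(dir(system.file("extdata", package = "csurv")))
  }
  path <- system.file("extdata", name, package = "csurv")
  if (path == "") {
    abort(sprintf("no packaged file '%s'", name), class = "csurv_file_error")
  }
  path
}

valid_strategies <- c("SC", "AT", "S")

#' Load and validate a C-Surv harmonisation schema
#'
#' Reads a JSON schema document containing a `themes` list (the 18 C-Surv
#' level-1 data themes) and a `variables` list (the harmonisation target
#' variables with their strategy tags, codebooks and units), and validates
#' every structural invariant: unique identifiers, known themes, known
#' strategy tags, codebooks for categorical variables and units for
#' quantitative ones.
#'
#' Each variable carries two strategy tags: `declared_strategy`, the tag in
#' the published core variable list, and `applied_strategy`, the
#' classification used when the rules were actually applied to cohorts
#' (where many yes/no items counted as algorithmic transformations).
#' [strategy_tally()] can count either.
#'
#' @param path Path to a schema JSON file. Defaults to the packaged
#'   124-variable core schema.
#' @return An object of class `csurv_schema`: a list with `schema_name`,
#'   `version`, `themes` (a tibble) and `variables` (a tibble with
#'   list-columns `codebook`).
#' @export
#' @examples
#' sch <- load_schema()
#' nrow(sch$variables)
#' themes_covered(sch)
load_schema <- function(path = csurv_file("csurv_core_124.json")) {
  doc <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) {
      abort(sprintf("cannot parse schema file '%s': %s", path,
                    conditionMessage(e)),
            class = "csurv_parse_error")
    }
  )

  themes <- tibble(
    theme_number = vapply(doc$themes, function(t) as.integer(t$theme_number),
                          integer(1)),
    theme_name = vapply(doc$themes, function(t) as.character(t$theme_name),
                        character(1))
  )
  if (anyDuplicated(themes$theme_number) ||
      any(themes$theme_number < 1 | themes$theme_number > 18)) {
    abort("theme numbers must be unique and within 1-18",
          class = "csurv_unknown_theme_error")
  }

  if (length(doc$variables) == 0) {
    abort("no variables defined", class = "csurv_empty_schema_error")
  }

  # tolerate absent / null / empty-list fields from any JSON writer
  scalar_or <- function(x, default) {
    if (is.null(x) || length(x) == 0) default else as.character(x[[1]])
  }

  parse_codebook <- function(cbk) {
    if (is.null(cbk) || length(cbk) == 0) return(NULL)
    tibble(
      code = vapply(cbk, function(e) as.integer(e$code), integer(1)),
      label = vapply(cbk, function(e) as.character(e$label), character(1))
    )
  }

  vars <- tibble(
    variable_id = vapply(doc$variables, function(x)
      as.character(x$variable_id), character(1)),
    display_name = vapply(doc$variables, function(x)
      as.character(x$display_name), character(1)),
    row_number = vapply(doc$variables, function(x)
      as.integer(x$row_number), integer(1)),
    theme_number = vapply(doc$variables, function(x)
      as.integer(x$theme_number), integer(1)),
    declared_strategy = vapply(doc$variables, function(x)
      as.character(x$declared_strategy), character(1)),
    applied_strategy = vapply(doc$variables, function(x)
      scalar_or(x$applied_strategy, as.character(x$declared_strategy)),
      character(1)),
    type = vapply(doc$variables, function(x) as.character(x$type),
                  character(1)),
    rule_text = vapply(doc$variables, function(x)
      scalar_or(x$rule_text, ""), character(1)),
    units = vapply(doc$variables, function(x)
      scalar_or(x$units, NA_character_), character(1)),
    codebook = lapply(doc$variables, function(x) parse_codebook(x$codebook)),
    missing_policy = vapply(doc$variables, function(x)
      scalar_or(x$missing_policy, "empty field"), character(1)),
    interpretive = vapply(doc$variables, function(x)
      isTRUE(x$interpretive), logical(1))
  )

  dup <- vars$variable_id[duplicated(vars$variable_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate variable_id: %s",
                  paste(unique(dup), collapse = ", ")),
          class = "csurv_duplicate_id_error")
  }
  unknown_theme <- setdiff(vars$theme_number, themes$theme_number)
  if (length(unknown_theme) > 0) {
    abort(sprintf("unknown theme number: %s",
                  paste(unknown_theme, collapse = ", ")),
          class = "csurv_unknown_theme_error")
  }
  for (col in c("declared_strategy", "applied_strategy")) {
    bad <- setdiff(unique(vars[[col]]), valid_strategies)
    if (length(bad) > 0) {
      abort(sprintf("unknown strategy tag: %s", paste(bad, collapse = ", ")),
            class = "csurv_unknown_strategy_error")
    }
  }

  # categorical variables need a codebook; quantitative ones need units
  for (i in seq_len(nrow(vars))) {
    cbk <- vars$codebook[[i]]
    if (vars$type[i] == "categorical") {
      if (is.null(cbk) || nrow(cbk) == 0) {
        abort(sprintf("categorical variable '%s' has no codebook",
                      vars$variable_id[i]),
              class = "csurv_invalid_variable_error")
      }
    }
    if (!is.null(cbk)) {
      if (anyDuplicated(cbk$code) || any(!nzchar(cbk$label))) {
        abort(sprintf("invalid codebook for '%s': codes must be unique and labels non-empty",
                      vars$variable_id[i]),
              class = "csurv_codebook_error")
      }
    }
    if (vars$type[i] == "quantitative" && is.na(vars$units[i])) {
      abort(sprintf("quantitative variable '%s' has no units",
                    vars$variable_id[i]),
            class = "csurv_invalid_variable_error")
    }
  }

  structure(
    list(
      schema_name = doc$schema_name %||% "csurv_schema",
      version = doc$version %||% "1.0",
      themes = themes,
      variables = vars
    ),
    class = "csurv_schema"
  )
}

#' Write a schema back to JSON
#'
#' Inverse of [load_schema()]; writing a loaded schema and re-loading it
#' yields an identical object (order, identifiers and codebooks preserved).
#'
#' @param schema A `csurv_schema` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "csurv_schema"))
  vars <- schema$variables
  doc <- list(
    schema_name = schema$schema_name,
    version = schema$version,
    themes = lapply(seq_len(nrow(schema$themes)), function(i)
      list(theme_number = schema$themes$theme_number[i],
           theme_name = schema$themes$theme_name[i])),
    variables = lapply(seq_len(nrow(vars)), function(i) {
      cbk <- vars$codebook[[i]]
      list(
        variable_id = vars$variable_id[i],
        display_name = vars$display_name[i],
        row_number = vars$row_number[i],
        theme_number = vars$theme_number[i],
        declared_strategy = vars$declared_strategy[i],
        applied_strategy = vars$applied_strategy[i],
        type = vars$type[i],
        rule_text = vars$rule_text[i],
        units = if (is.na(vars$units[i])) NULL else vars$units[i],
        codebook = if (is.null(cbk)) NULL else
          lapply(seq_len(nrow(cbk)), function(j)
            list(code = cbk$code[j], label = cbk$label[j])),
        missing_policy = vars$missing_policy[i],
        interpretive = vars$interpretive[i]
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @export
print.csurv_schema <- function(x, ...) {
  cat(sprintf("<csurv_schema> %s v%s\n", x$schema_name, x$version))
  cat(sprintf("  %d variables across %d of %d themes\n",
              nrow(x$variables), length(themes_covered(x)),
              nrow(x$themes)))
  tl <- strategy_tally(x, which = "declared")
  cat(sprintf("  declared strategies: SC %d, AT %d, S %d\n",
              tl[["SC"]], tl[["AT"]], tl[["S"]]))
  invisible(x)
}

schema_vars <- function(x) {
  if (inherits(x, "csurv_schema")) x$variables else as_tibble(x)
}

#' Data themes covered by a set of variable specifications
#'
#' @param specs A `csurv_schema` or its `variables` tibble (possibly
#'   subsetted).
#' @return Sorted integer vector of distinct theme numbers (empty for empty
#'   input).
#' @export
#' @examples
#' themes_covered(load_schema())  # 15 of the 18 themes
themes_covered <- function(specs) {
  vars <- schema_vars(specs)
  sort(unique(vars$theme_number))
}

#' Tally harmonisation strategies
#'
#' Counts variables per harmonisation strategy (`SC` simple calibration,
#' `AT` algorithmic transformation, `S` standardisation).  Counts always sum
#' to the number of (restricted) variables.
#'
#' @param specs A `csurv_schema` or its `variables` tibble.
#' @param restrict_to Optional character vector of variable ids to restrict
#'   the tally to (e.g. the variables represented in at least one cohort).
#'   Unknown ids are an error.
#' @param which Count the `"applied"` (default) or `"declared"` strategy
#'   tag.
#' @return Named integer vector with elements `SC`, `AT` and `S`.
#' @export
#' @examples
#' sch <- load_schema()
#' strategy_tally(sch, which = "declared")
strategy_tally <- function(specs, restrict_to = NULL,
                           which = c("applied", "declared")) {
  which <- match.arg(which)
  vars <- schema_vars(specs)
  if (!is.null(restrict_to)) {
    unknown <- setdiff(restrict_to, vars$variable_id)
    if (length(unknown) > 0) {
      abort(sprintf("unknown variable ids in restrict_to: %s",
                    paste(unknown, collapse = ", ")),
            class = "csurv_unknown_id_error")
    }
    vars <- vars[vars$variable_id %in% restrict_to, ]
  }
  col <- paste0(which, "_strategy")
  counts <- table(factor(vars[[col]], levels = valid_strategies))
  out <- as.integer(counts)
  names(out) <- valid_strategies
  out
}
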