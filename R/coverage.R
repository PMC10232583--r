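new_presence <- function(m) {
  stopifnot(is.matrix(m), all(m %in% c(0L, 1L)))
  storage.mode(m) <- "integer"
  structure(m, class = "csurv_presence")
}

#' The packaged presence-matrix fixture
#'
#' A binary variable-by-cohort grid recording which of the 124 core
#' variables each of the four evaluation cohorts can supply.  Per-variable
#' presence is not published; this matrix is constructed to jointly satisfy
#' every printed coverage count (theme-by-cohort table, per-cohort totals,
#' the cross-cohort overlap distribution, the four variables absent
#' everywhere, and the ELSA/Memento unique-variable counts).
#'
#' @return A `csurv_presence` integer matrix (rows = variable ids,
#'   columns = cohort ids).
#' @export
#' @examples
#' m <- presence_fixture()
#' colSums(m)
presence_fixture <- function() {
  df <- utils::read.csv(csurv_file("presence_matrix.csv"),
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$variable_id
  new_presence(m)
}

#' Build a presence matrix from harmonised tables
#'
#' A variable counts as present for a cohort when the cohort's rule set
#' produced a harmonised column for it (i.e. it has a rule and the source
#' fields exist); `not_collected` markers do not count.
#'
#' @param tables Named list of `csurv_harmonised` tables (or any data
#'   frames whose columns are variable ids), one per cohort.  Names (or
#'   `cohort_id` attributes) must be distinct cohort ids.
#' @param schema A `csurv_schema`; rows of the matrix cover all schema
#'   variables in schema order.
#' @return A `csurv_presence` matrix.
#' @export
build_presence <- function(tables, schema = load_schema()) {
  ids <- names(tables) %||% vapply(tables, function(t)
    attr(t, "cohort_id") %||% NA_character_, character(1))
  if (anyDuplicated(ids) || any(is.na(ids))) {
    abort("cohort ids must be present and distinct",
          class = "csurv_duplicate_cohort_error")
  }
  vids <- schema$variables$variable_id
  unknown <- setdiff(unlist(lapply(tables, names)), vids)
  if (length(unknown) > 0) {
    abort(sprintf("columns not in schema: %s",
                  paste(unknown, collapse = ", ")),
          class = "csurv_unknown_variable_error")
  }
  m <- vapply(tables, function(t) as.integer(vids %in% names(t)),
              integer(length(vids)))
  rownames(m) <- vids
  colnames(m) <- ids
  new_presence(m)
}

#' Theme-by-cohort coverage counts
#'
#' For each C-Surv theme with at least one schema variable, the number of
#' variables each cohort supplies, alongside the theme's size in the
#' schema.  Per-cohort totals (the column sums) are attached as the
#' `totals` attribute; conservation (totals = sum of theme counts) is
#' asserted on every call.
#'
#' @param matrix A `csurv_presence` matrix.
#' @param schema A `csurv_schema`.
#' @return Tibble with `theme_number`, `theme_name`, `n_variables` and one
#'   count column per cohort; attribute `totals`.
#' @export
#' @examples
#' theme_coverage(presence_fixture(), load_schema())
theme_coverage <- function(matrix, schema) {
  vars <- schema$variables
  unknown <- setdiff(rownames(matrix), vars$variable_id)
  if (length(unknown) > 0) {
    abort(sprintf("variables not in schema: %s",
                  paste(unknown, collapse = ", ")),
          class = "csurv_unknown_variable_error")
  }
  theme_of <- vars$theme_number[match(rownames(matrix), vars$variable_id)]
  counts <- rowsum(matrix + 0L, group = theme_of)
  themes_present <- as.integer(rownames(counts))
  out <- tibble(
    theme_number = themes_present,
    theme_name = schema$themes$theme_name[
      match(themes_present, schema$themes$theme_number)],
    n_variables = as.integer(table(factor(theme_of,
                                          levels = themes_present)))
  )
  for (cid in colnames(matrix)) out[[cid]] <- unname(counts[, cid])
  totals <- colSums(matrix)
  # conservation: per-cohort total equals the sum over themes
  stopifnot(all(colSums(counts) == totals))
  attr(out, "totals") <- totals
  out
}

#' Cross-cohort overlap distribution
#'
#' Tabulates, for k = 0 .. number of cohorts, how many variables are
#' present in exactly k cohorts.  The histogram always reports the 0-cohort
#' bin explicitly and sums to the number of variables.
#'
#' @param matrix A `csurv_presence` matrix.
#' @return Named integer vector over `"0" ... "<n_cohorts>"`.
#' @export
#' @examples
#' overlap_distribution(presence_fixture())
overlap_distribution <- function(matrix) {
  k <- ncol(matrix)
  h <- table(factor(rowSums(matrix), levels = 0:k))
  out <- as.integer(h)
  names(out) <- as.character(0:k)
  stopifnot(sum(out) == nrow(matrix))
  out
}

#' Correspondence between the schema and cohort data models
#'
#' Splits the represented variables (present in at least one cohort) into
#' those whose correspondence with the cohorts' own data models is
#' complete or close, and those requiring interpretive transformation
#' (simplified scales, proxy indices).  Percentages are reported against
#' the represented denominator, rounded half-up to whole percent.
#'
#' @param matrix A `csurv_presence` matrix.
#' @param interpretive_ids Character vector of variable ids flagged as
#'   interpretive; must all be represented.
#' @return List with `represented`, `interpretive`, `complete_or_close`,
#'   and the corresponding percentages.
#' @export
correspondence_summary <- function(matrix, interpretive_ids) {
  represented_ids <- rownames(matrix)[rowSums(matrix) > 0]
  missing <- setdiff(interpretive_ids, represented_ids)
  if (length(missing) > 0) {
    abort(sprintf("interpretive ids not represented in any cohort: %s",
                  paste(missing, collapse = ", ")),
          class = "csurv_unknown_variable_error")
  }
  represented <- length(represented_ids)
  interpretive <- length(unique(interpretive_ids))
  complete_or_close <- represented - interpretive
  list(
    represented = represented,
    interpretive = interpretive,
    complete_or_close = complete_or_close,
    pct_complete_or_close = pct(complete_or_close, represented),
    pct_interpretive = pct(interpretive, represented)
  )
}

#' Full coverage report
#'
#' Combines the coverage analytics into one object: theme-by-cohort
#' counts, per-cohort totals, the overlap distribution, the applied
#' strategy tally over represented variables, and the correspondence
#' summary.
#'
#' @param matrix A `csurv_presence` matrix (defaults to the packaged
#'   fixture).
#' @param schema A `csurv_schema`.
#' @param interpretive_ids Variable ids counted as interpretive; defaults
#'   to the schema's `interpretive` flags.
#' @return A `csurv_coverage_report` list.
#' @export
#' @examples
#' coverage_report()
coverage_report <- function(matrix = presence_fixture(),
                            schema = load_schema(),
                            interpretive_ids = NULL) {
  if (is.null(interpretive_ids)) {
    interpretive_ids <-
      schema$variables$variable_id[schema$variables$interpretive]
  }
  themes <- theme_coverage(matrix, schema)
  overlap <- overlap_distribution(matrix)
  represented_ids <- rownames(matrix)[rowSums(matrix) > 0]
  tally <- strategy_tally(schema, restrict_to = represented_ids,
                          which = "applied")
  structure(
    list(
      n_variables = nrow(matrix),
      n_represented = length(represented_ids),
      pct_represented = pct(length(represented_ids), nrow(matrix)),
      cohort_totals = attr(themes, "totals"),
      theme_coverage = themes,
      overlap = overlap,
      strategy_tally = tally,
      pct_strategy = setNames(
        vapply(tally, pct, 0, den = sum(tally)), names(tally)),
      correspondence = correspondence_summary(matrix, interpretive_ids)
    ),
    class = "csurv_coverage_report"
  )
}

#' @export
print.csurv_coverage_report <- function(x, ...) {
  cat("<csurv_coverage_report>\n")
  cat(sprintf("  variables: %d total, %d (%d%%) represented in >=1 cohort\n",
              x$n_variables, x$n_represented, x$pct_represented))
  cat("  per-cohort totals: ",
      paste(sprintf("%s %d", names(x$cohort_totals), x$cohort_totals),
            collapse = ", "), "\n", sep = "")
  cat("  overlap (cohorts -> variables): ",
      paste(sprintf("%s:%d", names(x$overlap), x$overlap), collapse = " "),
      "\n", sep = "")
  cat(sprintf(
    "  applied strategies (represented): SC %d (%d%%), AT %d (%d%%), S %d\n",
    x$strategy_tally[["SC"]], x$pct_strategy[["SC"]],
    x$strategy_tally[["AT"]], x$pct_strategy[["AT"]],
    x$strategy_tally[["S"]]))
  cat(sprintf("  correspondence: complete or close for %d (%d%%) of %d\n",
              x$correspondence$complete_or_close,
              x$correspondence$pct_complete_or_close,
              x$correspondence$represented))
  invisible(x)
}
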