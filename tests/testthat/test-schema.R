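test_that("packaged core schema loads with the expected structure", {
  expect_s3_class(sch, "csurv_schema")
  expect_equal(nrow(sch$variables), 124)
  expect_equal(nrow(sch$themes), 18)
  expect_true(all(sch$variables$theme_number %in% sch$themes$theme_number))
  # stable identifiers, unique
  expect_false(anyDuplicated(sch$variables$variable_id) > 0)
  # binary codebooks are exactly {1 yes, 0 no}
  yn <- sch$variables$codebook[[match("dna_extracted",
                                      sch$variables$variable_id)]]
  expect_equal(yn$code, c(1L, 0L))
  expect_equal(yn$label, c("yes", "no"))
  # the S strategy occurs only for the six cognitive performance scores
  s_rows <- sch$variables$row_number[sch$variables$declared_strategy == "S"]
  expect_equal(sort(s_rows), 69:74)
})

test_that("themes_covered reports 15 themes, excluding linkage/healthcare/device", {
  covered <- themes_covered(sch)
  expect_length(covered, 15)
  expect_equal(setdiff(1:18, covered), c(14, 15, 18))
  # singleton and set-identity behaviour
  one_theme <- sch$variables[sch$variables$theme_number == 13, ]
  expect_equal(themes_covered(one_theme), 13)
  split1 <- sch$variables[1:60, ]
  split2 <- sch$variables[61:124, ]
  expect_equal(sort(union(themes_covered(split1), themes_covered(split2))),
               covered)
})

test_that("strategy tallies conserve counts and support restriction", {
  full <- strategy_tally(sch, which = "declared")
  expect_equal(sum(full), nrow(sch$variables))
  expect_equal(full, c(SC = 74L, AT = 44L, S = 6L))
  # empty restriction -> all zero
  expect_equal(sum(strategy_tally(sch, restrict_to = character())), 0)
  # additivity over disjoint id sets
  ids <- sch$variables$variable_id
  a <- strategy_tally(sch, restrict_to = ids[1:40])
  b <- strategy_tally(sch, restrict_to = ids[41:124])
  expect_equal(a + b, strategy_tally(sch, restrict_to = ids))
  # unknown ids are rejected with their names
  expect_error(strategy_tally(sch, restrict_to = c("age", "nonexistent")),
               "nonexistent", class = "csurv_unknown_id_error")
})

test_that("schema validation raises distinct, named errors", {
  # writing and editing a copy lets us construct violations
  doc <- jsonlite::read_json(csurv_file("csurv_core_124.json"))

  empty <- doc
  empty$variables <- list()
  p <- tempfile(fileext = ".json")
  jsonlite::write_json(empty, p, auto_unbox = TRUE)
  expect_error(load_schema(p), "no variables defined",
               class = "csurv_empty_schema_error")

  dup <- doc
  dup$variables[[2]]$variable_id <- dup$variables[[1]]$variable_id
  jsonlite::write_json(dup, p, auto_unbox = TRUE)
  expect_error(load_schema(p), dup$variables[[1]]$variable_id,
               class = "csurv_duplicate_id_error")

  badtheme <- doc
  badtheme$variables[[5]]$theme_number <- 99
  jsonlite::write_json(badtheme, p, auto_unbox = TRUE)
  expect_error(load_schema(p), class = "csurv_unknown_theme_error")

  badstrat <- doc
  badstrat$variables[[5]]$declared_strategy <- "XX"
  jsonlite::write_json(badstrat, p, auto_unbox = TRUE)
  expect_error(load_schema(p), class = "csurv_unknown_strategy_error")

  writeLines("{ not json", p)
  expect_error(load_schema(p), class = "csurv_parse_error")
})

test_that("schema round-trips through write_schema/load_schema", {
  path <- write_schema_tmp(sch)
  sch2 <- load_schema(path)
  expect_equal(sch2$variables, sch$variables)
  expect_equal(sch2$themes, sch$themes)
})
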