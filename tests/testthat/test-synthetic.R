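test_that("generators use the native vocabularies of each cohort", {
  # Generation Scotland education labels
  gs <- raws$genscot
  expect_true(all(setdiff(gs$qualification, "") %in%
                    c("College/Uni", "Highers", "Standards",
                      "No qualification")))
  # ELSA ethnicity is white / non-white only
  expect_true(all(setdiff(raws$elsa$ethnicity, "") %in%
                    c("White", "Non white")))
  # memento has no ethnicity field at all
  expect_false("ethnicity" %in% names(raws$memento))
  # memento income arrives as monthly euro bands
  expect_true(any(grepl("^€", setdiff(raws$memento$monthly_income_band,
                                      ""))))
  # two-field smoking question is specific to genscot
  expect_true(all(c("ever_smoked", "smoking_now") %in% names(gs)))
})

test_that("generation is deterministic and substreams are independent", {
  a1 <- generate_cohort("airwave", n = 40, seed = 5)
  a2 <- generate_cohort("airwave", n = 40, seed = 5)
  expect_identical(a1, a2)
  # a different seed changes the draw
  a3 <- generate_cohort("airwave", n = 40, seed = 6)
  expect_false(identical(a1, a3))
  # the airwave stream does not depend on other cohorts being generated
  all4 <- generate_all(seed = 5, n = 40)
  expect_identical(all4$airwave, a1)
})

test_that("generated cohorts reproduce the packaged presence pattern", {
  # already harmonised at n=200 in the helper; scale-invariance at n=10
  small <- generate_all(seed = 3, n = 10)
  hs <- mapply(function(r, cid) harmonise_cohort(r, sch, maps[[cid]]),
               small, names(small), SIMPLIFY = FALSE)
  expect_equal(vapply(hs, nrow, 0L),
               c(airwave = 10L, elsa = 10L, genscot = 10L, memento = 10L))
  built <- build_presence(hs, sch)
  expect_equal(unclass(built), unclass(presence_fixture()))
  expect_equal(overlap_distribution(built),
               c(`0` = 4L, `1` = 46L, `2` = 30L, `3` = 10L, `4` = 34L))
})

test_that("every mapping rule is exercised by at least one non-missing value", {
  for (cid in names(harms)) {
    pr <- provenance(harms[[cid]])
    active <- pr[pr$rule_kind != "not_collected", ]
    expect_true(all(active$n_mapped > 0),
                info = paste(cid, ":",
                             paste(active$variable_id[active$n_mapped == 0],
                                   collapse = ", ")))
  }
})

test_that("the right-skewed reaction-time family triggers the log_e branch", {
  for (cid in c("airwave", "genscot", "memento")) {
    tr <- attr(harms[[cid]], "transforms")[["choice_reaction_time"]]
    expect_equal(tr$transform_applied, "log_e", info = cid)
    expect_gt(tr$skewness, 1)
  }
})

test_that("unknown cohorts and degenerate sizes are rejected", {
  expect_error(generate_cohort("ukbiobank"),
               class = "csurv_unknown_cohort_error")
  expect_error(generate_cohort("elsa", n = 0),
               class = "csurv_invalid_input_error")
})
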