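pm <- presence_fixture()

test_that("the packaged presence fixture satisfies every published count at once", {
  expect_equal(dim(pm), c(124, 4))
  # 120 of 124 variables found in at least one cohort
  expect_equal(sum(rowSums(pm) > 0), 120)
  # the four absences are the known ones
  expect_setequal(rownames(pm)[rowSums(pm) == 0],
                  c("loneliness_score", "adas_cog_score", "mci_diagnosis",
                    "pollution_grime"))
  # per-cohort totals
  expect_equal(colSums(pm),
               c(airwave = 47, elsa = 73, genscot = 60, memento = 92))
  # ELSA and Memento unique-variable counts
  uniq <- rowSums(pm) == 1
  expect_equal(sum(uniq & pm[, "elsa"] == 1), 13)
  expect_equal(sum(uniq & pm[, "memento"] == 1), 26)
})

test_that("theme coverage reproduces the theme-by-cohort table", {
  tc <- theme_coverage(pm, sch)
  expect_equal(nrow(tc), 15)
  # spot rows: imaging is memento-only; family history splits 15/12
  imaging <- tc[tc$theme_number == 13, ]
  expect_equal(unlist(imaging[, c("airwave", "elsa", "genscot", "memento")]),
               c(airwave = 0, elsa = 0, genscot = 0, memento = 6))
  famhist <- tc[tc$theme_number == 5, ]
  expect_equal(famhist$n_variables, 18L)
  expect_equal(unlist(famhist[, c("airwave", "elsa", "genscot", "memento")]),
               c(airwave = 0, elsa = 0, genscot = 15, memento = 12))
  # conservation: totals equal the sum over themes
  expect_equal(attr(tc, "totals"), colSums(pm))
  # degenerate input: an all-absent matrix gives zeros
  zero <- pm
  zero[] <- 0L
  tc0 <- theme_coverage(zero, sch)
  expect_true(all(tc0[, c("airwave", "elsa", "genscot", "memento")] == 0))
})

test_that("overlap distribution matches the published histogram and an oracle", {
  expect_equal(overlap_distribution(pm),
               c(`0` = 4L, `1` = 46L, `2` = 30L, `3` = 10L, `4` = 34L))
  # identity case: everything everywhere
  all1 <- matrix(1L, nrow = 7, ncol = 4,
                 dimnames = list(paste0("v", 1:7), letters[1:4]))
  expect_equal(unname(overlap_distribution(csurv:::new_presence(all1))[["4"]]), 7L)
  # random matrices agree with brute-force tabulation
  set.seed(99)
  for (i in 1:5) {
    m <- matrix(rbinom(200 * 4, 1, runif(1, 0.2, 0.8)), ncol = 4,
                dimnames = list(paste0("v", 1:200), letters[1:4]))
    expect_equal(unname(overlap_distribution(csurv:::new_presence(m))),
                 unname(oracle_overlap(m)))
  }
})

test_that("correspondence splits represented variables against the interpretive set", {
  interp <- sch$variables$variable_id[sch$variables$interpretive]
  expect_length(interp, 9)
  cs <- correspondence_summary(pm, interp)
  expect_equal(cs$represented, 120)
  expect_equal(cs$complete_or_close, 111)
  expect_equal(cs$pct_complete_or_close, 93)
  # edge cases
  cs0 <- correspondence_summary(pm, character())
  expect_equal(cs0$complete_or_close, 120)
  represented <- rownames(pm)[rowSums(pm) > 0]
  cs_all <- correspondence_summary(pm, represented)
  expect_equal(cs_all$complete_or_close, 0)
  expect_error(correspondence_summary(pm, "mci_diagnosis"),
               class = "csurv_unknown_variable_error")
})

test_that("percentages round half-up as conventionally reported", {
  expect_equal(csurv:::pct(120, 124), 97)  # 96.77
  expect_equal(csurv:::pct(61, 120), 51)   # 50.83
  expect_equal(csurv:::pct(53, 120), 44)   # 44.17
  expect_equal(csurv:::pct(111, 120), 93)  # 92.5 rounds up, not to even
})

test_that("build_presence from harmonised tables equals the fixture", {
  built <- build_presence(harms, sch)
  expect_equal(unclass(built), unclass(pm))
  # duplicate cohort ids are rejected
  expect_error(build_presence(list(a = harms$elsa, a = harms$elsa), sch),
               class = "csurv_duplicate_cohort_error")
  # an empty cohort contributes an all-absent column
  empty <- tibble::tibble(.rows = 5)
  b2 <- build_presence(list(elsa = harms$elsa, empty = empty), sch)
  expect_equal(sum(b2[, "empty"]), 0)
})
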