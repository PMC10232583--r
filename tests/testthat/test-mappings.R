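test_that("packaged mapping files cover exactly each cohort's present variables", {
  pm <- presence_fixture()
  for (cid in colnames(pm)) {
    rules <- maps[[cid]]$rules
    with_col <- names(rules)[vapply(rules, function(r)
      r$kind != "not_collected", TRUE)]
    expect_setequal(with_col, rownames(pm)[pm[, cid] == 1])
  }
  # memento additionally carries the ethnicity "not collected" marker
  expect_equal(maps$memento$rules$ethnicity$kind, "not_collected")
})

test_that("mapping validation rejects unknown variables and codebook violations", {
  doc <- jsonlite::read_json(csurv_file("mappings_genscot.json"))
  p <- tempfile(fileext = ".json")

  bad <- doc
  bad$rules[[1]]$variable_id <- "nonexistent"
  jsonlite::write_json(bad, p, auto_unbox = TRUE)
  expect_error(load_mappings(p, sch), "nonexistent",
               class = "csurv_unknown_variable_error")

  dup <- doc
  dup$rules[[length(dup$rules) + 1]] <- dup$rules[[1]]
  jsonlite::write_json(dup, p, auto_unbox = TRUE)
  expect_error(load_mappings(p, sch), class = "csurv_duplicate_rule_error")

  # recode of "Highers" to code 9, outside the 4-level education codebook
  viol <- doc
  idx <- which(vapply(viol$rules, function(r)
    r$variable_id == "educational_level", TRUE))
  viol$rules[[idx]]$map[[2]]$code <- 9
  jsonlite::write_json(viol, p, auto_unbox = TRUE)
  expect_error(load_mappings(p, sch),
               class = "csurv_codebook_violation_error")
})

test_that("apply_recode maps native education labels to the 4-level scale", {
  edu_gs <- maps$genscot$rules$educational_level
  expect_equal(as.integer(apply_recode("Highers", edu_gs)), 3L)
  # "No qualification" maps to junior-or-less in every cohort
  for (cid in names(maps)) {
    r <- maps[[cid]]$rules$educational_level
    expect_equal(as.integer(apply_recode("No qualification", r)), 4L,
                 info = cid)
  }
  # unmapped labels become missing with a provenance note, never an error
  out <- apply_recode(c("astronaut school", "Highers"), edu_gs)
  expect_equal(as.integer(out), c(NA_integer_, 3L))
  expect_match(attr(out, "notes"), "unmapped label")
})

test_that("infer_binary handles dates, thresholds and proxies", {
  dp <- list(kind = "date_presence", dialect = "ymd")
  expect_equal(as.integer(infer_binary(c("2009-03-02", ""), dp)),
               c(1L, 0L))

  # score thresholds agree with a brute-force comparator over a full grid
  for (dir in c("ge", "le")) {
    rule <- list(kind = "score_threshold", threshold = 16, direction = dir)
    scores <- as.character(0:50)
    got <- as.integer(infer_binary(scores, rule))
    want <- vapply(0:50, function(s)
      if (dir == "ge") as.integer(s >= 16) else as.integer(s <= 16), 1L)
    expect_equal(got, want)
  }
  out <- infer_binary(c("12", "not a score"),
                      list(kind = "score_threshold", threshold = 10,
                           direction = "ge"))
  expect_equal(as.integer(out), c(1L, NA_integer_))
  expect_match(attr(out, "notes"), "unparseable score value")

  px <- list(kind = "proxy_condition", trigger = "Y")
  expect_equal(as.integer(infer_binary(c("Y", "N", ""), px)),
               c(1L, 0L, NA_integer_))
})

test_that("truncate_date normalises to ISO dates and rejects partials", {
  expect_equal(as.character(truncate_date("2001-05-17T13:45:00")),
               "2001-05-17")
  expect_equal(as.character(truncate_date("2001-05-17 13:45:00")),
               "2001-05-17")
  expect_equal(as.character(truncate_date("17/05/2001", dialect = "dmy")),
               "2001-05-17")
  out <- truncate_date("2001")
  expect_true(is.na(as.character(out)))
  expect_match(attr(out, "notes"), "partial date")
  # calendar-invalid dates are rejected
  expect_true(is.na(as.character(truncate_date("2001-02-30"))))
})

test_that("encode_apoe is order-insensitive over all allele pairs", {
  expect_equal(as.integer(encode_apoe("3/4")), 5L)
  expect_equal(as.integer(encode_apoe("2/2")), 1L)
  pairs <- expand.grid(a = c(2, 3, 4), b = c(2, 3, 4))
  fwd <- encode_apoe(sprintf("%d/%d", pairs$a, pairs$b))
  rev <- encode_apoe(sprintf("%d/%d", pairs$b, pairs$a))
  expect_equal(as.integer(fwd), as.integer(rev))
  expect_true(all(fwd %in% 1:6))
  # native formats from all four generators resolve identically
  expect_equal(as.integer(encode_apoe(c("e3/e4", "3/4", "E4E3", "E3/E4"))),
               c(5L, 5L, 5L, 5L))
  out <- encode_apoe("1/5")
  expect_true(is.na(as.integer(out)))
  expect_match(attr(out, "notes"), "invalid APOE")
})

test_that("income_quantiles splits at order statistics with ties to the lower quantile", {
  q <- income_quantiles(1:100)
  expect_equal(as.vector(table(as.integer(q))), c(25, 25, 25, 25))
  # all identical -> everyone in the lowest quantile
  expect_equal(unique(as.integer(income_quantiles(rep(42, 10)))), 1L)
  # monotone: a higher income never gets a lower code
  set.seed(11)
  x <- rlnorm(1000, 10, 0.6)
  codes <- as.integer(income_quantiles(x))
  ord <- order(x)
  expect_true(all(diff(codes[ord]) >= 0))
  # matches the independent sort-and-split oracle
  expect_equal(codes, oracle_quantiles(x))
  # banded incomes resolve through midpoints first
  bands <- c(low = 500, mid = 1500, high = 3000)
  labs <- rep(c("low", "mid", "high"), c(6, 2, 4))
  viamid <- as.integer(income_quantiles(labs, bands = bands))
  direct <- oracle_quantiles(bands[labs])
  expect_equal(viamid, unname(direct))
  # too few values -> all missing with a warning note
  out <- income_quantiles(c(1, 2, NA))
  expect_true(all(is.na(as.integer(out))))
  expect_match(attr(out, "notes"), "insufficient data", all = FALSE)
})
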