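# shared objects, built once per test run

sch <- load_schema()
maps <- load_all_mappings(sch)
raws <- generate_all(seed = 7, n = 200)
harms <- mapply(function(r, m) harmonise_cohort(r, sch, m),
                raws, maps, SIMPLIFY = FALSE)

# deterministic sample with a prescribed skewness: gamma quantiles have
# skew 2/sqrt(shape), sign-flipped for left skew; near-zero targets use
# normal quantiles
make_skewed_sample <- function(skew, n = 2000) {
  if (abs(skew) < 0.05) return(qnorm(ppoints(n)))
  shape <- (2 / abs(skew))^2
  sign(skew) * qgamma(ppoints(n), shape = shape)
}

# independent brute-force tabulation of the overlap histogram
oracle_overlap <- function(m) {
  counts <- integer(ncol(m) + 1)
  for (i in seq_len(nrow(m))) {
    k <- 0
    for (j in seq_len(ncol(m))) if (m[i, j] == 1) k <- k + 1
    counts[k + 1] <- counts[k + 1] + 1
  }
  names(counts) <- as.character(0:ncol(m))
  counts
}

# independent sort-and-split quantile oracle (ties to the lower quantile)
oracle_quantiles <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  s <- sort(x[ok])
  cuts <- s[ceiling(n * c(1, 2, 3) / 4)]
  out <- rep(NA_integer_, length(x))
  for (i in which(ok)) {
    out[i] <- if (x[i] <= cuts[1]) 1L else if (x[i] <= cuts[2]) 2L else
      if (x[i] <= cuts[3]) 3L else 4L
  }
  out
}

# drop pipeline attributes so tables can be compared on their data alone
strip_attrs <- function(x) {
  x <- as.data.frame(x)
  attr(x, "provenance") <- NULL
  attr(x, "transforms") <- NULL
  attr(x, "cohort_id") <- NULL
  x
}

write_schema_tmp <- function(schema) {
  path <- tempfile(fileext = ".json")
  write_schema(schema, path)
  path
}
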