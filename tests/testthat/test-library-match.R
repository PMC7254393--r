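# Dot-product matching and hit curation.

test_that("dot-product score hits the closed-form values", {
  a <- unit_spec(c(50, 60, 73), c(100, 50, 999))
  expect_equal(dot_product_score(a, a), 999)
  b <- unit_spec(c(100, 120), c(10, 10))
  expect_equal(dot_product_score(a, b), 0)
  # direct arithmetic: sqrt weights (10, 7.0711) vs (10, 10) give
  # cosine 170.711 / (12.2474 * 14.1421) = 0.985599 -> 984.6
  q <- unit_spec(c(50, 60), c(100, 50))
  r <- unit_spec(c(50, 60), c(100, 100))
  expect_equal(dot_product_score(q, r), 999 * 0.9855986, tolerance = 1 / 984)
  expect_error(
    dot_product_score(q, acc_spec(c(50.01, 60.01), c(1, 1))),
    "mismatch"
  )
})

test_that("score is symmetric and scale-invariant", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    q <- unit_spec(sample(50:300, n), stats::rlnorm(n, 3, 1))
    r <- unit_spec(sample(50:300, n), stats::rlnorm(n, 3, 1))
    s1 <- dot_product_score(q, r)
    expect_equal(s1, dot_product_score(r, q))
    q_scaled <- q
    q_scaled$peaks[[1]]$intensity <- q_scaled$peaks[[1]]$intensity * 37.5
    expect_equal(s1, dot_product_score(q_scaled, r))
    # NIST-like preset stays within range
    expect_true(dplyr::between(
      dot_product_score(q, r, preset = "nist"), 0, 999
    ))
  }
})

test_that("library search ranks deterministically", {
  lib <- dplyr::bind_rows(
    unit_spec(c(50, 60, 73), c(100, 50, 999), id = "A"),
    unit_spec(c(51, 61, 74), c(100, 50, 999), id = "B"),
    unit_spec(c(50, 60, 73), c(90, 60, 999), id = "C")
  )
  q <- lib[1, ]
  q$id <- "query"
  hits <- search_library(q, lib, top_k = 3)
  expect_identical(hits$library_id[1], "A")
  expect_equal(hits$score[1], 999)
  expect_identical(hits$rank, 1:3)
  expect_identical(nrow(search_library(q, lib, top_k = 0)), 0L)
  expect_identical(nrow(search_library(q, lib[2, ], top_k = 5)), 1L)
})

test_that("curation flags the stated failure modes", {
  lib <- unit_spec(50 + 2 * (1:25), stats::rlnorm(25, 3, 0.5), id = "ref")
  good <- lib
  good$id <- "good"
  trace <- unit_spec(c(52, 54, 56), c(999, 500, 100), id = "trace")
  hits_good <- curate_hits(
    search_library(good, lib), good,
    min_score = 700, min_matched_peaks = 5, min_query_peaks = 20
  )
  expect_true(hits_good$plausible[1])
  expect_identical(hits_good$reasons[1], "")

  hits_trace <- curate_hits(
    search_library(trace, lib), trace,
    min_score = 700, min_matched_peaks = 5, min_query_peaks = 20
  )
  expect_false(hits_trace$plausible[1])
  expect_match(hits_trace$reasons[1], "few-signals")

  hits_low <- curate_hits(
    search_library(good, lib), good,
    min_score = 1000, min_matched_peaks = 5, min_query_peaks = 20
  )
  expect_match(hits_low$reasons[1], "low-score")
})

test_that("true library entries rank first under 5% intensity noise", {
  set.seed(31)
  comp <- generate_compounds(40, seed = 31, library_fraction = 1)
  truth <- comp$truth
  hits <- 0L
  total <- 0L
  for (i in seq_len(nrow(truth))) {
    fr <- truth$fragments[[i]]
    if (nrow(fr) < 20) next # non-trace compounds only
    noisy <- acc_spec(
      fr$mz,
      fr$intensity * exp(stats::rnorm(nrow(fr)) * 0.05),
      id = truth$compound[i]
    )
    top <- search_library(to_unit_mass(noisy), comp$library, top_k = 1)
    total <- total + 1L
    hits <- hits + (top$library_id[1] == truth$library_id[i])
  }
  expect_gte(total, 20)
  expect_gte(hits / total, 0.95)
})
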