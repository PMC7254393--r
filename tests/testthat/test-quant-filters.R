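# Feature-data construction, drift correction and the three compound
# filters, including their boundary conventions.

classes6 <- c(
  c1 = "control", c2 = "control", s1 = "stress", s2 = "stress",
  q1 = "QC", q2 = "QC", q3 = "QC", b1 = "blank"
)

test_that("feature data builds from wide areas plus a sample sheet", {
  areas <- tibble::tibble(
    compound = c("x", "y"),
    A = c(1, 2), B = c(3, NA)
  )
  sheet <- tibble::tibble(
    sample = c("A", "B"), class = c("control", "QC"),
    injection_order = c(1L, 2L)
  )
  fd <- as_feature_data(areas, sheet)
  expect_identical(nrow(fd), 4L)
  expect_identical(
    names(fd),
    c("compound", "sample", "class", "injection_order", "area")
  )
  expect_error(
    as_feature_data(areas, dplyr::mutate(sheet, class = c("ctrl", "QC"))),
    "class"
  )
  expect_error(
    as_feature_data(areas, dplyr::mutate(sheet, injection_order = c(1L, 1L))),
    "unique"
  )
  # round trip through delimited text
  fa <- withr::local_tempfile(fileext = ".tsv")
  fs <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(fd, fa, fs)
  expect_equal(as.data.frame(read_feature_table(fa, fs)), as.data.frame(fd))
})

test_that("drift correction is the identity on a drift-free table", {
  fd <- make_feature_data(
    list(x = c(100, 110, 120, 130, 50, 50, 50, NA)),
    classes6
  )
  out <- drift_correct(fd)
  expect_equal(out$area, fd$area, tolerance = 1e-9)
})

test_that("drift correction shrinks QC dispersion under monotone drift", {
  set.seed(61)
  n <- 20
  cls <- c(
    rep("control", 6), rep("stress", 6), rep("QC", 6),
    rep("blank", 2)
  )
  ord <- sample(n)
  drift <- 1 + (ord - 1) / (n - 1) # 2x linear drift across the run
  fd <- tibble::tibble(
    compound = "x",
    sample = sprintf("s%02d", 1:n),
    class = cls,
    injection_order = ord,
    area = 1000 * drift * stats::rlnorm(n, 0, 0.02)
  )
  out <- drift_correct(fd)
  rsd <- function(v) 100 * stats::sd(v) / mean(v)
  expect_lt(
    rsd(out$area[out$class == "QC"]),
    rsd(fd$area[fd$class == "QC"])
  )
})

test_that("drift trend interpolates between QC anchors", {
  # QCs 100 at order 1 and 200 at order 10: trend at order 5.5 is 150,
  # QC median 150, so a sample at 150 stays 150
  fd <- tibble::tibble(
    compound = "x",
    sample = c("q1", "q2", "q3", "m"),
    class = c("QC", "QC", "QC", "control"),
    injection_order = c(1L, 10L, 12L, 5L),
    area = c(100, 200, 200, 150)
  )
  fd$injection_order <- c(1L, 10L, 12L, 6L)
  out <- drift_correct(fd)
  # trend at order 6: 100 + 5/9 * 100 = 155.6; median QC = 200
  expect_equal(
    out$area[out$sample == "m"],
    150 / (100 + 100 * 5 / 9) * 200,
    tolerance = 1e-9
  )
  expect_error(
    drift_correct(make_feature_data(
      list(x = 1:4),
      c(a = "control", b = "control", c = "stress", d = "stress")
    )),
    "QC"
  )
})

test_that("QC RSD filter keeps the 20% boundary", {
  fd <- make_feature_data(
    list(
      flat = c(1, 1, 1, 1, 100, 100, 100, NA),
      mild = c(1, 1, 1, 1, 90, 100, 110, NA),
      wild = c(1, 1, 1, 1, 50, 100, 150, NA)
    ),
    classes6
  )
  res <- qc_rsd_filter(fd, threshold_pct = 20)
  expect_setequal(unique(res$kept$compound), c("flat", "mild"))
  expect_setequal(unique(res$removed$compound), "wild")
  expect_equal(res$metrics$qc_rsd[res$metrics$compound == "mild"], 10)
  expect_equal(res$metrics$qc_rsd[res$metrics$compound == "wild"], 50)
  # exactly 20%: kept ("exceeding" is strict)
  qc_vals <- c(80, 100, 120)
  stopifnot(abs(100 * stats::sd(qc_vals) / mean(qc_vals) - 20) < 1e-9)
  fd20 <- make_feature_data(list(edge = c(1, 1, 1, 1, qc_vals, NA)), classes6)
  expect_identical(unique(qc_rsd_filter(fd20, 20)$kept$compound), "edge")
})

test_that("blank filter applies the 5-fold rule with inclusivity", {
  fd <- make_feature_data(
    list(
      weak = c(400, 400, 100, 100, 1, 1, 1, 100), # best 400 < 5x100
      strong = c(600, 600, 50, 50, 1, 1, 1, 100), # 600 >= 5x100, one group
      edge = c(500, 500, 10, 10, 1, 1, 1, 100), # exactly 5-fold: kept
      clean = c(10, 10, 10, 10, 1, 1, 1, NA) # absent from blanks
    ),
    classes6
  )
  res <- blank_filter(fd, fold = 5)
  expect_setequal(unique(res$kept$compound), c("strong", "edge", "clean"))
  expect_setequal(unique(res$removed$compound), "weak")
})

test_that("missing-value filter needs presence in one full group", {
  cls <- c(
    c1 = "control", c2 = "control", c3 = "control", c4 = "control",
    c5 = "control", s1 = "stress", s2 = "stress", s3 = "stress",
    s4 = "stress", s5 = "stress", q1 = "QC", q2 = "QC", q3 = "QC"
  )
  fd <- make_feature_data(
    list(
      full = c(rep(1, 10), 1, 1, 1),
      gone = c(rep(NA_real_, 10), NA, NA, NA),
      stress_only = c(rep(NA_real_, 5), 1, 1, 1, 1, NA, 1, 1, 1)
    ),
    cls
  )
  res <- missing_value_filter(fd, min_presence = 0.8)
  expect_setequal(unique(res$kept$compound), c("full", "stress_only"))
  expect_setequal(unique(res$removed$compound), "gone")
})

test_that("filters split the input into disjoint exhaustive parts", {
  set.seed(62)
  comp <- generate_compounds(15, seed = 62)
  ex <- generate_experiment(comp$truth, seed = 63)
  fd <- drift_correct(ex$hr$features)
  for (res in list(
    qc_rsd_filter(fd), blank_filter(fd), missing_value_filter(fd)
  )) {
    expect_identical(nrow(res$kept) + nrow(res$removed), nrow(fd))
    expect_length(
      intersect(unique(res$kept$compound), unique(res$removed$compound)), 0
    )
    got <- dplyr::arrange(
      dplyr::bind_rows(res$kept, res$removed),
      compound, sample
    )
    want <- dplyr::arrange(fd, compound, sample)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})
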