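# Synthetic ground truth and the twin experiment generator.

test_that("compound generation is deterministic and internally consistent", {
  a <- generate_compounds(20, seed = 91, library_fraction = 0.5)
  b <- generate_compounds(20, seed = 91, library_fraction = 0.5)
  expect_identical(a, b)

  truth <- a$truth
  expect_equal(nrow(a$library), round(20 * 0.5))
  expect_true(all(truth$n_fragments >= 5 & truth$n_fragments <= 41))
  # every fragment is a subformula of its derivatized parent
  for (i in seq_len(nrow(truth))) {
    expect_true(all(vapply(
      truth$fragments[[i]]$formula, is_subformula,
      logical(1),
      whole = truth$formula[i]
    )))
  }
  # RIs collision-free at 2 units
  expect_true(all(diff(sort(truth$ri)) >= 2))
  # derivatized formula equals base + increments
  i <- 1L
  expect_identical(
    truth$formula[i],
    format_formula(derivatize(
      truth$base_formula[i], truth$n_tms[i], truth$n_meox[i]
    ))
  )
})

test_that("generated spectra survive an MSP round trip", {
  comp <- generate_compounds(6, seed = 92)
  ex <- generate_experiment(comp$truth, seed = 93)
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(ex$hr$ei, path)
  back <- read_msp(path)
  expect_identical(back$id, ex$hr$ei$id)
  for (i in seq_len(nrow(back))) {
    expect_equal(back$peaks[[i]]$mz, ex$hr$ei$peaks[[i]]$mz, tolerance = 1e-7)
  }
})

test_that("the twin experiment encodes the stated phenomenology", {
  comp <- generate_compounds(40, seed = 94)
  ex <- generate_experiment(comp$truth, seed = 95)
  # same seed twice: identical
  ex2 <- generate_experiment(comp$truth, seed = 95)
  expect_identical(ex$hr$features, ex2$hr$features)

  # unit channel detects strictly fewer compounds (8-fold handicap)
  expect_lt(
    dplyr::n_distinct(ex$unit$features$compound),
    dplyr::n_distinct(ex$hr$features$compound)
  )
  # unit spectra carry no more fragments than their accurate twins
  for (id in ex$unit$ei$id) {
    n_unit <- nrow(ex$unit$ei$peaks[[match(id, ex$unit$ei$id)]])
    n_hr <- nrow(ex$hr$ei$peaks[[match(id, ex$hr$ei$id)]])
    expect_lte(n_unit, n_hr)
  }
  # non-planted compounds have fold change exactly 1
  expect_true(all(ex$truth$fold_change[ex$truth$fold_change == 1] == 1))
  n_planted <- sum(ex$truth$fold_change != 1)
  expect_equal(n_planted, round(0.25 * nrow(ex$truth)))
  # CI members below the 80 m/z scan floor are absent
  for (p in ex$hr$ci$peaks) expect_true(all(p$mz >= 80 * (1 - 1e-5)))
  # degenerate knobs: handicap 1 and no mass error make the channels agree
  ex0 <- generate_experiment(comp$truth,
    noise = list(cv = 0.1, ppm_sigma = 0, intensity_cv = 0.05),
    handicap = 1, seed = 96
  )
  expect_identical(
    dplyr::n_distinct(ex0$unit$features$compound),
    dplyr::n_distinct(ex0$hr$features$compound)
  )
  expect_identical(
    sort(unique(ex0$unit$features$compound)),
    sort(unique(ex0$hr$features$compound))
  )
})

test_that("decoys share the nominal mass but differ by more than 5 ppm", {
  comp <- generate_compounds(25, seed = 97)
  props <- generate_decoys(comp$truth, seed = 97)
  expect_true(all(c("true", "decoy") %in% props$role))
  decoys <- props[props$role == "decoy", ]
  expect_gte(nrow(decoys), 20)
  truth_mass <- stats::setNames(
    comp$truth$derivatized_mass, comp$truth$compound
  )
  truth_formula <- stats::setNames(comp$truth$formula, comp$truth$compound)
  nominal <- function(f) {
    cc <- parse_formula(f)
    sum(cc * c(C = 12, H = 1, N = 14, O = 16, P = 31, S = 32, Si = 28)[names(cc)])
  }
  for (i in seq_len(nrow(decoys))) {
    m_true <- truth_mass[[decoys$compound[i]]]
    m_dec <- monoisotopic_mass(decoys$proposal[i])
    expect_identical(
      nominal(decoys$proposal[i]),
      nominal(truth_formula[[decoys$compound[i]]])
    )
    expect_gt(abs(m_dec - m_true) / m_true * 1e6, 5)
  }
})
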