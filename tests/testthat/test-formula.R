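# Formula arithmetic: masses, windows, RDBE, SENIOR, subformula order,
# derivatization increments and isotope patterns.

test_that("monoisotopic masses match tabulated atomic masses", {
  expect_identical(monoisotopic_mass(""), 0)
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-5 / 18)
  # trimethylsilylium cation: electron mass subtracted
  expect_equal(monoisotopic_mass("C3H9Si", charge = 1), 73.04680,
    tolerance = 1e-4 / 73
  )
  expect_equal(
    monoisotopic_mass("C3H9Si", charge = 0) -
      monoisotopic_mass("C3H9Si", charge = 1),
    0.000548579909
  )
  expect_error(monoisotopic_mass("C2Xx3"), "Xx")
  expect_error(monoisotopic_mass("C6H12O6", charge = 2))
})

test_that("formula strings parse and format canonically", {
  expect_identical(format_formula("H12C6O6"), "C6H12O6")
  expect_identical(format_formula(parse_formula("C22H55NO6Si5")), "C22H55NO6Si5")
  expect_identical(parse_formula("CH4")[["H"]], 4L)
  expect_identical(format_formula(""), "")
})

test_that("ppm windows are symmetric and exact", {
  expect_equal(ppm_window(300, 3), c(299.9991, 300.0009))
  expect_identical(ppm_window(123.4, 0), c(123.4, 123.4))
  w <- ppm_window(73.04680, 3)
  expect_equal(diff(w), 2 * 3e-6 * 73.04680, tolerance = 1e-6 / 4.4e-4)
})

test_that("RDBE follows the fixed-valence formula", {
  expect_equal(rdbe("CH4"), 0)
  expect_equal(rdbe("C6H6"), 4)
  expect_equal(rdbe("C3H9Si"), 0.5)
  expect_equal(rdbe("C6H12O6"), 1)
})

test_that("SENIOR condition separates molecules from radicals", {
  expect_true(senior_check("H2O"))
  expect_false(senior_check("CH3")) # odd valence sum
  expect_true(senior_check("C6H12O6"))
})

test_that("is_subformula is a partial order", {
  expect_true(is_subformula("C2H5O", "C6H12O6"))
  expect_false(is_subformula("C7H5", "C6H12O6"))
  set.seed(11)
  rand_formula <- function() {
    els <- sample(supported_elements(), sample(2:4, 1))
    stats::setNames(sample(0:6, length(els), replace = TRUE), els)
  }
  for (i in 1:50) {
    a <- rand_formula()
    b <- rand_formula()
    c <- rand_formula()
    expect_true(is_subformula(a, a)) # reflexive
    if (is_subformula(a, b) && is_subformula(b, a)) { # antisymmetric
      expect_identical(format_formula(a), format_formula(b))
    }
    if (is_subformula(a, b) && is_subformula(b, c)) { # transitive
      expect_true(is_subformula(a, c))
    }
  }
})

test_that("derivatization adds the TMS and MeOX increments", {
  expect_identical(
    format_formula(derivatize("C6H12O6", n_tms = 5, n_meox = 1)),
    "C22H55NO6Si5"
  )
  expect_identical(
    format_formula(derivatize("C2H5NO2", n_tms = 2)),
    "C8H21NO2Si2"
  )
  expect_identical(format_formula(derivatize("C5H9NO2")), "C5H9NO2")
  # no carbonyl to oximate
  expect_error(derivatize("C4H12N2", n_meox = 1), "oxygen")
})

test_that("derivatized masses are exactly additive in the increments", {
  tms <- monoisotopic_mass("C3H8Si")
  meox <- monoisotopic_mass("CH3N")
  for (f in c("C6H12O6", "C5H9NO4", "H3PO4", "C20H30O2")) {
    a <- sample(0:4, 1)
    b <- min(sample(0:1, 1), parse_formula(f)["O"], na.rm = TRUE)
    expect_equal(
      monoisotopic_mass(derivatize(f, a, b)),
      monoisotopic_mass(f) + a * tms + b * meox
    )
  }
})

test_that("isotope patterns reproduce published abundance ratios", {
  p_c <- isotope_pattern("C", n_peaks = 2)
  expect_equal(p_c$abundance[2], 0.0108, tolerance = 0.0005 / 0.0108)
  p_si <- isotope_pattern("Si", n_peaks = 3)
  expect_equal(p_si$abundance[2], 0.0508, tolerance = 0.001 / 0.05)
  expect_equal(p_si$abundance[3], 0.0335, tolerance = 0.001 / 0.033)
  p_w <- isotope_pattern("H2O", n_peaks = 2)
  expect_lt(p_w$abundance[2], 0.001)
  # M+1 of a C6 compound is about 6x the single-carbon ratio
  p6 <- isotope_pattern("C6H12O6", n_peaks = 2)
  expect_gt(p6$abundance[2], 6 * 0.0107 * 0.9)
  expect_true(all(isotope_pattern("C22H55NO6Si5", 4)$abundance >= 0))
})
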