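# High-resolution filtering: fragment selection, annotation against a
# proposal, verdict rules and decoy discrimination.

test_that("fragment selection unions intense and high-mz peaks", {
  p <- tibble::tibble(
    mz = c(60.1, 90.2, 150.3, 200.4, 310.5),
    intensity = c(999, 500, 100, 50, 10)
  )
  expect_identical(nrow(select_fragments(p[1:3, ], 5, 3)), 3L) # all kept
  expect_equal(select_fragments(p, 1, 0)$mz, 60.1) # base peak only
  sel <- select_fragments(p, 2, 2)
  expect_equal(sel$mz, c(60.1, 90.2, 200.4, 310.5))
  # intensity tie: higher m/z wins
  tie <- tibble::tibble(mz = c(100.1, 200.1, 300.1), intensity = c(5, 5, 1))
  expect_equal(select_fragments(tie, 1, 0)$mz, 200.1)
})

test_that("fragments are explained only under compatible proposals", {
  glc_tms <- derivatize("C6H12O6", n_tms = 5, n_meox = 1)
  a <- annotate_fragment(73.04680, glc_tms, tol_ppm = 3)
  expect_true(a$explained)
  expect_true("C3H9Si" %in% a$candidates[[1]]$formula)
  # underivatized glucose has no Si: nothing within 3 ppm
  b <- annotate_fragment(73.04680, "C6H12O6", tol_ppm = 3)
  expect_false(b$explained)
  # molecular ion of the proposal is explained by reflexivity
  m <- annotate_fragment(
    monoisotopic_mass(glc_tms, charge = 1), glc_tms,
    tol_ppm = 3
  )
  expect_true(m$explained)
  expect_true(format_formula(glc_tms) %in% m$candidates[[1]]$formula)
})

test_that("verdict logic follows the all-fragments-explained rule", {
  glc_tms <- derivatize("C6H12O6", n_tms = 5, n_meox = 1)
  frag_mz <- vapply(
    list(
      c(C = 3, H = 9, Si = 1), c(C = 5, H = 15, O = 1, Si = 2),
      c(C = 8, H = 21, O = 2, Si = 2), c(C = 19, H = 46, N = 1, O = 5, Si = 4)
    ),
    monoisotopic_mass, numeric(1), charge = 1
  )
  s <- acc_spec(frag_mz, c(999, 500, 200, 100), id = "glc")
  v <- hr_filter_verdict(s, glc_tms)
  expect_identical(v$verdict, "confirmed")
  expect_identical(v$n_explained, v$n_checked)

  # one alien fragment falsifies
  s_bad <- acc_spec(c(frag_mz, 256.777), c(999, 500, 200, 100, 400), id = "glc")
  expect_identical(hr_filter_verdict(s_bad, glc_tms)$verdict, "falsified")

  # fewer checkable fragments than required: inconclusive
  s_small <- acc_spec(frag_mz[1:2], c(999, 500), id = "glc")
  expect_identical(
    hr_filter_verdict(s_small, glc_tms, min_fragments = 3)$verdict,
    "inconclusive"
  )

  # unit-resolution spectra are rejected outright
  expect_error(
    hr_filter_verdict(to_unit_mass(s), glc_tms),
    "accurate"
  )
})

test_that("widening the tolerance never turns confirmed into falsified", {
  set.seed(41)
  comp <- generate_compounds(10, seed = 41)
  for (i in 1:5) {
    fr <- comp$truth$fragments[[i]]
    s <- acc_spec(fr$mz * (1 + stats::rnorm(nrow(fr)) * 0.5e-6), fr$intensity,
      id = comp$truth$compound[i]
    )
    v3 <- hr_filter_verdict(s, comp$truth$formula[i], tol_ppm = 3)
    v9 <- hr_filter_verdict(s, comp$truth$formula[i], tol_ppm = 9)
    expect_gte(v9$n_explained, v3$n_explained)
    if (v3$verdict == "confirmed") expect_identical(v9$verdict, "confirmed")
  }
})

test_that("decoy proposals are falsified, true proposals confirmed", {
  set.seed(43)
  comp <- generate_compounds(15, seed = 43)
  truth <- comp$truth
  props <- generate_decoys(truth, seed = 43)
  spectra <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    fr <- truth$fragments[[i]]
    acc_spec(fr$mz * (1 + stats::rnorm(nrow(fr)) * 0.5e-6), fr$intensity,
      id = truth$compound[i]
    )
  })
  res <- purrr::map_dfr(seq_len(nrow(props)), function(i) {
    v <- hr_filter_verdict(
      spectra[spectra$id == props$compound[i], ],
      props$proposal[i],
      tol_ppm = 3
    )
    v$role <- props$role[i]
    v
  })
  confirm_rate <- mean(res$verdict[res$role == "true"] == "confirmed")
  falsify_rate <- mean(res$verdict[res$role == "decoy"] == "falsified")
  expect_gte(confirm_rate, 0.9)
  expect_gte(falsify_rate, 0.8)
})
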