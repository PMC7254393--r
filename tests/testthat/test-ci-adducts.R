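# Methane-CI adduct series: offsets, detection, EI linkage.

test_that("adduct spacings equal CH4, C2H4 and C exactly", {
  offs <- adduct_offsets()$offset
  expect_equal(offs[2] - offs[1], 16.03130, tolerance = 1e-4 / 16)
  expect_equal(offs[3] - offs[2], 28.03130, tolerance = 1e-4 / 28)
  expect_equal(offs[4] - offs[3], 12.00000, tolerance = 1e-4 / 12)
})

make_ci <- function(M, members = 1:4, extra_mz = numeric(0), id = "ci",
                    ppm_noise = 0, ri = NA_real_) {
  offs <- adduct_offsets()$offset[members]
  mz <- c(M + offs, extra_mz)
  mz <- mz * (1 + stats::rnorm(length(mz)) * ppm_noise * 1e-6)
  msp_spectrum(mz, stats::runif(length(mz), 50, 999),
    id = id, mode = "CI", resolution = "accurate", ri = ri
  )
}

test_that("a planted full series is found with support 4", {
  set.seed(51)
  s <- make_ci(350.10000)
  h <- detect_adduct_series(s, tol_ppm = 3, min_support = 3)
  expect_identical(nrow(h), 1L)
  expect_identical(h$support[1], 4L)
  expect_lt(abs(h$M[1] - 350.1) / 350.1 * 1e6, 3)
})

test_that("insufficient members give no hit", {
  set.seed(52)
  s <- make_ci(350.1, members = 2) # only M+H
  expect_identical(nrow(detect_adduct_series(s, min_support = 3)), 0L)
  s2 <- make_ci(350.1, members = c(1, 2)) # two members
  expect_identical(nrow(detect_adduct_series(s2, min_support = 3)), 0L)
  expect_identical(nrow(detect_adduct_series(s2, min_support = 2)), 1L)
})

test_that("two separated molecules give two distinct hits", {
  set.seed(53)
  offs <- adduct_offsets()$offset
  mz <- c(300.2 + offs, 420.3 + offs)
  s <- msp_spectrum(mz, rep(500, 8),
    id = "ci2", mode = "CI",
    resolution = "accurate"
  )
  h <- detect_adduct_series(s, tol_ppm = 3, min_support = 3)
  expect_identical(nrow(h), 2L)
  expect_equal(sort(h$M), c(300.2, 420.3), tolerance = 1e-5)
})

test_that("recovery holds at 1 ppm noise and survives noise peaks", {
  set.seed(54)
  n_ok <- 0L
  for (i in 1:20) {
    M <- stats::runif(1, 200, 800)
    extra <- stats::runif(sample(10:50, 1), 80, 1000)
    s <- make_ci(M, extra_mz = extra, ppm_noise = 1)
    h <- detect_adduct_series(s, tol_ppm = 3, min_support = 3)
    if (nrow(h) && h$support[1] == 4L &&
      abs(h$M[1] - M) / M * 1e6 <= 2) {
      n_ok <- n_ok + 1L
    }
  }
  expect_identical(n_ok, 20L)
})

test_that("EI-CI links obey the RI window and shared-fragment tie-break", {
  ei <- acc_spec(c(100.05, 150.07, 200.09, 250.11), c(9, 8, 7, 6),
    id = "cmp", ri = 1500
  )
  mk_hit <- function(id, ri, M, frag) {
    tibble::tibble(
      ci_id = id, ri = ri, M = M,
      peaks = list(tibble::tibble(
        mz = c(M + adduct_offsets()$offset, frag),
        intensity = rep(10, 4 + length(frag))
      ))
    )
  }
  hits <- dplyr::bind_rows(
    mk_hit("near4", 1501, 400.2, c(100.05, 150.07, 200.09, 250.11)),
    mk_hit("near2", 1499, 410.2, c(100.05, 150.07)),
    mk_hit("far", 1550, 420.2, c(100.05, 150.07, 200.09, 250.11))
  )
  links <- link_ci_to_ei(ei, hits, ri_tol = 5, min_shared = 2)
  expect_identical(nrow(links), 1L)
  expect_identical(links$ci_id, "near4") # 4 shared beats 2 shared
  # out-of-window candidate alone: no link
  links2 <- link_ci_to_ei(ei, hits[3, ], ri_tol = 5)
  expect_identical(nrow(links2), 0L)
})

test_that("decomposing a recovered M contains the true molecular formula", {
  set.seed(55)
  comp <- generate_compounds(8, seed = 55)
  for (i in seq_len(nrow(comp$truth))) {
    M <- comp$truth$derivatized_mass[i]
    s <- make_ci(M, ppm_noise = 0.5)
    h <- detect_adduct_series(s, tol_ppm = 3, min_support = 3)
    expect_gte(nrow(h), 1L)
    cand <- decompose_mass(h$M[1], decomposition_constraints())
    expect_true(comp$truth$formula[i] %in% cand$formula, info = comp$truth$name[i])
  }
})
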