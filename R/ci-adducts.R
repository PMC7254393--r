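# Methane chemical-ionization adduct series: [M-CH3]+, [M+H]+, [M+C2H5]+,
# [M+C3H5]+. Their fixed mass spacings identify the neutral mass M in CI
# spectra even when [M+H]+ itself is ambiguous.

#' Fixed m/z offsets of the methane-CI adduct series from the neutral mass
#'
#' Offsets are cation m/z minus neutral M, electron mass included:
#' consecutive spacings are exactly CH4, C2H4 and C.
#'
#' @return Tibble with columns `member` and `offset` (Da).
#' @export
adduct_offsets <- function() {
  m <- monoisotopic_masses()
  e <- ELECTRON_MASS
  tibble::tibble(
    member = c("M-CH3", "M+H", "M+C2H5", "M+C3H5"),
    offset = c(
      -(m[["C"]] + 3 * m[["H"]]) - e,
      m[["H"]] - e,
      2 * m[["C"]] + 5 * m[["H"]] - e,
      3 * m[["C"]] + 5 * m[["H"]] - e
    )
  )
}

#' Detect molecular ions in a CI spectrum via the adduct series
#'
#' Every peak is hypothesized to be each series member in turn; the implied
#' neutral mass M is then tested against all four expected member m/z
#' within `tol_ppm`. Hypotheses supported by at least `min_support` members
#' are kept, near-duplicate M values (within the same ppm tolerance) are
#' merged, and hits are returned sorted by support and then summed member
#' intensity.
#'
#' @param spectrum One-row spectra tibble, CI mode, accurate resolution.
#' @param tol_ppm Member mass tolerance in ppm (default 3).
#' @param min_support Minimum members present, 2-4 (default 3).
#' @return Tibble with columns `M` (neutral mass estimate), `support`,
#'   `total_intensity`, `members` (list-column: `member`, `mz`,
#'   `error_ppm`).
#' @export
detect_adduct_series <- function(spectrum, tol_ppm = 3, min_support = 3L) {
  stopifnot(
    nrow(spectrum) == 1L, tol_ppm > 0,
    min_support >= 2L, min_support <= 4L
  )
  if (spectrum$resolution != "accurate" || spectrum$mode != "CI") {
    stop("adduct-series detection requires an accurate-mass CI spectrum",
      call. = FALSE
    )
  }
  peaks <- spectrum$peaks[[1]]
  offs <- adduct_offsets()
  hyp_M <- as.vector(outer(peaks$mz, offs$offset, "-"))
  hyp_M <- hyp_M[hyp_M > 0]

  eval_hypothesis <- function(M) {
    exp_mz <- M + offs$offset
    tol <- exp_mz * tol_ppm * 1e-6
    idx <- vapply(seq_len(4L), function(k) {
      d <- abs(peaks$mz - exp_mz[k])
      i <- which.min(d)
      if (d[i] <= tol[k]) i else NA_integer_
    }, integer(1))
    found <- !is.na(idx)
    if (sum(found) < min_support) {
      return(NULL)
    }
    # refine M from the matched members
    m_hat <- mean(peaks$mz[idx[found]] - offs$offset[found])
    exp_mz <- m_hat + offs$offset
    tibble::tibble(
      M = m_hat,
      support = sum(found),
      total_intensity = sum(peaks$intensity[idx[found]]),
      members = list(tibble::tibble(
        member = offs$member[found],
        mz = peaks$mz[idx[found]],
        error_ppm = (peaks$mz[idx[found]] - exp_mz[found]) / exp_mz[found] * 1e6
      ))
    )
  }
  hits <- purrr::map_dfr(hyp_M, eval_hypothesis)
  if (!nrow(hits)) {
    return(hits)
  }
  # merge near-duplicate M hypotheses (same ppm tolerance as detection)
  hits <- dplyr::arrange(hits, .data$M)
  grp <- cumsum(c(TRUE, diff(hits$M) > hits$M[-nrow(hits)] * tol_ppm * 1e-6))
  hits$grp <- grp
  merged <- dplyr::arrange(
    hits, .data$grp,
    dplyr::desc(.data$support), dplyr::desc(.data$total_intensity)
  )
  merged <- dplyr::slice_head(dplyr::group_by(merged, .data$grp), n = 1L)
  merged <- dplyr::ungroup(merged)
  merged$grp <- NULL
  dplyr::arrange(merged, dplyr::desc(.data$support), dplyr::desc(.data$total_intensity))
}

#' Link CI molecular-ion hits to EI compounds
#'
#' Pairs EI compounds with CI adduct-series hits at matching retention
#' index (|dRI| <= `ri_tol`) sharing at least `min_shared` fragment m/z
#' values within `frag_tol_ppm`; per EI compound the candidate with the
#' greatest shared-fragment count (ties: smallest |dRI|) is kept.
#'
#' @param ei_spectra Accurate EI spectra tibble with `ri`.
#' @param ci_hits Tibble with columns `ci_id`, `ri`, `M`, `peaks` (the CI
#'   spectrum's peaks tibble), e.g. assembled from
#'   [detect_adduct_series()] output.
#' @param ri_tol Retention-index window (default 5).
#' @param frag_tol_ppm Fragment match tolerance in ppm (default 3).
#' @param min_shared Minimum shared fragments (default 2).
#' @return Tibble with columns `ei_id`, `ci_id`, `M`, `d_ri`, `n_shared`.
#' @export
link_ci_to_ei <- function(ei_spectra, ci_hits, ri_tol = 5, frag_tol_ppm = 3,
                          min_shared = 2L) {
  stopifnot(
    all(c("ci_id", "ri", "M", "peaks") %in% names(ci_hits)),
    all(!is.na(ei_spectra$ri))
  )
  shared_count <- function(ei_peaks, ci_peaks) {
    sum(vapply(ei_peaks$mz, function(m) {
      any(abs(ci_peaks$mz - m) <= m * frag_tol_ppm * 1e-6)
    }, logical(1)))
  }
  purrr::map_dfr(seq_len(nrow(ei_spectra)), function(i) {
    ei <- ei_spectra[i, ]
    cand <- ci_hits[abs(ci_hits$ri - ei$ri) <= ri_tol, , drop = FALSE]
    if (!nrow(cand)) {
      return(NULL)
    }
    cand$n_shared <- vapply(
      cand$peaks,
      function(p) shared_count(ei$peaks[[1]], p), numeric(1)
    )
    cand$d_ri <- abs(cand$ri - ei$ri)
    cand <- cand[cand$n_shared >= min_shared, , drop = FALSE]
    if (!nrow(cand)) {
      return(NULL)
    }
    best <- cand[order(-cand$n_shared, cand$d_ri), ][1, ]
    tibble::tibble(
      ei_id = ei$id, ci_id = best$ci_id, M = best$M,
      d_ri = best$d_ri, n_shared = as.integer(best$n_shared)
    )
  })
}
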