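# High-resolution filtering: verify or falsify a proposed annotation by
# decomposing accurate-mass fragments and requiring every composition to be
# a subformula of the proposal's derivatized sum formula.

#' Select the fragments to verify
#'
#' Union of the `n_intense` most intense peaks and the `n_highmz` highest
#' m/z peaks; intensity ties are broken in favour of the higher m/z.
#'
#' @param peaks Peaks tibble (`mz`, `intensity`).
#' @param n_intense Number of most-intense peaks (default 5).
#' @param n_highmz Number of highest-m/z peaks (default 3).
#' @return Peaks tibble subset, sorted by m/z.
#' @export
select_fragments <- function(peaks, n_intense = 5L, n_highmz = 3L) {
  stopifnot(nrow(peaks) >= 1)
  by_int <- peaks[order(-peaks$intensity, -peaks$mz), , drop = FALSE]
  by_mz <- peaks[order(-peaks$mz), , drop = FALSE]
  sel <- dplyr::bind_rows(
    utils::head(by_int, n_intense),
    utils::head(by_mz, n_highmz)
  )
  sel <- dplyr::distinct(sel)
  dplyr::arrange(sel, .data$mz)
}

#' Annotate one accurate-mass fragment against a proposed formula
#'
#' Decomposes the fragment m/z as a cation (the target composition mass is
#' `mz + electron mass`, half-integer RDBE allowed, SENIOR skipped) with
#' element ranges capped elementwise by the proposal, then keeps only
#' compositions that are subformulas of the proposal. Golden-rules element
#' ratios are not applied to fragments: losses such as CO or retained
#' silyl cations legitimately fall outside molecular ratio ranges.
#'
#' @param mz Fragment m/z (singly charged cation).
#' @param proposal Proposed (derivatized) sum formula, string or counts.
#' @param tol_ppm Mass tolerance in ppm (default 3).
#' @return One-row tibble: `mz`, `explained`, `n_candidates`, `candidates`
#'   (list-column of [decompose_mass()] output).
#' @export
annotate_fragment <- function(mz, proposal, tol_ppm = 3) {
  counts <- parse_formula(proposal)
  stopifnot(length(counts) > 0, tol_ppm > 0)
  cons <- decomposition_constraints(
    tolerance_ppm = tol_ppm,
    element_max = counts,
    rdbe_range = c(-1, 60),
    senior = FALSE,
    ratio_check = FALSE
  )
  cand <- decompose_mass(mz, cons, as_fragment_ion = TRUE)
  if (nrow(cand)) {
    keep <- vapply(
      cand$formula,
      function(f) is_subformula(f, counts), logical(1)
    )
    cand <- cand[keep, , drop = FALSE]
  }
  tibble::tibble(
    mz = mz,
    explained = nrow(cand) > 0,
    n_candidates = nrow(cand),
    candidates = list(cand)
  )
}

#' High-resolution filter verdict for one spectrum and one proposal
#'
#' Selects the most intense and highest-m/z fragments, annotates each, and
#' rules: `"falsified"` as soon as any selected fragment admits no
#' subformula composition within tolerance; otherwise `"confirmed"` when
#' at least `min_fragments` fragments were checked and all are explained;
#' `"inconclusive"` when fewer were checkable. Unit-resolution spectra are
#' rejected: at nominal mass the test carries no information.
#'
#' @param spectrum One-row spectra tibble with `resolution == "accurate"`.
#' @param proposal Proposed (derivatized) sum formula.
#' @param tol_ppm Mass tolerance in ppm (default 3).
#' @param min_fragments Minimum fragments for a confirmation (default 3).
#' @param n_intense,n_highmz Fragment selection, see [select_fragments()].
#' @return One-row tibble: `id`, `proposal`, `n_checked`, `n_explained`,
#'   `verdict`, `fragments` (list-column of per-fragment annotations).
#' @export
hr_filter_verdict <- function(spectrum, proposal, tol_ppm = 3,
                              min_fragments = 3L, n_intense = 5L,
                              n_highmz = 3L) {
  stopifnot(nrow(spectrum) == 1L)
  if (spectrum$resolution != "accurate") {
    stop(
      "high-resolution filtering requires an accurate-mass spectrum; ",
      "unit-mass spectra carry no sum-formula information",
      call. = FALSE
    )
  }
  sel <- select_fragments(spectrum$peaks[[1]], n_intense, n_highmz)
  ann <- purrr::map_dfr(sel$mz, annotate_fragment,
    proposal = proposal, tol_ppm = tol_ppm
  )
  n_checked <- nrow(ann)
  n_explained <- sum(ann$explained)
  verdict <- if (n_explained < n_checked) {
    "falsified"
  } else if (n_checked < min_fragments) {
    "inconclusive"
  } else {
    "confirmed"
  }
  tibble::tibble(
    id = spectrum$id,
    proposal = format_formula(proposal),
    n_checked = n_checked,
    n_explained = n_explained,
    verdict = verdict,
    fragments = list(ann)
  )
}

#' Batch high-resolution filtering of proposed annotations
#'
#' @param spectra Accurate-mass spectra tibble.
#' @param proposals Tibble with columns `id` (matching spectrum ids),
#'   `formula` (base formula string), and optional `n_tms`, `n_meox`
#'   derivatization counts applied before checking.
#' @param ... Passed to [hr_filter_verdict()].
#' @return Tibble of verdicts, one row per proposal.
#' @export
hr_filter <- function(spectra, proposals, ...) {
  stopifnot(all(c("id", "formula") %in% names(proposals)))
  if (!"n_tms" %in% names(proposals)) proposals$n_tms <- 0L
  if (!"n_meox" %in% names(proposals)) proposals$n_meox <- 0L
  purrr::map_dfr(seq_len(nrow(proposals)), function(i) {
    s <- spectra[spectra$id == proposals$id[i], ]
    if (nrow(s) != 1) {
      stop("proposal ", i, ": no unique spectrum with id '",
        proposals$id[i], "'",
        call. = FALSE
      )
    }
    prop <- derivatize(
      proposals$formula[i],
      n_tms = proposals$n_tms[i], n_meox = proposals$n_meox[i]
    )
    hr_filter_verdict(s, prop, ...)
  })
}
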