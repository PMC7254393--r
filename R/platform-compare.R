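# Cross-platform compound matching and biomarker-overlap accounting
# between a high-resolution and a unit-mass dataset.

#' Match compounds across two platforms
#'
#' Greedy best-first pairing of compounds by unit-mass dot-product score
#' among candidates whose retention indices agree within `ri_tol` and
#' whose score reaches `spectral_min`; each compound enters at most one
#' pair.
#'
#' @param a,b Spectra tibbles (unit resolution, with `ri`) describing the
#'   compounds of the two platforms.
#' @param ri_tol Retention-index window (default 5).
#' @param spectral_min Minimum pairing score (default 700).
#' @param ... Passed to [dot_product_score()].
#' @return Tibble with columns `compound_a`, `compound_b`, `score`,
#'   `d_ri`.
#' @export
match_compounds_across_platforms <- function(a, b, ri_tol = 5,
                                             spectral_min = 700, ...) {
  stopifnot(
    all(a$resolution == "unit"), all(b$resolution == "unit"),
    all(!is.na(a$ri)), all(!is.na(b$ri))
  )
  cand <- purrr::map_dfr(seq_len(nrow(a)), function(i) {
    js <- which(abs(b$ri - a$ri[i]) <= ri_tol)
    if (!length(js)) {
      return(NULL)
    }
    tibble::tibble(
      compound_a = a$id[i],
      compound_b = b$id[js],
      score = vapply(js, function(j) {
        dot_product_score(a[i, ], b[j, ], ...)
      }, numeric(1)),
      d_ri = abs(b$ri[js] - a$ri[i])
    )
  })
  if (!nrow(cand)) {
    return(cand)
  }
  cand <- cand[cand$score >= spectral_min, , drop = FALSE]
  cand <- dplyr::arrange(
    cand, dplyr::desc(.data$score), .data$d_ri,
    .data$compound_a, .data$compound_b
  )
  used_a <- used_b <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$compound_a[i] %in% used_a) && !(cand$compound_b[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, cand$compound_a[i])
      used_b <- c(used_b, cand$compound_b[i])
    }
  }
  cand[keep, , drop = FALSE]
}

#' Overlap percentage from shared/unique significant counts
#'
#' `100 * shared / (shared + unique_a + unique_b)`, rounded to the nearest
#' integer — the union-denominator convention for reporting how far two
#' platforms agree on their significant compounds.
#'
#' @param shared Compounds significant on both platforms.
#' @param unique_a,unique_b Compounds significant on exactly one platform.
#' @return Integer percentage.
#' @examples
#' overlap_percent(21, 9, 46) # 28
#' @export
overlap_percent <- function(shared, unique_a, unique_b) {
  stopifnot(shared >= 0, unique_a >= 0, unique_b >= 0)
  total <- shared + unique_a + unique_b
  if (total == 0) {
    return(100L)
  }
  as.integer(round(100 * shared / total))
}

#' Biomarker-overlap report between two platforms
#'
#' Counts significant compounds shared across the pairing and unique to
#' each platform, computes the union-denominator overlap percentage, and
#' assigns a cause code to every compound significant on one platform but
#' not the other: `"below-LOD"` (absent from the other platform's feature
#' table), `"blank-excluded"` (removed by the other platform's blank
#' filter), `"threshold-fail"` (present and paired but missing the FC/p
#' cutoffs), or `"unmatched"` (present but no spectral pairing found).
#'
#' @param significant_a,significant_b Character vectors of significant
#'   compound ids on each platform.
#' @param pairing Pairing tibble from
#'   [match_compounds_across_platforms()] (columns `compound_a`,
#'   `compound_b`).
#' @param compounds_a,compounds_b All compound ids present in each
#'   platform's (post-deconvolution) feature table.
#' @param blank_removed_a,blank_removed_b Compound ids removed by each
#'   platform's blank filter.
#' @return List of class `overlap_report`: `counts` (shared, unique_a,
#'   unique_b, overlap_percent), `causes` (per-compound cause codes).
#' @export
platform_overlap <- function(significant_a, significant_b, pairing,
                             compounds_a = NULL, compounds_b = NULL,
                             blank_removed_a = character(0),
                             blank_removed_b = character(0)) {
  partner_in_b <- stats::setNames(pairing$compound_b, pairing$compound_a)
  partner_in_a <- stats::setNames(pairing$compound_a, pairing$compound_b)
  shared_a <- significant_a[significant_a %in% names(partner_in_b) &
    partner_in_b[significant_a] %in% significant_b]
  shared <- length(shared_a)
  uniq_a <- setdiff(significant_a, shared_a)
  uniq_b <- setdiff(
    significant_b,
    partner_in_b[shared_a]
  )
  cause_of <- function(id, partner_map, other_compounds, other_blank_removed) {
    partner <- if (id %in% names(partner_map)) partner_map[[id]] else NA_character_
    if (!is.na(partner)) {
      if (partner %in% other_blank_removed) {
        return("blank-excluded")
      }
      return("threshold-fail")
    }
    if (id %in% other_blank_removed) {
      return("blank-excluded")
    }
    if (!is.null(other_compounds) && !(id %in% other_compounds)) {
      return("below-LOD")
    }
    "unmatched"
  }
  cause_vec <- function(ids, partner_map, other_compounds, other_blank_removed) {
    unname(vapply(
      ids, cause_of,
      character(1),
      partner_map = partner_map, other_compounds = other_compounds,
      other_blank_removed = other_blank_removed
    ))
  }
  causes <- dplyr::bind_rows(
    tibble::tibble(
      compound = uniq_a, platform = "A",
      cause = cause_vec(uniq_a, partner_in_b, compounds_b, blank_removed_b)
    ),
    tibble::tibble(
      compound = uniq_b, platform = "B",
      cause = cause_vec(uniq_b, partner_in_a, compounds_a, blank_removed_a)
    )
  )
  structure(
    list(
      counts = tibble::tibble(
        shared = shared,
        unique_a = length(uniq_a),
        unique_b = length(uniq_b),
        overlap_percent = overlap_percent(
          shared, length(uniq_a), length(uniq_b)
        )
      ),
      causes = causes,
      shared_pairs = tibble::tibble(
        compound_a = shared_a,
        compound_b = unname(partner_in_b[shared_a])
      )
    ),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cnt <- x$counts
  cat(
    "Platform overlap: ", cnt$shared, " shared, ", cnt$unique_a,
    " unique to A, ", cnt$unique_b, " unique to B (",
    cnt$overlap_percent, "% overlap)\n",
    sep = ""
  )
  if (nrow(x$causes)) {
    print(dplyr::count(x$causes, .data$platform, .data$cause))
  }
  invisible(x)
}
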