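# Unit-mass EI library matching by weighted-cosine (dot product) scoring,
# plus the plausibility curation applied to raw hits.

weighted_vector <- function(peaks, mz_power, intensity_power) {
  (peaks$mz^mz_power) * (peaks$intensity^intensity_power)
}

#' Dot-product (match factor) score between two spectra
#'
#' Cosine similarity of weighted intensity vectors
#' `w = mz^mz_power * intensity^intensity_power` over the union of integer
#' m/z bins, scaled to the conventional 0-999 range. The score is symmetric
#' and invariant under uniform intensity scaling of either spectrum.
#' Defaults are the square-root-intensity cosine (`mz_power = 0`,
#' `intensity_power = 0.5`); `preset = "nist"` selects the NIST-like
#' weighting (`mz_power = 3`, `intensity_power = 0.6`).
#'
#' @param query,reference One-row spectra tibbles of the same resolution
#'   class.
#' @param mz_power,intensity_power Weighting exponents.
#' @param preset `"sqrt"` (default weighting) or `"nist"`; overrides the
#'   exponents when given.
#' @return Score in `[0, 999]`.
#' @export
dot_product_score <- function(query, reference, mz_power = 0,
                              intensity_power = 0.5, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("sqrt", "nist"))
    if (preset == "nist") {
      mz_power <- 3
      intensity_power <- 0.6
    } else {
      mz_power <- 0
      intensity_power <- 0.5
    }
  }
  stopifnot(nrow(query) == 1L, nrow(reference) == 1L)
  if (query$resolution != reference$resolution) {
    stop("resolution class mismatch between query and reference", call. = FALSE)
  }
  qp <- query$peaks[[1]]
  rp <- reference$peaks[[1]]
  bins <- sort(union(round_half_away(qp$mz), round_half_away(rp$mz)))
  q <- r <- numeric(length(bins))
  q[match(round_half_away(qp$mz), bins)] <- weighted_vector(qp, mz_power, intensity_power)
  r[match(round_half_away(rp$mz), bins)] <- weighted_vector(rp, mz_power, intensity_power)
  denom <- sqrt(sum(q^2)) * sqrt(sum(r^2))
  if (denom == 0) {
    return(0)
  }
  999 * sum(q * r) / denom
}

n_matched_bins <- function(query, reference) {
  qb <- round_half_away(query$peaks[[1]]$mz)
  rb <- round_half_away(reference$peaks[[1]]$mz)
  length(intersect(qb, rb))
}

#' Search a spectral library with one or more query spectra
#'
#' Scores every query against every library entry and returns the top
#' ranked hits per query, sorted by score descending with deterministic
#' tie-breaking by library identifier.
#'
#' @param queries Spectra tibble of query spectra.
#' @param library Spectra tibble forming the library (unique ids).
#' @param top_k Hits to keep per query (default 5; 0 gives an empty
#'   result).
#' @param ... Passed to [dot_product_score()] (`mz_power`,
#'   `intensity_power`, `preset`).
#' @return Tibble with columns `query`, `rank`, `library_id`, `score`,
#'   `n_matched_peaks`.
#' @export
search_library <- function(queries, library, top_k = 5L, ...) {
  validate_library(library)
  stopifnot(nrow(library) >= 1)
  purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    hits <- tibble::tibble(
      query = q$id,
      library_id = library$id,
      score = vapply(
        seq_len(nrow(library)),
        function(j) dot_product_score(q, library[j, ], ...),
        numeric(1)
      ),
      n_matched_peaks = vapply(
        seq_len(nrow(library)),
        function(j) n_matched_bins(q, library[j, ]),
        integer(1)
      )
    )
    hits <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$library_id)
    hits <- utils::head(hits, top_k)
    hits$rank <- seq_len(nrow(hits))
    dplyr::relocate(hits, "rank", .after = "query")
  })
}

#' Curate library hits for plausibility
#'
#' Extracted pseudospectra with few signals can reach high dot-product
#' scores on very few matching peaks, so raw hits are vetted against three
#' criteria: a minimum score, a minimum number of matched peaks, and a
#' minimum number of peaks in the query spectrum (trace spectra with few
#' fragments cannot be matched reliably).
#'
#' @param hits Result of [search_library()].
#' @param queries The query spectra tibble the hits came from.
#' @param min_score Minimum plausible score (default 700).
#' @param min_matched_peaks Minimum matched integer bins (default 5).
#' @param min_query_peaks Minimum peaks in the query spectrum (default 20).
#' @return `hits` with logical `plausible` and a `reasons` column listing
#'   failed criteria (`"low-score"`, `"few-matched-peaks"`,
#'   `"few-signals"`), comma-separated, empty when plausible.
#' @export
curate_hits <- function(hits, queries, min_score = 700,
                        min_matched_peaks = 5L, min_query_peaks = 20L) {
  n_peaks <- tibble::tibble(
    query = queries$id,
    query_peaks = vapply(queries$peaks, nrow, integer(1))
  )
  hits <- dplyr::left_join(hits, n_peaks, by = "query")
  hits$reasons <- vapply(seq_len(nrow(hits)), function(i) {
    r <- character(0)
    if (hits$score[i] < min_score) r <- c(r, "low-score")
    if (hits$n_matched_peaks[i] < min_matched_peaks) r <- c(r, "few-matched-peaks")
    if (hits$query_peaks[i] < min_query_peaks) r <- c(r, "few-signals")
    paste(r, collapse = ",")
  }, character(1))
  hits$plausible <- hits$reasons == ""
  hits
}
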