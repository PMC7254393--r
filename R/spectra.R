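# Spectra as a tidy tibble: one row per spectrum, peak lists nested in a
# `peaks` list-column of tibbles (mz, intensity). This plays well with
# dplyr verbs while keeping per-spectrum metadata (ionization mode,
# resolution class, retention information) as ordinary columns.

#' Construct a one-row spectra tibble
#'
#' @param mz Peak m/z values (> 0). Sorted on construction; peaks landing
#'   on identical m/z are merged by summing intensities.
#' @param intensity Peak intensities (>= 0), same length as `mz`.
#' @param id Spectrum identifier (unique within a library).
#' @param name Optional compound name.
#' @param formula Optional sum formula string.
#' @param mode Ionization mode, `"EI"` or `"CI"`.
#' @param resolution Resolution class, `"accurate"` or `"unit"`.
#' @param rt Optional retention time in minutes.
#' @param ri Optional Kovats retention index.
#' @return One-row tibble with metadata columns and a `peaks` list-column.
#' @examples
#' msp_spectrum(c(73.0468, 147.0654), c(999, 500), id = "cmp1")
#' @export
msp_spectrum <- function(mz, intensity, id, name = NA_character_,
                         formula = NA_character_, mode = "EI",
                         resolution = "accurate", rt = NA_real_,
                         ri = NA_real_) {
  stopifnot(
    length(mz) == length(intensity), length(mz) >= 1,
    all(mz > 0), all(intensity >= 0),
    mode %in% c("EI", "CI"),
    resolution %in% c("accurate", "unit")
  )
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  if (anyDuplicated(mz)) {
    intensity <- as.vector(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  }
  tibble::tibble(
    id = as.character(id),
    name = as.character(name),
    formula = as.character(formula),
    mode = mode,
    resolution = resolution,
    rt = as.numeric(rt),
    ri = as.numeric(ri),
    peaks = list(tibble::tibble(mz = mz, intensity = intensity))
  )
}

#' Validate a spectra tibble as a spectral library
#'
#' @param spectra Spectra tibble (rows from [msp_spectrum()] or
#'   [read_msp()]).
#' @return The input, invisibly, after checking identifier uniqueness and
#'   peak-list validity.
#' @export
validate_library <- function(spectra) {
  stopifnot(is.data.frame(spectra), all(c("id", "peaks") %in% names(spectra)))
  if (anyDuplicated(spectra$id)) {
    stop("spectrum identifiers must be unique within a library", call. = FALSE)
  }
  ok <- vapply(spectra$peaks, function(p) {
    nrow(p) >= 1 && !is.unsorted(p$mz, strictly = TRUE) && all(p$intensity >= 0)
  }, logical(1))
  if (!all(ok)) {
    stop(
      "invalid peak list(s) in spectra: ",
      paste(spectra$id[!ok], collapse = ", "),
      call. = FALSE
    )
  }
  invisible(spectra)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Degrade accurate-mass spectra to unit-mass resolution
#'
#' Each m/z is rounded half-away-from-zero to the nearest integer (the
#' convention nominal-mass libraries index by); intensities of peaks
#' landing in the same integer bin are summed, so total intensity is
#' conserved exactly.
#'
#' @param spectra Spectra tibble with `resolution == "accurate"` rows.
#' @return Spectra tibble with `resolution = "unit"` and integer m/z.
#' @export
to_unit_mass <- function(spectra) {
  stopifnot(all(spectra$resolution == "accurate"))
  spectra$peaks <- lapply(spectra$peaks, function(p) {
    bin <- round_half_away(p$mz)
    agg <- tapply(p$intensity, bin, sum)
    tibble::tibble(
      mz = as.numeric(names(agg)),
      intensity = as.vector(agg)
    )
  })
  spectra$resolution <- "unit"
  spectra
}

#' Normalize spectra to a fixed base-peak intensity
#'
#' @param spectra Spectra tibble.
#' @param base Intensity assigned to the base peak (default 999).
#' @return Spectra tibble with scaled intensities.
#' @export
normalize_spectra <- function(spectra, base = 999) {
  spectra$peaks <- lapply(spectra$peaks, function(p) {
    m <- max(p$intensity)
    if (m <= 0) stop("cannot normalize an all-zero spectrum", call. = FALSE)
    p$intensity <- p$intensity / m * base
    p
  })
  spectra
}

#' Remove peaks below a relative-abundance cutoff
#'
#' Drops peaks with intensity strictly below `fraction` of the base peak
#' (peaks exactly at the cutoff are retained). Scale-invariant, so applying
#' it before or after [normalize_spectra()] is equivalent, and idempotent.
#'
#' @param spectra Spectra tibble.
#' @param fraction Relative cutoff as a fraction of the base peak
#'   (default 0.05).
#' @return Spectra tibble with low-abundance peaks removed.
#' @export
abundance_cutoff <- function(spectra, fraction = 0.05) {
  stopifnot(fraction >= 0, fraction <= 1)
  spectra$peaks <- lapply(spectra$peaks, function(p) {
    m <- max(p$intensity)
    if (m <= 0) stop("cannot apply a cutoff to an all-zero spectrum", call. = FALSE)
    p[p$intensity >= fraction * m, , drop = FALSE]
  })
  spectra
}

#' Export spectra peak lists as one long table
#'
#' @param spectra Spectra tibble.
#' @return Long tibble with columns `id`, `mz`, `intensity`.
#' @export
peaks_table <- function(spectra) {
  tidyr::unnest(
    dplyr::select(spectra, dplyr::all_of(c("id", "peaks"))),
    "peaks"
  )
}
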