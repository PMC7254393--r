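# Feature data: one long tibble holding the compound x sample peak-area
# matrix together with the sample annotations (class, injection order).
# Canonical columns: compound, sample, class, injection_order, area.

FEATURE_CLASSES <- c("control", "stress", "QC", "blank")

#' Build feature data from a wide area table and a sample sheet
#'
#' @param areas Wide tibble/data frame: first column compound identifiers,
#'   remaining columns one per sample holding peak areas (`NA` = missing).
#' @param samples Sample sheet tibble with columns `sample`, `class`
#'   (control/stress/QC/blank) and `injection_order` (unique positive
#'   integers).
#' @return Long tibble with columns `compound`, `sample`, `class`,
#'   `injection_order`, `area`.
#' @export
as_feature_data <- function(areas, samples) {
  stopifnot(
    ncol(areas) >= 2,
    all(c("sample", "class", "injection_order") %in% names(samples))
  )
  if (!all(samples$class %in% FEATURE_CLASSES)) {
    stop(
      "sample classes must be one of: ",
      paste(FEATURE_CLASSES, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(samples$injection_order) || any(samples$injection_order < 1)) {
    stop("injection orders must be unique positive integers", call. = FALSE)
  }
  names(areas)[1] <- "compound"
  long <- tidyr::pivot_longer(
    tibble::as_tibble(areas), -"compound",
    names_to = "sample", values_to = "area"
  )
  missing_sheet <- setdiff(long$sample, samples$sample)
  if (length(missing_sheet)) {
    stop(
      "samples absent from the sample sheet: ",
      paste(missing_sheet, collapse = ", "),
      call. = FALSE
    )
  }
  dplyr::relocate(
    dplyr::left_join(long, samples, by = "sample"),
    "compound", "sample", "class", "injection_order", "area"
  )
}

assert_feature_data <- function(data) {
  need <- c("compound", "sample", "class", "injection_order", "area")
  if (!all(need %in% names(data))) {
    stop(
      "feature data must carry columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(data)
}

#' Write / read feature data as a delimited area table plus sample sheet
#'
#' @param data Feature data (long form, see [as_feature_data()]).
#' @param areas_path,samples_path Paths for the wide area TSV (first column
#'   `compound`) and the sample sheet TSV.
#' @return `areas_path` invisibly (write); feature data tibble (read).
#' @export
write_feature_table <- function(data, areas_path, samples_path) {
  assert_feature_data(data)
  wide <- tidyr::pivot_wider(
    dplyr::select(data, dplyr::all_of(c("compound", "sample", "area"))),
    names_from = "sample", values_from = "area"
  )
  readr::write_tsv(wide, areas_path)
  readr::write_tsv(
    dplyr::distinct(
      dplyr::select(data, dplyr::all_of(c("sample", "class", "injection_order")))
    ),
    samples_path
  )
  invisible(areas_path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(areas_path, samples_path) {
  as_feature_data(
    readr::read_tsv(areas_path, show_col_types = FALSE, progress = FALSE),
    readr::read_tsv(samples_path, show_col_types = FALSE, progress = FALSE)
  )
}
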