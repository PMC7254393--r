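# Preprocessing filters on feature data: QC-anchored signal-drift
# correction, QC reproducibility (RSD) filter, media-blank filter and
# missing-value filter. All filters return disjoint kept/removed splits
# whose union is the input.

#' QC-anchored signal drift correction
#'
#' Divides each compound's areas by a drift trend estimated from the
#' pooled-QC injections: linear interpolation between consecutive QC
#' values over injection order (flat extension beyond the first/last QC),
#' rescaled to the compound's overall QC median so QC areas keep their
#' scale. Compounds with fewer than two QC observations pass through
#' untouched; a drift-free table (constant QC trend) is returned
#' unchanged.
#'
#' @param data Feature data with at least 3 QC samples.
#' @return Feature data with corrected areas.
#' @export
drift_correct <- function(data) {
  assert_feature_data(data)
  n_qc <- dplyr::n_distinct(data$sample[data$class == "QC"])
  if (n_qc < 3) {
    stop("drift correction needs at least 3 QC injections", call. = FALSE)
  }
  correct_one <- function(d) {
    qc <- d[d$class == "QC" & !is.na(d$area), ]
    if (nrow(qc) < 2) {
      return(d)
    }
    # one value per injection order (median if QCs ever share an order)
    agg <- stats::aggregate(area ~ injection_order, data = qc, FUN = stats::median)
    trend <- stats::approx(
      x = agg$injection_order, y = agg$area,
      xout = d$injection_order, rule = 2
    )$y
    d$area <- d$area / trend * stats::median(qc$area)
    d
  }
  dplyr::ungroup(
    dplyr::group_modify(
      dplyr::group_by(data, .data$compound),
      ~ correct_one(.x)
    )
  )
}

split_by_compound <- function(data, removed_ids) {
  list(
    kept = data[!(data$compound %in% removed_ids), , drop = FALSE],
    removed = data[data$compound %in% removed_ids, , drop = FALSE]
  )
}

#' QC relative-standard-deviation filter
#'
#' Removes compounds whose RSD (100 * sd / mean) across QC injections
#' exceeds the threshold; an RSD exactly at the threshold is kept. Run
#' after [drift_correct()].
#'
#' @param data Drift-corrected feature data.
#' @param threshold_pct RSD threshold in percent (default 20).
#' @return List with `kept` and `removed` feature data and a `metrics`
#'   tibble (`compound`, `qc_rsd`).
#' @export
qc_rsd_filter <- function(data, threshold_pct = 20) {
  assert_feature_data(data)
  metrics <- dplyr::summarise(
    dplyr::group_by(data[data$class == "QC", ], .data$compound),
    qc_rsd = 100 * stats::sd(.data$area, na.rm = TRUE) /
      mean(.data$area, na.rm = TRUE),
    .groups = "drop"
  )
  removed_ids <- metrics$compound[!is.na(metrics$qc_rsd) &
    metrics$qc_rsd > threshold_pct]
  c(split_by_compound(data, removed_ids), list(metrics = metrics))
}

#' Media-blank filter
#'
#' A compound detected in blanks is kept only when its best experimental
#' group mean (control or stress) is at least `fold` times the blank mean;
#' the boundary (exactly `fold`-fold) is kept. Compounds absent from
#' blanks always pass.
#'
#' @param data Feature data containing blank samples.
#' @param fold Required enrichment over blanks (default 5).
#' @return List with `kept` and `removed` feature data and a `metrics`
#'   tibble.
#' @export
blank_filter <- function(data, fold = 5) {
  assert_feature_data(data)
  if (!any(data$class == "blank")) {
    stop("blank filter requires blank samples", call. = FALSE)
  }
  grp_mean <- function(d, cls) {
    v <- d$area[d$class == cls]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  metrics <- dplyr::group_modify(
    dplyr::group_by(data, .data$compound),
    function(d, key) {
      blank_v <- d$area[d$class == "blank"]
      in_blank <- any(!is.na(blank_v) & blank_v > 0)
      bg <- suppressWarnings(max(
        grp_mean(d, "control"), grp_mean(d, "stress"),
        na.rm = TRUE
      ))
      tibble::tibble(
        in_blank = in_blank,
        blank_mean = if (in_blank) mean(blank_v, na.rm = TRUE) else NA_real_,
        best_group_mean = if (is.finite(bg)) bg else NA_real_
      )
    }
  )
  metrics <- dplyr::ungroup(metrics)
  removed_ids <- metrics$compound[metrics$in_blank & !dplyr::coalesce(
    metrics$best_group_mean >= fold * metrics$blank_mean, FALSE
  )]
  c(split_by_compound(data, removed_ids), list(metrics = metrics))
}

#' Missing-value filter
#'
#' Keeps compounds present (non-missing and positive) in at least
#' `min_presence` of the samples of at least one experimental group.
#'
#' @param data Feature data.
#' @param min_presence Required presence fraction (default 0.8).
#' @return List with `kept` and `removed` feature data and a `metrics`
#'   tibble.
#' @export
missing_value_filter <- function(data, min_presence = 0.8) {
  assert_feature_data(data)
  exp_data <- data[data$class %in% c("control", "stress"), ]
  metrics <- dplyr::summarise(
    dplyr::group_by(exp_data, .data$compound, .data$class),
    presence = mean(!is.na(.data$area) & .data$area > 0),
    .groups = "drop"
  )
  metrics <- dplyr::summarise(
    dplyr::group_by(metrics, .data$compound),
    best_presence = max(.data$presence),
    .groups = "drop"
  )
  removed_ids <- metrics$compound[metrics$best_presence < min_presence]
  c(split_by_compound(data, removed_ids), list(metrics = metrics))
}
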