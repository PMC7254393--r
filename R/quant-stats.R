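# Statistics on filtered feature data: log/autoscale transform, volcano
# analysis (Welch t-tests + Benjamini-Hochberg FDR, fold-change
# thresholding) and principal component analysis.

half_min_impute <- function(v) {
  pos <- v[!is.na(v) & v > 0]
  if (!length(pos)) {
    return(v)
  }
  v[is.na(v) | v <= 0] <- min(pos) / 2
  v
}

#' Log-transform and autoscale feature data for statistics
#'
#' Restricted to experimental samples (control/stress). Missing or
#' non-positive areas are imputed as half the compound's minimum positive
#' area, areas are natural-log transformed (correcting
#' heteroscedasticity), then each compound is centred and scaled to unit
#' variance (autoscaling) so concentrated and trace compounds contribute
#' equally. Compounds with zero variance after the log are set to all-zero
#' rows with a warning.
#'
#' @param data Filtered feature data.
#' @return Long tibble with columns `compound`, `sample`, `class`, `z`.
#' @export
transform_features <- function(data) {
  assert_feature_data(data)
  exp_data <- data[data$class %in% c("control", "stress"), ]
  out <- dplyr::group_modify(
    dplyr::group_by(exp_data, .data$compound),
    function(d, key) {
      v <- log(half_min_impute(d$area))
      if (all(is.na(v))) {
        z <- rep(NA_real_, length(v))
      } else if (stats::sd(v, na.rm = TRUE) == 0 || is.na(stats::sd(v, na.rm = TRUE))) {
        warning("compound '", key$compound, "' has zero variance after log; ",
          "autoscaled to zeros",
          call. = FALSE
        )
        z <- rep(0, length(v))
      } else {
        z <- as.vector(scale(v))
      }
      tibble::tibble(sample = d$sample, class = d$class, z = z)
    }
  )
  dplyr::ungroup(out)
}

#' Pivot transformed feature data to a sample x compound matrix
#'
#' @param transformed Output of [transform_features()].
#' @return Numeric matrix, samples in rows.
#' @export
feature_matrix <- function(transformed) {
  wide <- tidyr::pivot_wider(
    dplyr::select(transformed, dplyr::all_of(c("sample", "compound", "z"))),
    names_from = "compound", values_from = "z"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample
  m
}

#' Volcano analysis: fold change and FDR-adjusted group tests
#'
#' Fold changes are computed on the raw area scale as the ratio of
#' stress to control group means (a zero control mean yields `Inf`).
#' P-values come from two-sided Welch t-tests on log-transformed
#' (half-minimum imputed) areas and are adjusted across compounds with
#' Benjamini-Hochberg FDR by default. A compound is significantly
#' dysregulated when its fold change strictly exceeds `fc_threshold` in
#' either direction (`FC > 2` or `FC < 1/2` at the default; `FC` exactly
#' at the threshold does not qualify) and its adjusted p-value is below
#' `alpha`.
#'
#' @param data Filtered feature data (>= 2 samples per group).
#' @param fc_threshold Fold-change threshold (default 2).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param adjust `"BH"` (default) or `"none"` for raw p-values.
#' @return Object of class `volcano_result`; use [generics::tidy()] for
#'   the per-compound table, [generics::glance()] for the summary and
#'   [ggplot2::autoplot()] for the volcano plot.
#' @export
volcano <- function(data, fc_threshold = 2, alpha = 0.05,
                    adjust = c("BH", "none")) {
  assert_feature_data(data)
  adjust <- match.arg(adjust)
  exp_data <- data[data$class %in% c("control", "stress"), ]
  tab <- dplyr::group_modify(
    dplyr::group_by(exp_data, .data$compound),
    function(d, key) {
      ctrl <- d$area[d$class == "control"]
      strs <- d$area[d$class == "stress"]
      m_c <- mean(ctrl, na.rm = TRUE)
      m_s <- mean(strs, na.rm = TRUE)
      fc <- if (is.na(m_c) || is.na(m_s)) {
        NA_real_
      } else if (m_c == 0) {
        Inf
      } else {
        m_s / m_c
      }
      lg <- log(half_min_impute(d$area))
      lc <- lg[d$class == "control"]
      ls <- lg[d$class == "stress"]
      p <- if (sum(!is.na(lc)) >= 2 && sum(!is.na(ls)) >= 2 &&
        (stats::sd(lc, na.rm = TRUE) > 0 || stats::sd(ls, na.rm = TRUE) > 0)) {
        stats::t.test(ls, lc, var.equal = FALSE)$p.value
      } else {
        NA_real_
      }
      tibble::tibble(fold_change = fc, p_value = p)
    }
  )
  tab <- dplyr::ungroup(tab)
  tab$p_adjusted <- if (adjust == "BH") {
    stats::p.adjust(tab$p_value, method = "BH")
  } else {
    tab$p_value
  }
  tab$log2_fc <- log2(tab$fold_change)
  tab$significant <- !is.na(tab$fold_change) & !is.na(tab$p_adjusted) &
    (tab$fold_change > fc_threshold | tab$fold_change < 1 / fc_threshold) &
    tab$p_adjusted < alpha
  tab$direction <- dplyr::case_when(
    !tab$significant ~ "none",
    tab$fold_change > 1 ~ "up",
    TRUE ~ "down"
  )
  structure(
    list(
      table = dplyr::relocate(
        tab, "compound", "fold_change", "log2_fc",
        "p_value", "p_adjusted", "significant", "direction"
      ),
      fc_threshold = fc_threshold, alpha = alpha, adjust = adjust
    ),
    class = "volcano_result"
  )
}

#' @export
print.volcano_result <- function(x, ...) {
  g <- glance(x)
  cat(
    "Volcano analysis: ", g$n_compounds, " compounds, ",
    g$n_significant, " significant (", g$n_up, " up / ", g$n_down,
    " down) at |FC| > ", x$fc_threshold, " and adjusted p < ", x$alpha,
    "\n",
    sep = ""
  )
  print(x$table, ...)
  invisible(x)
}

#' @rdname volcano
#' @param x,object A `volcano_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.volcano_result <- function(x, ...) x$table

#' @rdname volcano
#' @exportS3Method generics::glance
glance.volcano_result <- function(x, ...) {
  tibble::tibble(
    n_compounds = nrow(x$table),
    n_significant = sum(x$table$significant),
    n_up = sum(x$table$direction == "up"),
    n_down = sum(x$table$direction == "down"),
    fc_threshold = x$fc_threshold,
    alpha = x$alpha
  )
}

#' Principal component analysis of transformed feature data
#'
#' Standard PCA on the sample x compound autoscaled matrix. For
#' deterministic output the sign of each component is fixed so its
#' largest-magnitude loading is positive. Explained variance fractions
#' are non-increasing and sum to at most 1.
#'
#' @param transformed Output of [transform_features()].
#' @param n_components Components to retain (default 2; truncated with a
#'   warning if above the matrix rank).
#' @return Object of class `feature_pca` with tidy/glance/autoplot
#'   methods.
#' @export
pca_features <- function(transformed, n_components = 2L) {
  m <- feature_matrix(transformed)
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  fit <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  rank <- sum(fit$sdev > 1e-12)
  if (n_components > rank) {
    warning("n_components (", n_components, ") exceeds the matrix rank (",
      rank, "); truncated",
      call. = FALSE
    )
    n_components <- rank
  }
  # fix the sign convention: largest-magnitude loading positive
  for (k in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[i, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  classes <- dplyr::distinct(
    dplyr::select(transformed, dplyr::all_of(c("sample", "class")))
  )
  scores <- tibble::as_tibble(fit$x[, seq_len(n_components), drop = FALSE])
  scores$sample <- rownames(m)
  scores <- dplyr::left_join(scores, classes, by = "sample")
  structure(
    list(
      scores = dplyr::relocate(scores, "sample", "class"),
      explained_variance = ev[seq_len(n_components)],
      loadings = fit$rotation[, seq_len(n_components), drop = FALSE]
    ),
    class = "feature_pca"
  )
}

#' @rdname pca_features
#' @param x,object A `feature_pca`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.feature_pca <- function(x, ...) x$scores

#' @rdname pca_features
#' @exportS3Method generics::glance
glance.feature_pca <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$explained_variance),
    explained_variance_pc1 = x$explained_variance[1],
    explained_variance_total = sum(x$explained_variance)
  )
}
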