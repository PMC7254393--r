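# End-to-end orchestration of the twin-platform study on synthetic ground
# truth: simulate -> preprocess/filter -> library match -> high-resolution
# filter -> CI molecular ions -> volcano/PCA -> platform overlap, with
# stage-level bookkeeping and ground-truth scoring.

#' Configuration for a full twin-platform run
#'
#' Collects every tunable threshold of the workflow in one validated
#' list. Unknown keys passed via `...` are rejected.
#'
#' @param n_compounds Compounds to simulate (default 60).
#' @param library_fraction Fraction of compounds present in the library.
#' @param design,effect,noise,drift_slope,handicap,lod Generator knobs,
#'   see [generate_experiment()].
#' @param tolerance_ppm Accurate-mass tolerance for decomposition,
#'   fragment annotation and adduct detection (default 3).
#' @param cutoff_fraction Relative-abundance spectrum cutoff
#'   (default 0.05).
#' @param top_k,min_score,min_matched_peaks,min_query_peaks Library
#'   search and curation thresholds.
#' @param min_fragments,n_intense,n_highmz High-resolution filter knobs.
#' @param min_support,ri_tol,min_shared CI adduct-series and EI-CI link
#'   knobs.
#' @param rsd_threshold,blank_fold,min_presence Feature-filter
#'   thresholds.
#' @param fc_threshold,alpha Volcano thresholds.
#' @param spectral_min Cross-platform pairing score threshold.
#' @return Named list of class `twin_config`.
#' @export
twin_config <- function(n_compounds = 60L,
                        library_fraction = 0.8,
                        design = list(
                          n_control = 6L, n_stress = 6L,
                          n_qc = 5L, n_blank = 3L
                        ),
                        effect = list(
                          planted_fraction = 0.25, fc_range = c(2, 8)
                        ),
                        noise = list(
                          cv = 0.1, ppm_sigma = 0.5, intensity_cv = 0.05
                        ),
                        drift_slope = 0.15,
                        handicap = 8,
                        lod = 5e3,
                        tolerance_ppm = 3,
                        cutoff_fraction = 0.05,
                        top_k = 5L,
                        min_score = 700,
                        min_matched_peaks = 5L,
                        min_query_peaks = 20L,
                        min_fragments = 3L,
                        n_intense = 5L,
                        n_highmz = 3L,
                        min_support = 3L,
                        ri_tol = 5,
                        min_shared = 2L,
                        rsd_threshold = 20,
                        blank_fold = 5,
                        min_presence = 0.8,
                        fc_threshold = 2,
                        alpha = 0.05,
                        spectral_min = 700) {
  cfg <- as.list(environment())
  structure(cfg, class = "twin_config")
}

process_channel <- function(features, cfg) {
  n0 <- dplyr::n_distinct(features$compound)
  corrected <- drift_correct(features)
  f_rsd <- qc_rsd_filter(corrected, threshold_pct = cfg$rsd_threshold)
  f_blank <- blank_filter(f_rsd$kept, fold = cfg$blank_fold)
  f_miss <- missing_value_filter(f_blank$kept, min_presence = cfg$min_presence)
  kept <- f_miss$kept
  transformed <- transform_features(kept)
  volc <- volcano(kept, fc_threshold = cfg$fc_threshold, alpha = cfg$alpha)
  pca <- if (dplyr::n_distinct(kept$compound) >= 2) {
    pca_features(transformed, n_components = 2L)
  } else {
    NULL
  }
  list(
    features = kept,
    transformed = transformed,
    volcano = volc,
    pca = pca,
    removed = list(
      qc_rsd = unique(f_rsd$removed$compound),
      blank = unique(f_blank$removed$compound),
      missing = unique(f_miss$removed$compound)
    ),
    counts = tibble::tibble(
      stage = c(
        "input", "after_qc_rsd_filter", "after_blank_filter",
        "after_missing_filter", "significant"
      ),
      n = c(
        n0,
        dplyr::n_distinct(f_rsd$kept$compound),
        dplyr::n_distinct(f_blank$kept$compound),
        dplyr::n_distinct(kept$compound),
        sum(volc$table$significant)
      )
    )
  )
}

#' Run the full twin-platform workflow on synthetic ground truth
#'
#' Simulates a compound set and twin experiment, then executes the staged
#' study on both channels: the unit-mass channel runs library matching
#' only; the accurate-mass channel additionally runs high-resolution
#' filtering of its plausible library hits and CI molecular-ion detection
#' with formula-candidate generation. Both channels pass through drift
#' correction, QC/blank/missing-value filters, volcano statistics and
#' PCA, and the run closes with cross-platform compound pairing and the
#' biomarker-overlap report. Ground truth is carried along, so the
#' summary includes recovery scores at every stage.
#'
#' @param config A [twin_config()].
#' @param seed Integer seed controlling all randomness.
#' @return List of class `twin_run`: `truth`, `channels` (hr/unit
#'   processing results), `annotation` (hits, verdicts, CI links),
#'   `comparison` (pairing + overlap report), `summary` (named stage
#'   counts and recovery scores).
#' @export
full_run <- function(config = twin_config(), seed = 1L) {
  stopifnot(inherits(config, "twin_config"))
  comp <- generate_compounds(
    n = config$n_compounds, seed = seed,
    library_fraction = config$library_fraction
  )
  expt <- generate_experiment(
    comp$truth,
    design = config$design, effect = config$effect, noise = config$noise,
    drift_slope = config$drift_slope, handicap = config$handicap,
    lod = config$lod, seed = seed + 1L
  )
  truth <- expt$truth

  hr_chan <- process_channel(expt$hr$features, config)
  unit_chan <- process_channel(expt$unit$features, config)

  # --- Step 1: library matching (both channels) ---
  match_channel <- function(ei_unit) {
    if (!nrow(ei_unit)) {
      return(NULL)
    }
    queries <- abundance_cutoff(ei_unit, fraction = config$cutoff_fraction)
    hits <- search_library(queries, comp$library, top_k = config$top_k)
    curate_hits(
      hits, queries,
      min_score = config$min_score,
      min_matched_peaks = config$min_matched_peaks,
      min_query_peaks = config$min_query_peaks
    )
  }
  hr_unit_ei <- if (nrow(expt$hr$ei)) to_unit_mass(expt$hr$ei) else expt$hr$ei
  hits_hr <- match_channel(hr_unit_ei)
  hits_unit <- match_channel(expt$unit$ei)

  # --- Step 2: high-resolution filtering of plausible top hits (hr only) ---
  top_hits <- dplyr::filter(hits_hr, .data$rank == 1L, .data$plausible)
  lib_formula <- stats::setNames(comp$library$formula, comp$library$id)
  proposals <- tibble::tibble(
    id = top_hits$query,
    formula = unname(lib_formula[top_hits$library_id])
  )
  verdicts <- if (nrow(proposals)) {
    hr_filter(
      expt$hr$ei, proposals,
      tol_ppm = config$tolerance_ppm,
      min_fragments = config$min_fragments,
      n_intense = config$n_intense, n_highmz = config$n_highmz
    )
  } else {
    NULL
  }

  # --- Step 3: CI molecular ions and formula candidates (hr only) ---
  ci_hits <- purrr::map_dfr(seq_len(nrow(expt$hr$ci)), function(i) {
    s <- expt$hr$ci[i, ]
    h <- detect_adduct_series(
      s,
      tol_ppm = config$tolerance_ppm, min_support = config$min_support
    )
    if (!nrow(h)) {
      return(NULL)
    }
    h <- h[1, ]
    tibble::tibble(
      ci_id = s$id, ri = s$ri, M = h$M, support = h$support,
      peaks = s$peaks
    )
  })
  ci_links <- if (nrow(ci_hits) && nrow(expt$hr$ei)) {
    link_ci_to_ei(
      expt$hr$ei, ci_hits,
      ri_tol = config$ri_tol,
      frag_tol_ppm = config$tolerance_ppm,
      min_shared = config$min_shared
    )
  } else {
    NULL
  }
  mol_candidates <- if (!is.null(ci_links) && nrow(ci_links)) {
    purrr::map_dfr(seq_len(nrow(ci_links)), function(i) {
      cand <- decompose_mass(
        ci_links$M[i],
        decomposition_constraints(tolerance_ppm = config$tolerance_ppm)
      )
      tibble::tibble(
        ei_id = ci_links$ei_id[i],
        n_candidates = nrow(cand),
        top_formula = if (nrow(cand)) cand$formula[1] else NA_character_,
        candidates = list(cand)
      )
    })
  } else {
    NULL
  }

  # --- platform comparison ---
  post_ids_hr <- unique(hr_chan$features$compound)
  post_ids_unit <- unique(unit_chan$features$compound)
  spec_hr <- hr_unit_ei[hr_unit_ei$id %in% post_ids_hr, ]
  spec_unit <- expt$unit$ei[expt$unit$ei$id %in% post_ids_unit, ]
  pairing <- if (nrow(spec_hr) && nrow(spec_unit)) {
    match_compounds_across_platforms(
      spec_hr, spec_unit,
      ri_tol = config$ri_tol, spectral_min = config$spectral_min
    )
  } else {
    tibble::tibble(
      compound_a = character(0), compound_b = character(0),
      score = numeric(0), d_ri = numeric(0)
    )
  }
  sig_hr <- hr_chan$volcano$table$compound[hr_chan$volcano$table$significant]
  sig_unit <- unit_chan$volcano$table$compound[unit_chan$volcano$table$significant]
  overlap <- platform_overlap(
    sig_hr, sig_unit, pairing,
    compounds_a = unique(expt$hr$features$compound),
    compounds_b = unique(expt$unit$features$compound),
    blank_removed_a = hr_chan$removed$blank,
    blank_removed_b = unit_chan$removed$blank
  )

  # --- ground-truth scoring ---
  lib_of <- stats::setNames(truth$library_id, truth$compound)
  score_matching <- function(hits) {
    if (is.null(hits) || !nrow(hits)) {
      return(NA_real_)
    }
    top <- hits[hits$rank == 1L, ]
    top <- top[top$query %in% truth$compound[truth$in_library], ]
    if (!nrow(top)) {
      return(NA_real_)
    }
    mean(top$library_id == lib_of[top$query])
  }
  verdict_confirm_rate <- if (!is.null(verdicts) && nrow(verdicts)) {
    true_prop <- verdicts$id[verdicts$proposal ==
      stats::setNames(truth$formula, truth$compound)[verdicts$id]]
    mean(verdicts$verdict[verdicts$id %in% true_prop] == "confirmed")
  } else {
    NA_real_
  }
  ci_recovery <- if (!is.null(ci_links) && nrow(ci_links)) {
    true_mass <- stats::setNames(truth$derivatized_mass, truth$compound)
    mean(abs(ci_links$M - true_mass[ci_links$ei_id]) /
      true_mass[ci_links$ei_id] * 1e6 <= 2)
  } else {
    NA_real_
  }

  summary <- tibble::tibble(
    metric = c(
      "n_compounds_truth",
      "hr_detected", "unit_detected",
      "hr_post_filter", "unit_post_filter",
      "hr_significant", "unit_significant",
      "overlap_percent",
      "library_top1_accuracy_hr", "library_top1_accuracy_unit",
      "hr_filter_confirm_rate", "ci_mass_recovery_rate"
    ),
    value = c(
      nrow(truth),
      dplyr::n_distinct(expt$hr$features$compound),
      dplyr::n_distinct(expt$unit$features$compound),
      length(post_ids_hr), length(post_ids_unit),
      length(sig_hr), length(sig_unit),
      overlap$counts$overlap_percent,
      score_matching(hits_hr), score_matching(hits_unit),
      verdict_confirm_rate, ci_recovery
    )
  )

  structure(
    list(
      truth = truth,
      samples = expt$samples,
      channels = list(hr = hr_chan, unit = unit_chan),
      annotation = list(
        hits_hr = hits_hr, hits_unit = hits_unit,
        verdicts = verdicts, ci_hits = ci_hits, ci_links = ci_links,
        mol_candidates = mol_candidates
      ),
      comparison = list(pairing = pairing, overlap = overlap),
      summary = summary,
      config = config,
      seed = seed
    ),
    class = "twin_run"
  )
}

#' @export
print.twin_run <- function(x, ...) {
  cat("Twin-platform synthetic study (seed ", x$seed, ")\n", sep = "")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}
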