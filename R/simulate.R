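# Ground-truthed synthetic data: a derivatized-metabolite compound set with
# theoretical EI fragment spectra and CI adduct series, and paired
# high-resolution / unit-mass twin experiments with planted dysregulation,
# injection-order drift, pooled QCs and media blanks.

# neutral-loss pool for building EI fragments (all subtracted from the
# derivatized formula, so every fragment is a subformula by construction)
fragment_losses <- function() {
  list(
    CH3 = c(C = 1, H = 3),
    H = c(H = 1),
    H2O = c(H = 2, O = 1),
    CO = c(C = 1, O = 1),
    CO2 = c(C = 1, O = 2),
    CH4 = c(C = 1, H = 4),
    C2H4 = c(C = 2, H = 4),
    CH2O = c(C = 1, H = 2, O = 1),
    NH3 = c(N = 1, H = 3),
    HCN = c(C = 1, H = 1, N = 1),
    TMSOH = c(C = 3, H = 10, O = 1, Si = 1),
    OTMS = c(C = 3, H = 9, O = 1, Si = 1),
    CH3O = c(C = 1, H = 3, O = 1),
    C2H4O2 = c(C = 2, H = 4, O = 2)
  )
}

subtract_counts <- function(whole, loss) {
  out <- full_counts(whole)
  lf <- full_counts(loss)
  res <- out - lf
  if (any(res < 0)) {
    return(NULL)
  }
  res <- res[res > 0]
  if (!length(res)) {
    return(NULL)
  }
  res
}

#' Generate a ground-truthed compound set and spectral library
#'
#' Draws `n` compounds from the curated metabolite list, assigns TMS/MeOX
#' derivatization counts, retention indices (800-3600, no collisions
#' closer than 2 units), EI fragment sets built by subtracting random
#' neutral-loss combinations from the derivatized formula (10-40
#' fragments, all subformulas of the parent by construction, ion m/z
#' within the 50-600 EI scan range), molecular ions emitted weakly or
#' omitted with probability 0.5, true mean abundances, and blank/library
#' membership. The returned library holds unit-mass degraded theoretical
#' spectra of the `library_fraction` subset.
#'
#' @param n Number of compounds (>= 1).
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @param library_fraction Fraction of compounds present in the spectral
#'   library (default 0.8).
#' @return List with `truth` (ground-truth tibble, one row per compound,
#'   fragment sets nested) and `library` (spectra tibble).
#' @export
generate_compounds <- function(n = 60L, seed = 1L, library_fraction = 0.8) {
  stopifnot(n >= 1, library_fraction >= 0, library_fraction <= 1)
  set.seed(seed)
  pool <- metabolite_formulas()
  idx <- if (n <= nrow(pool)) {
    sample(nrow(pool), n)
  } else {
    c(seq_len(nrow(pool)), sample(nrow(pool), n - nrow(pool), replace = TRUE))
  }
  base <- pool[idx, ]

  # collision-free retention indices on a jittered grid
  grid <- seq(800, 3600, by = 2.5)
  ri <- sort(sample(grid, n)) + stats::runif(n, -0.2, 0.2)

  losses <- fragment_losses()
  truth <- purrr::map_dfr(seq_len(n), function(i) {
    counts <- parse_formula(base$formula[i])
    fc_full <- full_counts(counts)
    n_heter <- fc_full[["O"]] + fc_full[["N"]]
    n_tms <- if (n_heter == 0) 0L else sample(seq_len(min(6L, n_heter)), 1L)
    n_meox <- if (fc_full[["O"]] >= 1) {
      sample(c(0L, 1L), 1L, prob = c(0.6, 0.4))
    } else {
      0L
    }
    deriv <- derivatize(counts, n_tms = n_tms, n_meox = n_meox)
    d_mass <- monoisotopic_mass(deriv)

    n_frag <- sample(10:40, 1L)
    frags <- list()
    seen <- character(0)
    # canonical silyl fragments first
    if (full_counts(deriv)[["Si"]] >= 1) {
      for (f in list(c(C = 3, H = 9, Si = 1), c(C = 5, H = 15, O = 1, Si = 2))) {
        if (is_subformula(f, deriv)) {
          key <- format_formula(f)
          if (!(key %in% seen)) {
            frags[[length(frags) + 1L]] <- parse_formula(key)
            seen <- c(seen, key)
          }
        }
      }
    }
    attempt <- 0L
    while (length(frags) < n_frag && attempt < 500L) {
      attempt <- attempt + 1L
      k <- sample(1:4, 1L)
      pick <- sample(names(losses), k, replace = TRUE)
      total_loss <- Reduce(`+`, lapply(pick, function(nm) full_counts(losses[[nm]])))
      f <- subtract_counts(deriv, total_loss)
      if (is.null(f)) next
      # keep compositions chemically possible (no H beyond saturation)
      if (rdbe(f) < -0.5) next
      ion_mz <- monoisotopic_mass(f, charge = 1L)
      if (ion_mz < 50 || ion_mz > 600) next
      key <- format_formula(f)
      if (key %in% seen) next
      frags[[length(frags) + 1L]] <- f
      seen <- c(seen, key)
    }
    intensity <- stats::rlnorm(length(frags), meanlog = log(80), sdlog = 1.1)
    frag_tbl <- tibble::tibble(
      formula = vapply(frags, format_formula, character(1)),
      mz = vapply(frags, monoisotopic_mass, numeric(1), charge = 1L),
      intensity = intensity
    )
    # molecular ion: weak, and absent half of the time
    mol_mz <- monoisotopic_mass(deriv, charge = 1L)
    if (stats::runif(1) < 0.5 && mol_mz >= 50 && mol_mz <= 600) {
      frag_tbl <- dplyr::bind_rows(
        frag_tbl,
        tibble::tibble(
          formula = format_formula(deriv),
          mz = mol_mz,
          intensity = stats::runif(1, 1, 6)
        )
      )
    }
    frag_tbl$intensity <- frag_tbl$intensity / max(frag_tbl$intensity) * 999
    frag_tbl <- dplyr::arrange(frag_tbl, .data$mz)

    tibble::tibble(
      compound = sprintf("cmp%03d", i),
      name = base$name[i],
      base_formula = format_formula(counts),
      n_tms = n_tms,
      n_meox = n_meox,
      formula = format_formula(deriv),
      derivatized_mass = d_mass,
      ri = ri[i],
      n_fragments = nrow(frag_tbl),
      fragments = list(frag_tbl),
      mean_abundance = 10^stats::runif(1, 4, 8),
      in_blank = stats::runif(1) < 0.15,
      in_library = FALSE
    )
  })
  truth$blank_mean <- ifelse(
    truth$in_blank,
    truth$mean_abundance * 10^stats::runif(nrow(truth), -2, 0.3),
    NA_real_
  )
  n_lib <- round(n * library_fraction)
  lib_rows <- sample(n, n_lib)
  truth$in_library[lib_rows] <- TRUE
  truth$library_id <- ifelse(truth$in_library, paste0("lib_", truth$compound), NA)

  lib_idx <- which(truth$in_library)
  library <- if (length(lib_idx)) {
    acc <- purrr::map_dfr(lib_idx, function(i) {
      fr <- truth$fragments[[i]]
      msp_spectrum(fr$mz, fr$intensity,
        id = truth$library_id[i], name = truth$name[i],
        formula = truth$formula[i], mode = "EI",
        resolution = "accurate", ri = truth$ri[i]
      )
    })
    to_unit_mass(acc)
  } else {
    msp_spectrum(1, 1, id = "x")[0, ]
  }
  list(truth = truth, library = library)
}

drift_factor <- function(order, n_total, slope) {
  if (n_total <= 1) {
    return(rep(1, length(order)))
  }
  1 + slope * ((order - 1) / (n_total - 1) - 0.5)
}

rlnorm_mean <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a paired high-resolution / unit-mass twin experiment
#'
#' Builds a two-group (control vs osmotic stress) design with pooled-QC
#' and media-blank injections, plants fold changes on a fraction of
#' compounds, applies multiplicative injection-order drift and log-normal
#' biological/technical noise, and renders the same ground truth through
#' two instrument channels: an accurate-mass channel (EI + methane-CI
#' spectra with ppm-scale mass error) and a unit-mass channel (rounded
#' m/z, detection limit raised by `handicap`, so weak fragments and
#' trace compounds drop out).
#'
#' @param truth Ground-truth tibble from [generate_compounds()].
#' @param design List: `n_control`, `n_stress` (>= 2 each), `n_qc` (>= 3),
#'   `n_blank` (>= 2).
#' @param effect List: `planted_fraction`, `fc_range` (fold-change
#'   magnitude range; direction is drawn at random).
#' @param noise List: `cv` (area coefficient of variation), `ppm_sigma`
#'   (mass error, ppm), `intensity_cv` (spectral intensity noise).
#' @param drift_slope Total relative drift across the sequence.
#' @param handicap Detection-limit ratio unit : accurate channel
#'   (default 8).
#' @param lod Detection limit of the accurate channel, area units.
#' @param seed Integer RNG seed.
#' @return List of class `twin_dataset`: `truth` (with `fold_change`),
#'   `samples`, `hr` (`ei`, `ci`, `features`), `unit` (`ei`,
#'   `features`), `params`.
#' @export
generate_experiment <- function(truth,
                                design = list(
                                  n_control = 6L, n_stress = 6L,
                                  n_qc = 5L, n_blank = 3L
                                ),
                                effect = list(
                                  planted_fraction = 0.25,
                                  fc_range = c(2, 8)
                                ),
                                noise = list(
                                  cv = 0.1, ppm_sigma = 0.5,
                                  intensity_cv = 0.05
                                ),
                                drift_slope = 0.15,
                                handicap = 8,
                                lod = 5e3,
                                seed = 1L) {
  stopifnot(
    design$n_control >= 2, design$n_stress >= 2,
    design$n_qc >= 3, design$n_blank >= 2
  )
  set.seed(seed)
  n_cmp <- nrow(truth)

  # planted dysregulation
  n_planted <- round(effect$planted_fraction * n_cmp)
  planted <- sample(n_cmp, n_planted)
  fc <- rep(1, n_cmp)
  if (n_planted > 0) {
    mag <- stats::runif(n_planted, effect$fc_range[1], effect$fc_range[2])
    up <- stats::runif(n_planted) < 0.5
    fc[planted] <- ifelse(up, mag, 1 / mag)
  }
  truth$fold_change <- fc

  # injection sequence: experimental samples and blanks shuffled, QCs
  # evenly interleaved across the run
  ids <- list(
    control = sprintf("ctrl%02d", seq_len(design$n_control)),
    stress = sprintf("strs%02d", seq_len(design$n_stress)),
    QC = sprintf("qc%02d", seq_len(design$n_qc)),
    blank = sprintf("blk%02d", seq_len(design$n_blank))
  )
  non_qc <- sample(c(ids$control, ids$stress, ids$blank))
  n_total <- length(non_qc) + design$n_qc
  qc_pos <- round(seq(1, n_total, length.out = design$n_qc))
  if (anyDuplicated(qc_pos)) qc_pos <- seq_len(design$n_qc)
  seq_ids <- character(n_total)
  seq_ids[qc_pos] <- ids$QC
  seq_ids[-qc_pos] <- non_qc
  class_of <- function(s) {
    dplyr::case_when(
      s %in% ids$control ~ "control",
      s %in% ids$stress ~ "stress",
      s %in% ids$QC ~ "QC",
      TRUE ~ "blank"
    )
  }
  samples <- tibble::tibble(
    sample = seq_ids,
    class = class_of(seq_ids),
    injection_order = seq_len(n_total)
  )

  # expected (noise-free) mean per compound x sample
  mu_for <- function(i, cls) {
    switch(cls,
      control = truth$mean_abundance[i],
      stress = truth$mean_abundance[i] * truth$fold_change[i],
      QC = truth$mean_abundance[i] * (1 + truth$fold_change[i]) / 2,
      blank = if (truth$in_blank[i]) truth$blank_mean[i] else NA_real_
    )
  }
  areas <- purrr::map_dfr(seq_len(n_cmp), function(i) {
    mu <- vapply(samples$class, function(cl) mu_for(i, cl), numeric(1))
    mu <- mu * drift_factor(samples$injection_order, n_total, drift_slope)
    area <- rep(NA_real_, n_total)
    ok <- !is.na(mu)
    area[ok] <- rlnorm_mean(sum(ok), mu[ok], noise$cv)
    tibble::tibble(
      compound = truth$compound[i],
      sample = samples$sample,
      area = area
    )
  })

  # render one instrument channel
  render_channel <- function(channel_lod, unit) {
    detected <- logical(n_cmp)
    spectra <- vector("list", n_cmp)
    for (i in seq_len(n_cmp)) {
      fr <- truth$fragments[[i]]
      frag_abund <- truth$mean_abundance[i] * fr$intensity / 999
      keep <- frag_abund >= channel_lod
      if (sum(keep) < 3) next
      detected[i] <- TRUE
      fr <- fr[keep, , drop = FALSE]
      mz <- fr$mz * (1 + stats::rnorm(nrow(fr)) * noise$ppm_sigma * 1e-6)
      int <- fr$intensity * exp(stats::rnorm(nrow(fr)) * noise$intensity_cv)
      spectra[[i]] <- msp_spectrum(mz, int,
        id = truth$compound[i], name = truth$name[i],
        formula = truth$formula[i], mode = "EI",
        resolution = "accurate", ri = truth$ri[i]
      )
    }
    ei <- dplyr::bind_rows(spectra[detected])
    if (nrow(ei) && unit) ei <- to_unit_mass(ei)
    feats <- areas[areas$compound %in% truth$compound[detected], ]
    feats <- dplyr::left_join(feats, samples, by = "sample")
    feats$area[!is.na(feats$area) & feats$area < channel_lod] <- NA_real_
    feats <- dplyr::relocate(
      feats, "compound", "sample", "class", "injection_order", "area"
    )
    list(ei = ei, features = feats, detected = truth$compound[detected])
  }
  hr <- render_channel(lod, unit = FALSE)
  unit <- render_channel(lod * handicap, unit = TRUE)

  # CI channel (accurate only): adduct series of the derivatized molecular
  # mass plus a few strong shared EI fragments; members below the 80 m/z
  # scan floor are dropped
  offs <- adduct_offsets()
  ci <- purrr::map_dfr(which(truth$compound %in% hr$detected), function(i) {
    m <- truth$derivatized_mass[i]
    mzs <- m + offs$offset
    ints <- c(999, 600, 200, 80) * exp(stats::rnorm(4) * noise$intensity_cv)
    keep <- mzs >= 80
    fr <- truth$fragments[[i]]
    fr <- fr[fr$mz >= 80, , drop = FALSE]
    fr <- utils::head(fr[order(-fr$intensity), , drop = FALSE], 3L)
    mz_all <- c(mzs[keep], fr$mz)
    int_all <- c(ints[keep], fr$intensity * 0.1)
    mz_all <- mz_all * (1 + stats::rnorm(length(mz_all)) * noise$ppm_sigma * 1e-6)
    msp_spectrum(mz_all, int_all,
      id = paste0("ci_", truth$compound[i]), name = truth$name[i],
      mode = "CI", resolution = "accurate",
      ri = truth$ri[i] + stats::runif(1, -0.5, 0.5)
    )
  })

  structure(
    list(
      truth = truth,
      samples = samples,
      hr = list(ei = hr$ei, ci = ci, features = hr$features),
      unit = list(ei = unit$ei, features = unit$features),
      params = list(
        design = design, effect = effect, noise = noise,
        drift_slope = drift_slope, handicap = handicap, lod = lod,
        seed = seed
      )
    ),
    class = "twin_dataset"
  )
}

# formula-swap moves preserving nominal mass but not exact mass
decoy_swaps <- function() {
  list(
    "O->NH2" = function(f) {
      if (f[["O"]] >= 1) {
        f[["O"]] <- f[["O"]] - 1L
        f[["N"]] <- f[["N"]] + 1L
        f[["H"]] <- f[["H"]] + 2L
        f
      }
    },
    "NH2->O" = function(f) {
      if (f[["N"]] >= 1 && f[["H"]] >= 2) {
        f[["N"]] <- f[["N"]] - 1L
        f[["H"]] <- f[["H"]] - 2L
        f[["O"]] <- f[["O"]] + 1L
        f
      }
    },
    "CH2->N" = function(f) {
      if (f[["C"]] >= 1 && f[["H"]] >= 2) {
        f[["C"]] <- f[["C"]] - 1L
        f[["H"]] <- f[["H"]] - 2L
        f[["N"]] <- f[["N"]] + 1L
        f
      }
    },
    "N->CH2" = function(f) {
      if (f[["N"]] >= 1) {
        f[["N"]] <- f[["N"]] - 1L
        f[["C"]] <- f[["C"]] + 1L
        f[["H"]] <- f[["H"]] + 2L
        f
      }
    },
    "Si->C2H4" = function(f) {
      if (f[["Si"]] >= 1) {
        f[["Si"]] <- f[["Si"]] - 1L
        f[["C"]] <- f[["C"]] + 2L
        f[["H"]] <- f[["H"]] + 4L
        f
      }
    },
    "C2H4->Si" = function(f) {
      if (f[["C"]] >= 2 && f[["H"]] >= 4) {
        f[["C"]] <- f[["C"]] - 2L
        f[["H"]] <- f[["H"]] - 4L
        f[["Si"]] <- f[["Si"]] + 1L
        f
      }
    }
  )
}

#' Generate same-nominal-mass decoy proposals for each compound
#'
#' For every compound, returns the true derivatized formula and at least
#' one decoy obtained by a nominal-mass-preserving element swap
#' (O <-> NH2, CH2 <-> N, Si <-> C2H4). Every decoy has the same nominal
#' molecular mass as the truth but an exact mass differing by more than
#' 5 ppm, so accurate-mass filtering can discriminate them while
#' unit-mass matching cannot.
#'
#' @param truth Ground-truth tibble from [generate_compounds()].
#' @param seed Integer RNG seed (ordering of attempted swaps).
#' @return Tibble with columns `compound`, `proposal`, `role`
#'   (`"true"`/`"decoy"`), `swap`, `delta_ppm` (exact-mass difference from
#'   truth; 0 for the true proposal).
#' @export
generate_decoys <- function(truth, seed = 1L) {
  set.seed(seed)
  swaps <- decoy_swaps()
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    d <- full_counts(truth$formula[i])
    d_mass <- monoisotopic_mass(d)
    out <- tibble::tibble(
      compound = truth$compound[i],
      proposal = truth$formula[i],
      role = "true", swap = NA_character_, delta_ppm = 0
    )
    for (nm in sample(names(swaps))) {
      cand <- swaps[[nm]](d)
      if (is.null(cand)) next
      cand <- cand[cand > 0]
      dppm <- abs(monoisotopic_mass(cand) - d_mass) / d_mass * 1e6
      if (dppm <= 5) next
      out <- dplyr::bind_rows(out, tibble::tibble(
        compound = truth$compound[i],
        proposal = format_formula(cand),
        role = "decoy", swap = nm, delta_ppm = dppm
      ))
      break
    }
    out
  })
}
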