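# Exhaustive formula decomposition of an accurate mass under
# chemical-plausibility constraints (RDBE window, SENIOR condition,
# element-ratio ranges).

#' Element-ratio plausibility ranges (99.7% coverage)
#'
#' The "golden rules" element-ratio ranges covering 99.7% of known organic
#' molecules: H/C in \[0.2, 3.1\], N/C <= 1.3, O/C <= 1.2, P/C <= 0.3,
#' S/C <= 0.8. Silicon is counted as carbon for ratio purposes (TMS groups
#' extend the skeleton the way carbons do). Returned as a list so callers
#' can tighten or relax individual ranges.
#'
#' @return Named list of `c(min, max)` ranges keyed `h_c`, `n_c`, `o_c`,
#'   `p_c`, `s_c`.
#' @export
golden_ratio_limits <- function() {
  list(
    h_c = c(0.2, 3.1),
    n_c = c(0, 1.3),
    o_c = c(0, 1.2),
    p_c = c(0, 0.3),
    s_c = c(0, 0.8)
  )
}

#' Constraints for formula decomposition
#'
#' Bundles every knob of [decompose_mass()]: the ppm tolerance, per-element
#' count ranges, the admissible RDBE window, and which plausibility filters
#' are active.
#'
#' @param tolerance_ppm Mass tolerance in ppm (> 0, default 3).
#' @param element_max Named vector of maximum counts per element; elements
#'   absent from the vector are excluded from the search.
#' @param element_min Named vector of minimum counts (default all 0).
#' @param rdbe_range Admissible RDBE interval (default `c(-0.5, 40)`).
#' @param allow_half_integer_rdbe Keep half-integer RDBE compositions
#'   (radical/ion compositions); forced on for fragment-ion decomposition.
#' @param senior Apply the SENIOR condition (neutral molecules only).
#' @param ratio_check Apply the element-ratio ranges.
#' @param ratio_limits Ranges as produced by [golden_ratio_limits()].
#' @return A list of class `decomposition_constraints`.
#' @export
decomposition_constraints <- function(tolerance_ppm = 3,
                                      element_max = c(
                                        C = 40, H = 80, N = 6, O = 15,
                                        P = 3, S = 3, Si = 8
                                      ),
                                      element_min = NULL,
                                      rdbe_range = c(-0.5, 40),
                                      allow_half_integer_rdbe = FALSE,
                                      senior = TRUE,
                                      ratio_check = TRUE,
                                      ratio_limits = golden_ratio_limits()) {
  stopifnot(tolerance_ppm > 0)
  bad <- setdiff(names(element_max), supported_elements())
  if (length(bad)) {
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  mins <- stats::setNames(integer(length(element_max)), names(element_max))
  if (!is.null(element_min)) {
    stopifnot(all(names(element_min) %in% names(element_max)))
    mins[names(element_min)] <- as.integer(element_min)
  }
  if (any(mins > element_max)) {
    stop("element_min exceeds element_max", call. = FALSE)
  }
  stopifnot(length(rdbe_range) == 2L, rdbe_range[1] <= rdbe_range[2])
  structure(
    list(
      tolerance_ppm = tolerance_ppm,
      element_max = stats::setNames(as.integer(element_max), names(element_max)),
      element_min = mins,
      rdbe_range = rdbe_range,
      allow_half_integer_rdbe = allow_half_integer_rdbe,
      senior = senior,
      ratio_check = ratio_check,
      ratio_limits = ratio_limits
    ),
    class = "decomposition_constraints"
  )
}

# ratio filter over count columns (vectorized); Si counted as C
ratio_pass <- function(counts, limits) {
  cc <- counts[, "C"] + counts[, "Si"]
  ok <- rep(TRUE, nrow(counts))
  has_c <- cc > 0
  ratio_of <- function(el) ifelse(has_c, counts[, el] / pmax(cc, 1), 0)
  ok[has_c] <- ok[has_c] &
    (ratio_of("H")[has_c] >= limits$h_c[1]) &
    (ratio_of("H")[has_c] <= limits$h_c[2]) &
    (ratio_of("N")[has_c] <= limits$n_c[2]) &
    (ratio_of("O")[has_c] <= limits$o_c[2]) &
    (ratio_of("P")[has_c] <= limits$p_c[2]) &
    (ratio_of("S")[has_c] <= limits$s_c[2])
  # heteroatoms without any skeleton atom: only tiny inorganics (e.g. H2O)
  # are sensible; ratio rules do not apply to them
  ok
}

#' Decompose an accurate mass into candidate elemental formulas
#'
#' Exhaustively enumerates the constrained element-count lattice and
#' returns every composition whose (neutral or ionic) mass falls inside the
#' ppm window, filtered by RDBE range, optional SENIOR condition and
#' optional element-ratio ranges. For fragment ions
#' (`as_fragment_ion = TRUE`) the target composition mass is
#' `mass + electron mass` (the measured m/z lacks one electron), the SENIOR
#' condition is skipped and half-integer RDBE is allowed.
#'
#' Candidates are ordered by absolute ppm error, ties broken by lower RDBE
#' and then lexicographic element counts, so output order is deterministic.
#'
#' @param mass Target mass in Da: a neutral mass, or a singly charged
#'   cation m/z when `as_fragment_ion = TRUE`.
#' @param constraints A [decomposition_constraints()] object.
#' @param as_fragment_ion Treat `mass` as a cation m/z (see above).
#' @return Tibble with columns `formula`, `theoretical_mass` (in the same
#'   mass space as `mass`), `error_ppm` (signed, theoretical minus target),
#'   `rdbe`, and one count column per searched element. Zero rows is a
#'   valid outcome.
#' @examples
#' decompose_mass(73.04680,
#'   decomposition_constraints(element_max = c(C = 10, H = 20, Si = 2)),
#'   as_fragment_ion = TRUE
#' )
#' @export
decompose_mass <- function(mass, constraints = decomposition_constraints(),
                           as_fragment_ion = FALSE) {
  stopifnot(mass > 0, inherits(constraints, "decomposition_constraints"))
  target <- if (as_fragment_ion) mass + ELECTRON_MASS else mass
  win <- ppm_window(target, constraints$tolerance_ppm)

  lattice <- prod(as.numeric(constraints$element_max - constraints$element_min + 1L))
  if (lattice > 1e8) {
    stop(
      "element ranges span ~", format(lattice, scientific = TRUE),
      " lattice points (limit 1e8); tighten the ranges",
      call. = FALSE
    )
  }

  mono <- monoisotopic_masses()
  els <- names(constraints$element_max)
  heavy <- setdiff(els, "H")
  # cap every count by what fits under the window's upper edge
  cap <- pmin(
    constraints$element_max[heavy],
    floor(win[2] / mono[heavy])
  )
  lo_cnt <- constraints$element_min[heavy]
  if (any(cap < lo_cnt)) {
    return(empty_candidates(els))
  }

  grid <- do.call(expand.grid, lapply(heavy, function(el) {
    seq.int(lo_cnt[[el]], cap[[el]])
  }))
  names(grid) <- heavy
  grid <- as.matrix(grid)
  partial <- as.vector(grid %*% mono[heavy])

  if ("H" %in% els) {
    h_min <- constraints$element_min[["H"]]
    h_max <- constraints$element_max[["H"]]
    lo_h <- pmax(h_min, ceiling((win[1] - partial) / mono[["H"]] - 1e-9))
    hi_h <- pmin(h_max, floor((win[2] - partial) / mono[["H"]] + 1e-9))
    n_opt <- pmax(0L, hi_h - lo_h + 1L)
    keep <- n_opt > 0L
    if (!any(keep)) {
      return(empty_candidates(els))
    }
    idx <- rep(which(keep), n_opt[keep])
    h_cnt <- unlist(lapply(which(keep), function(i) seq.int(lo_h[i], hi_h[i])))
    counts <- cbind(grid[idx, , drop = FALSE], H = h_cnt)
  } else {
    keep <- partial >= win[1] & partial <= win[2]
    if (!any(keep)) {
      return(empty_candidates(els))
    }
    counts <- grid[keep, , drop = FALSE]
  }
  # pad absent alphabet columns with zeros, canonical column order
  all_els <- supported_elements()
  full <- matrix(0L, nrow(counts), length(all_els),
    dimnames = list(NULL, all_els)
  )
  full[, colnames(counts)] <- counts
  counts <- full

  theo <- as.vector(counts %*% mono[all_els])
  rdbe_v <- 1 + as.vector(counts %*% (ELEMENT_VALENCE[all_els] - 2)) / 2
  valsum <- as.vector(counts %*% ELEMENT_VALENCE[all_els])
  n_atoms <- rowSums(counts)

  ok <- theo >= win[1] & theo <= win[2] & n_atoms > 0
  ok <- ok & rdbe_v >= constraints$rdbe_range[1] & rdbe_v <= constraints$rdbe_range[2]
  if (!as_fragment_ion && !constraints$allow_half_integer_rdbe) {
    ok <- ok & (rdbe_v %% 1 == 0)
  }
  if (!as_fragment_ion && constraints$senior) {
    ok <- ok & (valsum %% 2 == 0) & (valsum >= 2 * (n_atoms - 1))
  }
  if (constraints$ratio_check) {
    ok <- ok & ratio_pass(counts, constraints$ratio_limits)
  }
  if (!any(ok)) {
    return(empty_candidates(els))
  }
  counts <- counts[ok, , drop = FALSE]
  theo <- theo[ok]
  rdbe_v <- rdbe_v[ok]

  theo_out <- if (as_fragment_ion) theo - ELECTRON_MASS else theo
  err <- (theo - target) / target * 1e6
  ord <- do.call(order, c(
    list(abs(err), rdbe_v),
    lapply(all_els, function(el) counts[, el])
  ))
  counts <- counts[ord, , drop = FALSE]
  out <- tibble::tibble(
    formula = apply(counts, 1L, function(cc) {
      format_formula(cc[cc > 0])
    }),
    theoretical_mass = theo_out[ord],
    error_ppm = err[ord],
    rdbe = rdbe_v[ord]
  )
  dplyr::bind_cols(out, tibble::as_tibble(counts))
}

empty_candidates <- function(els) {
  all_els <- supported_elements()
  zero <- stats::setNames(
    rep(list(integer(0)), length(all_els)), all_els
  )
  dplyr::bind_cols(
    tibble::tibble(
      formula = character(0),
      theoretical_mass = numeric(0),
      error_ppm = numeric(0),
      rdbe = numeric(0)
    ),
    tibble::as_tibble(zero)
  )
}
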