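# Elemental formula arithmetic over the {C, H, N, O, P, S, Si} alphabet.
#
# A formula is represented as a named integer vector of element counts
# (absent element == count 0). User-facing functions also accept formula
# strings such as "C6H12O6", which are parsed on the fly.

#' Parse a molecular formula string
#'
#' Converts a formula string such as `"C6H12O6"` or `"C22H55NO6Si5"` into a
#' named integer count vector over the supported element alphabet. Counts of
#' repeated symbols are summed. The empty string yields the empty formula.
#'
#' @param x A formula string, or an already-parsed named count vector
#'   (returned unchanged after validation).
#' @return Named integer vector of element counts, in canonical element
#'   order, zero counts dropped.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("C3H9Si")
#' @export
parse_formula <- function(x) {
  if (is.numeric(x)) {
    return(validate_formula(x))
  }
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (x == "") {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x, perl = TRUE)[[1]]
  tokens <- regmatches(x, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(x)) {
    stop("cannot parse formula string: '", x, "'", call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Z][a-z]?", "", tokens)
  cnts <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
  counts <- tapply(cnts, syms, sum)
  validate_formula(stats::setNames(as.integer(counts), names(counts)))
}

validate_formula <- function(counts) {
  if (length(counts)) {
    bad <- setdiff(names(counts), supported_elements())
    if (length(bad)) {
      stop("unsupported element symbol(s): ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
      stop("element counts must be non-negative integers", call. = FALSE)
    }
  }
  counts <- counts[counts > 0]
  ord <- match(names(counts), supported_elements())
  counts <- counts[order(ord)]
  stats::setNames(as.integer(counts), names(counts))
}

#' Format a count vector as a formula string
#'
#' @param counts Named count vector (or formula string, returned canonical).
#' @return Single string in canonical element order; `""` for the empty
#'   formula.
#' @export
format_formula <- function(counts) {
  counts <- parse_formula(counts)
  if (!length(counts)) {
    return("")
  }
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

# counts over the full alphabet (zeros included), used internally
full_counts <- function(formula) {
  counts <- parse_formula(formula)
  out <- stats::setNames(integer(length(supported_elements())), supported_elements())
  out[names(counts)] <- counts
  out
}

#' Monoisotopic mass of a (possibly charged) composition
#'
#' Sums most-abundant-isotope atomic masses and subtracts `charge` electron
#' masses, so `charge = 0` gives the neutral mass and `charge = 1` the mass
#' of the corresponding cation. Only charges -1, 0, +1 are meaningful for
#' GC-MS ions and larger magnitudes are rejected.
#'
#' @param formula Formula string or named count vector.
#' @param charge Integer charge in `-1:1` (default 0).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass("C3H9Si", charge = 1)
#' @export
monoisotopic_mass <- function(formula, charge = 0L) {
  stopifnot(length(charge) == 1L, abs(charge) <= 1)
  counts <- parse_formula(formula)
  if (!length(counts)) {
    return(-charge * ELECTRON_MASS)
  }
  sum(monoisotopic_masses()[names(counts)] * counts) - charge * ELECTRON_MASS
}

#' Symmetric ppm mass window
#'
#' @param mass Mass in Da (> 0).
#' @param tol_ppm Tolerance in parts per million (>= 0).
#' @return Numeric vector `c(lo, hi)` in Da.
#' @export
ppm_window <- function(mass, tol_ppm) {
  stopifnot(mass > 0, tol_ppm >= 0)
  c(mass * (1 - tol_ppm * 1e-6), mass * (1 + tol_ppm * 1e-6))
}

#' Ring-and-double-bond equivalents
#'
#' RDBE = 1 + sum n_i (v_i - 2) / 2 with fixed valences C 4, Si 4, N 3,
#' P 3, O 2, S 2, H 1. Half-integer values indicate radical/ion
#' compositions rather than neutral molecules.
#'
#' @inheritParams monoisotopic_mass
#' @return RDBE as a real number (may be half-integer or negative).
#' @examples
#' rdbe("C6H6") # 4
#' rdbe("C3H9Si") # 0.5
#' @export
rdbe <- function(formula) {
  counts <- parse_formula(formula)
  if (!length(counts)) {
    return(1)
  }
  1 + sum(counts * (ELEMENT_VALENCE[names(counts)] - 2)) / 2
}

#' SENIOR necessary condition for a neutral molecular formula
#'
#' A formula can correspond to a connected neutral molecule only if the sum
#' of valences is even and at least `2 * (atom count - 1)`. Intended for
#' candidate molecules; fragment ions legitimately fail it.
#'
#' @inheritParams monoisotopic_mass
#' @return `TRUE` or `FALSE`.
#' @export
senior_check <- function(formula) {
  counts <- parse_formula(formula)
  stopifnot(length(counts) > 0)
  vsum <- sum(counts * ELEMENT_VALENCE[names(counts)])
  n_atoms <- sum(counts)
  (vsum %% 2 == 0) && (vsum >= 2 * (n_atoms - 1))
}

#' Is one formula an elementwise subset of another?
#'
#' Used by high-resolution filtering: a fragment composition is admissible
#' only when every element count is bounded by the proposed compound's
#' (derivatized) sum formula. The relation is a partial order (reflexive,
#' antisymmetric, transitive).
#'
#' @param part,whole Formula strings or named count vectors.
#' @return `TRUE` iff `count(part) <= count(whole)` for every element.
#' @export
is_subformula <- function(part, whole) {
  p <- full_counts(part)
  w <- full_counts(whole)
  all(p <= w)
}

#' Apply TMS / MeOX derivatization increments to a neutral formula
#'
#' Trimethylsilylation replaces an active hydrogen with Si(CH3)3, a net gain
#' of C3H8Si per TMS group. Methoximation of a carbonyl adds CH3N (the
#' carbonyl oxygen is retained in the methoxime). Because only the formula
#' (not the structure) is known, the oxygen count serves as the proxy
#' precondition for methoximation.
#'
#' @inheritParams monoisotopic_mass
#' @param n_tms Number of trimethylsilyl groups (>= 0).
#' @param n_meox Number of methoxime groups (>= 0, at most the O count).
#' @return Named count vector of the derivatized formula.
#' @examples
#' format_formula(derivatize("C6H12O6", n_tms = 5, n_meox = 1))
#' @export
derivatize <- function(formula, n_tms = 0L, n_meox = 0L) {
  stopifnot(n_tms >= 0, n_meox >= 0)
  counts <- full_counts(formula)
  if (n_meox > counts[["O"]]) {
    stop(
      "n_meox (", n_meox, ") exceeds the oxygen count (", counts[["O"]],
      "): no carbonyl available to oximate",
      call. = FALSE
    )
  }
  counts[["C"]] <- counts[["C"]] + 3L * n_tms + 1L * n_meox
  counts[["H"]] <- counts[["H"]] + 8L * n_tms + 3L * n_meox
  counts[["Si"]] <- counts[["Si"]] + n_tms
  counts[["N"]] <- counts[["N"]] + n_meox
  validate_formula(counts)
}

#' Aggregated nominal-mass isotope pattern
#'
#' Convolves per-element isotopologue distributions (from the shipped
#' natural-abundance table) into the relative abundances of the M, M+1,
#' M+2, ... nominal isotopologue peaks, normalized to the monoisotopic
#' peak.
#'
#' @inheritParams monoisotopic_mass
#' @param n_peaks Number of isotopologue peaks to return (>= 1).
#' @return Tibble with columns `offset` (0, 1, 2, ...) and `abundance`
#'   (relative to the monoisotopic peak, which has abundance 1).
#' @examples
#' isotope_pattern("Si", n_peaks = 3)
#' @export
isotope_pattern <- function(formula, n_peaks = 3L) {
  counts <- parse_formula(formula)
  stopifnot(length(counts) > 0, n_peaks >= 1)
  iso <- isotope_table()
  width <- as.integer(n_peaks)
  # distribution over nominal offsets for one atom of an element
  atom_dist <- function(el) {
    sub <- iso[iso$element == el, ]
    offs <- sub$isotope - min(sub$isotope)
    d <- numeric(width)
    for (i in seq_len(nrow(sub))) {
      if (offs[i] < width) d[offs[i] + 1L] <- d[offs[i] + 1L] + sub$abundance[i]
    }
    d
  }
  conv <- function(a, b) {
    out <- numeric(width)
    for (i in seq_len(width)) {
      j <- seq_len(i)
      out[i] <- sum(a[j] * b[i - j + 1L])
    }
    out
  }
  total <- c(1, numeric(width - 1L))
  for (el in names(counts)) {
    d <- atom_dist(el)
    acc <- c(1, numeric(width - 1L))
    n <- counts[[el]]
    # exponentiation by squaring of the single-atom polynomial
    base <- d
    while (n > 0) {
      if (n %% 2 == 1) acc <- conv(acc, base)
      n <- n %/% 2
      if (n > 0) base <- conv(base, base)
    }
    total <- conv(total, acc)
  }
  tibble::tibble(
    offset = seq_len(width) - 1L,
    abundance = total / total[1L]
  )
}
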