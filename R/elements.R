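# Element tables and physical constants shared by all mass arithmetic.
#
# Isotope masses and natural abundances are shipped as a plain-text table in
# inst/extdata/isotopes.tsv so that every computed mass is bit-stable and the
# provenance of the numbers is inspectable without reading code.

the <- new.env(parent = emptyenv())

#' Supported element alphabet, in canonical ordering
#'
#' All formula arithmetic in the package runs over this fixed alphabet of
#' elements common in derivatized primary metabolites: C, H, N, O, P, S and
#' Si (silicon enters through trimethylsilylation).
#'
#' @return Character vector of element symbols.
#' @export
supported_elements <- function() {
  c("C", "H", "N", "O", "P", "S", "Si")
}

# rest mass of the electron in Da (CODATA)
ELECTRON_MASS <- 0.000548579909

# one valence per element; multivalent states (e.g. S(VI), P(V)) are not
# enumerated -- see the methods vignette
ELEMENT_VALENCE <- c(C = 4, H = 1, N = 3, O = 2, P = 3, S = 2, Si = 4)

#' Isotope mass and abundance table
#'
#' Returns the package's isotope table (element, isotope nominal mass,
#' exact mass in Da, natural abundance), read once per session from the
#' plain-text copy shipped with the package.
#'
#' @return A tibble with columns `element`, `isotope`, `mass`, `abundance`.
#' @export
isotope_table <- function() {
  if (is.null(the$isotopes)) {
    path <- system.file("extdata", "isotopes.tsv", package = "hrgcms")
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    the$isotopes <- tibble::as_tibble(tab)
  }
  the$isotopes
}

# named vector of monoisotopic (most abundant isotope) masses
monoisotopic_masses <- function() {
  if (is.null(the$mono)) {
    iso <- isotope_table()
    mono <- vapply(supported_elements(), function(el) {
      sub <- iso[iso$element == el, ]
      sub$mass[which.max(sub$abundance)]
    }, numeric(1))
    the$mono <- mono
  }
  the$mono
}

#' Mass of a proton, TMS and MeOX increments (internal helpers)
#' @noRd
tms_increment_mass <- function() monoisotopic_mass(c(C = 3, H = 8, Si = 1))

#' @noRd
meox_increment_mass <- function() monoisotopic_mass(c(C = 1, H = 3, N = 1))
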