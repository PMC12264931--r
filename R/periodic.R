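#' Element reference data
#'
#' Covalent radii (single-bond, Cordero-style consensus values, in Angstrom),
#' standard atomic masses (g/mol) and maximum standard valences for the
#' elements the audit supports. The radius table drives distance-based bond
#' perception; the mass table drives molecular-weight distributions.
#'
#' @format A data.frame with columns `symbol`, `mass`, `radius`, `valence`.
#' @keywords internal
.element_table <- data.frame(
  symbol  = c("H",  "B",   "C",    "N",    "O",    "F",
              "Si", "P",   "S",    "Cl",   "Br",   "I",
              "Se", "As",  "Au",   "Li",   "Na",   "K"),
  mass    = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998,
              28.085, 30.974, 32.06, 35.45, 79.904, 126.904,
              78.971, 74.922, 196.967, 6.94, 22.990, 39.098),
  radius  = c(0.31, 0.84, 0.76, 0.71, 0.66, 0.57,
              1.11, 1.07, 1.05, 1.02, 1.20, 1.39,
              1.20, 1.19, 1.36, 1.28, 1.66, 2.03),
  valence = c(1L, 3L, 4L, 3L, 2L, 1L,
              4L, 5L, 6L, 1L, 1L, 1L,
              6L, 5L, 1L, 1L, 1L, 1L),
  stringsAsFactors = FALSE
)

#' Covalent radii lookup
#'
#' @param symbols Character vector of element symbols.
#' @return Numeric vector of covalent radii in Angstrom.
#' @export
#' @examples
#' covalent_radii(c("C", "H"))
covalent_radii <- function(symbols) {
  idx <- match(symbols, .element_table$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  r <- .element_table$radius[idx]
  names(r) <- symbols
  r
}

#' Standard atomic masses lookup
#'
#' @param symbols Character vector of element symbols.
#' @return Numeric vector of atomic masses in g/mol.
#' @export
atomic_masses <- function(symbols) {
  idx <- match(symbols, .element_table$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  m <- .element_table$mass[idx]
  names(m) <- symbols
  m
}

#' Maximum standard valences lookup
#'
#' Used only for validity screening (a carbon engaged in more than four
#' bond-order units is chemically impossible), not for charge or
#' hypervalence modelling.
#'
#' @param symbols Character vector of element symbols.
#' @return Integer vector of maximum valences.
#' @export
standard_valences <- function(symbols) {
  idx <- match(symbols, .element_table$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  v <- .element_table$valence[idx]
  names(v) <- symbols
  v
}
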