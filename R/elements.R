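#' @title Built-in element data
#' @description Atomic masses (amu), Bondi-style van der Waals radii (Angstrom)
#'   and UFF nonbonded parameters for the elements supported by the toolkit.
#'   Unknown elements raise an error rather than falling back to a silent
#'   default.
#' @name element-data
#' @keywords internal
NULL

# masses: CIAAW conventional; vdw: Bondi radii (Angstrom)
.element_table <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "S", "Cl", "Br"),
  mass   = c(1.008, 12.011, 14.007, 15.999, 18.998, 32.06, 35.45, 79.904),
  vdw    = c(1.20, 1.70, 1.55, 1.52, 1.47, 1.80, 1.75, 1.85),
  stringsAsFactors = FALSE
)

# UFF nonbonded: x_I is the LJ minimum distance (Angstrom), D_I the well depth
# (kcal/mol); sigma = x_I / 2^(1/6)
.uff_table <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "S", "Cl", "Br"),
  x      = c(2.886, 3.851, 3.660, 3.500, 3.364, 4.035, 3.947, 4.189),
  d      = c(0.044, 0.105, 0.069, 0.060, 0.050, 0.274, 0.227, 0.251),
  stringsAsFactors = FALSE
)

# Coulomb constant in kcal * Angstrom / (mol * e^2)
.coulomb_k <- 332.06371

.element_lookup <- function(symbols, column, table = .element_table) {
  idx <- match(symbols, table$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(table$symbol, collapse = ", "), ")",
         call. = FALSE)
  }
  table[[column]][idx]
}

#' Atomic masses for element symbols
#' @param symbols character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @export
element_masses <- function(symbols) .element_lookup(symbols, "mass")

#' Van der Waals radii for element symbols
#' @param symbols character vector of element symbols.
#' @return numeric vector of Bondi-style vdW radii in Angstrom.
#' @export
element_vdw_radii <- function(symbols) .element_lookup(symbols, "vdw")
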