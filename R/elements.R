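# Element reference data: atomic numbers, covalent radii (Cordero 2008, A)
# and van der Waals radii (Bondi 1964, A). Covers the organic set plus the
# metals that occur in typical binding-site residues.

.element_table <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
             "Fe", "Zn", "Br", "I"),
  number = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L,
             11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L, 20L,
             26L, 30L, 35L, 53L),
  r_cov  = c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
             1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
             1.32, 1.22, 1.20, 1.39),
  r_vdw  = c(1.20, 1.40, 1.82, 1.53, 1.92, 1.70, 1.55, 1.52, 1.47, 1.54,
             2.27, 1.73, 1.84, 2.10, 1.80, 1.80, 1.75, 1.88, 2.75, 2.31,
             2.04, 1.39, 1.85, 1.98),
  stringsAsFactors = FALSE
)

#' Look up element properties
#'
#' Returns atomic number, covalent radius and van der Waals radius for a
#' vector of element symbols. Symbols are matched case-insensitively on the
#' conventional capitalisation (e.g. `"CL"` and `"cl"` both resolve to Cl).
#'
#' @param symbols Character vector of element symbols.
#' @return A data frame with columns `symbol`, `number`, `r_cov`, `r_vdw`,
#'   one row per input symbol, in input order.
#' @examples
#' element_info(c("C", "N", "O"))
#' @export
element_info <- function(symbols) {
  norm <- normalize_element(symbols)
  idx <- match(norm, .element_table$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  out <- .element_table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Canonical capitalisation: first letter upper, rest lower.
normalize_element <- function(symbols) {
  s <- trimws(as.character(symbols))
  paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, nchar(s))))
}

#' Atomic numbers for element symbols
#' @param symbols Character vector of element symbols.
#' @return Integer vector of atomic numbers.
#' @export
atomic_number <- function(symbols) element_info(symbols)$number

is_heavy <- function(symbols) normalize_element(symbols) != "H"

# Round half away from zero, the convention used by the printed descriptor
# tables this package mirrors (base round() rounds half to even).
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
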