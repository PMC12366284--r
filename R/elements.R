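# Periodic-table lookup shared by the MRV reader and printers.

#' @keywords internal
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Convert element symbols to atomic numbers
#'
#' @param symbol character vector of element symbols (e.g. `"O"`).
#' @return integer vector of atomic numbers.
#' @keywords internal
element_number <- function(symbol) {
  z <- match(symbol, ELEMENT_SYMBOLS)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "))
  }
  as.integer(z)
}

#' @keywords internal
element_symbol <- function(z) {
  if (any(z < 1L | z > length(ELEMENT_SYMBOLS))) {
    stop("atomic number out of range")
  }
  ELEMENT_SYMBOLS[z]
}

# Bond orders used throughout; aromatic is a first-class order, never
# kekulized, so equality does not depend on a kekulization choice.
BOND_ORDERS <- c("single", "double", "triple", "aromatic")
BOND_SMARTS <- c(single = "-", double = "=", triple = "#", aromatic = ":")
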