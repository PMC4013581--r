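# Element data used when building Structure objects from PDB records and when
# assigning van der Waals radii in the pocket grid.

# Standard atomic weights (Da), common biomolecular elements plus a generic
# coarse-grained bead ("X", one residue per bead, average residue mass).
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, MN = 54.938,
  `NA` = 22.990, K = 39.098, CL = 35.45, CA = 40.078, X = 110.0
)

# Bondi-style van der Waals radii (Angstrom); coarse-grained beads get a
# residue-sized radius.
.element_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
  SE = 1.90, FE = 1.50, ZN = 1.39, MG = 1.73, MN = 1.50,
  `NA` = 2.27, K = 2.75, CL = 1.75, CA = 2.31, X = 3.40
)

#' Atomic mass for an element symbol
#'
#' @param element character vector of element symbols (case-insensitive);
#'   the symbol `"X"` denotes a coarse-grained residue bead.
#' @return numeric vector of masses in Da. Unknown symbols give `NA`.
#' @export
element_mass <- function(element) {
  unname(.element_masses[toupper(element)])
}

#' Van der Waals radius for an element symbol
#'
#' @inheritParams element_mass
#' @return numeric vector of radii in Angstrom. Unknown symbols give `NA`.
#' @export
element_radius <- function(element) {
  unname(.element_radii[toupper(element)])
}

# Infer the element from a PDB atom name when columns 77-78 are blank or
# unrecognised. PDB convention: the element starts in column 13 unless the
# name is a 4-character hydrogen ("HG11") or begins with a digit ("1HB").
.element_from_name <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[^A-Za-z]", "", nm)
    if (!nzchar(nm)) return("X")
    two <- toupper(substr(nm, 1, 2))
    if (two %in% c("CL", "SE", "FE", "ZN", "MG", "MN") &&
        two %in% names(.element_masses)) {
      return(two)
    }
    one <- toupper(substr(nm, 1, 1))
    if (one %in% names(.element_masses)) one else "X"
  }, character(1), USE.NAMES = FALSE)
}
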