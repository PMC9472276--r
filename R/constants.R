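## Physical constants and element bookkeeping shared across modules.
## Internal energy unit is eV; coordinates are Angstrom throughout.

#' Unit conversion constants
#'
#' All energies inside the package are carried in electron-volts (eV) and
#' converted to kcal/mol only at the free-energy stage, so that mixed-unit
#' bugs cannot creep into the per-frame bookkeeping.
#'
#' @format Named numeric vector with elements
#'   \describe{
#'     \item{ev_per_hartree}{27.211386245988 eV per Hartree (CODATA).}
#'     \item{kcalmol_per_ev}{23.060548 kcal/mol per eV.}
#'     \item{coulomb_ke}{14.399645 eV Angstrom e^-2, the Coulomb prefactor.}
#'     \item{bohr_per_angstrom}{1/0.529177210903 Bohr per Angstrom.}
#'     \item{gas_constant_kcal}{1.987204e-3 kcal mol^-1 K^-1.}
#'   }
#' @export
lie_constants <- c(
  ev_per_hartree    = 27.211386245988,
  kcalmol_per_ev    = 23.060548,
  coulomb_ke        = 14.399645,
  bohr_per_angstrom = 1 / 0.529177210903,
  gas_constant_kcal = 1.987204e-3
)

## Chemical symbols the readers recognise (organics, halogens, common
## counter-ions and a few metals seen in PDB files).
.known_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Se", "Br", "I"
)

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN"
)

.water_residues <- c("HOH", "SOL", "WAT", "TIP3")

## "NA" etc. may arrive as R's missing value after a round-trip through a
## parser; treat that as an empty token, never as sodium.
.normalize_element <- function(x) {
  x <- ifelse(is.na(x), "", trimws(x))
  out <- paste0(
    toupper(substr(x, 1, 1)),
    tolower(substr(x, 2, nchar(x)))
  )
  out[x == ""] <- ""
  out
}

#' Convert an energy in eV to kcal/mol
#'
#' @param x Numeric energy (eV).
#' @return `x * 23.060548`, in kcal/mol.
#' @examples
#' ev_to_kcalmol(0.02) # ~0.46 kcal/mol
#' @export
ev_to_kcalmol <- function(x) {
  stopifnot(is.numeric(x))
  x * lie_constants[["kcalmol_per_ev"]]
}

#' Convert an energy in kcal/mol to eV
#'
#' @param x Numeric energy (kcal/mol).
#' @return Energy in eV.
#' @export
kcalmol_to_ev <- function(x) {
  stopifnot(is.numeric(x))
  x / lie_constants[["kcalmol_per_ev"]]
}
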