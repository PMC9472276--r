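## Published reference single-point energies shipped with the package.

#' Reference single-point energies for the truncated HIV-1 protease
#' complex (PDB 5IVS)
#'
#' Published absolute single-point energies (eV) of the truncated
#' protein+ligand complex of HIV-1 protease with its ligand (PDB id
#' 5IVS, ~920 atoms, 55 residues around the ligand), for selected MD
#' frames, evaluated both by DFT (wb97x/6-31G*) and by the ANI-2x
#' neural-network potential.  Columns give the complex (PL), receptor
#' (P) and ligand (L) energies per method, the printed interaction
#' energies (`g16_de`, `ani_de`) and the printed absolute error between
#' the two methods (`abs_err`).  The `mean` row averages all 100 frames
#' of the source data, so its `abs_err` is the mean of the per-frame
#' errors, not the error of the means.
#'
#' Useful as a worked example for [interaction_energy()]: the absolute
#' energies are in the hundreds of thousands of eV while the
#' interaction energies are a few eV — the bias cancels in the
#' subtraction.
#'
#' @return Data frame with one row per frame (`frame` is character:
#'   "0", "1", "2", "3", "100", "mean").
#' @export
ref_spe_5ivs <- function() {
  path <- system.file("extdata", "hiv1pr_5ivs_truncated_spe_ev.csv",
                      package = "nnlie", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(frame = "character"))
}
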