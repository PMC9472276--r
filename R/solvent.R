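## Explicit-solvent handling: order waters by distance to the solute,
## reduce the solvation shell to a cutoff (whole molecules only), and
## strip backend-unsupported counter-ions.  Distances are plain Euclidean
## min atom-atom distances: frames are assumed PBC-whole and centered, so
## no minimum-image convention is applied.

.default_strippable <- c("NA", "CL", "K", "SOD", "CLA", "POT", "NA+", "CL-", "ION")

.solute_positions <- function(frame, selection, solute_names) {
  idx <- sort(unique(unlist(selection[solute_names], use.names = FALSE)))
  if (length(idx) == 0L) stop("solute groups are empty")
  pos <- match(idx, frame$atoms$serial)
  if (anyNA(pos)) stop("solute index ", idx[is.na(pos)][1L], " not in frame")
  pos
}

## min solute-water atom distance per water molecule, vectorised
.water_min_dists <- function(frame, solute_pos) {
  atoms <- frame$atoms
  wat <- which(atoms$residue_name %in% .water_residues)
  if (length(wat) == 0L) {
    return(data.frame(mol_id = integer(0), dist = numeric(0)))
  }
  sxyz <- frame$coords[solute_pos, , drop = FALSE]
  wxyz <- frame$coords[wat, , drop = FALSE]
  ## squared cross-distance matrix (waters x solute)
  d2 <- outer(rowSums(wxyz^2), rowSums(sxyz^2), `+`) - 2 * wxyz %*% t(sxyz)
  dmin_atom <- sqrt(pmax(apply(d2, 1L, min), 0))
  agg <- tapply(dmin_atom, atoms$mol_id[wat], min)
  data.frame(mol_id = as.integer(names(agg)), dist = as.numeric(agg))
}

#' Order water molecules by distance to the solute
#'
#' Waters (residue names HOH/SOL/WAT/TIP3) are ranked by the minimum
#' atom-atom Euclidean distance between any of their atoms (hydrogens
#' included) and any solute atom; ties break by ascending molecule id.
#'
#' @param frame A [structure_frame()].
#' @param selection A `group_selection`.
#' @param solute_names Group names forming the solute (e.g. c("P","L")).
#' @return Integer vector of water `mol_id`s, nearest first (empty when
#'   the frame holds no waters).
#' @export
order_waters <- function(frame, selection, solute_names) {
  solute_pos <- .solute_positions(frame, selection, solute_names)
  d <- .water_min_dists(frame, solute_pos)
  if (nrow(d) == 0L) return(integer(0))
  d$mol_id[order(d$dist, d$mol_id)]
}

#' Reduce the explicit solvation shell to a distance cutoff
#'
#' Keeps the solute atoms plus every water molecule whose minimum
#' atom-atom distance to the solute is at most `cutoff`; water molecules
#' are kept or dropped whole, never split.  Atom order and serials are
#' preserved, so an existing `group_selection` stays valid on the reduced
#' frame.  Atoms that are neither solute nor water (e.g. counter-ions)
#' are dropped.
#'
#' @param frame A [structure_frame()].
#' @param selection A `group_selection`.
#' @param solute_names Group names forming the solute; the 4 A default
#'   shell is conventionally measured around the whole PL complex, but
#'   passing only the ligand group gives a ligand-centred shell.
#' @param cutoff Positive shell radius in Angstrom (default 4).
#' @return List with `frame` (the reduced [structure_frame()]), `report`
#'   (a `solvent_reduction_report`) and `selection` (the input groups
#'   restricted to the atoms that survived, for use on the reduced frame).
#' @export
reduce_solvation <- function(frame, selection, solute_names, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  atoms <- frame$atoms
  solute_pos <- .solute_positions(frame, selection, solute_names)
  d <- .water_min_dists(frame, solute_pos)
  kept_mols <- d$mol_id[d$dist <= cutoff]
  wat_rows <- which(atoms$residue_name %in% .water_residues)
  keep <- sort(unique(c(solute_pos, wat_rows[atoms$mol_id[wat_rows] %in% kept_mols])))
  dropped_other <- setdiff(seq_len(nrow(atoms)), union(keep, wat_rows))
  report <- structure(
    list(n_waters_in = nrow(d), n_waters_kept = length(kept_mols),
         cutoff = cutoff, n_ions_stripped = length(dropped_other)),
    class = "solvent_reduction_report"
  )
  out <- structure_frame(atoms[keep, , drop = FALSE],
                         frame$coords[keep, , drop = FALSE],
                         time_ps = frame$time_ps,
                         frame_index = frame$frame_index)
  ## structure_frame() recomputes mol_id from scratch; keep the originals
  ## so whole-molecule identity survives the reduction
  out$atoms$mol_id <- atoms$mol_id[keep]
  kept_serials <- atoms$serial[keep]
  reduced_sel <- structure(
    lapply(unclass(selection), function(g) g[g %in% kept_serials]),
    class = "group_selection"
  )
  list(frame = out, report = report, selection = reduced_sel)
}

#' @export
print.solvent_reduction_report <- function(x, ...) {
  cat(sprintf("<solvent_reduction> kept %d / %d waters within %.2f A (%d non-solute/non-water atoms dropped)\n",
              x$n_waters_kept, x$n_waters_in, x$cutoff, x$n_ions_stripped))
  invisible(x)
}

#' Strip backend-unsupported ions from a frame
#'
#' Atoms whose element the backend cannot evaluate are removed if and
#' only if their residue name is in `strippable_residues` (counter-ion
#' residues by default).  An unsupported element anywhere else — e.g. a
#' bromine in the ligand — raises an error instead of being silently
#' dropped: losing a ligand atom would corrupt the interaction energy,
#' while distant neutralising ions are legitimately negligible.
#'
#' @param frame A [structure_frame()].
#' @param spec A [calculator_spec()].
#' @param strippable_residues Residue names that may be dropped.
#' @param selection Optional `group_selection`; used only to name the
#'   offending group in error messages.
#' @return The (possibly reduced) [structure_frame()], with the number of
#'   stripped atoms attached as attribute `"n_stripped"`.
#' @export
strip_unsupported <- function(frame, spec,
                              strippable_residues = .default_strippable,
                              selection = NULL) {
  atoms <- frame$atoms
  bad <- !(atoms$element %in% spec$supported_elements)
  if (!any(bad)) {
    return(structure(frame, n_stripped = 0L))
  }
  strippable <- bad & toupper(atoms$residue_name) %in% toupper(strippable_residues)
  hard <- which(bad & !strippable)
  if (length(hard) > 0L) {
    a <- hard[1L]
    grp <- ""
    if (!is.null(selection)) {
      hit <- names(selection)[vapply(selection,
                                     function(g) atoms$serial[a] %in% g, TRUE)]
      if (length(hit) > 0L) grp <- paste0(" (group ", hit[1L], ")")
    }
    stop("element '", atoms$element[a], "' of atom ", atoms$serial[a],
         " in residue ", atoms$residue_name[a], grp,
         " is unsupported by backend '", spec$backend,
         "' and not strippable")
  }
  keep <- which(!strippable)
  out <- structure_frame(atoms[keep, , drop = FALSE],
                         frame$coords[keep, , drop = FALSE],
                         time_ps = frame$time_ps,
                         frame_index = frame$frame_index)
  out$atoms$mol_id <- atoms$mol_id[keep]
  structure(out, n_stripped = sum(strippable))
}
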