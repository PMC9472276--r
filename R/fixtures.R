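## Deterministic synthetic systems and datasets.  The toy complexes are
## geometric stand-ins for solvated protein-ligand systems: a rigid
## receptor cluster, a small ligand in a pocket 3-5 A away, whole water
## molecules outside the solute, optional sodium counter-ions, and
## per-frame Gaussian jitter.  They validate plumbing and arithmetic, not
## chemistry.

.random_unit_vec <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

.place_cluster <- function(n, center, radius, elements, min_sep = 0.95,
                           other_coords = NULL, min_other = 2.2,
                           max_retry = 500L) {
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      p <- center + .random_unit_vec() * radius * stats::runif(1)^(1 / 3)
      ok <- TRUE
      if (i > 1L) {
        d2 <- rowSums((coords[seq_len(i - 1L), , drop = FALSE] -
                         matrix(p, i - 1L, 3, byrow = TRUE))^2)
        ok <- all(d2 >= min_sep^2)
      }
      if (ok && !is.null(other_coords)) {
        d2 <- rowSums((other_coords - matrix(p, nrow(other_coords), 3,
                                             byrow = TRUE))^2)
        ok <- all(d2 >= min_other^2)
      }
      if (ok) { coords[i, ] <- p; placed <- TRUE; break }
    }
    if (!placed) stop("could not place atom ", i, " without overlap after ",
                      max_retry, " retries; loosen the geometry spec")
  }
  list(coords = coords, elements = rep_len(elements, n))
}

## one rigidly oriented TIP3P-like water at oxygen position p
.water_geometry <- function(p) {
  b1 <- .random_unit_vec()
  ## second O-H direction at ~104.5 degrees from the first
  perp <- .random_unit_vec()
  perp <- perp - sum(perp * b1) * b1
  perp <- perp / sqrt(sum(perp^2))
  ang <- 104.5 * pi / 180
  b2 <- cos(ang) * b1 + sin(ang) * perp
  rbind(p, p + 0.9572 * b1, p + 0.9572 * b2)
}

#' Generate a deterministic toy solvated complex trajectory
#'
#' Builds a receptor cluster of C/N/O/H atoms around the origin, a small
#' C/H/O ligand with its centre 3-5 Angstrom away, `n_waters` whole water
#' molecules (residue HOH) packed outside the solute, and optional sodium
#' ions (residue SOD), then applies seeded per-frame Gaussian jitter.
#' Index groups P, L, SOL (and ION when ions are present) partition the
#' atom serial range exactly.
#'
#' @param n_receptor_atoms,n_ligand_atoms,n_waters,n_ions Component sizes.
#' @param box_edge Box edge length (Angstrom) bounding water placement.
#' @param n_frames Number of frames (>= 1).
#' @param jitter Per-coordinate Gaussian jitter s.d. (Angstrom).
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @param write_dir Optional directory; when given, a multi-model PDB
#'   (`toy_traj.pdb`) and index file (`toy.ndx`) are written there.
#' @return List with `trajectory` ([trajectory()]), `selection`
#'   (`group_selection`), and `paths` (written files, or NULL).
#' @export
make_toy_trajectory <- function(n_receptor_atoms = 24L, n_ligand_atoms = 8L,
                                n_waters = 20L, n_ions = 0L, box_edge = 24,
                                n_frames = 3L, jitter = 0.05, seed = 1L,
                                write_dir = NULL) {
  stopifnot(n_receptor_atoms >= 1L, n_ligand_atoms >= 1L, n_waters >= 0L,
            n_ions >= 0L, box_edge > 0, n_frames >= 1L, jitter >= 0)
  set.seed(as.integer(seed))

  rec <- .place_cluster(n_receptor_atoms, c(0, 0, 0),
                        radius = max(2.5, 0.8 * n_receptor_atoms^(1 / 3) * 1.8),
                        elements = c("C", "N", "C", "O", "H", "C"))
  ## ligand pocket: centre sits 3-5 A beyond the receptor surface
  lig_center <- .random_unit_vec() * (max(sqrt(rowSums(rec$coords^2))) +
                                        stats::runif(1, 3, 5))
  lig <- .place_cluster(n_ligand_atoms, lig_center, radius = 1.4,
                        elements = c("C", "C", "O", "H"),
                        other_coords = rec$coords, min_other = 2.4)
  solute <- rbind(rec$coords, lig$coords)

  wat_coords <- NULL
  wat_oxygens <- matrix(numeric(0), 0, 3)
  half <- box_edge / 2
  for (w in seq_len(n_waters)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      p <- stats::runif(3, -half, half)
      d2s <- rowSums((solute - matrix(p, nrow(solute), 3, byrow = TRUE))^2)
      ok <- all(d2s >= 2.4^2)
      if (ok && nrow(wat_oxygens) > 0L) {
        d2w <- rowSums((wat_oxygens - matrix(p, nrow(wat_oxygens), 3,
                                             byrow = TRUE))^2)
        ok <- all(d2w >= 2.6^2)
      }
      if (ok) {
        wat_oxygens <- rbind(wat_oxygens, p)
        wat_coords <- rbind(wat_coords, .water_geometry(p))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place water ", w,
                      "; enlarge box_edge or reduce n_waters")
  }

  ion_coords <- NULL
  occupied <- rbind(solute, wat_coords)
  for (k in seq_len(n_ions)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      p <- stats::runif(3, -half, half)
      d2 <- rowSums((occupied - matrix(p, nrow(occupied), 3, byrow = TRUE))^2)
      if (all(d2 >= 3.0^2)) {
        ion_coords <- rbind(ion_coords, p)
        occupied <- rbind(occupied, p)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place ion ", k)
  }

  elements <- c(rec$elements, lig$elements,
                rep(c("O", "H", "H"), n_waters), rep("Na", n_ions))
  base <- rbind(solute, wat_coords, ion_coords)
  n_total <- nrow(base)

  atom_name <- character(n_total)
  residue_name <- character(n_total)
  residue_id <- integer(n_total)
  i_rec <- seq_len(n_receptor_atoms)
  i_lig <- n_receptor_atoms + seq_len(n_ligand_atoms)
  residue_name[i_rec] <- "REC"; residue_id[i_rec] <- 1L
  residue_name[i_lig] <- "LIG"; residue_id[i_lig] <- 2L
  atom_name[i_rec] <- paste0(elements[i_rec], seq_along(i_rec))
  atom_name[i_lig] <- paste0(elements[i_lig], seq_along(i_lig))
  off <- n_receptor_atoms + n_ligand_atoms
  if (n_waters > 0L) {
    i_wat <- off + seq_len(3L * n_waters)
    residue_name[i_wat] <- "HOH"
    residue_id[i_wat] <- 2L + rep(seq_len(n_waters), each = 3L)
    atom_name[i_wat] <- rep(c("OW", "HW1", "HW2"), n_waters)
  }
  if (n_ions > 0L) {
    i_ion <- off + 3L * n_waters + seq_len(n_ions)
    residue_name[i_ion] <- "SOD"
    residue_id[i_ion] <- 2L + n_waters + seq_len(n_ions)
    atom_name[i_ion] <- "NA"
  }

  atoms <- data.frame(serial = seq_len(n_total), element = elements,
                      atom_name = atom_name, residue_name = residue_name,
                      residue_id = residue_id, stringsAsFactors = FALSE)
  frames <- lapply(seq_len(n_frames), function(f) {
    xyz <- base + matrix(stats::rnorm(n_total * 3, 0, jitter), n_total, 3)
    structure_frame(atoms, xyz, time_ps = f - 1L, frame_index = f - 1L)
  })
  traj <- trajectory(frames, source = sprintf("toy(seed=%d)", seed))

  groups <- list(P = i_rec, L = i_lig)
  if (n_waters > 0L) groups$SOL <- off + seq_len(3L * n_waters)
  if (n_ions > 0L) groups$ION <- off + 3L * n_waters + seq_len(n_ions)
  selection <- structure(lapply(groups, as.integer), class = "group_selection")

  paths <- NULL
  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    pdb_path <- file.path(write_dir, "toy_traj.pdb")
    ndx_path <- file.path(write_dir, "toy.ndx")
    write_frames_pdb(traj, pdb_path)
    write_ndx(selection, ndx_path)
    paths <- list(pdb = pdb_path, ndx = ndx_path)
  }
  list(trajectory = traj, selection = selection, paths = paths)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Standard fixed-width ATOM records wrapped in MODEL/ENDMDL, with the
#' element symbol in columns 77-78.  Coordinates are truncated to PDB's
#' 3-decimal precision.
#'
#' @param traj A [trajectory()] or single [structure_frame()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(traj, path) {
  if (inherits(traj, "structure_frame")) traj <- trajectory(list(traj))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    writeLines(sprintf("MODEL     %4d", f$frame_index + 1L), con)
    a <- f$atoms
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial, substr(a$atom_name, 1, 4), substr(a$residue_name, 1, 3), "A",
      a$residue_id, f$coords[, 1], f$coords[, 2], f$coords[, 3], 1, 0,
      toupper(a$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Generate a synthetic single-term LIE fitting dataset
#'
#' Ensemble means `x` are drawn uniformly from the realistic
#' ligand-protein interaction range (-90 to -20 kcal/mol) and responses
#' follow `y = beta_true * x + gamma_true + N(0, noise_sd)`.  Used for
#' parameter-recovery checks of [fit_coefficients()].
#'
#' @param beta_true,gamma_true Generating coefficients.
#' @param n Number of complexes (>= 3).
#' @param noise_sd Gaussian noise s.d. in kcal/mol (>= 0).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `x` (kcal/mol) and `y` (kcal/mol).
#' @export
make_synthetic_lie_dataset <- function(beta_true = 0.106, gamma_true = -5.0,
                                       n = 54L, noise_sd = 1.5, seed = 1L) {
  stopifnot(n >= 3L, noise_sd >= 0)
  set.seed(as.integer(seed))
  x <- stats::runif(n, -90, -20)
  y <- beta_true * x + gamma_true + stats::rnorm(n, 0, noise_sd)
  data.frame(x = x, y = y)
}
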