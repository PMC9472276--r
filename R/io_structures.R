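## Reading MD snapshot structures (multi-model PDB, directories of PDB
## frames, multi-frame XYZ) and Gromacs-style index groups, and carving
## component subsets (PL, P, L, LS, S) out of frames.

.assign_mol_ids <- function(residue_id, residue_name) {
  key <- paste(residue_id, residue_name, sep = "\r")
  changed <- c(TRUE, key[-1] != key[-length(key)])
  cumsum(changed)
}

#' Construct a single MD snapshot
#'
#' A `structure_frame` holds one snapshot: an atom table (serial, element,
#' atom name, residue bookkeeping, molecule label) plus an N x 3 coordinate
#' matrix in Angstrom.  Molecules are defined as contiguous runs of
#' identical residue id + residue name; waters are recognised by residue
#' name (HOH/SOL/WAT/TIP3).
#'
#' @param atoms Data frame with columns `serial`, `element`, `atom_name`,
#'   `residue_name`, `residue_id` (and optionally `mol_id`, recomputed when
#'   absent).
#' @param coords Numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param time_ps Non-negative frame time in picoseconds.
#' @param frame_index Non-negative integer index of the frame.
#' @return Object of class `structure_frame`.
#' @export
structure_frame <- function(atoms, coords, time_ps = 0, frame_index = 0L) {
  stopifnot(is.data.frame(atoms), is.matrix(coords), ncol(coords) == 3)
  if (nrow(atoms) < 1L) stop("a structure_frame needs at least one atom")
  if (nrow(atoms) != nrow(coords)) {
    stop("atom table and coordinate matrix disagree: ",
         nrow(atoms), " atoms vs ", nrow(coords), " coordinate rows")
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates in frame")
  atoms$element <- .normalize_element(atoms$element)
  bad <- setdiff(unique(atoms$element), .known_elements)
  if (length(bad) > 0L) {
    stop("unknown element token(s): ", paste(bad, collapse = ", "))
  }
  if (is.unsorted(atoms$serial, strictly = TRUE)) {
    stop("atom serials must be strictly increasing")
  }
  if (is.null(atoms$mol_id)) {
    atoms$mol_id <- .assign_mol_ids(atoms$residue_id, atoms$residue_name)
  }
  rownames(atoms) <- NULL
  dimnames(coords) <- NULL
  structure(
    list(atoms = atoms, coords = coords,
         time_ps = as.numeric(time_ps), frame_index = as.integer(frame_index)),
    class = "structure_frame"
  )
}

#' @export
print.structure_frame <- function(x, ...) {
  cat("<structure_frame> ", nrow(x$atoms), " atoms, frame ", x$frame_index,
      " (t = ", x$time_ps, " ps)\n", sep = "")
  invisible(x)
}

n_atoms <- function(frame) nrow(frame$atoms)

#' Assemble frames into a trajectory
#'
#' Enforces the constant-composition invariant: every frame must have the
#' same atom count and the same element sequence.
#'
#' @param frames List of [structure_frame()] objects.
#' @param source Free-text provenance string.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(frames, source = "") {
  stopifnot(is.list(frames), length(frames) >= 1L)
  ref <- frames[[1L]]$atoms$element
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!inherits(f, "structure_frame")) stop("frames must be structure_frame objects")
    if (n_atoms(f) != length(ref) || any(f$atoms$element != ref)) {
      stop("frame ", i, " breaks the constant-composition invariant ",
           "(atom count or element sequence differs from frame 1)")
    }
  }
  structure(list(frames = frames, source = source), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$frames), " frame(s) of ",
      n_atoms(x$frames[[1L]]), " atoms", sep = "")
  if (nzchar(x$source)) cat(" [", x$source, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

## ---------------------------------------------------------------------------
## Gromacs index files

#' Read a Gromacs-format index (.ndx) file
#'
#' Every `[ name ]` section becomes a group of 1-based atom indices;
#' indices may wrap over any number of lines.  A duplicated group name is
#' resolved to the last definition, with a warning.  Empty groups are kept
#' (and flagged with a warning) so that a typo in a group name fails loudly
#' downstream rather than silently selecting nothing.
#'
#' @param path Path to the index file.
#' @return Object of class `group_selection`: a named list of sorted,
#'   duplicate-free integer vectors.
#' @export
read_ndx <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  groups <- list()
  current <- NULL
  header_seen <- FALSE
  for (ln in seq_along(lines)) {
    line <- sub(";.*$", "", lines[ln])     # Gromacs comment
    if (!nzchar(trimws(line))) next
    m <- regmatches(line, regexec("^\\s*\\[\\s*(.+?)\\s*\\]\\s*$", line))[[1L]]
    if (length(m) == 2L) {
      header_seen <- TRUE
      current <- m[2L]
      if (!is.null(groups[[current]])) {
        warning("group '", current, "' defined more than once; last definition wins")
      }
      groups[[current]] <- integer(0)
      next
    }
    if (is.null(current)) {
      stop("line ", ln, ": atom indices before any [ group ] header")
    }
    tokens <- strsplit(trimws(line), "\\s+")[[1L]]
    vals <- suppressWarnings(as.integer(tokens))
    if (anyNA(vals) || any(as.numeric(tokens) != vals)) {
      stop("line ", ln, ": non-integer token in group '", current, "'")
    }
    groups[[current]] <- c(groups[[current]], vals)
  }
  if (!header_seen) stop("no [ group ] header found in ", path)
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (length(g) == 0L) {
      warning("group '", nm, "' is empty")
    }
    if (any(g < 1L)) stop("group '", nm, "' contains indices < 1")
    groups[[nm]] <- sort(unique(g))
  }
  structure(groups, class = "group_selection")
}

#' Write a group selection as a Gromacs-format index file
#'
#' @param selection A `group_selection` (named list of 1-based indices).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ndx <- function(selection, path) {
  stopifnot(length(names(selection)) == length(selection))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(selection)) {
    writeLines(sprintf("[ %s ]", nm), con)
    idx <- selection[[nm]]
    if (length(idx) > 0L) {
      rows <- split(idx, ceiling(seq_along(idx) / 15))
      writeLines(vapply(rows, function(r) paste(r, collapse = " "), ""), con)
    }
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Element inference for PDB atom names

## Fallback when the PDB element column (77-78) is blank: strip digits,
## prefer the 2-letter symbol unless the atom sits in a standard amino
## acid, where names like "HG" (gamma hydrogen) must resolve to H.
.infer_element <- function(atom_name, residue_name) {
  name <- gsub("[0-9'\"*]", "", trimws(atom_name))
  if (!nzchar(name)) stop("cannot infer element from atom name '", atom_name, "'")
  two <- .normalize_element(substr(name, 1, 2))
  one <- .normalize_element(substr(name, 1, 1))
  in_aa <- toupper(residue_name) %in% .standard_aa
  if (nchar(name) >= 2L && two %in% .known_elements && !(in_aa && one %in% .known_elements)) {
    return(two)
  }
  if (one %in% .known_elements) return(one)
  if (two %in% .known_elements) return(two)
  stop("cannot infer element for atom '", atom_name, "' in residue '",
       residue_name, "'")
}

.elements_from_pdb_atom <- function(atom) {
  ele <- if (!is.null(atom$elesy)) .normalize_element(atom$elesy) else rep("", nrow(atom))
  blank <- !(ele %in% .known_elements)
  if (any(blank)) {
    ele[blank] <- mapply(.infer_element, atom$elety[blank], atom$resid[blank],
                         USE.NAMES = FALSE)
  }
  ele
}

## Warn (once per frame) when an intra-molecular nearest-neighbour distance
## exceeds 5 A -- the symptom of a frame that was not made whole before
## export.  The reader never re-images.
.check_whole_molecules <- function(frame, max_bond = 5) {
  atoms <- frame$atoms
  for (m in unique(atoms$mol_id)) {
    idx <- which(atoms$mol_id == m)
    if (length(idx) < 2L || length(idx) > 400L) next
    d <- as.matrix(stats::dist(frame$coords[idx, , drop = FALSE]))
    diag(d) <- Inf
    if (any(apply(d, 1, min) > max_bond)) {
      warning("frame ", frame$frame_index, ": molecule ", m,
              " has an atom > ", max_bond,
              " A from its nearest intramolecular neighbour; ",
              "was the trajectory made PBC-whole before export?")
      return(invisible(FALSE))
    }
  }
  invisible(TRUE)
}

.frame_from_bio3d <- function(pdb, xyz_row, frame_index, time_ps) {
  atom <- pdb$atom
  coords <- matrix(xyz_row, ncol = 3, byrow = TRUE)
  atoms <- data.frame(
    serial = seq_len(nrow(atom)),
    element = .elements_from_pdb_atom(atom),
    atom_name = trimws(atom$elety),
    residue_name = trimws(atom$resid),
    residue_id = as.integer(atom$resno),
    stringsAsFactors = FALSE
  )
  structure_frame(atoms, coords, time_ps = time_ps, frame_index = frame_index)
}

#' Read a multi-frame structure into a trajectory
#'
#' Accepts (a) a PDB file, possibly with MODEL/ENDMDL multi-frame records,
#' (b) a directory of single-frame PDB files taken in lexicographic order,
#' or (c) a multi-frame XYZ file.  Elements come from the PDB element
#' column when present and are otherwise inferred from the atom name.
#' Frame times are `frame_index * time_per_frame` since exported PDBs
#' rarely carry usable time stamps.
#'
#' @param path File or directory.
#' @param time_per_frame Picoseconds between consecutive frames (default 1).
#' @param check_whole Validate that molecules look PBC-whole (warning only).
#' @return A [trajectory()].
#' @export
read_structure_frames <- function(path, time_per_frame = 1, check_whole = TRUE) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (length(files) == 0L) stop("no .pdb files in directory ", path)
    frames <- vector("list", length(files))
    counts <- integer(length(files))
    for (i in seq_along(files)) {
      pdb <- bio3d::read.pdb(files[i], multi = FALSE, verbose = FALSE)
      frames[[i]] <- .frame_from_bio3d(pdb, pdb$xyz[1L, ], i - 1L,
                                       (i - 1L) * time_per_frame)
      counts[i] <- n_atoms(frames[[i]])
    }
    if (length(unique(counts)) != 1L) {
      off <- which(counts != counts[1L])
      stop("inconsistent atom counts across frames; offending file(s): ",
           paste(basename(files[off]), collapse = ", "))
    }
  } else if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    frames <- .read_xyz_frames(path, time_per_frame)
  } else {
    if (!file.exists(path)) stop("structure file not found: ", path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    nf <- nrow(pdb$xyz)
    frames <- lapply(seq_len(nf), function(i) {
      .frame_from_bio3d(pdb, pdb$xyz[i, ], i - 1L, (i - 1L) * time_per_frame)
    })
  }
  if (check_whole) .check_whole_molecules(frames[[1L]])
  trajectory(frames, source = path)
}

.read_xyz_frames <- function(path, time_per_frame = 1) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("bad atom count at line ", i, " of ", path)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame at line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(block), "\\s+")
    el <- vapply(tok, `[[`, "", 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    atoms <- data.frame(
      serial = seq_len(n), element = el, atom_name = el,
      residue_name = "MOL", residue_id = 1L, stringsAsFactors = FALSE
    )
    frames[[length(frames) + 1L]] <-
      structure_frame(atoms, xyz, time_ps = fidx * time_per_frame,
                      frame_index = fidx)
    fidx <- fidx + 1L
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no frames found in ", path)
  frames
}

## ---------------------------------------------------------------------------
## Component extraction

#' Extract the union of named index groups from a frame
#'
#' Atoms are returned in ascending serial order, never duplicated; the
#' protein-ligand component PL is simply `names = c("P", "L")`.  Indices in
#' the selection refer to atom serials, so extraction still works on frames
#' whose atom set was reduced (solvent shell, ion stripping) as long as
#' serials were preserved.
#'
#' @param frame A [structure_frame()].
#' @param selection A `group_selection` from [read_ndx()].
#' @param names Character vector of group names to take the union of.
#' @param label Component tag carried on the subset (default: names pasted).
#' @return Object of class `atom_subset` with fields `elements`, `coords`,
#'   `label`, and the originating serials as `serials`.
#' @export
extract_group <- function(frame, selection, names, label = NULL) {
  stopifnot(inherits(frame, "structure_frame"))
  missing_groups <- setdiff(names, base::names(selection))
  if (length(missing_groups) > 0L) {
    stop("group(s) not in selection: ", paste(missing_groups, collapse = ", "))
  }
  idx <- sort(unique(unlist(selection[names], use.names = FALSE)))
  pos <- match(idx, frame$atoms$serial)
  if (anyNA(pos)) {
    bad <- idx[is.na(pos)][1L]
    gname <- names[vapply(names, function(nm) bad %in% selection[[nm]], TRUE)][1L]
    stop("index ", bad, " of group '", gname, "' is not present in the frame")
  }
  if (is.null(label)) label <- paste(names, collapse = "")
  atom_subset(frame$atoms$element[pos],
              frame$coords[pos, , drop = FALSE],
              label = label, serials = idx)
}

#' Construct an atom subset
#'
#' @param elements Character vector of chemical symbols.
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param label Component tag (PL, P, L, LS, S, or custom).
#' @param serials Optional originating atom serials.
#' @return Object of class `atom_subset`.
#' @export
atom_subset <- function(elements, coords, label = "custom", serials = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  elements <- .normalize_element(elements)
  if (length(elements) != nrow(coords)) {
    stop("elements and coords disagree in length")
  }
  structure(list(elements = elements, coords = coords, label = label,
                 serials = serials),
            class = "atom_subset")
}

#' @export
print.atom_subset <- function(x, ...) {
  cat("<atom_subset> '", x$label, "': ", length(x$elements), " atoms\n", sep = "")
  invisible(x)
}

#' Write an atom subset as a standard XYZ file
#'
#' The comment line carries the component label and, when supplied, the
#' frame index, so downstream calculators can trace every geometry back to
#' its snapshot.
#'
#' @param subset An [atom_subset()].
#' @param path Output path.
#' @param frame_index Optional frame index for the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(subset, path, frame_index = NULL) {
  stopifnot(inherits(subset, "atom_subset"))
  n <- length(subset$elements)
  if (n == 0L) stop("refusing to write an empty subset")
  comment <- paste0("label=", subset$label)
  if (!is.null(frame_index)) comment <- paste0(comment, " frame=", frame_index)
  body <- sprintf("%-2s %14.6f %14.6f %14.6f", subset$elements,
                  subset$coords[, 1], subset$coords[, 2], subset$coords[, 3])
  writeLines(c(as.character(n), comment, body), path)
  invisible(path)
}

#' Read a (single- or multi-frame) XYZ file into atom subsets
#'
#' @param path Path to an XYZ file.
#' @return List of [atom_subset()] objects, labels recovered from the
#'   comment line when present.
#' @export
read_xyz <- function(path) {
  frames <- .read_xyz_frames(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  for (f in frames) {
    n <- n_atoms(f)
    comment <- lines[i + 1L]
    label <- sub(".*label=(\\S+).*", "\\1", comment)
    if (identical(label, comment)) label <- "custom"
    out[[length(out) + 1L]] <- atom_subset(f$atoms$element, f$coords, label)
    i <- i + 2L + n
  }
  out
}
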