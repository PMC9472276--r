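## Per-frame interaction energies, ensemble statistics and convergence
## analysis.  The central identity is
##   dE_int = E(A u B) - E(A) - E(B)
## evaluated with three single-point calculations per frame: the huge
## absolute energies (hundreds of thousands of eV for a solvated complex)
## are a bias that cancels in the subtraction, leaving an interaction of a
## few eV.

#' Interaction energy from three component energies
#'
#' @param e_ab Energy of the combined system A u B (eV).
#' @param e_a,e_b Energies of the isolated components (eV).
#' @return `e_ab - e_a - e_b`, in eV; negative means attraction.
#' @export
interaction_energy <- function(e_ab, e_a, e_b) {
  stopifnot(is.finite(e_ab), is.finite(e_a), is.finite(e_b))
  e_ab - e_a - e_b
}

#' Interaction energy between two index groups in one frame
#'
#' Extracts A, B and their union from the frame and combines three
#' single-point evaluations.  For a pairwise backend (mock, dispersion)
#' the intra-group terms cancel exactly and the result equals the
#' cross-group pair sum.
#'
#' @param spec A [calculator_spec()].
#' @param frame A [structure_frame()].
#' @param selection A `group_selection`.
#' @param group_a,group_b Group names; must be disjoint.
#' @return Interaction energy in eV, with the three component energies
#'   attached as attribute `"components"`.
#' @export
frame_interaction <- function(spec, frame, selection, group_a, group_b) {
  ia <- selection[[group_a]]
  ib <- selection[[group_b]]
  if (is.null(ia)) stop("group '", group_a, "' not in selection")
  if (is.null(ib)) stop("group '", group_b, "' not in selection")
  overlap <- intersect(ia, ib)
  if (length(overlap) > 0L) {
    stop("groups '", group_a, "' and '", group_b, "' overlap (e.g. index ",
         overlap[1L], ")")
  }
  sub_a <- extract_group(frame, selection, group_a, label = group_a)
  sub_b <- extract_group(frame, selection, group_b, label = group_b)
  for (nm in c(group_a, group_b)) {
    bad <- check_supported(spec, if (nm == group_a) sub_a else sub_b)
    if (length(bad) > 0L) {
      stop("group '", nm, "' contains element(s) unsupported by backend '",
           spec$backend, "': ", paste(bad, collapse = ", "))
    }
  }
  sub_ab <- extract_group(frame, selection, c(group_a, group_b),
                          label = paste0(group_a, group_b))
  e_ab <- single_point_energy(spec, sub_ab, frame$frame_index)$value
  e_a <- single_point_energy(spec, sub_a, frame$frame_index)$value
  e_b <- single_point_energy(spec, sub_b, frame$frame_index)$value
  structure(interaction_energy(e_ab, e_a, e_b),
            components = c(e_ab = e_ab, e_a = e_a, e_b = e_b))
}

#' Construct an interaction-energy series
#'
#' @param frame_index Strictly increasing integer frame indices.
#' @param value Interaction energies (eV).
#' @param pair Length-2 character vector of component tags, e.g. c("L","P").
#' @param backend Backend tag.
#' @return Object of class `interaction_series`.
#' @export
interaction_series <- function(frame_index, value, pair, backend) {
  stopifnot(length(frame_index) == length(value), length(value) >= 1L)
  if (is.unsorted(frame_index, strictly = TRUE)) {
    stop("frame indices must be strictly increasing")
  }
  structure(
    list(values = data.frame(frame_index = as.integer(frame_index),
                             value = as.numeric(value)),
         pair = pair, backend = backend),
    class = "interaction_series"
  )
}

#' @export
print.interaction_series <- function(x, ...) {
  cat(sprintf("<interaction_series> %s-%s [%s], %d frame(s)\n",
              x$pair[1], x$pair[2], x$backend, nrow(x$values)))
  invisible(x)
}

#' Ensemble average of an interaction series
#'
#' The uncertainty is the standard error of the mean by default (the
#' plain iid estimator, no autocorrelation correction); pass
#' `error = "sd"` for the sample standard deviation instead.
#'
#' @param series An [interaction_series()] or bare numeric vector.
#' @param error `"sem"` (default) or `"sd"`.
#' @return Object of class `ensemble_stat` with fields `mean` (eV),
#'   `sem` (eV, meaning of the chosen estimator), `n_frames`.
#' @export
ensemble_average <- function(series, error = c("sem", "sd")) {
  error <- match.arg(error)
  v <- if (inherits(series, "interaction_series")) series$values$value else as.numeric(series)
  if (length(v) == 0L) stop("cannot average an empty series")
  s <- if (length(v) == 1L) 0 else stats::sd(v)
  if (error == "sem") s <- s / sqrt(length(v))
  ensemble_stat(mean(v), s, length(v))
}

#' Construct an ensemble statistic
#'
#' @param mean Mean energy (eV unless stated otherwise by the caller).
#' @param sem Non-negative uncertainty.
#' @param n_frames Number of frames averaged.
#' @return Object of class `ensemble_stat`.
#' @export
ensemble_stat <- function(mean, sem = 0, n_frames = 1L) {
  stopifnot(is.finite(mean), sem >= 0, n_frames >= 1L)
  structure(list(mean = mean, sem = sem, n_frames = as.integer(n_frames)),
            class = "ensemble_stat")
}

#' @export
print.ensemble_stat <- function(x, ...) {
  cat(sprintf("<ensemble_stat> %.4f +/- %.4f (n = %d)\n",
              x$mean, x$sem, x$n_frames))
  invisible(x)
}

#' Convergence of the ensemble mean with the number of frames
#'
#' For each requested frame count `n`, frames are subsampled by an even
#' stride over the reference window — the first frame of each of `n`
#' equal intervals, positions `floor(k * N / n) + 1` for k = 0..n-1 —
#' and the absolute deviation of that mean from the full reference mean
#' is reported.  Deterministic: no RNG is involved.
#'
#' @param series An [interaction_series()].
#' @param frame_counts Integer vector of subsample sizes.
#' @param reference_count Size of the reference window (defaults to the
#'   full series length).
#' @return Data frame with columns `n` and `abs_dev` (eV).
#' @export
convergence_profile <- function(series, frame_counts,
                                reference_count = NULL) {
  stopifnot(inherits(series, "interaction_series"))
  v <- series$values$value
  if (is.null(reference_count)) reference_count <- length(v)
  if (reference_count > length(v)) {
    stop("reference_count exceeds the series length")
  }
  if (any(frame_counts <= 0)) stop("frame counts must be positive")
  if (any(frame_counts > reference_count)) {
    stop("frame counts must not exceed reference_count")
  }
  ref_mean <- mean(v[seq_len(reference_count)])
  dev <- vapply(frame_counts, function(n) {
    idx <- floor((seq_len(n) - 1L) * reference_count / n) + 1L
    abs(mean(v[idx]) - ref_mean)
  }, numeric(1))
  data.frame(n = as.integer(frame_counts), abs_dev = dev)
}

## ---------------------------------------------------------------------------
## Per-frame energy data files

#' Write a per-frame interaction energy table
#'
#' One row per frame with the three component energies and the
#' interaction energy, as tab-separated text.
#'
#' @param df Data frame with columns `frame_index`, `E_AB`, `E_A`, `E_B`,
#'   `dE_int`, `backend`, `pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(df, path) {
  needed <- c("frame_index", "E_AB", "E_A", "E_B", "dE_int", "backend", "pair")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("energy table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  utils::write.table(df[needed], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-frame interaction energy table written by
#' [write_energy_table()]
#'
#' @param path Path to the tab-separated table.
#' @return Data frame.
#' @export
read_energy_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
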