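## End-to-end workflows: frames + index file in, per-frame energy tables
## and a binding free energy report out.
##
## Pipeline (bound state): read frames -> strip backend-unsupported ions
## -> optionally reduce the solvation shell -> extract PL/P/L -> per-frame
## interaction energies per backend -> ensemble statistics -> chosen LIE
## estimator.  All intermediates are written as delimited text plus a JSON
## run summary, so a run can be resumed from the per-frame files.

#' Build a workflow configuration
#'
#' @param trajectory A [trajectory()] or a path accepted by
#'   [read_structure_frames()].
#' @param ndx A `group_selection` or path to a Gromacs index file.
#' @param protein,ligand,solvent Group names (solvent NULL to skip L-S
#'   terms).
#' @param backends List of [calculator_spec()] objects.
#' @param frame_stride Keep every `frame_stride`-th frame.
#' @param max_frames Optional cap on the number of frames used.
#' @param cutoff Optional solvation-shell cutoff in Angstrom; NULL keeps
#'   the full solvent.
#' @param equation LIE estimator tag: `"eq4"`, `"eq5"`, `"eq6"`, `"eq7"`.
#' @param coefficients A [lie_coefficients()] used by the estimator.
#' @param ls_terms Optional result of [run_free_ligand_workflow()],
#'   required by eq6/eq7.
#' @param seed Integer seed recorded in the summary (the mock and
#'   dispersion backends are deterministic; the seed exists so stochastic
#'   evaluators stay reproducible).
#' @param outdir Output directory for energy tables and the summary.
#' @return A `run_config` list.
#' @export
run_config <- function(trajectory, ndx, protein = "P", ligand = "L",
                       solvent = NULL,
                       backends = list(calculator_spec("mock")),
                       frame_stride = 1L, max_frames = NULL, cutoff = NULL,
                       equation = c("eq4", "eq5", "eq6", "eq7"),
                       coefficients = lie_coefficients(beta = 1, gamma = 0),
                       ls_terms = NULL, seed = 1L, outdir = tempfile("lie_run_")) {
  equation <- match.arg(equation)
  structure(list(trajectory = trajectory, ndx = ndx, protein = protein,
                 ligand = ligand, solvent = solvent, backends = backends,
                 frame_stride = as.integer(frame_stride),
                 max_frames = max_frames, cutoff = cutoff,
                 equation = equation, coefficients = coefficients,
                 ls_terms = ls_terms, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

.load_traj <- function(x) {
  if (inherits(x, "trajectory")) x else read_structure_frames(x)
}

.load_ndx <- function(x) {
  if (inherits(x, "group_selection")) x else read_ndx(x)
}

.select_frames <- function(traj, stride, max_frames) {
  idx <- seq(1L, length(traj$frames), by = stride)
  if (!is.null(max_frames)) idx <- idx[seq_len(min(length(idx), max_frames))]
  traj$frames[idx]
}

.backend_slot <- function(backend) {
  if (backend == "dispersion") "d3" else "nnp"
}

.stage <- function(name, frame_index = NULL, expr) {
  tryCatch(expr, error = function(e) {
    at <- if (is.null(frame_index)) "" else paste0(", frame ", frame_index)
    stop("workflow stage '", name, "'", at, ": ", conditionMessage(e),
         call. = FALSE)
  })
}

## per-frame interaction table for one backend and one group pair
.pair_energy_table <- function(spec, frames, selection, group_a, group_b,
                               cutoff, solute_names, pair_tag) {
  rows <- vector("list", length(frames))
  report <- NULL
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    fr <- .stage("strip_ions", fr$frame_index,
                 strip_unsupported(fr, spec, selection = selection))
    frame_sel <- selection
    if (!is.null(cutoff)) {
      red <- .stage("reduce_solvation", fr$frame_index,
                    reduce_solvation(fr, selection, solute_names, cutoff))
      fr <- red$frame
      frame_sel <- red$selection
      if (is.null(report)) report <- red$report
    }
    de <- .stage("interaction", fr$frame_index,
                 frame_interaction(spec, fr, frame_sel, group_a, group_b))
    comp <- attr(de, "components")
    rows[[i]] <- data.frame(frame_index = fr$frame_index,
                            E_AB = comp[["e_ab"]], E_A = comp[["e_a"]],
                            E_B = comp[["e_b"]], dE_int = as.numeric(de),
                            backend = spec$backend, pair = pair_tag,
                            stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), reduction = report)
}

#' Run the bound-state (PLS) workflow
#'
#' Computes per-frame ligand-protein (and, when a solvent group is
#' configured, ligand-solvent) interaction energies for every backend,
#' writes one energy table per backend and pair under `outdir`, and
#' combines the ensemble averages into the configured LIE estimator.
#' eq6/eq7 additionally require `ls_terms` from
#' [run_free_ligand_workflow()].
#'
#' @param config A [run_config()].
#' @return List of class `lie_run` with `series` (interaction series per
#'   backend/pair), `stats` (ensemble stats), `inputs` ([lie_inputs()]),
#'   `dg` (`dg_estimate`), `tables` (paths), `reduction` (solvent report
#'   or NULL) and `summary_path`.
#' @export
run_bound_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(config$outdir, "MANIFEST")
  writeLines("INCOMPLETE", manifest)

  traj <- .stage("read_frames", NULL, .load_traj(config$trajectory))
  selection <- .stage("read_ndx", NULL, .load_ndx(config$ndx))
  frames <- .select_frames(traj, config$frame_stride, config$max_frames)
  solute_names <- c(config$protein, config$ligand)
  need_ls <- !is.null(config$solvent) &&
    config$equation %in% c("eq6", "eq7")

  series <- list()
  stats <- list()
  tables <- character(0)
  reduction <- NULL
  terms <- list()
  for (spec in config$backends) {
    slot <- .backend_slot(spec$backend)
    lp <- .pair_energy_table(spec, frames, selection, config$ligand,
                             config$protein, config$cutoff, solute_names,
                             "L-P")
    if (is.null(reduction)) reduction <- lp$reduction
    key <- paste0(spec$backend, ".L-P")
    series[[key]] <- interaction_series(lp$table$frame_index, lp$table$dE_int,
                                        c(config$ligand, config$protein),
                                        spec$backend)
    stats[[key]] <- ensemble_average(series[[key]])
    terms[[paste0("dE_", slot, "_LP")]] <- stats[[key]]
    path <- file.path(config$outdir,
                      sprintf("energies_%s_LP.tsv", spec$backend))
    write_energy_table(lp$table, path)
    tables <- c(tables, path)

    if (need_ls) {
      if (is.null(selection[[config$solvent]])) {
        stop("equation ", config$equation, " needs solvent group '",
             config$solvent, "', which is absent from the index file")
      }
      ls <- .pair_energy_table(spec, frames, selection, config$ligand,
                               config$solvent, config$cutoff, solute_names,
                               "L-S")
      key <- paste0(spec$backend, ".L-S")
      series[[key]] <- interaction_series(ls$table$frame_index,
                                          ls$table$dE_int,
                                          c(config$ligand, config$solvent),
                                          spec$backend)
      stats[[key]] <- ensemble_average(series[[key]])
      terms[[paste0("dE_", slot, "_LS_bound")]] <- stats[[key]]
      path <- file.path(config$outdir,
                        sprintf("energies_%s_LS.tsv", spec$backend))
      write_energy_table(ls$table, path)
      tables <- c(tables, path)
    }
  }

  if (config$equation %in% c("eq6", "eq7")) {
    if (is.null(config$ls_terms)) {
      stop("equation ", config$equation, " needs free-ligand (LS) terms; ",
           "run run_free_ligand_workflow() and pass its result as ls_terms")
    }
    terms <- c(terms, config$ls_terms$terms)
  }

  inputs <- do.call(lie_inputs, terms)
  dg <- .stage("estimate", NULL, switch(config$equation,
    eq4 = dg_eq4(inputs, config$coefficients),
    eq5 = dg_eq5(inputs, config$coefficients),
    eq6 = dg_eq6(inputs, config$coefficients),
    eq7 = dg_eq7(inputs, config$coefficients)
  ))

  summary_path <- file.path(config$outdir, "run_summary.json")
  summary <- list(
    package = as.character(utils::packageVersion("nnlie")),
    equation = config$equation,
    backends = vapply(config$backends, `[[`, "", "backend"),
    groups = list(protein = config$protein, ligand = config$ligand,
                  solvent = config$solvent),
    n_frames = length(frames),
    cutoff = config$cutoff,
    seed = config$seed,
    solvent_reduction = if (is.null(reduction)) NULL else unclass(reduction),
    ensemble = lapply(stats, unclass),
    dg_kcalmol = dg$value,
    dg_uncertainty = dg$se,
    energy_tables = basename(tables)
  )
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  writeLines("COMPLETE", manifest)
  structure(list(series = series, stats = stats, inputs = inputs, dg = dg,
                 tables = tables, reduction = reduction,
                 summary_path = summary_path),
            class = "lie_run")
}

#' @export
print.lie_run <- function(x, ...) {
  cat("<lie_run>\n")
  print(x$dg)
  invisible(x)
}

#' Run the free-ligand (LS) workflow
#'
#' Computes the ligand-solvent ensemble terms from a free-ligand-in-water
#' trajectory for every backend, for combination with a bound-state run
#' in the solvent-included estimators.
#'
#' @param config A [run_config()]; `solvent` must name a group present in
#'   the index file.
#' @return List of class `ls_run` with `terms` (named [ensemble_stat()]s:
#'   `dE_nnp_LS_free` and/or `dE_d3_LS_free`), `series`, and `tables`.
#' @export
run_free_ligand_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$solvent)) {
    stop("free-ligand workflow needs a solvent group name")
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  traj <- .stage("read_frames", NULL, .load_traj(config$trajectory))
  selection <- .stage("read_ndx", NULL, .load_ndx(config$ndx))
  if (is.null(selection[[config$solvent]]) ||
      length(selection[[config$solvent]]) == 0L) {
    stop("solvent group '", config$solvent,
         "' is missing or empty in the index file")
  }
  frames <- .select_frames(traj, config$frame_stride, config$max_frames)

  terms <- list()
  series <- list()
  tables <- character(0)
  for (spec in config$backends) {
    slot <- .backend_slot(spec$backend)
    ls <- .pair_energy_table(spec, frames, selection, config$ligand,
                             config$solvent, config$cutoff, config$ligand,
                             "L-S")
    key <- paste0(spec$backend, ".L-S")
    series[[key]] <- interaction_series(ls$table$frame_index, ls$table$dE_int,
                                        c(config$ligand, config$solvent),
                                        spec$backend)
    terms[[paste0("dE_", slot, "_LS_free")]] <- ensemble_average(series[[key]])
    path <- file.path(config$outdir,
                      sprintf("energies_%s_LS_free.tsv", spec$backend))
    write_energy_table(ls$table, path)
    tables <- c(tables, path)
  }
  structure(list(terms = terms, series = series, tables = tables),
            class = "ls_run")
}

#' Rebuild an ensemble statistic from a written energy table
#'
#' Lets a run be resumed from its per-frame files: the statistic equals
#' the one computed in the original run.
#'
#' @param path Path to a table written by [write_energy_table()].
#' @param error Passed to [ensemble_average()].
#' @return An [ensemble_stat()] of the `dE_int` column.
#' @export
ensemble_from_table <- function(path, error = "sem") {
  df <- read_energy_table(path)
  ensemble_average(interaction_series(df$frame_index, df$dE_int,
                                      strsplit(df$pair[1L], "-")[[1L]],
                                      df$backend[1L]),
                   error = error)
}
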