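## Uniform single-point-energy contract over three backends:
##   "ani2x"      -- neural-network potential evaluated through a
##                   user-supplied hook (the model weights are an external
##                   artifact; the package owns the contract, not the net),
##   "dispersion" -- pairwise D3-style dispersion correction (see
##                   dispersion.R),
##   "mock"       -- deterministic Lennard-Jones + Coulomb pair potential
##                   used as an offline oracle in tests and examples.
## All backends return energies in eV for isolated (non-periodic) clusters.

.ani2x_elements <- c("H", "C", "N", "O", "F", "S", "Cl")

## Mock per-element parameters: well depth (eV), LJ diameter (A), charge (e).
## Organic elements are neutral so long-range behaviour is pure r^-6 decay;
## alkali ions carry their formal charge so the ion-stripping path is
## exercisable.  Values are plausible, not fitted to anything.
.mock_default_table <- data.frame(
  element = c("H",    "C",    "N",    "O",    "F",    "S",    "Cl",   "Na",  "K"),
  eps     = c(0.0020, 0.0040, 0.0070, 0.0080, 0.0060, 0.0110, 0.0120, 0.0050, 0.0040),
  sigma   = c(2.50,   3.40,   3.30,   3.10,   3.00,   3.60,   3.50,   2.60,  3.30),
  q       = c(0,      0,      0,      0,      0,      0,      0,      1,     1),
  stringsAsFactors = FALSE
)

#' Describe a single-point-energy backend
#'
#' @param backend One of `"mock"`, `"dispersion"`, `"ani2x"`.
#' @param params Backend parameters:
#'   \describe{
#'     \item{mock}{`table`: data frame with columns element/eps/sigma/q
#'       overriding the built-in pair-potential parameters.}
#'     \item{dispersion}{`damping`: `"bj"` (Becke-Johnson, default) or
#'       `"zero"`; optional numeric overrides `s6`, `s8`, `a1`, `a2`,
#'       `sr6`, `sr8`.}
#'     \item{ani2x}{`energy_fn`: function(elements, coords) returning eV,
#'       wrapping the caller's NNP evaluator; optional `model_version`
#'       string recorded in run summaries.}
#'   }
#' @return Object of class `calculator_spec` with a `supported_elements`
#'   field.
#' @export
calculator_spec <- function(backend = c("mock", "dispersion", "ani2x"),
                            params = list()) {
  backend <- match.arg(backend)
  supported <- switch(backend,
    mock = {
      tab <- params$table
      if (is.null(tab)) tab <- .mock_default_table
      tab$element <- .normalize_element(tab$element)
      params$table <- tab
      tab$element
    },
    dispersion = .dispersion_elements(),
    ani2x = .ani2x_elements
  )
  structure(list(backend = backend, params = params,
                 supported_elements = supported),
            class = "calculator_spec")
}

#' @export
print.calculator_spec <- function(x, ...) {
  cat("<calculator_spec> backend:", x$backend, "\n  supports:",
      paste(x$supported_elements, collapse = " "), "\n")
  invisible(x)
}

#' List elements of a subset a backend cannot handle
#'
#' Pure query: the ANI-2x element set is H/C/N/O/F/S/Cl, so e.g. sodium
#' counter-ions must be stripped (see [strip_unsupported()]) before the
#' NNP sees a frame.
#'
#' @param spec A [calculator_spec()].
#' @param subset An [atom_subset()].
#' @return Character vector of unsupported element symbols (possibly empty).
#' @export
check_supported <- function(spec, subset) {
  stopifnot(inherits(spec, "calculator_spec"), inherits(subset, "atom_subset"))
  sort(setdiff(unique(subset$elements), spec$supported_elements))
}

#' Mock pair potential: Lennard-Jones plus Coulomb
#'
#' u(r) = 4 eps_ij \[(sigma_ij/r)^12 - (sigma_ij/r)^6\] + k_e q_i q_j / r
#' with Lorentz-Berthelot combination (arithmetic sigma, geometric eps)
#' and k_e = 14.399645 eV A e^-2.  Deterministic closed form, used as the
#' test oracle standing in for expensive backends.
#'
#' @param el_i,el_j Element symbols.
#' @param r Distance (Angstrom), must be > 0.
#' @param table Parameter table (defaults to the built-in one).
#' @return Pair energy in eV.
#' @export
mock_pair_potential <- function(el_i, el_j, r, table = NULL) {
  if (any(r <= 0)) stop("pair distance must be positive")
  if (is.null(table)) table <- .mock_default_table
  i <- match(.normalize_element(el_i), table$element)
  j <- match(.normalize_element(el_j), table$element)
  if (anyNA(i) || anyNA(j)) {
    stop("element(s) missing from mock table: ",
         paste(unique(c(el_i[is.na(i)], el_j[is.na(j)])), collapse = ", "))
  }
  sig <- (table$sigma[i] + table$sigma[j]) / 2
  eps <- sqrt(table$eps[i] * table$eps[j])
  sr6 <- (sig / r)^6
  4 * eps * (sr6^2 - sr6) + lie_constants[["coulomb_ke"]] * table$q[i] * table$q[j] / r
}

## Total mock energy: sum over unique pairs, vectorised over the distance
## matrix.  Exact (no cutoff), matching the brute-force double loop.
.mock_total_energy <- function(subset, table) {
  n <- length(subset$elements)
  if (n < 2L) return(0)
  d <- as.matrix(stats::dist(subset$coords))
  if (any(d[upper.tri(d)] <= 0)) stop("coincident atoms in subset")
  i <- match(subset$elements, table$element)
  if (anyNA(i)) {
    stop("unsupported element(s): ",
         paste(unique(subset$elements[is.na(i)]), collapse = ", "))
  }
  sig <- outer(table$sigma[i], table$sigma[i], `+`) / 2
  eps <- sqrt(outer(table$eps[i], table$eps[i]))
  qq <- outer(table$q[i], table$q[i])
  ut <- upper.tri(d)
  sr6 <- (sig[ut] / d[ut])^6
  sum(4 * eps[ut] * (sr6^2 - sr6) +
      lie_constants[["coulomb_ke"]] * qq[ut] / d[ut])
}

#' Single-point energy of an atom subset
#'
#' Evaluates the potential energy of an isolated cluster with the chosen
#' backend.  Deterministic for the mock and dispersion backends; the
#' ani2x hook is as reproducible as the caller's evaluator.
#'
#' @param spec A [calculator_spec()].
#' @param subset An [atom_subset()].
#' @param frame_index Frame index recorded on the result.
#' @return Object of class `energy_value` with fields `value` (eV),
#'   `backend`, `component` (the subset label) and `frame_index`.
#' @export
single_point_energy <- function(spec, subset, frame_index = NA_integer_) {
  stopifnot(inherits(spec, "calculator_spec"), inherits(subset, "atom_subset"))
  if (length(subset$elements) == 0L) stop("cannot evaluate an empty subset")
  unsupported <- check_supported(spec, subset)
  if (length(unsupported) > 0L) {
    stop("backend '", spec$backend, "' does not support element(s): ",
         paste(unsupported, collapse = ", "))
  }
  value <- switch(spec$backend,
    mock = .mock_total_energy(subset, spec$params$table),
    dispersion = .dispersion_energy(subset, spec$params),
    ani2x = {
      fn <- spec$params$energy_fn
      if (is.null(fn)) {
        stop("the ani2x backend needs params$energy_fn, a function(elements, ",
             "coords) wrapping your NNP evaluator (e.g. an external ",
             "TorchANI service); no evaluator is bundled with the package")
      }
      as.numeric(fn(subset$elements, subset$coords))
    }
  )
  if (!is.finite(value)) stop("backend returned a non-finite energy")
  structure(list(value = value, backend = spec$backend,
                 component = subset$label,
                 frame_index = as.integer(frame_index)),
            class = "energy_value")
}

#' @export
print.energy_value <- function(x, ...) {
  cat(sprintf("<energy_value> %s/%s frame %s: %.6f eV\n",
              x$backend, x$component,
              ifelse(is.na(x$frame_index), "-", x$frame_index), x$value))
  invisible(x)
}

#' Evaluate single-point energies over an ordered list of subsets
#'
#' Semantically identical to mapping [single_point_energy()]; `batch_size`
#' only controls how work is chunked and never changes results or order.
#'
#' @param spec A [calculator_spec()].
#' @param subsets List of [atom_subset()] objects.
#' @param batch_size Positive chunk size.
#' @param frame_indices Optional integer vector recorded on the results.
#' @return Data frame with columns `frame_index`, `component`, `backend`,
#'   `value` (eV), one row per subset, in input order.
#' @export
batch_energies <- function(spec, subsets, batch_size = 8L,
                           frame_indices = NULL) {
  stopifnot(batch_size >= 1L)
  if (length(subsets) == 0L) {
    return(data.frame(frame_index = integer(0), component = character(0),
                      backend = character(0), value = numeric(0)))
  }
  if (is.null(frame_indices)) frame_indices <- seq_along(subsets) - 1L
  stopifnot(length(frame_indices) == length(subsets))
  out <- vector("list", length(subsets))
  starts <- seq(1L, length(subsets), by = batch_size)
  for (s in starts) {
    chunk <- s:min(s + batch_size - 1L, length(subsets))
    for (k in chunk) {
      ev <- tryCatch(
        single_point_energy(spec, subsets[[k]], frame_indices[k]),
        error = function(e) {
          stop("subset ", k, " (frame ", frame_indices[k], "): ",
               conditionMessage(e), call. = FALSE)
        }
      )
      out[[k]] <- data.frame(frame_index = ev$frame_index,
                             component = ev$component,
                             backend = ev$backend, value = ev$value,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
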