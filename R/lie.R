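## Binding free energy estimators in the linear interaction energy (LIE)
## formalism.
##
## Classical LIE writes the binding free energy as a linear combination of
## ensemble-averaged ligand-surroundings interaction energies,
##   dG = alpha * (<E_vdw^L-surr>_PLS - <E_vdw^L-S>_LS)
##      + beta  * (<E_el^L-surr>_PLS  - <E_el^L-S>_LS) + gamma,
## with empirical coefficients fitted to experiment.  The NNP variants
## replace the electrostatic term with neural-network-potential interaction
## energies and the van der Waals term with a D3-style dispersion energy:
##   solvent ignored:   dG = beta * <dE_nnp^L-P> + gamma
##                      dG = alpha * <dE_d3^L-P> + beta * <dE_nnp^L-P> + gamma
##   solvent included:  the L-P term is augmented with the bound-state L-S
##                      term minus the free-ligand L-S term, per backend.
## Ensemble terms are carried in eV and converted to kcal/mol before the
## coefficients are applied, so gamma is always kcal/mol.

#' LIE coefficients
#'
#' @param alpha Coefficient on the dispersion / van der Waals term
#'   (NA when the model has none).
#' @param beta Coefficient on the NNP / electrostatic term.
#' @param gamma Intercept, kcal/mol.
#' @param se_alpha,se_beta,se_gamma Standard errors (NA when user-supplied).
#' @param units_in Unit the x-terms were expressed in when the
#'   coefficients were determined (`"kcal/mol"` or `"eV"`).  Slope
#'   coefficients are not transferable across unit conventions, so this
#'   is recorded rather than assumed.
#' @return Object of class `lie_coefficients`.
#' @export
lie_coefficients <- function(alpha = NA_real_, beta, gamma,
                             se_alpha = NA_real_, se_beta = NA_real_,
                             se_gamma = NA_real_, units_in = "kcal/mol") {
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 se_alpha = se_alpha, se_beta = se_beta, se_gamma = se_gamma,
                 units_in = units_in),
            class = "lie_coefficients")
}

#' @export
print.lie_coefficients <- function(x, ...) {
  fmt <- function(v, s) {
    if (is.na(v)) return("-")
    if (is.na(s)) sprintf("%.5g", v) else sprintf("%.5g +/- %.3g", v, s)
  }
  cat("<lie_coefficients> alpha:", fmt(x$alpha, x$se_alpha),
      " beta:", fmt(x$beta, x$se_beta),
      " gamma:", fmt(x$gamma, x$se_gamma),
      " (x-terms in ", x$units_in, ")\n", sep = "")
  invisible(x)
}

#' Bundle ensemble-averaged terms for the LIE estimators
#'
#' Fields are [ensemble_stat()] objects (bare numbers are promoted with
#' zero uncertainty).  NNP/dispersion terms are in eV:
#' `dE_nnp_LP`, `dE_d3_LP` (ligand-protein, bound PLS ensemble),
#' `dE_nnp_LS_bound`, `dE_d3_LS_bound` (ligand-solvent, bound ensemble),
#' `dE_nnp_LS_free`, `dE_d3_LS_free` (ligand-solvent, free-ligand LS
#' ensemble).  Classical MM terms are in kcal/mol:
#' `dE_el_Lsurr`, `dE_vdw_Lsurr` (bound), `dE_el_LS_free`,
#' `dE_vdw_LS_free` (free ligand).
#'
#' @param ... Named terms.
#' @return Object of class `lie_inputs`.
#' @export
lie_inputs <- function(...) {
  terms <- list(...)
  if (length(terms) > 0L && is.null(names(terms))) stop("terms must be named")
  terms <- lapply(terms, .as_stat)
  structure(terms, class = "lie_inputs")
}

.as_stat <- function(x) {
  if (inherits(x, "ensemble_stat")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(ensemble_stat(x, 0, 1L))
  stop("terms must be ensemble_stat objects or single numbers")
}

.get_term <- function(inputs, name, hint = NULL) {
  t <- inputs[[name]]
  if (is.null(t)) {
    msg <- paste0("missing LIE input term '", name, "'")
    if (!is.null(hint)) msg <- paste0(msg, "; ", hint)
    stop(msg, call. = FALSE)
  }
  t
}

.dg_estimate <- function(value, se, equation) {
  structure(list(value = value, se = se, equation = equation,
                 units = "kcal/mol"),
            class = "dg_estimate")
}

#' @export
print.dg_estimate <- function(x, ...) {
  cat(sprintf("<dG %s> %.3f +/- %.3f kcal/mol\n", x$equation, x$value, x$se))
  invisible(x)
}

## linear combination of eV-unit ensemble terms; uncertainties first-order,
## summed in quadrature
.linear_dg <- function(groups, gamma, equation) {
  val <- gamma
  var <- 0
  k <- lie_constants[["kcalmol_per_ev"]]
  for (g in groups) {
    means <- vapply(g$terms, function(t) t$mean, numeric(1)) * k
    sems <- vapply(g$terms, function(t) t$sem, numeric(1)) * k
    val <- val + g$coef * sum(means * g$signs)
    var <- var + g$coef^2 * sum(sems^2)
  }
  .dg_estimate(val, sqrt(var), equation)
}

#' Binding free energy, solvent-ignored NNP form
#'
#' `dG = beta * <dE_nnp^L-P> + gamma`, with the ensemble mean converted
#' from eV to kcal/mol before scaling.
#'
#' @param inputs A [lie_inputs()] with `dE_nnp_LP`.
#' @param coeffs A [lie_coefficients()] with `beta` and `gamma`.
#' @return A `dg_estimate` (kcal/mol, first-order uncertainty).
#' @export
dg_eq4 <- function(inputs, coeffs) {
  t <- .get_term(inputs, "dE_nnp_LP")
  .linear_dg(list(list(coef = coeffs$beta, terms = list(t), signs = 1)),
             coeffs$gamma, "eq4")
}

#' Binding free energy, solvent-ignored NNP + dispersion form
#'
#' `dG = alpha * <dE_d3^L-P> + beta * <dE_nnp^L-P> + gamma`.
#'
#' @inheritParams dg_eq4
#' @return A `dg_estimate`.
#' @export
dg_eq5 <- function(inputs, coeffs) {
  if (is.na(coeffs$alpha)) stop("dg_eq5 needs a non-missing alpha")
  tn <- .get_term(inputs, "dE_nnp_LP")
  td <- .get_term(inputs, "dE_d3_LP")
  .linear_dg(list(
    list(coef = coeffs$alpha, terms = list(td), signs = 1),
    list(coef = coeffs$beta, terms = list(tn), signs = 1)
  ), coeffs$gamma, "eq5")
}

#' Binding free energy, solvent-included NNP form
#'
#' `dG = beta * (<dE_nnp^L-P>_PLS + <dE_nnp^L-S>_PLS - <E_nnp^L-S>_LS)
#'  + gamma`.  The last term comes from a separate free-ligand-in-water
#' run (see [run_free_ligand_workflow()]).
#'
#' @inheritParams dg_eq4
#' @return A `dg_estimate`.
#' @export
dg_eq6 <- function(inputs, coeffs) {
  hint <- "run the free-ligand (LS) workflow to obtain the ligand-solvent terms"
  tp <- .get_term(inputs, "dE_nnp_LP")
  tb <- .get_term(inputs, "dE_nnp_LS_bound", hint)
  tf <- .get_term(inputs, "dE_nnp_LS_free", hint)
  .linear_dg(list(
    list(coef = coeffs$beta, terms = list(tp, tb, tf), signs = c(1, 1, -1))
  ), coeffs$gamma, "eq6")
}

#' Binding free energy, solvent-included NNP + dispersion form
#'
#' Dispersion and NNP triples (bound L-P, bound L-S, minus free L-S) are
#' scaled by alpha and beta respectively.
#'
#' @inheritParams dg_eq4
#' @return A `dg_estimate`.
#' @export
dg_eq7 <- function(inputs, coeffs) {
  if (is.na(coeffs$alpha)) stop("dg_eq7 needs a non-missing alpha")
  hint <- "run the free-ligand (LS) workflow to obtain the ligand-solvent terms"
  np <- .get_term(inputs, "dE_nnp_LP")
  nb <- .get_term(inputs, "dE_nnp_LS_bound", hint)
  nf <- .get_term(inputs, "dE_nnp_LS_free", hint)
  dp <- .get_term(inputs, "dE_d3_LP")
  db <- .get_term(inputs, "dE_d3_LS_bound", hint)
  df <- .get_term(inputs, "dE_d3_LS_free", hint)
  .linear_dg(list(
    list(coef = coeffs$alpha, terms = list(dp, db, df), signs = c(1, 1, -1)),
    list(coef = coeffs$beta, terms = list(np, nb, nf), signs = c(1, 1, -1))
  ), coeffs$gamma, "eq7")
}

#' Binding free energy from classical MM interaction terms
#'
#' `dG = alpha * (<E_vdw^L-surr>_PLS - <E_vdw^L-S>_LS)
#'     + beta  * (<E_el^L-surr>_PLS  - <E_el^L-S>_LS) + gamma`,
#' with all terms already in kcal/mol.  The conventional default
#' coefficients are alpha = 0.181, beta = 0.5, gamma = 0.
#'
#' @param inputs A [lie_inputs()] with `dE_vdw_Lsurr`, `dE_vdw_LS_free`,
#'   `dE_el_Lsurr`, `dE_el_LS_free` (kcal/mol).
#' @param coeffs A [lie_coefficients()].
#' @return A `dg_estimate`.
#' @export
dg_mm_lie <- function(inputs,
                      coeffs = lie_coefficients(alpha = 0.181, beta = 0.5,
                                                gamma = 0)) {
  if (is.na(coeffs$alpha)) stop("dg_mm_lie needs a non-missing alpha")
  vb <- .get_term(inputs, "dE_vdw_Lsurr")
  vf <- .get_term(inputs, "dE_vdw_LS_free")
  eb <- .get_term(inputs, "dE_el_Lsurr")
  ef <- .get_term(inputs, "dE_el_LS_free")
  ## terms are already kcal/mol: bypass the eV conversion
  val <- coeffs$alpha * (vb$mean - vf$mean) +
    coeffs$beta * (eb$mean - ef$mean) + coeffs$gamma
  se <- sqrt(coeffs$alpha^2 * (vb$sem^2 + vf$sem^2) +
             coeffs$beta^2 * (eb$sem^2 + ef$sem^2))
  .dg_estimate(val, se, "mm_lie")
}

## ---------------------------------------------------------------------------
## Experimental reference values

#' An experimental affinity record
#'
#' @param complex_id Identifier (e.g. a PDB id).
#' @param ic50,ki Molar concentrations (optional, must be positive).
#' @param dg_exp Direct experimental binding free energy (kcal/mol,
#'   optional; takes precedence over the concentrations).
#' @return Object of class `experiment_record`.
#' @export
experiment_record <- function(complex_id, ic50 = NULL, ki = NULL,
                              dg_exp = NULL) {
  if (is.null(ic50) && is.null(ki) && is.null(dg_exp)) {
    stop("record '", complex_id, "' needs at least one of ic50, ki, dg_exp")
  }
  for (v in list(ic50, ki)) {
    if (!is.null(v) && v <= 0) {
      stop("record '", complex_id, "': concentrations must be positive")
    }
  }
  structure(list(complex_id = complex_id, ic50 = ic50, ki = ki,
                 dg_exp = dg_exp),
            class = "experiment_record")
}

#' Experimental binding free energy from an affinity record
#'
#' For competitive inhibitors `dG = R T ln(K)` with K the molar Ki
#' (preferred) or IC50; a directly supplied `dg_exp` is returned
#' unchanged.  The default temperature is the thermochemical standard
#' 298.15 K; pass the simulation temperature (e.g. 310 K) to match an MD
#' protocol instead.
#'
#' @param record An [experiment_record()].
#' @param temperature_K Absolute temperature (default 298.15).
#' @return Binding free energy in kcal/mol.
#' @export
dg_exp <- function(record, temperature_K = 298.15) {
  stopifnot(inherits(record, "experiment_record"), temperature_K > 0)
  if (!is.null(record$dg_exp)) return(record$dg_exp)
  conc <- if (!is.null(record$ki)) record$ki else record$ic50
  if (conc <= 0) stop("non-positive concentration")
  lie_constants[["gas_constant_kcal"]] * temperature_K * log(conc)
}

#' Read a table of experimental affinities
#'
#' Delimited text with a header: column `complex_id` plus at least one of
#' `ic50_nM`, `ki_nM`, `dg_exp_kcal`.  Concentrations are nanomolar and
#' converted to molar.
#'
#' @param path Path to the table.
#' @param sep Field separator (default: any whitespace).
#' @return List of [experiment_record()] objects.
#' @export
read_experiment_table <- function(path, sep = "") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"complex_id" %in% names(df)) stop("table needs a complex_id column")
  lapply(seq_len(nrow(df)), function(i) {
    experiment_record(
      complex_id = as.character(df$complex_id[i]),
      ic50 = if ("ic50_nM" %in% names(df) && !is.na(df$ic50_nM[i])) df$ic50_nM[i] * 1e-9 else NULL,
      ki = if ("ki_nM" %in% names(df) && !is.na(df$ki_nM[i])) df$ki_nM[i] * 1e-9 else NULL,
      dg_exp = if ("dg_exp_kcal" %in% names(df) && !is.na(df$dg_exp_kcal[i])) df$dg_exp_kcal[i] else NULL
    )
  })
}

## ---------------------------------------------------------------------------
## Coefficient fitting and cross-validation

#' Fit diagnostics
#'
#' @param r Pearson correlation between predictions and observations.
#' @param mae Mean absolute error, kcal/mol.
#' @param rmse Root mean squared error, kcal/mol.
#' @param n Number of complexes.
#' @return Object of class `fit_diagnostics`.
#' @export
fit_diagnostics <- function(r, mae, rmse, n) {
  stopifnot(r >= -1, r <= 1, mae >= 0, rmse >= 0)
  structure(list(r = r, mae = mae, rmse = rmse, n = as.integer(n)),
            class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("<fit_diagnostics> R = %.3f, MAE = %.3f, RMSE = %.3f kcal/mol (n = %d)\n",
              x$r, x$mae, x$rmse, x$n))
  invisible(x)
}

.x_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

#' Fit LIE coefficients by ordinary least squares
#'
#' Regresses experimental binding free energies on ensemble-averaged
#' interaction terms (all in kcal/mol) with an intercept gamma.  One
#' predictor column fits (beta, gamma); two columns fit (alpha, beta,
#' gamma) with the dispersion / van der Waals term first.
#'
#' @param x Numeric vector or 1-2 column matrix of ensemble means
#'   (kcal/mol), one row per complex.
#' @param y Experimental binding free energies (kcal/mol).
#' @param model Equation tag recorded on the result
#'   (`"eq4"`, `"eq5"`, `"eq6"`, `"eq7"`, `"eq2"`, `"eq3"`).
#' @return List of class `lie_fit` with `coefficients`
#'   ([lie_coefficients()] with OLS standard errors), `diagnostics`
#'   ([fit_diagnostics()]) and `fitted` values.
#' @export
fit_coefficients <- function(x, y,
                             model = c("eq4", "eq5", "eq6", "eq7", "eq2", "eq3")) {
  model <- match.arg(model)
  x <- .x_matrix(x)
  p <- ncol(x)
  if (!p %in% c(1L, 2L)) stop("x must have 1 or 2 predictor columns")
  n <- nrow(x)
  if (length(y) != n) stop("x and y disagree in length")
  if (n < p + 2L) stop("need at least ", p + 2L, " complexes to fit ",
                       p + 1L, " coefficients")
  X <- cbind(x, 1)
  q <- qr(X)
  if (q$rank < ncol(X)) stop("rank-deficient design: predictors are collinear")
  fit <- stats::lm.fit(X, y)
  cf <- unname(fit$coefficients)
  res <- fit$residuals
  sigma2 <- sum(res^2) / (n - ncol(X))
  se <- unname(sqrt(diag(chol2inv(qr.R(q))) * sigma2))
  fitted <- as.numeric(X %*% cf)
  r <- if (stats::sd(fitted) == 0 || stats::sd(y) == 0) 0 else stats::cor(fitted, y)
  diag_ <- fit_diagnostics(r = r, mae = mean(abs(res)),
                           rmse = sqrt(mean(res^2)), n = n)
  coeffs <- if (p == 1L) {
    lie_coefficients(beta = cf[1L], gamma = cf[2L],
                     se_beta = se[1L], se_gamma = se[2L])
  } else {
    lie_coefficients(alpha = cf[1L], beta = cf[2L], gamma = cf[3L],
                     se_alpha = se[1L], se_beta = se[2L], se_gamma = se[3L])
  }
  structure(list(coefficients = coeffs, diagnostics = diag_,
                 fitted = fitted, model = model),
            class = "lie_fit")
}

#' @export
print.lie_fit <- function(x, ...) {
  cat("<lie_fit> model:", x$model, "\n")
  print(x$coefficients)
  print(x$diagnostics)
  invisible(x)
}

#' Repeated random-split cross-validation of a LIE fit
#'
#' Repeatedly holds out `ceiling(n * test_fraction)` complexes sampled
#' without replacement, fits the coefficients on the remainder, and
#' evaluates train/test RMSE.  With the conventional n = 54 and 10%
#' test fraction this gives 48 training and 6 test points per split.
#' Fully determined by `seed`.
#'
#' @inheritParams fit_coefficients
#' @param n_splits Number of random splits (default 100).
#' @param test_fraction Fraction held out per split (default 0.1).
#' @param seed Integer RNG seed.
#' @return List of class `lie_cv` with a per-split data frame `splits`
#'   (coefficients and RMSEs), a `summary` data frame (mean and sd of
#'   each quantity), the split sizes, and the held-out index sets.
#' @export
cross_validate <- function(x, y, n_splits = 100L, test_fraction = 0.1,
                           seed = 1L,
                           model = c("eq4", "eq5", "eq6", "eq7", "eq2", "eq3")) {
  model <- match.arg(model)
  stopifnot(n_splits >= 1L, test_fraction > 0, test_fraction < 1)
  x <- .x_matrix(x)
  n <- nrow(x)
  n_test <- as.integer(ceiling(n * test_fraction))
  if (n_test < 1L) stop("test set would be empty")
  n_train <- n - n_test
  if (n_train < ncol(x) + 2L) stop("training set too small to fit")
  set.seed(as.integer(seed))
  test_sets <- lapply(seq_len(n_splits), function(i) sort(sample.int(n, n_test)))
  rows <- lapply(seq_len(n_splits), function(i) {
    test <- test_sets[[i]]
    train <- setdiff(seq_len(n), test)
    f <- fit_coefficients(x[train, , drop = FALSE], y[train], model = model)
    cf <- f$coefficients
    Xte <- cbind(x[test, , drop = FALSE], 1)
    beta_vec <- if (is.na(cf$alpha)) c(cf$beta, cf$gamma) else c(cf$alpha, cf$beta, cf$gamma)
    pred <- as.numeric(Xte %*% beta_vec)
    data.frame(split = i, alpha = cf$alpha, beta = cf$beta, gamma = cf$gamma,
               rmse_train = f$diagnostics$rmse,
               rmse_test = sqrt(mean((pred - y[test])^2)))
  })
  splits <- do.call(rbind, rows)
  num <- splits[, c("alpha", "beta", "gamma", "rmse_train", "rmse_test")]
  summary <- data.frame(
    quantity = names(num),
    mean = vapply(num, mean, numeric(1)),
    sd = vapply(num, stats::sd, numeric(1)),
    row.names = NULL
  )
  structure(list(splits = splits, summary = summary, model = model,
                 n_train = n_train, n_test = n_test, seed = as.integer(seed),
                 test_sets = test_sets),
            class = "lie_cv")
}

#' @export
print.lie_cv <- function(x, ...) {
  cat(sprintf("<lie_cv> %d split(s), %d train / %d test, model %s\n",
              nrow(x$splits), x$n_train, x$n_test, x$model))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
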