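test_that("solvent-ignored estimators evaluate the linear form", {
  # intercept-only: zero mean returns gamma
  cf <- lie_coefficients(beta = 0.10639, gamma = -4.9875)
  expect_equal(dg_eq4(lie_inputs(dE_nnp_LP = 0), cf)$value, -4.9875)

  # published-style coefficients on a -2.183 eV ensemble mean
  got <- dg_eq4(lie_inputs(dE_nnp_LP = -2.183), cf)
  expect_equal(got$value, 0.10639 * ev_to_kcalmol(-2.183) - 4.9875,
               tolerance = 1e-10)
  expect_equal(got$value, -10.343, tolerance = 2e-3)

  # beta = 1, gamma = 0 is the identity on the converted mean
  ident <- lie_coefficients(beta = 1, gamma = 0)
  expect_equal(dg_eq4(lie_inputs(dE_nnp_LP = -1.5), ident)$value,
               ev_to_kcalmol(-1.5), tolerance = 1e-12)

  # uncertainty propagates as |beta| * sem (converted)
  st <- ensemble_stat(-2.183, sem = 0.05, n_frames = 100)
  expect_equal(dg_eq4(lie_inputs(dE_nnp_LP = st), cf)$se,
               0.10639 * ev_to_kcalmol(0.05), tolerance = 1e-12)

  expect_error(dg_eq4(lie_inputs(dE_d3_LP = -1), cf), "dE_nnp_LP")

  # eq5 with alpha = 0 reduces exactly to eq4
  cf5 <- lie_coefficients(alpha = 0, beta = 0.10639, gamma = -4.9875)
  expect_equal(dg_eq5(lie_inputs(dE_nnp_LP = -2.183, dE_d3_LP = -0.9), cf5)$value,
               dg_eq4(lie_inputs(dE_nnp_LP = -2.183), cf)$value,
               tolerance = 1e-12)
  # all means zero: gamma
  expect_equal(dg_eq5(lie_inputs(dE_nnp_LP = 0, dE_d3_LP = 0), cf5)$value,
               -4.9875)
})

test_that("solvent-included estimators reduce to the solvent-ignored ones on cancellation", {
  cf <- lie_coefficients(alpha = 0.3, beta = 0.11, gamma = -5)
  # identical bound and free L-S terms cancel: eq6 == eq4
  inp <- lie_inputs(dE_nnp_LP = -2.0, dE_nnp_LS_bound = -0.7,
                    dE_nnp_LS_free = -0.7)
  expect_equal(dg_eq6(inp, cf)$value,
               dg_eq4(lie_inputs(dE_nnp_LP = -2.0), cf)$value,
               tolerance = 1e-12)
  # all zeros: gamma
  zero6 <- lie_inputs(dE_nnp_LP = 0, dE_nnp_LS_bound = 0, dE_nnp_LS_free = 0)
  expect_equal(dg_eq6(zero6, cf)$value, -5)
  # missing LS terms direct the user to the LS workflow
  expect_error(dg_eq6(lie_inputs(dE_nnp_LP = -2), cf), "free-ligand")

  inp7 <- lie_inputs(dE_nnp_LP = -2.0, dE_nnp_LS_bound = -0.7,
                     dE_nnp_LS_free = -0.4, dE_d3_LP = -1.0,
                     dE_d3_LS_bound = -0.3, dE_d3_LS_free = -0.3)
  eq6_val <- dg_eq6(lie_inputs(dE_nnp_LP = -2.0, dE_nnp_LS_bound = -0.7,
                               dE_nnp_LS_free = -0.4), cf)$value
  # bound and free L-S dispersion cancel, leaving only the alpha-scaled
  # ligand-protein dispersion on top of the eq6 value
  expect_equal(dg_eq7(inp7, cf)$value,
               eq6_val + 0.3 * ev_to_kcalmol(-1.0), tolerance = 1e-12)
  # and with alpha = 0 the dispersion channel drops out entirely
  cf0 <- lie_coefficients(alpha = 0, beta = 0.11, gamma = -5)
  expect_equal(dg_eq7(inp7, cf0)$value,
               dg_eq6(lie_inputs(dE_nnp_LP = -2.0, dE_nnp_LS_bound = -0.7,
                                 dE_nnp_LS_free = -0.4), cf0)$value,
               tolerance = 1e-12)
})

test_that("all estimators agree with a brute-force evaluation of their linear form", {
  set.seed(31)
  k <- 23.060548
  for (rep in 1:10) {
    v <- rnorm(6, -1, 0.5)
    cf <- lie_coefficients(alpha = rnorm(1), beta = rnorm(1), gamma = rnorm(1))
    inp <- lie_inputs(dE_nnp_LP = v[1], dE_nnp_LS_bound = v[2],
                      dE_nnp_LS_free = v[3], dE_d3_LP = v[4],
                      dE_d3_LS_bound = v[5], dE_d3_LS_free = v[6])
    expect_equal(dg_eq4(inp, cf)$value, cf$beta * k * v[1] + cf$gamma,
                 tolerance = 1e-10)
    expect_equal(dg_eq5(inp, cf)$value,
                 cf$alpha * k * v[4] + cf$beta * k * v[1] + cf$gamma,
                 tolerance = 1e-10)
    expect_equal(dg_eq6(inp, cf)$value,
                 cf$beta * k * (v[1] + v[2] - v[3]) + cf$gamma,
                 tolerance = 1e-10)
    expect_equal(dg_eq7(inp, cf)$value,
                 cf$alpha * k * (v[4] + v[5] - v[6]) +
                   cf$beta * k * (v[1] + v[2] - v[3]) + cf$gamma,
                 tolerance = 1e-10)
    # linearity: scaling the means scales dG - gamma
    c_ <- 2.5
    inp_s <- lie_inputs(dE_nnp_LP = c_ * v[1], dE_nnp_LS_bound = c_ * v[2],
                        dE_nnp_LS_free = c_ * v[3], dE_d3_LP = c_ * v[4],
                        dE_d3_LS_bound = c_ * v[5], dE_d3_LS_free = c_ * v[6])
    expect_equal(dg_eq7(inp_s, cf)$value - cf$gamma,
                 c_ * (dg_eq7(inp, cf)$value - cf$gamma), tolerance = 1e-9)
  }
})

test_that("classical MM LIE combines bound/free differences in kcal/mol", {
  # conventional defaults with zero differences give zero
  zero <- lie_inputs(dE_vdw_Lsurr = -12, dE_vdw_LS_free = -12,
                     dE_el_Lsurr = -30, dE_el_LS_free = -30)
  expect_equal(dg_mm_lie(zero)$value, 0)
  # refit coefficients: intercept passes through
  refit <- lie_coefficients(alpha = 0.25, beta = -0.06, gamma = -3.09)
  expect_equal(dg_mm_lie(zero, refit)$value, -3.09)
  # brute-force linear form on random inputs
  set.seed(8)
  for (rep in 1:5) {
    v <- rnorm(4, -20, 5)
    inp <- lie_inputs(dE_vdw_Lsurr = v[1], dE_vdw_LS_free = v[2],
                      dE_el_Lsurr = v[3], dE_el_LS_free = v[4])
    expect_equal(dg_mm_lie(inp, refit)$value,
                 0.25 * (v[1] - v[2]) - 0.06 * (v[3] - v[4]) - 3.09,
                 tolerance = 1e-12)
  }
  expect_error(dg_mm_lie(lie_inputs(dE_vdw_Lsurr = -1)), "dE_vdw_LS_free")
})

test_that("experimental dG derives from RT ln K with the documented precedence", {
  # Ki = 1 M: ln 1 = 0 at any temperature
  expect_equal(dg_exp(experiment_record("a", ki = 1), 298.15), 0)
  expect_equal(dg_exp(experiment_record("a", ki = 1), 310), 0)
  # IC50 = 1 uM at 298.15 K
  expect_equal(dg_exp(experiment_record("b", ic50 = 1e-6)),
               1.987204e-3 * 298.15 * log(1e-6), tolerance = 1e-12)
  expect_equal(dg_exp(experiment_record("b", ic50 = 1e-6)), -8.186,
               tolerance = 1e-3)
  # direct dg_exp takes precedence over concentrations
  rec <- experiment_record("c", ic50 = 1e-6, dg_exp = -7.5)
  expect_equal(dg_exp(rec), -7.5)
  # validation
  expect_error(experiment_record("d"), "at least one")
  expect_error(experiment_record("e", ic50 = -1), "positive")
})

test_that("experiment tables parse with nanomolar concentration units", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("complex_id ic50_nM dg_exp_kcal",
               "5IVS 1000 NA",
               "XXXX NA -9.1"), f)
  recs <- read_experiment_table(f)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$ic50, 1e-6)
  expect_equal(dg_exp(recs[[2]]), -9.1)
})

test_that("OLS fitting recovers exact coefficients and closed-form regression", {
  # noiseless single-term data: exact recovery, r = 1, mae = 0
  x <- seq(-80, -30, length.out = 12)
  y <- 0.12 * x - 4.2
  fit <- fit_coefficients(x, y, model = "eq4")
  expect_equal(fit$coefficients$beta, 0.12, tolerance = 1e-10)
  expect_equal(fit$coefficients$gamma, -4.2, tolerance = 1e-10)
  expect_equal(fit$diagnostics$r, 1, tolerance = 1e-10)
  expect_equal(fit$diagnostics$mae, 0, tolerance = 1e-10)

  # noisy single-predictor fit equals the closed-form simple regression
  set.seed(5)
  xn <- runif(30, -90, -20)
  yn <- 0.1 * xn - 5 + rnorm(30, 0, 1.5)
  fit2 <- fit_coefficients(xn, yn)
  slope <- cov(xn, yn) / var(xn)
  expect_equal(fit2$coefficients$beta, slope, tolerance = 1e-10)
  expect_equal(fit2$coefficients$gamma, mean(yn) - slope * mean(xn),
               tolerance = 1e-10)
  # standard errors match the textbook formulas
  res <- yn - (slope * xn + mean(yn) - slope * mean(xn))
  s2 <- sum(res^2) / (30 - 2)
  expect_equal(fit2$coefficients$se_beta,
               sqrt(s2 / sum((xn - mean(xn))^2)), tolerance = 1e-10)

  # two-predictor fit: alpha on the first column
  x2 <- cbind(runif(30, -15, -5), xn)
  y2 <- 0.3 * x2[, 1] + 0.1 * x2[, 2] - 2 + rnorm(30, 0, 0.5)
  fit3 <- fit_coefficients(x2, y2, model = "eq5")
  lmref <- lm(y2 ~ x2[, 1] + x2[, 2])
  expect_equal(fit3$coefficients$alpha, unname(coef(lmref)[2]), tolerance = 1e-10)
  expect_equal(fit3$coefficients$beta, unname(coef(lmref)[3]), tolerance = 1e-10)
  expect_equal(fit3$coefficients$gamma, unname(coef(lmref)[1]), tolerance = 1e-10)

  # diagnostics agree with a naive reimplementation
  pred <- fit3$fitted
  expect_equal(fit3$diagnostics$r, cor(pred, y2), tolerance = 1e-12)
  expect_equal(fit3$diagnostics$mae, mean(abs(y2 - pred)), tolerance = 1e-12)
  expect_equal(fit3$diagnostics$rmse, sqrt(mean((y2 - pred)^2)),
               tolerance = 1e-12)

  # degenerate designs are rejected
  expect_error(fit_coefficients(cbind(xn, xn), yn), "rank-deficient")
  expect_error(fit_coefficients(x[1:2], y[1:2]), "at least")
})

test_that("fit followed by the matching estimator reproduces the fitted values", {
  set.seed(77)
  x <- runif(20, -90, -20)            # kcal/mol ensemble means
  y <- 0.11 * x - 4 + rnorm(20, 0, 1)
  fit <- fit_coefficients(x, y, model = "eq4")
  dgs <- vapply(x, function(xi) {
    dg_eq4(lie_inputs(dE_nnp_LP = kcalmol_to_ev(xi)), fit$coefficients)$value
  }, numeric(1))
  expect_equal(dgs, fit$fitted, tolerance = 1e-9)
  expect_equal(mean(abs(y - dgs)), fit$diagnostics$mae, tolerance = 1e-9)
})

test_that("cross-validation is seeded, sized correctly and exact on noiseless data", {
  d <- make_synthetic_lie_dataset(n = 54, noise_sd = 1.5, seed = 3)
  cv1 <- cross_validate(d$x, d$y, n_splits = 20, test_fraction = 0.1, seed = 99)
  cv2 <- cross_validate(d$x, d$y, n_splits = 20, test_fraction = 0.1, seed = 99)
  # 54 points at 10% test fraction: the conventional 48/6 split
  expect_equal(cv1$n_train, 48L)
  expect_equal(cv1$n_test, 6L)
  expect_identical(cv1$test_sets, cv2$test_sets)
  expect_equal(cv1$splits, cv2$splits)
  # different seed, different splits
  cv3 <- cross_validate(d$x, d$y, n_splits = 20, test_fraction = 0.1, seed = 100)
  expect_false(identical(cv1$test_sets, cv3$test_sets))

  # noiseless data: zero test RMSE in every split
  dn <- make_synthetic_lie_dataset(n = 30, noise_sd = 0, seed = 4)
  cvn <- cross_validate(dn$x, dn$y, n_splits = 10, seed = 1)
  expect_true(all(cvn$splits$rmse_test < 1e-9))
  expect_error(cross_validate(d$x, d$y, test_fraction = 0), "test_fraction")
})
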