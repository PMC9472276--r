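test_that("interaction energy cancels the absolute-energy bias", {
  # truncated HIV-1 protease complex (5IVS): absolute energies are
  # hundreds of thousands of eV, the interaction is a few eV
  expect_equal(interaction_energy(-601409.137, -543088.071, -58316.912),
               -4.154, tolerance = 1e-9)
  expect_equal(interaction_energy(-601407.549, -543086.919, -58316.653),
               -3.977, tolerance = 1e-9)
  # E(AB) = E(A), E(B) = 0 gives exactly zero
  expect_equal(interaction_energy(123.456, 123.456, 0), 0)
})

test_that("frame_interaction equals the cross-group pair sum for a pairwise backend", {
  spec <- calculator_spec("mock")
  # two single atoms: dE is exactly the pair potential
  atoms <- data.frame(serial = 1:2, element = c("C", "O"),
                      atom_name = c("C1", "O1"), residue_name = "LIG",
                      residue_id = 1:2)
  r <- 3.7
  fr <- structure_frame(atoms, matrix(c(0, 0, 0, r, 0, 0), 2, 3, byrow = TRUE))
  sel <- structure(list(A = 1L, B = 2L), class = "group_selection")
  de <- frame_interaction(spec, fr, sel, "A", "B")
  expect_equal(as.numeric(de), mock_pair_potential("C", "O", r),
               tolerance = 1e-12)

  # arbitrary groups on toy fixtures: intra-group terms cancel exactly
  for (seed in c(2, 3)) {
    fx <- make_toy_trajectory(n_waters = 6, seed = seed)
    fr <- fx$trajectory$frames[[1]]
    de <- frame_interaction(spec, fr, fx$selection, "L", "P")
    oracle <- brute_mock_cross(extract_group(fr, fx$selection, "L"),
                               extract_group(fr, fx$selection, "P"))
    expect_equal(as.numeric(de), oracle, tolerance = 1e-9)
    # symmetry of roles
    expect_equal(as.numeric(frame_interaction(spec, fr, fx$selection, "P", "L")),
                 as.numeric(de), tolerance = 1e-9)
  }

  # non-interacting limit: neutral groups 500 A apart
  atoms2 <- data.frame(serial = 1:4, element = c("C", "H", "O", "H"),
                       atom_name = c("C1", "H1", "O1", "H2"),
                       residue_name = c("A", "A", "B", "B"),
                       residue_id = c(1L, 1L, 2L, 2L))
  xyz <- rbind(c(0, 0, 0), c(1.1, 0, 0), c(500, 0, 0), c(501, 0, 0))
  fr2 <- structure_frame(atoms2, xyz)
  sel2 <- structure(list(A = 1:2, B = 3:4), class = "group_selection")
  expect_lt(abs(as.numeric(frame_interaction(spec, fr2, sel2, "A", "B"))), 1e-6)

  # overlapping groups are rejected
  sel3 <- structure(list(A = 1:3, B = 3:4), class = "group_selection")
  expect_error(frame_interaction(spec, fr2, sel3, "A", "B"), "overlap")
})

test_that("interaction additivity over a partitioned environment holds for pairwise potentials", {
  # dE(L, P u S) = dE(L, P) + dE(L, S)
  spec <- calculator_spec("mock")
  fx <- make_toy_trajectory(n_waters = 8, seed = 13)
  fr <- fx$trajectory$frames[[1]]
  sel <- fx$selection
  sel$PS <- sort(c(sel$P, sel$SOL))
  lhs <- as.numeric(frame_interaction(spec, fr, sel, "L", "PS"))
  rhs <- as.numeric(frame_interaction(spec, fr, sel, "L", "P")) +
    as.numeric(frame_interaction(spec, fr, sel, "L", "SOL"))
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("ensemble averages use the iid sem estimator", {
  s <- interaction_series(0:3, c(-4.154, -4.053, -3.876, -1.164),
                          c("L", "P"), "mock")
  st <- ensemble_average(s)
  expect_equal(st$mean, -3.31175, tolerance = 1e-10)
  expect_equal(st$sem, sd(c(-4.154, -4.053, -3.876, -1.164)) / 2,
               tolerance = 1e-12)
  expect_equal(st$n_frames, 4L)
  # sd flavour on request
  expect_equal(ensemble_average(s, error = "sd")$sem,
               sd(c(-4.154, -4.053, -3.876, -1.164)))
  # single value: mean v, sem 0
  one <- ensemble_average(interaction_series(0L, -2.5, c("L", "P"), "mock"))
  expect_equal(one$mean, -2.5)
  expect_equal(one$sem, 0)
  # constant series: sem 0
  const <- ensemble_average(interaction_series(0:9, rep(-1.5, 10), c("L", "P"), "mock"))
  expect_equal(const$sem, 0)
  expect_error(ensemble_average(numeric(0)), "empty")
})

test_that("convergence profile uses the deterministic equal-interval stride", {
  # constant series: all deviations zero, including self-reference
  const <- interaction_series(0:99, rep(-2, 100), c("L", "P"), "mock")
  prof <- convergence_profile(const, c(5, 10, 100), reference_count = 100)
  expect_equal(prof$abs_dev, c(0, 0, 0))

  # linear drift: compare against direct recomputation of the stride means
  v <- seq(-3, -1, length.out = 120)
  drift <- interaction_series(0:119, v, c("L", "P"), "mock")
  counts <- c(3, 7, 30, 100)
  prof <- convergence_profile(drift, counts, reference_count = 100)
  ref_mean <- mean(v[1:100])
  for (k in seq_along(counts)) {
    n <- counts[k]
    idx <- floor((0:(n - 1)) * 100 / n) + 1
    expect_equal(prof$abs_dev[k], abs(mean(v[idx]) - ref_mean),
                 tolerance = 1e-12)
  }
  # self-reference deviation is exactly zero
  expect_equal(convergence_profile(drift, 100, 100)$abs_dev, 0)
  expect_error(convergence_profile(drift, c(0, 5), 100), "positive")
  expect_error(convergence_profile(drift, 10, 1000), "exceeds")
})

test_that("eV/kcal conversion uses the fixed constant", {
  expect_equal(round(ev_to_kcalmol(0.02), 2), 0.46)
  expect_equal(ev_to_kcalmol(0), 0)
  expect_equal(ev_to_kcalmol(1), 23.060548)
  expect_equal(kcalmol_to_ev(ev_to_kcalmol(1.37)), 1.37, tolerance = 1e-12)
})

test_that("per-frame energy tables round-trip through disk", {
  df <- data.frame(frame_index = 0:2, E_AB = c(-10, -11, -12),
                   E_A = c(-4, -4.5, -5), E_B = c(-5, -5, -5),
                   dE_int = c(-1, -1.5, -2), backend = "mock", pair = "L-P")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_energy_table(df, f)
  back <- read_energy_table(f)
  expect_equal(back$dE_int, df$dE_int)
  expect_identical(back$pair, df$pair)
  expect_error(write_energy_table(df[, -2], f), "E_AB")
})
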