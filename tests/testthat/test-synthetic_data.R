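test_that("cohort sampling is seeded, truncated and sized correctly", {
  cfg <- cohort_config(n_cells = 0, seed = 1)
  expect_identical(nrow(sample_cohort(cfg)), 0L)
  cfg2 <- cohort_config(n_cells = 40, seed = 9)
  expect_identical(sample_cohort(cfg2), sample_cohort(cfg2))
  tr <- sample_cohort(cfg2)
  d <- cfg2$distributions
  for (p in names(d))
    expect_true(all(tr[[p]] >= d[[p]]$lower & tr[[p]] <= d[[p]]$upper))
  expect_true(all(tr$P_aspiration >= 0.5 & tr$P_aspiration <= 1.2))
  # impossible truncation bounds are rejected
  bad <- cohort_config(n_cells = 5, distributions = modifyList(
    d, list(E_instantaneous = list(mean = 5, sd = 1, lower = 9, upper = 8))))
  expect_error(sample_cohort(bad), "truncation")
})

test_that("sampled means converge to the configured locations", {
  cfg <- cohort_config(n_cells = 1000, seed = 77)
  tr <- sample_cohort(cfg)
  sp <- cfg$distributions$E_instantaneous
  # truncation at +->3 sd is mild; allow 3 standard errors around the location
  expect_lt(abs(mean(tr$E_instantaneous) - sp$mean), 3 * sp$sd / sqrt(1000))
})

test_that("volume conservation maps diameter to elongation and back", {
  expect_equal(elongation_from_diameter(17.525, default_geom), 28.18,
               tolerance = 1e-3)
  d <- c(13, 17.5, 21)
  expect_equal(diameter_from_elongation(
    elongation_from_diameter(d, default_geom), default_geom), d,
    tolerance = 1e-12)
  expect_error(elongation_from_diameter(0, default_geom), "> 0")
})

test_that("simulated trajectory realizes the forward entry model", {
  cfg <- cohort_config(n_cells = 5, seed = 5, amplitude_noise = 0,
                       length_noise = 0)
  truth <- simulate_cohort(cfg)$truth[1, ]   # first feasible draw
  traj <- simulate_trajectory(truth, cfg)
  fw <- forward_entry_lengths(truth$f_c, truth$P_aspiration / truth$E_instantaneous)
  ent <- extract_entry_lengths(traj, detect_entry_onset(traj, 2))
  expect_equal(ent$L_instantaneous, fw$l_inst * 10, tolerance = 1e-6)
  expect_equal(ent$L_transitional, fw$l_trans * 10, tolerance = 1e-6)
  # vanishing creep time degenerates to a two-step function
  truth2 <- truth; truth2$tau_creep <- 1e-7
  traj2 <- simulate_trajectory(truth2, cfg)
  creep <- traj2$length[102:159]
  expect_true(all(abs(creep - fw$l_trans * 10) < 1e-9))
})

test_that("infeasible parameter draws are refused with a reason", {
  cfg <- cohort_config(n_cells = 1, seed = 5, amplitude_noise = 0,
                       length_noise = 0)
  truth <- sample_cohort(cfg)
  truth$E_instantaneous <- 1   # pressure ratio far beyond the ordered domain
  expect_error(simulate_trajectory(truth, cfg), class = "infeasible_cell")
})

test_that("simulated impedance reproduces the circuit ratios exactly", {
  cfg <- cohort_config(n_cells = 1, seed = 5, amplitude_noise = 0,
                       length_noise = 0)
  truth <- sample_cohort(cfg)
  trace <- simulate_impedance(truth, cfg)
  le <- elongation_from_diameter(truth$D_cell, cfg$geom)
  circ <- intrinsic_to_circuit(truth$C_specific_membrane,
                               truth$sigma_cytoplasm, le, cfg$geom)
  cc <- circuit_params(truth$R_leak, circ$R_cytoplasm, circ$C_membrane)
  a1 <- forward_cell_impedance_ratio(cc, cfg$geom, cfg$medium, le, 1e3)
  a2 <- forward_cell_impedance_ratio(cc, cfg$geom, cfg$medium, le, 1e5)
  r <- extract_amplitude_ratios(trace)
  expect_equal(r$A_1kHz, Mod(a1), tolerance = 1e-12)
  expect_equal(r$A_100kHz, Mod(a2), tolerance = 1e-12)
  expect_equal(r$phase_ratio_100kHz, Arg(a2), tolerance = 1e-12)
})

test_that("cohort simulation is deterministic and isolates failures", {
  cfg <- cohort_config(n_cells = 30, seed = 13)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$cells[[1]]$trace, s2$cells[[1]]$trace)
  expect_identical(s1$skipped, s2$skipped)
  # every sampled cell is either simulated or logged as skipped
  expect_identical(nrow(s1$truth) + nrow(s1$skipped), 30L)
})

test_that("noiseless simulator output round-trips through extraction", {
  cfg <- cohort_config(n_cells = 12, seed = 21, amplitude_noise = 0,
                       length_noise = 0)
  sim <- simulate_cohort(cfg)
  for (i in seq_along(sim$cells)) {
    truth <- sim$truth[i, ]
    mk <- extract_markers(sim$cells[[i]]$trace, sim$cells[[i]]$trajectory)
    fw <- forward_entry_lengths(truth$f_c,
                                truth$P_aspiration / truth$E_instantaneous)
    le <- elongation_from_diameter(truth$D_cell, cfg$geom)
    expect_equal(mk$L_instantaneous, fw$l_inst * 10, tolerance = 1e-6)
    expect_equal(mk$L_transitional, fw$l_trans * 10, tolerance = 1e-6)
    expect_equal(mk$L_elongation, le, tolerance = 1e-9)
    # marker ordering holds on every noiseless cell
    expect_true(mk$L_instantaneous < mk$L_transitional &&
                mk$L_transitional < mk$L_elongation)
    expect_true(mk$A_1kHz > mk$A_100kHz && mk$A_100kHz > 1)
  }
})
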