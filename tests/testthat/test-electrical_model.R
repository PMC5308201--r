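test_that("baseline impedance is resistive and additive", {
  z <- baseline_impedance(default_geom, default_medium, 1e3)
  expect_equal(Re(z), 200e-6 / (1.5 * 1e-10), tolerance = 1e-12)
  expect_equal(Im(z), 0)
  # resistive model is frequency-independent
  expect_equal(z, baseline_impedance(default_geom, default_medium, 1e5))
  # series access resistance adds
  med2 <- medium_model(1.5, access_resistance = 1e5)
  expect_equal(Re(baseline_impedance(default_geom, med2, 1e3)),
               1.4333333e6, tolerance = 1e-7)
  expect_error(baseline_impedance(default_geom, default_medium, 0), "> 0")
})

test_that("forward impedance ratio matches the complex-arithmetic oracle", {
  cc <- circuit_params(R_leak = 3e6, R_cytoplasm = 2.8e5, C_membrane = 1e-12)
  a <- forward_cell_impedance_ratio(cc, default_geom, default_medium, 28, 1e5)
  # frozen from an independent numpy evaluation of the lumped circuit
  expect_equal(Mod(a), 1.6550495101, tolerance = 1e-9)
  expect_equal(Arg(a), -0.5102108745, tolerance = 1e-8)
})

test_that("forward ratio approaches the capacitor open/short limits", {
  cc <- circuit_params(R_leak = 3e6, R_cytoplasm = 2.8e5, C_membrane = 1e-12)
  r_total <- Re(baseline_impedance(default_geom, default_medium, 1e3))
  r_rest <- (200 - 28) * 1e-6 / (1.5 * 1e-10)
  # w -> 0: membrane open, occupied segment -> R_leak
  a_lo <- forward_cell_impedance_ratio(cc, default_geom, default_medium, 28, 1e-3)
  expect_equal(Mod(a_lo), (r_rest + cc$R_leak) / r_total, tolerance = 1e-6)
  # w -> Inf: membrane short, occupied segment -> R_leak || R_cytoplasm
  a_hi <- forward_cell_impedance_ratio(cc, default_geom, default_medium, 28, 1e12)
  rp <- cc$R_leak * cc$R_cytoplasm / (cc$R_leak + cc$R_cytoplasm)
  expect_equal(Mod(a_hi), (r_rest + rp) / r_total, tolerance = 1e-6)
  # |A(f)| is non-increasing in frequency between the limits
  freqs <- 10^seq(1, 8, by = 0.25)
  mods <- vapply(freqs, function(f)
    Mod(forward_cell_impedance_ratio(cc, default_geom, default_medium, 28, f)),
    numeric(1))
  expect_true(all(diff(mods) <= 1e-12))
})

test_that("leak-resistance inversion matches hand arithmetic and its bounds", {
  expect_equal(invert_leak_resistance(3.41, default_geom, default_medium, 28),
               3.4e6, tolerance = 1e-9)
  # electrically invisible cell: A = 1 leaves just the displaced medium
  r_seg <- 0.01 * 1e-6 / (1.5 * 1e-10)
  expect_equal(invert_leak_resistance(1, default_geom, default_medium, 0.01),
               r_seg, tolerance = 1e-6)
  expect_error(invert_leak_resistance(0.5, default_geom, default_medium, 28),
               "infeasible")
})

test_that("cell-circuit inversion round-trips and flags degeneracy", {
  cc <- circuit_params(3e6, 2.8e5, 1e-12)
  a <- forward_cell_impedance_ratio(cc, default_geom, default_medium, 28, 1e5)
  sol <- invert_cell_circuit(Mod(a), Arg(a), 3e6, default_geom,
                             default_medium, 28)
  expect_equal(sol$R_cytoplasm, 2.8e5, tolerance = 1e-6)
  expect_equal(sol$C_membrane, 1e-12, tolerance = 1e-6)
  # zero phase at the low-frequency amplitude limit: capacitance unidentifiable
  a0 <- (172e-6 / (1.5 * 1e-10) + 3e6) / Re(baseline_impedance(default_geom,
                                                               default_medium, 1e5))
  expect_error(invert_cell_circuit(a0, 0, 3e6, default_geom, default_medium, 28),
               "capacitance|indistinguishable")
  expect_error(invert_cell_circuit(Mod(a), Arg(a), -1, default_geom,
                                   default_medium, 28), "positive")
})

test_that("geometric translation to intrinsic markers is exact both ways", {
  intr <- circuit_to_intrinsic(2.8e5, 1e-12, 28, default_geom)
  expect_equal(intr$C_specific_membrane, 2, tolerance = 1e-12)
  expect_equal(intr$sigma_cytoplasm, 1, tolerance = 1e-12)
  back <- intrinsic_to_circuit(intr$C_specific_membrane,
                               intr$sigma_cytoplasm, 28, default_geom)
  expect_equal(back$R_cytoplasm, 2.8e5, tolerance = 1e-12)
  expect_equal(back$C_membrane, 1e-12, tolerance = 1e-12)
  expect_error(circuit_to_intrinsic(2.8e5, 1e-12, 0, default_geom), "> 0")
  expect_warning(circuit_to_intrinsic(2.8e5, 1e-10, 28, default_geom),
                 "plausible range")
})

test_that("full electrical chain recovers intrinsic markers on a grid", {
  worst <- 0
  for (c_spec in c(1, 2, 3)) for (sigma in c(0.5, 1, 1.5))
    for (r_leak in c(1e6, 3e6, 1e7)) {
      le <- 28
      circ <- intrinsic_to_circuit(c_spec, sigma, le, default_geom)
      cc <- circuit_params(r_leak, circ$R_cytoplasm, circ$C_membrane)
      a1 <- forward_cell_impedance_ratio(cc, default_geom, default_medium, le, 1e3)
      a2 <- forward_cell_impedance_ratio(cc, default_geom, default_medium, le, 1e5)
      sol <- invert_electrical(Mod(a1), Mod(a2), Arg(a2), default_geom,
                               default_medium, le)
      worst <- max(worst,
                   abs(sol$C_specific_membrane - c_spec) / c_spec,
                   abs(sol$sigma_cytoplasm - sigma) / sigma,
                   abs(sol$R_leak - r_leak) / r_leak)
    }
  expect_lt(worst, 1e-8)
})

test_that("amplitude ratios order as 1 kHz > 100 kHz > 1 at cohort scale", {
  for (r_leak in c(2e6, 3.4e6, 5e6)) for (c_spec in c(1.8, 2.5)) {
    circ <- intrinsic_to_circuit(c_spec, 0.9, 28, default_geom)
    cc <- circuit_params(r_leak, circ$R_cytoplasm, circ$C_membrane)
    a1 <- Mod(forward_cell_impedance_ratio(cc, default_geom, default_medium, 28, 1e3))
    a2 <- Mod(forward_cell_impedance_ratio(cc, default_geom, default_medium, 28, 1e5))
    expect_gt(a1, a2)
    expect_gt(a2, 1)
  }
})
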