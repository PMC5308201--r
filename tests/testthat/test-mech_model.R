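test_that("default coefficients have the fixed sign structure", {
  co <- mech_coefficients()
  expect_equal(co$a_inst, c(44.27, -37.24, 13.70))
  expect_equal(co$b_inst, c(-5.31, 2.84, -0.59))
  expect_equal(co$a_trans, c(-60.40, 40.05, -8.68))
  expect_equal(co$b_trans, c(1.99, 0.03, 1.60))
  # slope polynomials are sign-definite: instantaneous always increases with
  # pressure, transitional always decreases, for any real friction
  f <- seq(-5, 5, by = 0.01)
  a_i <- co$a_inst[1] * f^2 + co$a_inst[2] * f + co$a_inst[3]
  a_t <- co$a_trans[1] * f^2 + co$a_trans[2] * f + co$a_trans[3]
  expect_true(all(a_i > 0))
  expect_true(all(a_t < 0))
})

test_that("forward model reproduces hand-evaluated lengths", {
  # zero friction, zero pressure: the two printed intercepts
  fw0 <- forward_entry_lengths(0, 0)
  expect_equal(fw0$l_inst, -0.59)
  expect_equal(fw0$l_trans, 1.60)
  # hand evaluation at f_c = 0, x = 0.1
  fw1 <- forward_entry_lengths(0, 0.1)
  expect_equal(fw1$l_inst, 0.78, tolerance = 1e-12)
  expect_equal(fw1$l_trans, 0.732, tolerance = 1e-12)
  # hand evaluation at f_c = 0.2, x = 0.1
  fw2 <- forward_entry_lengths(0.2, 0.1)
  expect_equal(fw2$l_inst, 0.56788, tolerance = 1e-12)
  expect_equal(fw2$l_trans, 1.37700, tolerance = 1e-12)
  # unit pressure-ratio step at zero friction recovers the slope constants
  fw3 <- forward_entry_lengths(0, 1)
  expect_equal(fw3$l_inst - fw0$l_inst, 13.70)
  expect_equal(fw3$l_trans - fw0$l_trans, -8.68)
})

test_that("forward model rejects bad inputs and never clips", {
  expect_error(forward_entry_lengths(NA, 0.1), "finite")
  expect_error(forward_entry_lengths(0.2, Inf), "finite")
  expect_error(forward_entry_lengths(0.2, -0.1), ">= 0")
  # negative prediction at small x is returned as-is
  expect_lt(forward_entry_lengths(0, 0.01)$l_inst, 0)
})

test_that("normalized lengths are monotone in the pressure ratio", {
  xs <- seq(0, 0.5, by = 0.05)
  for (f in c(0, 0.1, 0.25, 0.4)) {
    fw <- forward_entry_lengths(rep(f, length(xs)), xs)
    expect_true(all(diff(fw$l_inst) > 0))
    expect_true(all(diff(fw$l_trans) < 0))
  }
})

test_that("inversion round-trips the forward model on the lower branch", {
  for (f in seq(0.15, 0.33, by = 0.03)) {
    for (x in seq(0.04, 0.16, by = 0.04)) {
      fw <- forward_entry_lengths(f, x)
      if (fw$l_inst <= 0 || fw$l_trans <= fw$l_inst) next
      s <- invert_entry(fw$l_inst * 10, fw$l_trans * 10, D_channel = 10,
                        P_aspiration = 0.8)
      expect_true(s$status %in% c("ok", "multiple_solutions_resolved"))
      expect_equal(s$f_c, f, tolerance = 1e-6)
      expect_equal(s$E_instantaneous, 0.8 / x, tolerance = 1e-6)
    }
  }
})

test_that("the entry model is two-valued: both roots reproduce the data", {
  # above the fold the generating root has an exact measurement-equivalent
  # partner at lower f_c, which the smallest-f_c tie-break selects
  fw <- forward_entry_lengths(0.40, 0.14)
  s <- invert_entry(fw$l_inst * 10, fw$l_trans * 10, 10, 0.7)
  expect_identical(s$status, "multiple_solutions_resolved")
  expect_lt(s$f_c, 0.40)
  # the returned pair reproduces the measured lengths exactly
  fw2 <- forward_entry_lengths(s$f_c, 0.7 / s$E_instantaneous)
  expect_equal(fw2$l_inst, fw$l_inst, tolerance = 1e-8)
  expect_equal(fw2$l_trans, fw$l_trans, tolerance = 1e-8)
})

test_that("infeasible measurements give no_solution, not numbers", {
  # l_trans = 5 exceeds the transitional intercept everywhere, so no
  # candidate friction admits a positive pressure ratio
  s <- invert_entry(9, 50, D_channel = 10, P_aspiration = 0.8)
  expect_identical(s$status, "no_solution")
  expect_true(is.na(s$E_instantaneous))
  expect_true(is.na(s$f_c))
})

test_that("inversion validates its inputs", {
  expect_error(invert_entry(9, 18, 10, 0), "positive")
  expect_error(invert_entry(-1, 18, 10, 0.5), "positive")
  expect_error(invert_entry(9, 18, 10, 0.5, search_interval = c(1, 0)),
               "increasing")
})
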