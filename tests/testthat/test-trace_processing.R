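test_that("entry onset detection finds the jump frame", {
  traj <- aspiration_trajectory((0:9) / 200,
                                c(0, 0, 0, 6.1, 7, 7.5, 7.8, 8, 8.1, 8.2))
  expect_identical(detect_entry_onset(traj, 2), 4L)
  # all-zero trajectory has no entry
  flat <- aspiration_trajectory((0:9) / 200, rep(0, 10))
  expect_error(detect_entry_onset(flat, 2), "no entry event")
  # robust to baseline noise well below the threshold
  set.seed(101)
  noisy <- make_clean_trajectory(L_i = 6, L_t = 12, L_e = 20, noise = 0.2)
  expect_identical(detect_entry_onset(noisy, 2), 101L)
})

test_that("entry lengths are recovered from the creep law", {
  traj <- make_clean_trajectory(L_i = 9, L_t = 18, L_e = 28, tau = 0.05)
  onset <- detect_entry_onset(traj, 2)
  ent <- extract_entry_lengths(traj, onset)
  expect_identical(ent$method, "exp_fit")
  expect_equal(ent$L_instantaneous, 9, tolerance = 1e-9)
  expect_equal(ent$L_transitional, 18, tolerance = 1e-6)
  expect_equal(ent$tau, 0.05, tolerance = 1e-6)
  # creep end = tau * log 20 past the onset for the default 95% criterion
  expect_equal(ent$creep_end_time - traj$time[onset], 0.05 * log(20),
               tolerance = 1e-5)
})

test_that("a trajectory with no creep frames is rejected", {
  # jump straight from 0 to 9 to plateau: no frames between the two jumps
  traj <- aspiration_trajectory((0:29) / 200, c(rep(0, 10), 9, rep(28, 19)))
  onset <- detect_entry_onset(traj, 2)
  expect_error(extract_entry_lengths(traj, onset), "too short")
})

test_that("noisy creep recovery stays within a few percent", {
  set.seed(202)
  traj <- make_clean_trajectory(L_i = 9, L_t = 18, L_e = 28, tau = 0.05,
                                noise = 0.25)
  ent <- extract_entry_lengths(traj, detect_entry_onset(traj, 2))
  expect_lt(abs(ent$L_transitional - 18) / 18, 0.03)
  expect_lt(abs(ent$L_instantaneous - 9) / 9, 0.1)
})

test_that("elongation is the median of the travel plateau", {
  traj <- make_clean_trajectory(L_i = 9, L_t = 18, L_e = 28.18, tau = 0.05)
  expect_equal(extract_elongation_length(traj, 0.8), 28.18)
  set.seed(303)
  noisy <- make_clean_trajectory(L_i = 9, L_t = 18, L_e = 28.18, tau = 0.05,
                                 noise = 0.25)
  expect_lt(abs(extract_elongation_length(noisy, 0.8) - 28.18), 0.2)
  # a monotone ramp has no plateau: value returned, loudly
  ramp <- aspiration_trajectory((0:99) / 200, seq(0, 49.5, by = 0.5))
  expect_warning(extract_elongation_length(ramp, 0.1), "not a plateau")
  expect_error(extract_elongation_length(traj, 10), "insufficient")
})

test_that("amplitude ratios come from the event plateau over the baseline", {
  trace <- make_clean_trace(A1 = 3.41, A2 = 1.17)
  r <- extract_amplitude_ratios(trace)
  expect_equal(r$A_1kHz, 3.41, tolerance = 1e-12)
  expect_equal(r$A_100kHz, 1.17, tolerance = 1e-12)
  expect_equal(r$phase_ratio_100kHz, -0.5, tolerance = 1e-12)
  # flat trace: nothing to detect
  flat <- impedance_trace((0:19) / 25, rep(1e6, 20), rep(0, 20),
                          rep(1e6, 20), rep(0, 20))
  expect_error(extract_amplitude_ratios(flat), "no impedance event")
  # event running into the end of the trace is unusable
  open_ended <- make_clean_trace(n_post = 0)
  expect_error(extract_amplitude_ratios(open_ended), "edge")
})

test_that("amplitude ratios survive 1% multiplicative noise", {
  trace <- make_clean_trace(A1 = 3.41, A2 = 1.17, amp_noise = 0.01, seed = 404)
  r <- extract_amplitude_ratios(trace)
  expect_lt(abs(r$A_1kHz - 3.41) / 3.41, 0.01)
  expect_lt(abs(r$A_100kHz - 1.17) / 1.17, 0.01)
})

test_that("extraction is invariant to time offset and amplitude rescale", {
  traj <- make_clean_trajectory()
  trace <- make_clean_trace()
  mk <- extract_markers(trace, traj)
  # camera and impedance clocks are arbitrary: shift both
  traj2 <- aspiration_trajectory(traj$time + 123.4, traj$length)
  trace2 <- impedance_trace(trace$time + 7.7, trace$amplitude_1kHz * 3.3,
                            trace$phase_1kHz, trace$amplitude_100kHz * 3.3,
                            trace$phase_100kHz)
  mk2 <- extract_markers(trace2, traj2)
  for (m in c("A_1kHz", "A_100kHz", "L_instantaneous", "L_transitional",
              "L_elongation"))
    expect_equal(mk2[[m]], mk[[m]], tolerance = 1e-12)
})

test_that("marker ordering violations warn rather than fail", {
  # slow creep towards an asymptote above the travel plateau: the fitted
  # L_transitional exceeds L_elongation
  traj <- make_clean_trajectory(L_i = 9, L_t = 30, L_e = 22, tau = 0.5)
  trace <- make_clean_trace()
  expect_warning(extract_markers(trace, traj), "ordering")
})

test_that("stream constructors enforce their invariants", {
  expect_error(impedance_trace((0:8) / 25, 1:9, 1:9, 1:9, 1:9), "10 samples")
  expect_error(aspiration_trajectory(c(0, 0.1, 0.1), c(1, 2, 3)),
               "strictly increasing")
  expect_error(aspiration_trajectory(c(0, 0.1), c(1, -2)), ">= 0")
})
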