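test_that("capacitance and leak are recovered from a synthetic triangle recording", {
  wf <- make_waveform("triangle", amplitude = 0.1, frequency = 2, n_cycles = 20)
  rec <- recording_model(
    capacitance_pf = 100, leak_ns = 0.05, noise_sigma = 0.01,
    sampling_rate = 1e4, seed = 11
  )
  # mostly dry pore so the pore conductance barely contaminates the leak
  tr <- synth_recording(constant_rates(0.2, 100), wf, conductance_params(), rec, duration = 10)
  fit <- subtract_capacitance(tr)
  truth <- attr(tr, "meta")
  expect_equal(fit$capacitance_pf, truth$capacitance_pf, tolerance = 0.01)
  expect_equal(fit$leak_ns, truth$leak_ns, tolerance = 0.10)
  # corrected trace equals pore + leak + noise: residual against the known
  # non-capacitive part is at the noise scale
  clean <- tr$I - truth$capacitance_pf * 1e-3 * wf_slope(wf, tr$t)
  expect_lt(sd(fit$trace$I - clean), 0.3 * truth$noise_sigma)
})

test_that("zero-capacitance recordings pass through nearly unchanged", {
  wf <- make_waveform("triangle", amplitude = 0.1, frequency = 2, n_cycles = 10)
  rec <- recording_model(
    capacitance_pf = 0, leak_ns = 0.05, noise_sigma = 0.01,
    sampling_rate = 1e4, seed = 4
  )
  tr <- synth_recording(constant_rates(0.2, 100), wf, conductance_params(), rec, duration = 5)
  fit <- subtract_capacitance(tr)
  expect_lt(abs(fit$capacitance_pf), 1)
  expect_lt(max(abs(fit$trace$I - tr$I)), 0.02)
  flat <- recorded_trace(seq(0, 1, 1e-3), rep(0.05, 1001), rnorm(1001, 0, 0.01), 1e3)
  expect_error(subtract_capacitance(flat), class = "hymn_no_dvdt")
})

test_that("cycle averaging is idempotent on noiseless traces and shrinks noise", {
  fix <- reference_fixture()
  wf <- make_waveform("triangle", amplitude = 3, frequency = 1e4)
  orb <- trace_current(hymn:::periodic_orbit(fix$rates, wf), conductance_params())
  # 35 identical cycles: the averaged loop equals the single-cycle loop
  n_rep <- 35
  m <- nrow(orb) - 1
  t35 <- seq(0, by = orb$t[2] - orb$t[1], length.out = m * n_rep)
  v35 <- rep(orb$V[1:m], n_rep)
  i35 <- rep(orb$I[1:m], n_rep)
  loop35 <- average_cycles(recorded_trace(t35, v35, i35, 1e4 * m), period = 1e-4)
  t2 <- seq(0, by = orb$t[2] - orb$t[1], length.out = 2 * m)
  loop1 <- average_cycles(
    recorded_trace(t2, rep(orb$V[1:m], 2), rep(orb$I[1:m], 2), 1e4 * m),
    period = 1e-4
  )
  expect_equal(loop35$I_forward, loop1$I_forward, tolerance = 1e-9)
  expect_equal(loop35$I_backward, loop1$I_backward, tolerance = 1e-9)
  # additive noise shrinks about sqrt(35)-fold after averaging
  sigma <- 0.05
  noisy <- i35 + with(list(), {
    set.seed(42)
    rnorm(length(i35), 0, sigma)
  })
  loopn <- average_cycles(recorded_trace(t35, v35, noisy, 1e4 * m), period = 1e-4)
  resid <- c(
    loopn$I_forward - loop35$I_forward,
    loopn$I_backward - loop35$I_backward
  )
  per_bin <- length(i35) / (2 * 200)
  expect_equal(sd(resid, na.rm = TRUE), sigma / sqrt(per_bin), tolerance = 0.25)
  expect_error(average_cycles(as_recording(orb[1:50, ]), period = 1e-4), "shorter")
})

test_that("a pure resistor yields coincident branches and no polarity", {
  t <- seq(0, 1, length.out = 4001)
  wf <- make_waveform("triangle", amplitude = 0.1, frequency = 5)
  v <- wf_voltage(wf, t)
  tr <- recorded_trace(t, v, 0.8 * v, sampling_rate = 4000)
  loop <- average_cycles(tr, period = 0.2)
  ok <- !is.na(loop$I_forward) & !is.na(loop$I_backward)
  # branches agree to within the voltage-bin discretisation (bin width 5e-4 V)
  expect_lt(max(abs(loop$I_forward[ok] - loop$I_backward[ok])), 1e-3)
  lm0 <- loop_metrics(loop, pinch_tol = 1e-3)
  expect_equal(lm0$total_area, 0, tolerance = 1e-4)
  expect_identical(lm0$polarity, "none")
  expect_true(lm0$pinched_at_origin)
})

test_that("polarity classifies voltage-symmetric models unipolar and dipole-driven bipolar", {
  fix <- reference_fixture()
  wf <- make_waveform("triangle", amplitude = 3, frequency = 1e4)
  orb <- trace_current(hymn:::periodic_orbit(fix$rates, wf), conductance_params())
  lu <- loop_metrics(average_cycles(as_recording(orb), period = 1e-4), pinch_tol = 1e-4)
  expect_identical(lu$polarity, "unipolar")
  expect_true(lu$pinched_at_origin)
  # point symmetry makes the two lobes carry the same signed area
  expect_equal(sign(lu$area_positive_lobe), sign(lu$area_negative_lobe))
  bfix <- bipolar_fixture()
  wfb <- make_waveform("triangle", amplitude = 0.1, frequency = 1)
  orb2 <- trace_current(
    hymn:::periodic_orbit(bfix$rates, wfb, steps_per_cycle = 4000),
    conductance_params()
  )
  lb <- loop_metrics(average_cycles(as_recording(orb2), period = 1), pinch_tol = 1e-4)
  expect_identical(lb$polarity, "bipolar")
  # the self-intersecting loop carries opposite-signed lobes
  expect_true(lb$area_positive_lobe * lb$area_negative_lobe < 0)
  # polarity is invariant to conductance scaling
  orb10 <- orb2
  orb10$I <- orb10$I * 10
  lb10 <- loop_metrics(average_cycles(as_recording(orb10), period = 1), pinch_tol = 1e-3)
  expect_identical(lb10$polarity, "bipolar")
})

test_that("branch-difference lobe area agrees with the shoelace polygon oracle", {
  fix <- reference_fixture()
  wf <- make_waveform("triangle", amplitude = 3, frequency = 1e4)
  orb <- trace_current(hymn:::periodic_orbit(fix$rates, wf), conductance_params())
  loop <- average_cycles(as_recording(orb), period = 1e-4)
  lm0 <- loop_metrics(loop, pinch_tol = 1e-4)
  expect_equal(abs(lm0$total_area), branch_shoelace_oracle(loop), tolerance = 1e-3)
})

test_that("the area spectrum scales linearly with conductance, leaving the argmax fixed", {
  rates <- scaled_reference_rates(1e-5)
  f_grid <- 10^seq(-2, 3, by = 0.5)
  sp1 <- area_vs_frequency(rates, 1.5, f_grid, conductance_params(g0 = 1), kind = "triangle")
  sp2 <- area_vs_frequency(rates, 1.5, f_grid, conductance_params(g0 = 3), kind = "triangle")
  expect_equal(sp2$area, 3 * sp1$area, tolerance = 1e-9)
  expect_equal(attr(sp1, "f_max"), attr(sp2, "f_max"))
})

test_that("telegraph statistics round-trip the generator within 10%", {
  wf <- make_waveform("constant", amplitude = 0.05)
  rec <- recording_model(
    capacitance_pf = 0, leak_ns = 0.05, noise_sigma = 0.01,
    sampling_rate = 1e4, seed = 3
  )
  tr <- synth_recording(constant_rates(50, 10), wf, conductance_params(), rec, duration = 60)
  ts <- telegraph_stats(tr)
  expect_equal(ts$occupancy_high, 50 / 60, tolerance = 0.03)
  expect_equal(ts$rate_lowhigh, 50, tolerance = 0.10)
  expect_equal(ts$rate_highlow, 10, tolerance = 0.10)
  expect_equal(ts$rate_lowhigh, 1 / ts$mean_dwell_low)
  expect_gte(ts$two_peak_fraction, 0.9)
  expect_lt(ts$level_low, ts$level_high)
  # conductance levels sit near leak and leak + g0
  expect_equal(ts$level_low, 0.05, tolerance = 0.5)
  expect_equal(ts$level_high, 1.05, tolerance = 0.05)
})

test_that("telegraph rate estimates tighten as the dwell count grows", {
  wf <- make_waveform("constant", amplitude = 0.05)
  errs <- vapply(c(10, 80), function(dur) {
    rec <- recording_model(
      capacitance_pf = 0, leak_ns = 0, noise_sigma = 0.005,
      sampling_rate = 1e4, seed = 21
    )
    tr <- synth_recording(constant_rates(20, 20), wf, conductance_params(), rec, duration = dur)
    ts <- telegraph_stats(tr)
    abs(ts$rate_lowhigh - 20) / 20
  }, numeric(1))
  expect_lt(errs[2], errs[1] + 0.03) # 1/sqrt(n) trend, with slack
})

test_that("single-level recordings are rejected as non-gating", {
  wf <- make_waveform("constant", amplitude = 0.05)
  rec <- recording_model(
    capacitance_pf = 0, leak_ns = 0, noise_sigma = 0.01,
    sampling_rate = 1e4, seed = 5
  )
  tr <- synth_recording(constant_rates(1e-6, 100), wf, conductance_params(), rec, duration = 5)
  expect_error(telegraph_stats(tr), class = "hymn_no_gating")
})
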