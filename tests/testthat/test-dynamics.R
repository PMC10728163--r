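test_that("waveform conventions: sawtooth ascends over the period, triangle spans +-A", {
  saw <- make_waveform("sawtooth", amplitude = 3, frequency = 1e4)
  T <- 1e-4
  expect_equal(wf_voltage(saw, 0), 0)
  expect_equal(wf_voltage(saw, T / 4), 0.75)
  expect_equal(wf_voltage(saw, T * 0.999), 3 * 0.999)
  tri <- make_waveform("triangle", amplitude = 2, frequency = 10)
  expect_equal(
    wf_voltage(tri, c(0, 0.025, 0.05, 0.075, 0.1)),
    c(0, 2, 0, -2, 0)
  )
  expect_equal(wf_voltage(make_waveform("constant", amplitude = 0), c(0, 1, 7)), rep(0, 3))
})

test_that("pulse trains encode the excitatory/inhibitory pattern", {
  wf <- synapse_protocol(runs = c(4, -2, 4), peak = 0.1, duration = 0.2)
  pw <- pulse_windows(wf)
  expect_equal(nrow(pw), 10)
  expect_equal(pw$polarity, c(1, 1, 1, 1, -1, -1, 1, 1, 1, 1))
  expect_equal(wf_duration(wf), 2)
  # peak of pulse 5 is negative
  expect_equal(wf_voltage(wf, 0.9), -0.1)
  expect_equal(wf_voltage(wf, 0.1), 0.1)
})

test_that("master-equation update is exact for constant rates", {
  cr <- constant_rates(7, 3)
  wf <- make_waveform("constant", amplitude = 0)
  tr <- integrate_master_equation(cr, wf, n0 = 0.2, t_end = 0.7, steps_per_cycle = 937)
  exact <- 0.7 + (0.2 - 0.7) * exp(-10 * tr$t)
  expect_lt(max(abs(tr$n - exact)), 1e-12)
  # fixed point stays put
  trf <- integrate_master_equation(cr, wf, n0 = 0.7, t_end = 1, steps_per_cycle = 100)
  expect_equal(trf$n, rep(0.7, nrow(trf)))
  # pure filling: n(1/k_w) = 1 - e^-1
  gr <- integrate_master_equation(constant_rates(1, 1e-14), wf,
    n0 = 0, t_end = 1, steps_per_cycle = 1000
  )
  expect_equal(gr$n[nrow(gr)], 1 - exp(-1), tolerance = 1e-9)
})

test_that("wet probability stays within [0, 1] across a harsh sweep", {
  fix <- reference_fixture()
  wf <- make_waveform("sawtooth", amplitude = 3, frequency = 1e5, n_cycles = 5)
  tr <- integrate_master_equation(fix$rates, wf, n0 = 0)
  expect_true(all(tr$n >= 0 & tr$n <= 1))
})

test_that("stochastic arrays are reproducible by seed and telegraphic for one pore", {
  cr <- constant_rates(50, 10)
  wf <- make_waveform("constant", amplitude = 0.05)
  a1 <- simulate_pore_array(cr, wf, n_pores = 1, seed = 7, dt = 1e-4, t_end = 2)
  a2 <- simulate_pore_array(cr, wf, n_pores = 1, seed = 7, dt = 1e-4, t_end = 2)
  a3 <- simulate_pore_array(cr, wf, n_pores = 1, seed = 8, dt = 1e-4, t_end = 2)
  expect_identical(a1$n, a2$n)
  expect_false(identical(a1$n, a3$n))
  expect_true(all(a1$n %in% c(0, 1))) # random telegraph signal
  expect_error(
    simulate_pore_array(cr, wf, n_pores = 1, seed = 1, dt = 0.01, t_end = 1),
    class = "hymn_dt_too_coarse"
  )
  expect_error(
    simulate_pore_array(cr, wf, n_pores = 1, seed = NULL, dt = 1e-4, t_end = 1),
    class = "hymn_missing_seed"
  )
})

test_that("large arrays hover within binomial error of the equilibrium fixed point", {
  cr <- constant_rates(50, 10)
  wf <- make_waveform("constant", amplitude = 0.05)
  n_eq <- 50 / 60
  arr <- simulate_pore_array(cr, wf, n_pores = 1e4, seed = 12, dt = 1e-3, t_end = 1)
  t_avg <- mean(arr$n[arr$t > 0.1])
  expect_lt(abs(t_avg - n_eq), 3 * sqrt(n_eq * (1 - n_eq) / 1e4))
})

test_that("current and energy follow the constitutive relation", {
  tr <- hymn:::new_ensemble_trace(
    t = seq(0, 1, length.out = 101), V = rep(0.05, 101), n = rep(1, 101),
    mode = "deterministic"
  )
  out <- trace_current(tr, conductance_params(g0 = 1, n_pores = 1))
  expect_equal(out$I, rep(0.05, 101)) # 1 nS x 0.05 V = 0.05 nA
  out2 <- trace_current(tr, conductance_params(g0 = 1, n_pores = 2))
  expect_equal(out2$I, 2 * out$I)
  # V = 0 pins the loop to the origin
  tr0 <- hymn:::new_ensemble_trace(
    t = seq(0, 1, length.out = 11), V = rep(0, 11), n = runif(11),
    mode = "deterministic"
  )
  expect_equal(trace_current(tr0)$I, rep(0, 11))
  # constant 1 nS at 0.1 V for 1 s dissipates 10 pJ, monotonically
  trE <- hymn:::new_ensemble_trace(
    t = seq(0, 1, length.out = 1001), V = rep(0.1, 1001), n = rep(1, 1001),
    mode = "deterministic"
  )
  en <- dissipated_energy(trace_current(trE))
  expect_equal(tail(en, 1), 1e-11, tolerance = 1e-9)
  expect_true(all(diff(en) >= 0))
  expect_equal(dissipated_energy(trace_current(tr0)), rep(0, 11))
})

test_that("per-pulse conductance change is zero for a frozen (resistor) state", {
  wf <- synapse_protocol()
  t <- seq(0, wf_duration(wf), length.out = 4001)
  tr <- hymn:::new_ensemble_trace(
    t = t, V = wf_voltage(wf, t), n = rep(0.5, length(t)),
    mode = "deterministic"
  )
  pc <- pulse_conductance_change(trace_current(tr), wf)
  expect_equal(pc$change_pct, rep(0, 10), tolerance = 1e-9)
  expect_equal(pc$change_pct[1], 0) # pulse 1 vs itself
  expect_error(
    pulse_conductance_change(
      trace_current(tr),
      make_waveform("pulse_train",
        pulse_spec = tibble::tibble(polarity = 1, peak = 0.1, duration = 0.2)
      )
    ),
    "at least 2"
  )
})

test_that("stochastic ensemble mean tracks the master equation within binomial bands", {
  # moderate test-time version of the convergence property; the acceptance
  # suite runs the full 200-seed x 1e4-pore check
  cr <- constant_rates(50, 10)
  wf <- make_waveform("constant", amplitude = 0.05)
  n_seeds <- 40
  n_pores <- 2000
  acc <- 0
  for (s in seq_len(n_seeds)) {
    acc <- acc + simulate_pore_array(cr, wf,
      n_pores = n_pores, seed = 100 + s,
      dt = 1e-3, t_end = 0.05, n0 = 0
    )$n
  }
  mean_n <- acc / n_seeds
  ode <- integrate_master_equation(cr, wf, n0 = 0, t_end = 0.05, steps_per_cycle = 50)
  sigma <- sqrt(pmax(ode$n * (1 - ode$n), 1e-12) / (n_seeds * n_pores))
  expect_true(all(abs(mean_n - ode$n) <= pmax(4 * sigma, 2e-4)))
})

test_that("deterministic IV is antisymmetric under (V, I) -> (-V, -I) for mu = 0", {
  fix <- reference_fixture()
  wf <- make_waveform("triangle", amplitude = 3, frequency = 1e4)
  orb <- trace_current(hymn:::periodic_orbit(fix$rates, wf), conductance_params())
  m <- nrow(orb) - 1 # duplicated endpoint
  # half-period shift flips the sign of both V and I on the periodic orbit
  half <- m / 2
  i <- seq_len(half)
  j <- (i - 1 + half) %% m + 1
  expect_equal(orb$V[j], -orb$V[i], tolerance = 1e-9)
  expect_lt(max(abs(orb$I[j] + orb$I[i])), 1e-6)
})

test_that("loop area vanishes in the quasi-static and frozen limits away from barrier collapse", {
  rates <- scaled_reference_rates(1e-5)
  f_grid <- 10^seq(-4, 4, by = 0.5)
  sp <- area_vs_frequency(rates, amplitude = 1.5, f_grid = f_grid, kind = "triangle")
  rel <- sp$area / max(sp$area)
  expect_lt(rel[1], 0.05)
  expect_lt(rel[length(rel)], 0.05)
  im <- which.max(sp$area)
  expect_gt(im, 1)
  expect_lt(im, length(f_grid))
})
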