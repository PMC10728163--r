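#' Parametric double-well filling profile
#'
#' Smooth double well built from monotone cubic segments through the control
#' points (dry minimum at height 0, saddle at `B_w`, wet minimum at
#' `B_w - B_d`), emulating the equilibrium filling free-energy landscape of a
#' bistable hydrophobic pore. Monotone interpolation guarantees no spurious
#' extrema, so [locate_states()] recovers the inputs exactly (within one grid
#' step). Profile edges outside the minima rise by half the smaller barrier
#' so that both minima are interior.
#'
#' @param B_w Wetting barrier (dry minimum to saddle), kBT (> 0).
#' @param B_d Drying barrier (wet minimum to saddle), kBT (> 0).
#' @param xi_dry,xi_saddle,xi_wet Control positions,
#'   `0 <= xi_dry < xi_saddle < xi_wet <= 1`.
#' @param grid_size Number of grid points.
#' @return A [filling_profile()] at 0 V with gap `B_w - B_d`.
#' @examples
#' prof <- make_double_well() # the 18/5 kBT reference well
#' locate_states(prof)
#' @export
make_double_well <- function(B_w = 18, B_d = 5, xi_dry = 0.15,
                             xi_saddle = 0.5, xi_wet = 0.9, grid_size = 201) {
  if (!(xi_dry >= 0 && xi_dry < xi_saddle && xi_saddle < xi_wet && xi_wet <= 1)) {
    abort("need 0 <= xi_dry < xi_saddle < xi_wet <= 1")
  }
  if (B_w <= 0 || B_d <= 0) abort("barriers must be > 0")
  lift <- 0.5 * min(B_w, B_d)
  px <- c(xi_dry, xi_saddle, xi_wet)
  py <- c(0, B_w, B_w - B_d)
  if (xi_dry > 0) {
    px <- c(0, px)
    py <- c(lift, py)
  }
  if (xi_wet < 1) {
    px <- c(px, 1)
    py <- c(py, B_w - B_d + lift)
  }
  # C1 piecewise-cubic Hermite with zero slope at every control point:
  # each segment is the monotone smoothstep, so the only extrema are the
  # control points themselves
  xi <- seq(0, 1, length.out = grid_size)
  seg <- pmin(pmax(findInterval(xi, px), 1), length(px) - 1)
  u <- (xi - px[seg]) / (px[seg + 1] - px[seg])
  fe <- py[seg] + (py[seg + 1] - py[seg]) * (3 * u^2 - 2 * u^3)
  filling_profile(xi, fe,
    voltage = 0,
    metadata = sprintf("double-well Bw=%g Bd=%g", B_w, B_d)
  )
}

#' Reference memristive-pore model bundle
#'
#' The deterministic fixture used throughout: the 18/5 kBT double well
#' (minima at xi = 0.15 and 0.90, saddle at 0.50, gap 13 kBT), its quadratic
#' electrowetting coupling calibrated so the two minima are degenerate at
#' 1.2 V (a_ew approximately 12 kBT/V^2), Arrhenius kinetics with attempt
#' frequency 1e10 1/s, and rate curves tabulated on 601 voltages in
#' [-3, 3] V. Repeated calls return the identical (cached) bundle.
#'
#' @return A list with elements `profile` ([filling_profile()]),
#'   `ew` ([electrowetting()]), `model` ([rate_model()]) and
#'   `rates` (`hymn_rate_curves`).
#' @export
reference_fixture <- function() {
  if (!is.null(.hymn_cache$reference)) {
    return(.hymn_cache$reference)
  }
  profile <- make_double_well()
  ew <- calibrate_coupling(profile, target_vc = 1.2)
  model <- rate_model(prefactor = 1e10)
  rates <- rate_curves(profile, ew, model, v_grid = seq(-3, 3, length.out = 601))
  fix <- list(profile = profile, ew = ew, model = model, rates = rates)
  .hymn_cache$reference <- fix
  fix
}

#' Bipolar (dipole-dominated) synapse-demo model bundle
#'
#' A pore model that shows learning-and-forgetting under the
#' excitatory/inhibitory pulse protocol: a nearly degenerate double well with
#' 25 kBT barriers (equilibrium switching ~0.14 1/s, so the state persists
#' between 0.2 s pulses) and a dominant dipole coupling `mu_ew = 150` kBT/V,
#' so that +/- 100 mV pulses tilt the landscape by ~5 kBT in opposite
#' directions: positive voltage wets (potentiation), negative dries
#' (depression). These constants are declared fixture values, not measured
#' ones; see the methods vignette.
#'
#' @inherit reference_fixture return
#' @export
bipolar_fixture <- function() {
  if (!is.null(.hymn_cache$bipolar)) {
    return(.hymn_cache$bipolar)
  }
  profile <- make_double_well(B_w = 25, B_d = 25)
  ew <- electrowetting(a_ew = 12, mu_ew = 150)
  model <- rate_model(prefactor = 1e10)
  rates <- rate_curves(profile, ew, model, v_grid = seq(-0.3, 0.3, length.out = 241))
  fix <- list(profile = profile, ew = ew, model = model, rates = rates)
  .hymn_cache$bipolar <- fix
  fix
}

#' Recording model for synthetic electrophysiology traces
#'
#' Instrumental components added on top of the pore current: membrane
#' capacitance, ohmic leak through the membrane/seal, and Gaussian current
#' noise, at a stated sampling rate. Defaults follow typical planar-bilayer
#' recordings: 100 pF membrane, 0.05 nS leak, 10 kHz sampling.
#'
#' @param capacitance_pf Membrane capacitance, pF.
#' @param leak_ns Leak conductance, nS.
#' @param noise_sigma Current noise SD, nA.
#' @param sampling_rate Sampling frequency, Hz.
#' @param seed Mandatory RNG seed.
#' @return An object of class `hymn_recording_model`.
#' @export
recording_model <- function(capacitance_pf = 100, leak_ns = 0.05,
                            noise_sigma = 0.01, sampling_rate = 1e4, seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory", class = "hymn_missing_seed")
  }
  if (capacitance_pf < 0 || leak_ns < 0 || noise_sigma < 0) {
    abort("recording-model components must be non-negative")
  }
  structure(
    list(
      capacitance_pf = capacitance_pf, leak_ns = leak_ns,
      noise_sigma = noise_sigma, sampling_rate = sampling_rate,
      seed = as.integer(seed)
    ),
    class = "hymn_recording_model"
  )
}

#' Synthetic electrophysiology recording
#'
#' Generates a ground-truth recording:
#' `I(t) = N_p g0 s(t) V(t) + C dV/dt + G_leak V(t) + noise`, with `s(t)` the
#' stochastic wet fraction of the pore array from [simulate_pore_array()]
#' sampled at the recording rate. All true parameters (including the seed)
#' are stored in the trace metadata; analysis round-trips read the truth only
#' from there.
#'
#' @inheritParams simulate_pore_array
#' @param cp A [conductance_params()].
#' @param rec A [recording_model()] (carries the seed).
#' @param duration Recording length, s.
#' @return A [recorded_trace()].
#' @examples
#' wf <- make_waveform("constant", amplitude = 0.05)
#' rec <- recording_model(capacitance_pf = 0, leak_ns = 0, noise_sigma = 0, seed = 1)
#' tr <- synth_recording(constant_rates(50, 10), wf, conductance_params(), rec, 0.5)
#' @export
synth_recording <- function(rates, wf, cp = conductance_params(),
                            rec, duration) {
  stopifnot(
    inherits(wf, "hymn_waveform"), inherits(cp, "hymn_conductance"),
    inherits(rec, "hymn_recording_model")
  )
  dt <- 1 / rec$sampling_rate
  if (duration < 2 * dt) abort("`duration` must cover at least 2 samples")
  arr <- simulate_pore_array(rates, wf,
    n_pores = cp$n_pores, seed = rec$seed,
    dt = dt, t_end = duration
  )
  t <- arr$t
  v <- arr$V
  slope <- wf_slope(wf, t)
  noise <- with_local_seed(rec$seed + 1L, rnorm(length(t), 0, rec$noise_sigma))
  i <- cp$n_pores * cp$g0 * arr$n * v +
    rec$capacitance_pf * 1e-3 * slope + # pF * V/s = 1e-3 nA
    rec$leak_ns * v + noise
  recorded_trace(t, v, i,
    sampling_rate = rec$sampling_rate,
    meta = list(
      seed = rec$seed, g0 = cp$g0, n_pores = cp$n_pores,
      capacitance_pf = rec$capacitance_pf, leak_ns = rec$leak_ns,
      noise_sigma = rec$noise_sigma, waveform = wf
    )
  )
}
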