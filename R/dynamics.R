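#' Conductance parameters of a pore ensemble
#'
#' @param g0 Single wet-pore conductance, nS.
#' @param n_pores Number of independent pores.
#' @return An object of class `hymn_conductance`.
#' @export
conductance_params <- function(g0 = 1, n_pores = 1) {
  if (g0 <= 0) abort("`g0` must be > 0")
  if (n_pores < 1) abort("`n_pores` must be >= 1")
  structure(list(g0 = g0, n_pores = as.integer(n_pores)),
    class = "hymn_conductance"
  )
}

new_ensemble_trace <- function(t, V, n, mode, seed = NULL, params = list()) {
  new_tibble(
    list(t = t, V = V, n = n),
    nrow = length(t), class = "hymn_trace",
    mode = mode, seed = seed, params = params
  )
}

## per-step integration grid for a waveform: step ends `t`, midpoints `tm`
dyn_grid <- function(wf, t_end, steps_per_cycle) {
  dt_cycle <- switch(wf$kind,
    constant = t_end,
    pulse_train = min(wf$pulse_spec$duration),
    1 / wf$frequency
  )
  dt <- dt_cycle / steps_per_cycle
  n_steps <- max(1L, ceiling(t_end / dt - 1e-9))
  dt <- t_end / n_steps
  t <- seq_len(n_steps) * dt
  list(t = t, tm = t - dt / 2, dt = dt)
}

## exact piecewise-constant-rate update, sequential over steps.
## Returns n at step ends. E, ninf are per-step vectors.
propagate_n <- function(n0, ninf, E) {
  n <- numeric(length(E))
  cur <- n0
  for (i in seq_along(E)) {
    cur <- ninf[i] + (cur - ninf[i]) * E[i]
    n[i] <- cur
  }
  n
}

#' Integrate the two-state master equation
#'
#' Evolves the wet-pore probability under
#' `dn/dt = (1 - n) k_wet(V) - n k_dry(V)` with the voltage sampled at step
#' midpoints and the exact constant-rate solution applied per step:
#' `n <- n_inf + (n - n_inf) exp(-(k_wet + k_dry) dt)`. The update is
#' unconditionally stable and keeps `n` in [0, 1] to machine precision.
#'
#' @param rates A `hymn_rate_curves` (or [constant_rates()]) covering the
#'   waveform's voltage range.
#' @param wf A [make_waveform()].
#' @param n0 Initial wet probability; default the equilibrium value at V(0).
#' @param t_end End time, s; defaults to the waveform duration
#'   (`n_cycles` periods or the full pulse train).
#' @param steps_per_cycle Time steps per period (per shortest pulse for pulse
#'   trains; over `t_end` for constant waveforms).
#' @return A tibble of class `hymn_trace` with columns `t`, `V`, `n` and
#'   attribute `mode = "deterministic"`. Pipe into [trace_current()] to add
#'   the current.
#' @examples
#' fix <- reference_fixture()
#' wf <- make_waveform("sawtooth", amplitude = 3, frequency = 1e4, n_cycles = 3)
#' tr <- integrate_master_equation(fix$rates, wf)
#' @export
integrate_master_equation <- function(rates, wf, n0 = NULL, t_end = NULL,
                                      steps_per_cycle = 2000) {
  stopifnot(inherits(wf, "hymn_waveform"))
  t_end <- t_end %||% wf_duration(wf)
  if (is.na(t_end)) abort("`t_end` is required for constant waveforms")
  g <- dyn_grid(wf, t_end, steps_per_cycle)
  vm <- wf_voltage(wf, g$tm)
  k <- rates_at(rates, vm)
  ktot <- k$k_wet + k$k_dry
  ninf <- ifelse(ktot > 0, k$k_wet / pmax(ktot, .Machine$double.xmin), 0)
  if (is.null(n0)) {
    k0 <- rates_at(rates, wf_voltage(wf, 0))
    n0 <- k0$k_wet / (k0$k_wet + k0$k_dry)
  }
  if (n0 < 0 || n0 > 1) abort("`n0` must lie in [0, 1]")
  n <- propagate_n(n0, ninf, exp(-ktot * g$dt))
  new_ensemble_trace(
    t = c(0, g$t), V = wf_voltage(wf, c(0, g$t)), n = c(n0, n),
    mode = "deterministic",
    params = list(waveform = wf, n0 = n0, steps_per_cycle = steps_per_cycle)
  )
}

## Periodic orbit of the master equation under a periodic waveform.
## One cycle of the exact update is affine in n0 (n_end = A n0 + B with
## 0 <= A < 1), so the fixed point n* = B/(1-A) is found from two cycle
## integrations and the returned trace is exactly the periodic orbit.
periodic_orbit <- function(rates, wf, steps_per_cycle = 2000) {
  period <- wf_period(wf)
  g <- dyn_grid(wf, period, steps_per_cycle)
  vm <- wf_voltage(wf, g$tm)
  k <- rates_at(rates, vm)
  ktot <- k$k_wet + k$k_dry
  ninf <- ifelse(ktot > 0, k$k_wet / pmax(ktot, .Machine$double.xmin), 0)
  E <- exp(-ktot * g$dt)
  b <- propagate_n(0, ninf, E)
  a_end <- prod(E)
  if (!is.finite(a_end) || a_end >= 1) {
    abort("periodic orbit did not converge (zero total rate over the cycle)",
      class = "hymn_no_periodic_orbit"
    )
  }
  nstar <- b[length(b)] / (1 - a_end)
  n <- propagate_n(nstar, ninf, E)
  new_ensemble_trace(
    t = c(0, g$t), V = wf_voltage(wf, c(0, g$t)), n = c(nstar, n),
    mode = "deterministic",
    params = list(waveform = wf, n0 = nstar, steps_per_cycle = steps_per_cycle)
  )
}

#' Stochastic simulation of an independent pore array
#'
#' Each of `n_pores` pores is a two-state Markov chain with the
#' voltage-dependent rates; per time step a pore flips with the exact
#' conditional probability for the step (piecewise-constant voltage), so the
#' ensemble mean is unbiased with respect to the master equation. `n(t)` is
#' the wet fraction of the array; a single pore yields a random telegraph
#' signal.
#'
#' @inheritParams integrate_master_equation
#' @param n_pores Number of pores.
#' @param seed Mandatory RNG seed; the same seed reproduces the trace
#'   bit-for-bit and the caller's RNG state is untouched.
#' @param dt Time step, s; must satisfy `dt <= 0.1 / max(rate)` over the
#'   protocol's voltage range (error of class `hymn_dt_too_coarse`
#'   otherwise).
#' @param n0 Initial wet probability used to draw initial pore states.
#' @return A `hymn_trace` with `mode = "stochastic"` and the seed recorded.
#' @export
simulate_pore_array <- function(rates, wf, n_pores, seed, dt, t_end = NULL,
                                n0 = NULL) {
  stopifnot(inherits(wf, "hymn_waveform"))
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory for stochastic runs", class = "hymn_missing_seed")
  }
  t_end <- t_end %||% wf_duration(wf)
  if (is.na(t_end)) abort("`t_end` is required for constant waveforms")
  n_steps <- max(1L, floor(t_end / dt + 1e-9))
  tm <- (seq_len(n_steps) - 0.5) * dt
  vm <- wf_voltage(wf, tm)
  kmax <- rates_max(rates, min(vm), max(vm))
  if (dt > 0.1 / kmax) {
    abort(sprintf(
      "dt = %g s too coarse: need dt <= 0.1/max(rate) = %g s",
      dt, 0.1 / kmax
    ), class = "hymn_dt_too_coarse")
  }
  k <- rates_at(rates, vm)
  ktot <- k$k_wet + k$k_dry
  ninf <- ifelse(ktot > 0, k$k_wet / pmax(ktot, .Machine$double.xmin), 0)
  relax <- 1 - exp(-ktot * dt)
  if (is.null(n0)) {
    k0 <- rates_at(rates, wf_voltage(wf, 0))
    n0 <- k0$k_wet / (k0$k_wet + k0$k_dry)
  }
  n <- numeric(n_steps)
  n0_realised <- NA_real_
  with_local_seed(seed, {
    s <- runif(n_pores) < n0 # TRUE = wet
    n0_realised <- mean(s)
    for (i in seq_len(n_steps)) {
      # exact per-step flip probabilities toward the instantaneous equilibrium
      p_flip <- ifelse(s, (1 - ninf[i]) * relax[i], ninf[i] * relax[i])
      s <- xor(s, runif(n_pores) < p_flip)
      n[i] <- mean(s)
    }
  })
  new_ensemble_trace(
    t = c(0, seq_len(n_steps) * dt), V = wf_voltage(wf, c(0, seq_len(n_steps) * dt)),
    n = c(n0_realised, n), mode = "stochastic", seed = seed,
    params = list(waveform = wf, n0 = n0, dt = dt, n_pores = n_pores)
  )
}

#' Current through the pore ensemble
#'
#' `I = n_pores g0 n V` (nS x V = nA), the memristive constitutive relation:
#' conductance is `g0` times the wet fraction.
#'
#' @param trace A `hymn_trace` with `n` filled.
#' @param cp A [conductance_params()].
#' @return The trace with an added `I` column (nA).
#' @export
trace_current <- function(trace, cp = conductance_params()) {
  stopifnot(inherits(trace, "hymn_trace"), inherits(cp, "hymn_conductance"))
  trace$I <- cp$n_pores * cp$g0 * trace$n * trace$V
  attr(trace, "conductance") <- cp
  trace
}

#' Cumulative dissipated energy
#'
#' Trapezoidal cumulative integral of the electric power `I V` along the
#' trace, in joules. Monotone non-decreasing because current and voltage
#' share sign through the constitutive relation.
#'
#' @param trace A `hymn_trace` with `I` filled (nA).
#' @return Numeric vector, cumulative energy in J at each sample.
#' @export
dissipated_energy <- function(trace) {
  stopifnot(inherits(trace, "hymn_trace"))
  if (is.null(trace$I)) abort("trace has no current; call trace_current() first")
  as.vector(cumtrapz(trace$t, trace$I * trace$V * 1e-9))
}

#' Per-pulse conductance change
#'
#' Mean conductance `G = I/V` during each pulse of a pulse-train protocol,
#' averaged over samples with `|V|` at or above a floor fraction of the pulse
#' peak (avoiding 0/0 at the pulse edges), expressed as percent change
#' relative to the first pulse.
#'
#' @param trace A `hymn_trace` with `I` filled, simulated under `wf`.
#' @param wf The pulse-train [make_waveform()] that drove the trace.
#' @param v_floor_frac Voltage floor as a fraction of each pulse peak.
#' @return A tibble with one row per pulse: `pulse`, `polarity`,
#'   `conductance` (nS) and `change_pct` (% vs pulse 1).
#' @export
pulse_conductance_change <- function(trace, wf, v_floor_frac = 0.05) {
  stopifnot(inherits(trace, "hymn_trace"))
  pw <- pulse_windows(wf)
  if (nrow(pw) < 2) abort("need at least 2 pulses")
  g <- pmap(pw, function(pulse, polarity, peak, t_start, t_end) {
    sel <- trace$t >= t_start & trace$t <= t_end &
      abs(trace$V) >= v_floor_frac * peak
    mean(trace$I[sel] / trace$V[sel])
  })
  g <- unlist(g)
  tibble(
    pulse = pw$pulse, polarity = pw$polarity, conductance = g,
    change_pct = 100 * (g / g[1] - 1)
  )
}
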