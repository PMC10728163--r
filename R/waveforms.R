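#' Voltage waveforms
#'
#' Driving protocols used by the dynamical models and the synthetic
#' recording generator.
#'
#' Conventions:
#' * `constant` - `V(t) = amplitude + offset`.
#' * `sawtooth` - linear ascent from 0 to `amplitude` over one period, then
#'   an instantaneous reset; phase 0 at t = 0.
#' * `triangle` - symmetric ascent/descent spanning `-amplitude` to
#'   `+amplitude`: 0 up to +A at T/4, down to -A at 3T/4, back to 0.
#' * `pulse_train` - consecutive triangular pulses `0 -> polarity*peak -> 0`,
#'   each over its own `duration`, given as a data frame `pulse_spec` with
#'   columns `polarity` (+1/-1), `peak` (V, > 0) and `duration` (s, > 0).
#'
#' @param kind One of "constant", "sawtooth", "triangle", "pulse_train".
#' @param amplitude Peak voltage, V (periodic kinds; level for constant).
#' @param frequency Cycling frequency, Hz (periodic kinds).
#' @param n_cycles Number of cycles defining the default duration.
#' @param offset Additive offset, V.
#' @param pulse_spec Pulse table for `kind = "pulse_train"`.
#' @return An object of class `hymn_waveform`.
#' @examples
#' wf <- make_waveform("sawtooth", amplitude = 3, frequency = 1e4)
#' wf_voltage(wf, c(0, 2.5e-5, 5e-5))
#' @export
make_waveform <- function(kind = c("constant", "sawtooth", "triangle", "pulse_train"),
                          amplitude = 0, frequency = NULL, n_cycles = 1,
                          offset = 0, pulse_spec = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("sawtooth", "triangle")) {
    if (is.null(frequency) || frequency <= 0) {
      abort("periodic waveforms need `frequency` > 0")
    }
  }
  if (kind == "pulse_train") {
    pulse_spec <- as_tibble(pulse_spec)
    need <- c("polarity", "peak", "duration")
    if (!all(need %in% names(pulse_spec)) || nrow(pulse_spec) == 0) {
      abort("`pulse_spec` needs columns polarity, peak, duration (>= 1 pulse)")
    }
    if (any(pulse_spec$duration <= 0) || any(pulse_spec$peak <= 0)) {
      abort("pulse peaks and durations must be > 0")
    }
    if (!all(pulse_spec$polarity %in% c(-1, 1))) {
      abort("pulse `polarity` must be +1 or -1")
    }
  }
  structure(
    list(
      kind = kind, amplitude = amplitude, frequency = frequency,
      n_cycles = n_cycles, offset = offset, pulse_spec = pulse_spec
    ),
    class = "hymn_waveform"
  )
}

#' @rdname make_waveform
#' @param wf A `hymn_waveform`.
#' @param t Times, s (>= 0).
#' @return `wf_voltage()`: voltages at `t`, V.
#' @export
wf_voltage <- function(wf, t) {
  stopifnot(inherits(wf, "hymn_waveform"))
  v <- switch(wf$kind,
    constant = rep(wf$amplitude, length(t)),
    sawtooth = {
      ph <- (t * wf$frequency) %% 1
      wf$amplitude * ph
    },
    triangle = {
      ph <- (t * wf$frequency) %% 1
      wf$amplitude * ifelse(ph < 0.25, 4 * ph,
        ifelse(ph < 0.75, 2 - 4 * ph, 4 * ph - 4)
      )
    },
    pulse_train = {
      ps <- wf$pulse_spec
      ends <- cumsum(ps$duration)
      starts <- c(0, head(ends, -1))
      i <- findInterval(t, ends, left.open = TRUE) + 1L
      i <- pmin(i, nrow(ps))
      ph <- (t - starts[i]) / ps$duration[i]
      ph <- pmin(pmax(ph, 0), 1)
      ps$polarity[i] * ps$peak[i] * ifelse(ph < 0.5, 2 * ph, 2 * (1 - ph)) *
        (t <= ends[nrow(ps)] + 1e-15)
    }
  )
  v + wf$offset
}

#' @rdname make_waveform
#' @return `wf_slope()`: piecewise dV/dt at `t`, V/s (the value of the
#'   following segment at vertices and resets).
#' @export
wf_slope <- function(wf, t) {
  stopifnot(inherits(wf, "hymn_waveform"))
  switch(wf$kind,
    constant = rep(0, length(t)),
    sawtooth = rep(wf$amplitude * wf$frequency, length(t)),
    triangle = {
      ph <- (t * wf$frequency) %% 1
      4 * wf$amplitude * wf$frequency * ifelse(ph >= 0.25 & ph < 0.75, -1, 1)
    },
    pulse_train = {
      ps <- wf$pulse_spec
      ends <- cumsum(ps$duration)
      starts <- c(0, head(ends, -1))
      i <- findInterval(t, ends, left.open = TRUE) + 1L
      i <- pmin(i, nrow(ps))
      ph <- (t - starts[i]) / ps$duration[i]
      s <- 2 * ps$polarity[i] * ps$peak[i] / ps$duration[i]
      ifelse(ph < 0.5, s, -s) * (t <= ends[nrow(ps)] + 1e-15)
    }
  )
}

#' @rdname make_waveform
#' @return `wf_period()`: the period, s (NA for constant waveforms; the total
#'   pulse-train duration for pulse trains).
#' @export
wf_period <- function(wf) {
  stopifnot(inherits(wf, "hymn_waveform"))
  switch(wf$kind,
    constant = NA_real_,
    pulse_train = sum(wf$pulse_spec$duration),
    1 / wf$frequency
  )
}

#' @rdname make_waveform
#' @return `wf_duration()`: default protocol duration, s (`n_cycles` periods,
#'   or the full pulse train).
#' @export
wf_duration <- function(wf) {
  stopifnot(inherits(wf, "hymn_waveform"))
  switch(wf$kind,
    constant = NA_real_,
    pulse_train = sum(wf$pulse_spec$duration),
    wf$n_cycles / wf$frequency
  )
}

#' Pulse windows of a pulse-train waveform
#'
#' @param wf A pulse-train `hymn_waveform`.
#' @return A tibble with one row per pulse: `pulse`, `polarity`, `peak`,
#'   `t_start`, `t_end`.
#' @export
pulse_windows <- function(wf) {
  stopifnot(inherits(wf, "hymn_waveform"))
  if (wf$kind != "pulse_train") abort("`wf` is not a pulse train")
  ps <- wf$pulse_spec
  ends <- cumsum(ps$duration)
  tibble(
    pulse = seq_len(nrow(ps)), polarity = ps$polarity, peak = ps$peak,
    t_start = c(0, head(ends, -1)), t_end = ends
  )
}

#' Excitatory/inhibitory synapse protocol
#'
#' The learning-and-forgetting stimulation pattern: runs of positive
#' (excitatory) and negative (inhibitory) triangular pulses, e.g. the
#' default `c(4, -2, 4)` meaning 4 positive, 2 negative, 4 positive.
#'
#' @param runs Integer run lengths; the sign of each entry is the polarity.
#' @param peak Pulse peak voltage, V.
#' @param duration Single-pulse duration, s.
#' @return A pulse-train [make_waveform()].
#' @export
synapse_protocol <- function(runs = c(4, -2, 4), peak = 0.1, duration = 0.2) {
  pol <- unlist(map(runs, function(r) rep(sign(r), abs(r))))
  make_waveform("pulse_train",
    pulse_spec = tibble(polarity = pol, peak = peak, duration = duration)
  )
}
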