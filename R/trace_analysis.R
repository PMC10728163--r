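#' Recorded current trace
#'
#' A uniformly sampled electrophysiology-style recording: time, applied
#' voltage and measured current.
#'
#' @param t Sample times, s (uniform).
#' @param V Applied voltage, V.
#' @param I Measured current, nA.
#' @param sampling_rate Sampling frequency, Hz.
#' @param meta Provenance list; synthetic generators store the ground-truth
#'   parameters here.
#' @return A tibble of class `hymn_recording`.
#' @export
recorded_trace <- function(t, V, I, sampling_rate, meta = list()) {
  if (!(length(t) == length(V) && length(t) == length(I))) {
    abort("`t`, `V`, `I` lengths differ")
  }
  if (length(t) > 2 && sd(diff(t)) > 1e-6 * mean(diff(t))) {
    abort("sampling must be uniform")
  }
  new_tibble(
    list(t = t, V = V, I = I),
    nrow = length(t), class = "hymn_recording",
    sampling_rate = sampling_rate, meta = meta
  )
}

#' Subtract the membrane capacitive current
#'
#' Estimates the membrane capacitance and ohmic leak jointly by least squares
#' of the current on the numerically differentiated voltage and the voltage
#' itself: `I ~ C dV/dt + G_leak V + (pore current)`. Under triangular or
#' sawtooth driving the sign flips of `dV/dt` decorrelate the capacitive
#' component from anything proportional to `V`, so the regression separates
#' them over whole cycles. Only the capacitive component is removed from the
#' trace; the leak estimate is reported but left in place (it is part of the
#' device response).
#'
#' `dV/dt` comes from central differences and samples adjacent to slope
#' reversals (triangle vertices, sawtooth resets) are excluded from the
#' regression.
#'
#' @param trace A [recorded_trace()] driven by a waveform with non-constant
#'   voltage.
#' @return A list of class `hymn_capacitance_fit`: `trace` (corrected
#'   recording), `capacitance_pf` (pF), `leak_ns` (nS), `sigma` (residual SD
#'   of the regression, nA).
#' @section Errors: constant-voltage traces (`dV/dt == 0`) raise
#'   `hymn_no_dvdt`.
#' @export
subtract_capacitance <- function(trace) {
  stopifnot(inherits(trace, "hymn_recording"))
  t <- trace$t
  v <- trace$V
  i <- trace$I
  m <- length(t)
  if (m < 5) abort("trace too short")
  dvdt <- c(NA, (v[3:m] - v[1:(m - 2)]) / (t[3:m] - t[1:(m - 2)]), NA)
  if (all(abs(dvdt[!is.na(dvdt)]) < 1e-12)) {
    abort("constant-voltage trace: capacitance cannot be estimated",
      class = "hymn_no_dvdt"
    )
  }
  # drop samples next to slope reversals, where the central difference mixes
  # the two branches
  vertex <- c(FALSE, diff(sign(c(diff(v), 0))) != 0)
  bad <- vertex | c(vertex[-1], FALSE) | c(FALSE, vertex[-m]) | is.na(dvdt)
  fit <- lm(i[!bad] ~ 0 + dvdt[!bad] + v[!bad])
  cf <- coef(fit)
  c_nafs <- unname(cf[1]) # nA per V/s  = 1e-9 F
  g_leak <- unname(cf[2]) # nA per V    = nS
  corrected <- recorded_trace(
    t, v, i - c_nafs * ifelse(is.na(dvdt), 0, dvdt),
    sampling_rate = attr(trace, "sampling_rate"),
    meta = c(attr(trace, "meta"), list(capacitance_subtracted = TRUE))
  )
  structure(
    list(
      trace = corrected, capacitance_pf = c_nafs * 1e3, leak_ns = g_leak,
      sigma = sd(fit$residuals)
    ),
    class = "hymn_capacitance_fit"
  )
}

#' Cycle-averaged IV loop
#'
#' Folds the trace modulo the driving period, splits ascending and descending
#' branches by the sign of `dV/dt`, and bin-averages the current onto a
#' common voltage grid.
#'
#' @param trace A [recorded_trace()] at least two periods long.
#' @param period Driving period, s.
#' @param n_bins Number of uniform voltage bins.
#' @return A tibble of class `hymn_iv_loop` with columns `V`, `I_forward`
#'   (ascending branch), `I_backward` and attributes `n_cycles` and
#'   `noise_se` (median standard error of the bin means, nA).
#' @export
average_cycles <- function(trace, period, n_bins = 200) {
  stopifnot(inherits(trace, "hymn_recording"))
  if (max(trace$t) - min(trace$t) < period) {
    abort("trace shorter than one driving period")
  }
  m <- nrow(trace)
  v <- trace$V
  dv <- c(v[2] - v[1], (v[3:m] - v[1:(m - 2)]) / 2, v[m] - v[m - 1])
  branch <- ifelse(dv > 0, "forward", ifelse(dv < 0, "backward", NA))
  edges <- seq(min(v), max(v), length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1), n_bins)
  df <- tibble(bin = bin, branch = branch, I = trace$I)
  df <- df[!is.na(df$branch), ]
  agg <- df |>
    group_by(.data$bin, .data$branch) |>
    summarise(
      I_mean = mean(.data$I), se = sd(.data$I) / sqrt(max(n(), 1)),
      .groups = "drop"
    )
  wide_i <- tidyr::pivot_wider(agg[, c("bin", "branch", "I_mean")],
    names_from = "branch", values_from = "I_mean"
  )
  full <- tibble(bin = seq_len(n_bins)) |>
    left_join(wide_i, by = "bin")
  if (is.null(full$forward)) full$forward <- NA_real_
  if (is.null(full$backward)) full$backward <- NA_real_
  n_cycles <- floor((max(trace$t) - min(trace$t)) / period)
  new_tibble(
    list(
      V = mids, I_forward = full$forward, I_backward = full$backward
    ),
    nrow = n_bins, class = "hymn_iv_loop",
    n_cycles = n_cycles,
    noise_se = median(agg$se, na.rm = TRUE)
  )
}

#' Hysteresis-loop metrics
#'
#' Signed lobe areas of the loop by trapezoidal integration of
#' `I_forward - I_backward` over positive and negative voltages, a pinch
#' test at the origin, and the memristor polarity class.
#'
#' Polarity uses the point symmetry of the closed loop: a unipolar (state
#' driven by |V|) loop maps onto itself under `(V, I) -> (-V, -I)`, i.e. the
#' ascending branch at `V` matches minus the descending branch at `-V`; a
#' bipolar loop breaks that symmetry and self-intersects at the origin,
#' which shows up as oppositely signed lobe areas. Loops with negligible
#' area (or covering a single polarity) are classed `none`.
#'
#' @param loop A [average_cycles()] result covering the driving range.
#' @param pinch_tol Current tolerance (nA) for the origin pinch; defaults to
#'   3x the loop's `noise_se` attribute (or 1e-6 nA when absent).
#' @return An object of class `hymn_loop_metrics`: `area_positive_lobe`,
#'   `area_negative_lobe`, `total_area` (nA V), `pinched_at_origin`,
#'   `polarity`.
#' @export
loop_metrics <- function(loop, pinch_tol = NULL) {
  stopifnot(inherits(loop, "hymn_iv_loop"))
  ok <- !is.na(loop$I_forward) & !is.na(loop$I_backward)
  if (sum(ok) < 3) abort("degenerate loop: needs both branches on >= 3 bins")
  v <- loop$V[ok]
  dI <- loop$I_forward[ok] - loop$I_backward[ok]
  area_lobe <- function(sel) {
    if (sum(sel) < 2) {
      return(0)
    }
    trapz(v[sel], dI[sel])
  }
  a_pos <- area_lobe(v >= 0)
  a_neg <- area_lobe(v <= 0)
  tol <- pinch_tol %||% (3 * (attr(loop, "noise_se") %||% 0))
  if (!is.finite(tol) || tol <= 0) tol <- 1e-6
  i0f <- approx(v, loop$I_forward[ok], xout = 0, rule = 2)$y
  i0b <- approx(v, loop$I_backward[ok], xout = 0, rule = 2)$y
  pinched <- abs(i0f) <= tol && abs(i0b) <= tol
  scale_i <- max(abs(c(loop$I_forward[ok], loop$I_backward[ok])), 1e-300)
  v_span <- diff(range(v))
  tiny <- max(3 * tol * v_span, 0.005 * scale_i * v_span)
  two_sided <- min(v) < 0 && max(v) > 0
  polarity <- if (abs(a_pos) <= tiny && abs(a_neg) <= tiny) {
    "none"
  } else if (!two_sided) {
    "none"
  } else {
    # antisymmetry defect of the closed loop under (V, I) -> (-V, -I)
    fwd_at <- function(x) approx(v, loop$I_forward[ok], xout = x, rule = 2)$y
    bwd_at <- function(x) approx(v, loop$I_backward[ok], xout = x, rule = 2)$y
    grid <- seq(min(v), max(v), length.out = 101)
    defect <- sqrt(mean((fwd_at(grid) + bwd_at(-grid))^2)) /
      max(sqrt(mean(c(fwd_at(grid), bwd_at(grid))^2)), 1e-300)
    if (defect < 0.15) "unipolar" else "bipolar"
  }
  structure(
    list(
      area_positive_lobe = a_pos, area_negative_lobe = a_neg,
      total_area = a_pos + a_neg, pinched_at_origin = pinched,
      polarity = polarity
    ),
    class = "hymn_loop_metrics"
  )
}

#' Shoelace area of a closed sampled IV path
#'
#' Polygon (shoelace) area of the closed `(V, I)` cycle path, the quantity
#' tracked by [area_vs_frequency()].
#'
#' @param V,I Vertices of one full cycle (closure to the first vertex is
#'   implicit).
#' @return Absolute enclosed area, nA V.
#' @export
shoelace_area <- function(V, I) {
  if (length(V) != length(I) || length(V) < 3) abort("need >= 3 vertices")
  v2 <- c(V[-1], V[1])
  i2 <- c(I[-1], I[1])
  abs(sum(V * i2 - v2 * I)) / 2
}

#' Hysteresis-loop area versus cycling frequency
#'
#' For each frequency, finds the periodic orbit of the master equation under
#' the driving waveform (transients removed exactly via the affine
#' one-cycle map), computes the enclosed area of the periodic I-V loop, and
#' reports the spectrum and its argmax. The loop area vanishes in both the
#' quasi-static and frozen limits and peaks at intermediate frequency - the
#' memristive band.
#'
#' @inheritParams integrate_master_equation
#' @param amplitude Driving amplitude, V.
#' @param f_grid Frequencies, Hz (log-spaced recommended).
#' @param cp A [conductance_params()].
#' @param kind Waveform kind, "sawtooth" (default) or "triangle".
#' @return A tibble of class `hymn_area_spectrum` with columns `frequency`,
#'   `area` and attribute `f_max` (argmax frequency, Hz).
#' @export
area_vs_frequency <- function(rates, amplitude, f_grid,
                              cp = conductance_params(),
                              kind = c("sawtooth", "triangle"),
                              steps_per_cycle = 2000) {
  kind <- match.arg(kind)
  if (length(f_grid) < 3) abort("`f_grid` needs >= 3 frequencies")
  areas <- map_dbl(f_grid, function(f) {
    wf <- make_waveform(kind, amplitude = amplitude, frequency = f)
    orb <- periodic_orbit(rates, wf, steps_per_cycle = steps_per_cycle)
    orb <- trace_current(orb, cp)
    # drop the duplicated cycle endpoint; closure is implicit in the shoelace
    shoelace_area(orb$V[-1], orb$I[-1])
  })
  new_tibble(
    list(frequency = f_grid, area = areas),
    nrow = length(f_grid), class = "hymn_area_spectrum",
    f_max = f_grid[which.max(areas)]
  )
}

#' Random-telegraph statistics of a constant-voltage recording
#'
#' Converts the recording to conductance `G = I/V`, fits the two modal
#' levels (two-component location fit via k-means), thresholds at the
#' midpoint with a +/- 0.5 sigma hysteresis band to suppress noise-induced
#' false flips, and extracts dwell times from the crossings; the censored
#' first and last dwells are excluded. Rates are reciprocal mean dwells.
#'
#' @param trace A constant-voltage [recorded_trace()] with two separable
#'   conductance modes.
#' @param min_separation Minimum modal separation in pooled-sigma units
#'   below which the trace is declared non-gating. The default 3.5 sits
#'   above the ratio (about 2.7) that a two-component location fit reports
#'   on a single Gaussian mode, which is scale-free.
#' @return An object of class `hymn_telegraph`: `level_low`, `level_high`
#'   (nS), `occupancy_high`, `mean_dwell_low`, `mean_dwell_high` (s),
#'   `rate_lowhigh`, `rate_highlow` (1/s), `two_peak_fraction`, `n_dwells`.
#' @section Errors: single-mode histograms raise `hymn_no_gating`
#'   ("no gating detected").
#' @export
telegraph_stats <- function(trace, min_separation = 3.5) {
  stopifnot(inherits(trace, "hymn_recording"))
  v <- trace$V
  if (sd(v) > 1e-9 * max(abs(v)) || abs(mean(v)) < 1e-12) {
    abort("telegraph analysis needs a constant, nonzero holding voltage")
  }
  g <- trace$I / v
  centers0 <- unname(stats::quantile(g, c(0.1, 0.9)))
  if (diff(centers0) < 1e-12) centers0 <- c(min(g), max(g))
  km <- tryCatch(
    kmeans(g, centers = matrix(centers0, ncol = 1), iter.max = 100),
    error = function(e) abort("no gating detected", class = "hymn_no_gating")
  )
  ord <- order(km$centers)
  lev <- as.vector(km$centers)[ord]
  sds <- map_dbl(ord, function(cl) sd(g[km$cluster == cl]))
  sds[!is.finite(sds)] <- 0
  pooled <- sqrt(mean(sds^2))
  if (!is.finite(pooled) || pooled == 0 ||
    (lev[2] - lev[1]) / pooled < min_separation) {
    abort("no gating detected", class = "hymn_no_gating")
  }
  mid <- mean(lev)
  # short median prefilter for the crossing detector only: single-sample
  # noise excursions otherwise chop dwells at high sampling rates
  gf <- if (length(g) >= 9) stats::runmed(g, 5) else g
  zone <- ifelse(gf > mid + 0.5 * pooled, 1L, ifelse(gf < mid - 0.5 * pooled, -1L, 0L))
  nz <- which(zone != 0L)
  if (length(nz) == 0) abort("no gating detected", class = "hymn_no_gating")
  last_nz <- nz[pmax(findInterval(seq_along(zone), nz), 1)]
  state <- zone[last_nz] # +1 high, -1 low; samples before the first crossing
  state[seq_len(nz[1] - 1)] <- zone[nz[1]]
  runs <- rle(state)
  dt <- 1 / attr(trace, "sampling_rate")
  if (length(runs$lengths) < 3) abort("no gating detected", class = "hymn_no_gating")
  inner <- seq(2, length(runs$lengths) - 1) # censor first and last dwell
  dw <- runs$lengths[inner] * dt
  st <- runs$values[inner]
  if (!any(st == 1) || !any(st == -1)) {
    abort("no gating detected", class = "hymn_no_gating")
  }
  mean_high <- mean(dw[st == 1])
  mean_low <- mean(dw[st == -1])
  occ_high <- mean(state == 1)
  # share of the mean conductance carried by samples attributable to the two
  # modal levels
  in_low <- abs(g - lev[1]) <= 2.5 * max(sds[1], pooled / 2)
  in_high <- abs(g - lev[2]) <= 2.5 * max(sds[2], pooled / 2)
  two_peak <- (sum(in_low) * lev[1] + sum(in_high) * lev[2]) /
    (length(g) * mean(g))
  structure(
    list(
      level_low = lev[1], level_high = lev[2], occupancy_high = occ_high,
      mean_dwell_low = mean_low, mean_dwell_high = mean_high,
      rate_lowhigh = 1 / mean_low, rate_highlow = 1 / mean_high,
      two_peak_fraction = two_peak, n_dwells = length(dw)
    ),
    class = "hymn_telegraph"
  )
}
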