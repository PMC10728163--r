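#' Kinetic rate model
#'
#' @param prefactor Attempt frequency nu0, 1/s. The default 1e10 is a
#'   molecular attempt-frequency scale; with the reference barriers of 18 and
#'   5 kBT it puts the equilibrium wetting/drying rates at ~1.5e2 and
#'   ~6.7e7 1/s.
#' @param diffusivity Diffusivity of the filling coordinate, xi^2/s, used by
#'   the mean-first-passage-time method.
#' @param method "arrhenius" (barrier-exponential with prefactor) or "mfpt"
#'   (1D Smoluchowski mean first-passage time).
#' @return An object of class `hymn_rate_model`.
#' @export
rate_model <- function(prefactor = 1e10, diffusivity = 1,
                       method = c("arrhenius", "mfpt")) {
  method <- match.arg(method)
  if (prefactor <= 0) abort("`prefactor` must be > 0")
  if (method == "mfpt" && diffusivity <= 0) abort("`diffusivity` must be > 0")
  structure(
    list(prefactor = prefactor, diffusivity = diffusivity, method = method),
    class = "hymn_rate_model"
  )
}

new_rate_pair <- function(k_wet, k_dry, voltage = 0, capped = FALSE) {
  new_tibble(
    list(
      voltage = voltage, k_wet = k_wet, k_dry = k_dry,
      capped = capped
    ),
    nrow = length(voltage), class = "hymn_rate_pair"
  )
}

#' Arrhenius wetting and drying rates
#'
#' `k_wet = nu0 exp(-B_wet)`, `k_dry = nu0 exp(-B_dry)` with barriers in kBT.
#' A collapsed (non-positive) barrier caps the rate at the attempt frequency:
#' no rate exceeds `nu0`.
#'
#' @param states A state summary from [locate_states()].
#' @param model A [rate_model()] with `method = "arrhenius"`.
#' @return A one-row tibble of class `hymn_rate_pair` with columns `voltage`,
#'   `k_wet`, `k_dry`, `capped`.
#' @examples
#' prof <- make_double_well()
#' arrhenius_rates(locate_states(prof), rate_model())
#' @export
arrhenius_rates <- function(states, model = rate_model()) {
  stopifnot(inherits(states, "hymn_states"), inherits(model, "hymn_rate_model"))
  bw <- states$barrier_wetting
  bd <- states$barrier_drying
  new_rate_pair(
    k_wet = model$prefactor * exp(-max(bw, 0)),
    k_dry = model$prefactor * exp(-max(bd, 0)),
    voltage = states$voltage,
    capped = bw <= 0 || bd <= 0
  )
}

#' Mean first-passage time over a tabulated free-energy landscape
#'
#' Mean time for 1D overdamped diffusion with constant diffusivity `D` to
#' first reach the absorbing point `to_xi`, starting from `from_xi`, with a
#' reflecting boundary at the profile edge behind the start (so the whole
#' starting basin contributes, as in the Kramers picture):
#' `tau = (1/D) int_{from}^{to} dy e^{F(y)} int_{edge}^{y} e^{-F(z)} dz`
#' (F in kBT). The double integral is evaluated exactly for the
#' piecewise-linear interpolant of the tabulated profile, with log-shifts
#' guarding against overflow for large barriers.
#'
#' @param profile A [filling_profile()].
#' @param from_xi,to_xi Start and absorbing filling fractions; either order
#'   (the domain is mirrored for passages running to smaller xi).
#' @param diffusivity Diffusivity, xi^2/s.
#' @return Mean first-passage time, s.
#' @export
mfpt_time <- function(profile, from_xi, to_xi, diffusivity = 1) {
  stopifnot(inherits(profile, "hymn_profile"))
  xi <- profile$xi
  f <- profile$free_energy
  if (from_xi == to_xi) abort("`from_xi` and `to_xi` must differ")
  if (!all(is.finite(f))) abort("non-finite integrand in MFPT quadrature")
  if (to_xi < from_xi) { # mirror so the passage runs left -> right
    xi <- rev(1 - xi)
    f <- rev(f)
    from_xi <- 1 - from_xi
    to_xi <- 1 - to_xi
  }
  sel <- xi <= to_xi + 1e-12 # reflecting edge .. absorbing point
  xi <- xi[sel]
  f <- f[sel]
  m <- length(xi)
  if (m < 3) abort("MFPT domain too short")
  i0 <- which.min(abs(xi - from_xi))
  if (i0 >= m) abort("`from_xi` coincides with the absorbing boundary")
  h <- diff(xi)
  d <- diff(f)
  c_hi <- max(f)
  c_lo <- min(f)
  # per-cell integrals of e^{F - c_hi} and e^{-(F - c_lo)}, exact for linear F
  int_b <- ifelse(abs(d) < 1e-12,
    h * exp(f[-m] - c_hi) * (1 + d / 2),
    h * (exp(f[-1] - c_hi) - exp(f[-m] - c_hi)) / d
  )
  int_a <- ifelse(abs(d) < 1e-12,
    h * exp(-(f[-m] - c_lo)) * (1 - d / 2),
    h * (exp(-(f[-m] - c_lo)) - exp(-(f[-1] - c_lo))) / d
  )
  # same-cell contribution of the ordered double integral
  diag_cell <- ifelse(abs(d) < 1e-8, h^2 / 2, (exp(d) - 1 - d) * (h / d)^2)
  cum_a <- cumsum(int_a)
  cells <- i0:(m - 1)
  cross <- sum(int_b[cells] * c(0, cum_a)[cells])
  (exp(c_hi - c_lo) * cross + sum(diag_cell[cells])) / diffusivity
}

#' Mean-first-passage-time rates between the two states
#'
#' Wetting rate `1/tau(dry -> wet)` and drying rate `1/tau(wet -> dry)` from
#' [mfpt_time()] between the located minima.
#'
#' @param profile A bistable [filling_profile()].
#' @param model A [rate_model()] with `method = "mfpt"`.
#' @inherit arrhenius_rates return
#' @export
mfpt_rates <- function(profile, model = rate_model(method = "mfpt")) {
  stopifnot(inherits(model, "hymn_rate_model"))
  st <- locate_states(profile)
  tw <- mfpt_time(profile, st$xi_dry, st$xi_wet, model$diffusivity)
  td <- mfpt_time(profile, st$xi_wet, st$xi_dry, model$diffusivity)
  new_rate_pair(k_wet = 1 / tw, k_dry = 1 / td, voltage = st$voltage)
}

#' Voltage-dependent rate curves
#'
#' Tilts the equilibrium profile at each grid voltage, relocates states and
#' converts barriers to rates. Where the tilt removes one minimum entirely
#' the escape out of the vanished state is barrierless and is capped at the
#' attempt frequency, while the reverse rate is continued from the
#' equilibrium barriers under the frozen-position tilt; such voltages are
#' flagged in the `capped` column.
#'
#' @param profile0 Equilibrium (0 V) bistable profile.
#' @param ew An [electrowetting()] model.
#' @param model A [rate_model()].
#' @param v_grid Strictly increasing voltages, V.
#' @return A tibble of class `hymn_rate_curves` with columns `voltage`,
#'   `k_wet`, `k_dry`, `capped`; interpolation between grid points is linear
#'   in log10(rate) (see [rates_at()]).
#' @export
rate_curves <- function(profile0, ew, model = rate_model(),
                        v_grid = seq(-3, 3, length.out = 601)) {
  stopifnot(inherits(profile0, "hymn_profile"), inherits(ew, "hymn_electrowetting"))
  if (length(v_grid) < 1) abort("`v_grid` must be non-empty")
  if (any(diff(v_grid) <= 0)) abort("`v_grid` must be strictly increasing")
  st0 <- locate_states(profile0)
  rows <- map(v_grid, function(v) {
    tilted <- apply_voltage(profile0, ew, v)
    tryCatch(
      {
        st <- locate_states(tilted)
        if (model$method == "arrhenius") {
          arrhenius_rates(st, model)
        } else {
          mfpt_rates(tilted, model)
        }
      },
      hymn_single_state = function(cnd) {
        s <- ew$a_ew * v^2 + ew$mu_ew * v
        bw <- st0$barrier_wetting - s * (st0$xi_saddle - st0$xi_dry)
        bd <- st0$barrier_drying + s * (st0$xi_wet - st0$xi_saddle)
        new_rate_pair(
          k_wet = model$prefactor * exp(-max(bw, 0)),
          k_dry = model$prefactor * exp(-max(bd, 0)),
          voltage = v, capped = TRUE
        )
      }
    )
  })
  out <- bind_rows(rows)
  new_tibble(as.list(out),
    nrow = nrow(out), class = "hymn_rate_curves",
    prefactor = model$prefactor, interpolation = "log-linear"
  )
}

#' Constant (voltage-independent) rate pair
#'
#' Convenience source of rates for protocols where the voltage dependence is
#' irrelevant, e.g. telegraph-signal generation at constant holding voltage.
#' Accepted everywhere a `hymn_rate_curves` is.
#'
#' @param k_wet,k_dry Rates, 1/s (> 0).
#' @return An object of class `hymn_rate_constant`.
#' @export
constant_rates <- function(k_wet, k_dry) {
  if (k_wet <= 0 || k_dry <= 0) abort("rates must be > 0")
  structure(list(k_wet = k_wet, k_dry = k_dry), class = "hymn_rate_constant")
}

#' Interpolate rates at arbitrary voltages
#'
#' Log10-linear interpolation on the rate grid. Voltages outside the tabulated
#' range are an error, never an extrapolation.
#'
#' @param rates A `hymn_rate_curves` or [constant_rates()].
#' @param voltage Numeric vector of voltages, V.
#' @return A list with numeric vectors `k_wet` and `k_dry`.
#' @export
rates_at <- function(rates, voltage) {
  if (inherits(rates, "hymn_rate_constant")) {
    return(list(
      k_wet = rep(rates$k_wet, length(voltage)),
      k_dry = rep(rates$k_dry, length(voltage))
    ))
  }
  stopifnot(inherits(rates, "hymn_rate_curves"))
  rng <- range(rates$voltage)
  if (any(voltage < rng[1] - 1e-12 | voltage > rng[2] + 1e-12)) {
    abort(sprintf(
      "voltage outside tabulated rate grid [%g, %g] V; extrapolation is not performed",
      rng[1], rng[2]
    ), class = "hymn_rate_extrapolation")
  }
  voltage <- pmin(pmax(voltage, rng[1]), rng[2])
  if (nrow(rates) == 1) {
    return(list(
      k_wet = rep(rates$k_wet, length(voltage)),
      k_dry = rep(rates$k_dry, length(voltage))
    ))
  }
  list(
    k_wet = 10^approx(rates$voltage, log10(rates$k_wet), xout = voltage)$y,
    k_dry = 10^approx(rates$voltage, log10(rates$k_dry), xout = voltage)$y
  )
}

## voltage range covered by a rate source (infinite for constant pairs)
rates_range <- function(rates) {
  if (inherits(rates, "hymn_rate_constant")) c(-Inf, Inf) else range(rates$voltage)
}

## largest exit rate over a voltage interval, for stochastic dt bounds
rates_max <- function(rates, v_lo, v_hi) {
  if (inherits(rates, "hymn_rate_constant")) {
    return(max(rates$k_wet, rates$k_dry))
  }
  sel <- rates$voltage >= v_lo - 1e-12 & rates$voltage <= v_hi + 1e-12
  if (!any(sel)) sel <- rep(TRUE, nrow(rates))
  max(rates$k_wet[sel], rates$k_dry[sel])
}
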