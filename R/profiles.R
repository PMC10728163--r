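#' Pore geometry
#'
#' Describes the cylindrical pore used throughout: a hydrophobic channel of
#' given diameter and length whose lumen can be occupied by liquid water
#' (conductive, "wet") or by a vapour bubble (non-conductive, "dry").
#'
#' @param diameter Pore diameter in nm.
#' @param length Pore length in nm.
#' @param contact_angle Contact angle of water on the pore material, degrees.
#'   Values above 90 mean a hydrophobic wall, which is what makes the dry
#'   state competitive.
#' @return An object of class `hymn_geometry` with fields `diameter`,
#'   `length`, `contact_angle` and the derived `aspect_ratio = length/diameter`.
#' @examples
#' pore_geometry(diameter = 1.04, length = 2.8, contact_angle = 104)
#' @export
pore_geometry <- function(diameter, length, contact_angle) {
  if (!is.numeric(diameter) || diameter <= 0) abort("`diameter` must be > 0")
  if (!is.numeric(length) || length <= 0) abort("`length` must be > 0")
  if (!is.numeric(contact_angle) || contact_angle <= 0 || contact_angle >= 180) {
    abort("`contact_angle` must lie in (0, 180) degrees")
  }
  structure(
    list(
      diameter = diameter, length = length, contact_angle = contact_angle,
      aspect_ratio = length / diameter
    ),
    class = "hymn_geometry"
  )
}

#' Liquid and environment parameters
#'
#' @param surface_tension Liquid-vapour surface tension, N/m.
#' @param temperature Absolute temperature, K.
#' @param pressure_difference Liquid minus vapour pressure, Pa.
#' @param water_permittivity Relative permittivity of the liquid.
#' @param meniscus_count Number of liquid-vapour menisci charged to a
#'   (partially) dry pore; 1 corresponds to a bubble nucleating from one pore
#'   mouth.
#' @return An object of class `hymn_liquid`.
#' @export
liquid_params <- function(surface_tension = 0.070, temperature = 310,
                          pressure_difference = 0, water_permittivity = 78,
                          meniscus_count = 1) {
  if (surface_tension <= 0) abort("`surface_tension` must be > 0")
  if (temperature <= 0) abort("`temperature` must be > 0")
  if (water_permittivity < 1) abort("`water_permittivity` must be >= 1")
  if (meniscus_count < 0) abort("`meniscus_count` must be >= 0")
  structure(
    list(
      surface_tension = surface_tension, temperature = temperature,
      pressure_difference = pressure_difference,
      water_permittivity = water_permittivity,
      meniscus_count = meniscus_count
    ),
    class = "hymn_liquid"
  )
}

#' Electrowetting coupling model
#'
#' The applied voltage stabilises the wet state. The free-energy shift used
#' throughout is linear in the filling fraction and quadratic-plus-dipole in
#' voltage: `S(xi; V) = -(a_ew V^2 + mu_ew V) xi` (kBT). With `mu_ew = 0` the
#' response is symmetric under voltage reversal (unipolar); a dominant
#' `mu_ew` gives the asymmetric, bipolar response seen for pores with an
#' intrinsic dipole.
#'
#' @param a_ew Quadratic coupling, kBT/V^2 (>= 0).
#' @param mu_ew Dipole coupling, kBT/V (default 0).
#' @param alpha Dielectric efficiency in (0, 1], recorded when `a_ew` comes
#'   from the geometric capacitor estimate.
#' @param v_c_reference Critical voltage the model was calibrated to, if any.
#' @return An object of class `hymn_electrowetting`.
#' @seealso [ew_from_geometry()], [calibrate_coupling()]
#' @export
electrowetting <- function(a_ew, mu_ew = 0, alpha = NA_real_,
                           v_c_reference = NA_real_) {
  if (a_ew < 0) abort("`a_ew` must be >= 0")
  if (!is.na(alpha) && (alpha <= 0 || alpha > 1)) abort("`alpha` must be in (0, 1]")
  structure(
    list(
      a_ew = a_ew, mu_ew = mu_ew, alpha = alpha,
      v_c_reference = v_c_reference
    ),
    class = "hymn_electrowetting"
  )
}

#' Geometric estimate of the electrowetting coupling
#'
#' Treats the wet pore as a cylindrical capacitor filled with water instead of
#' vapour: `a_ew = alpha * eps0 (eps_w - 1) pi R^2 / (2 L kBT)`. The
#' dielectric efficiency `alpha` absorbs everything the parallel-plate picture
#' misses (field focusing, access resistance); its default 0.30 is a
#' calibration that places the 10-second wetting voltage of the reference
#' model pore near 1.2 V.
#'
#' @param geometry A [pore_geometry()].
#' @param liquid A [liquid_params()].
#' @param alpha Dielectric efficiency in (0, 1].
#' @inherit electrowetting return
#' @export
ew_from_geometry <- function(geometry, liquid, alpha = 0.30) {
  stopifnot(inherits(geometry, "hymn_geometry"), inherits(liquid, "hymn_liquid"))
  r <- geometry$diameter / 2 * 1e-9
  l <- geometry$length * 1e-9
  a <- alpha * 0.5 * .eps0 * (liquid$water_permittivity - 1) * pi * r^2 /
    (l * kbt_joule(liquid$temperature))
  electrowetting(a_ew = a, mu_ew = 0, alpha = alpha)
}

#' Filling free-energy profile
#'
#' A tabulated free energy F(xi) (kBT) over the filling fraction xi in [0, 1]
#' (0 = dry, 1 = wet), held at a single applied voltage.
#'
#' @param xi Strictly increasing filling fractions covering 0 and 1,
#'   length >= 21.
#' @param free_energy Free energy at each `xi`, kBT; finite.
#' @param voltage Voltage at which the profile holds, V.
#' @param metadata Provenance string.
#' @return A tibble of class `hymn_profile` with columns `xi`, `free_energy`
#'   and attributes `voltage`, `metadata`.
#' @export
filling_profile <- function(xi, free_energy, voltage = 0, metadata = "") {
  if (length(xi) != length(free_energy)) abort("`xi` and `free_energy` lengths differ")
  if (length(xi) < 21) abort("profile needs at least 21 grid points")
  if (any(diff(xi) <= 0)) abort("`xi` must be strictly increasing")
  if (abs(min(xi)) > 1e-12 || abs(max(xi) - 1) > 1e-12) {
    abort("`xi` must cover both endpoints 0 and 1")
  }
  if (!all(is.finite(free_energy))) abort("`free_energy` must be finite")
  new_tibble(
    list(xi = as.numeric(xi), free_energy = as.numeric(free_energy)),
    nrow = length(xi), class = "hymn_profile",
    voltage = voltage, metadata = metadata
  )
}

profile_voltage <- function(profile) attr(profile, "voltage") %||% 0

#' Capillarity (classical nucleation theory) filling profile
#'
#' Closed-form free energy of a single axial vapour bubble with flat menisci
#' in a cylindrical pore. For vapour fraction `v = 1 - xi`,
#' `W(v) = 2 pi R L gamma cos(theta) v + dP pi R^2 L v + c_m gamma pi R^2`
#' for `v > 0`, and `W = 0` for the fully wet pore, expressed in kBT. For a
#' hydrophobic wall (`cos(theta) < 0`) emptying the pore pays the meniscus
#' term once and then gains wall energy linearly, so the profile is a tilted
#' ramp with a jump at the wet end: the drying barrier is the meniscus cost
#' `c_m gamma pi R^2` and the wetting barrier is the full wall (+ pressure)
#' term.
#'
#' @inheritParams ew_from_geometry
#' @param grid_size Number of xi grid points (>= 21).
#' @return A [filling_profile()] at 0 V, energies relative to the wet state.
#' @examples
#' geo <- pore_geometry(1.04, 2.8, 104)
#' liq <- liquid_params()
#' prof <- build_cnt_profile(geo, liq)
#' locate_states(prof)
#' @export
build_cnt_profile <- function(geometry, liquid, grid_size = 201) {
  stopifnot(inherits(geometry, "hymn_geometry"), inherits(liquid, "hymn_liquid"))
  if (grid_size < 21) abort("`grid_size` must be >= 21")
  terms <- cnt_terms(geometry, liquid)
  xi <- seq(0, 1, length.out = grid_size)
  v <- 1 - xi
  w <- ifelse(v > 0, terms$slope * v + terms$meniscus, 0)
  filling_profile(xi, w,
    voltage = 0,
    metadata = sprintf(
      "cnt d=%gnm L=%gnm theta=%gdeg", geometry$diameter,
      geometry$length, geometry$contact_angle
    )
  )
}

## kBT-unit building blocks of the capillarity model; `slope` multiplies the
## vapour fraction (negative for a hydrophobic wall at dP = 0), `meniscus` is
## the flat-interface cost paid by any partially dry pore.
cnt_terms <- function(geometry, liquid) {
  r <- geometry$diameter / 2 * 1e-9
  l <- geometry$length * 1e-9
  kbt <- kbt_joule(liquid$temperature)
  wall <- 2 * pi * r * l * liquid$surface_tension *
    cos(geometry$contact_angle * pi / 180)
  press <- liquid$pressure_difference * pi * r^2 * l
  menisc <- liquid$meniscus_count * liquid$surface_tension * pi * r^2
  list(slope = (wall + press) / kbt, meniscus = menisc / kbt)
}

#' Tilt a profile by the electrowetting shift
#'
#' Applies `F(xi; V) = F(xi; 0) - (a_ew V^2 + mu_ew V) xi`. The shift vanishes
#' at `xi = 0` (a dry pore stores no extra dielectric energy) and lowers the
#' wet end by the full coupling.
#'
#' @param profile A [filling_profile()] at 0 V.
#' @param ew An [electrowetting()] model.
#' @param voltage Applied voltage, V.
#' @return The tilted profile, recording `voltage`.
#' @export
apply_voltage <- function(profile, ew, voltage) {
  stopifnot(inherits(profile, "hymn_profile"), inherits(ew, "hymn_electrowetting"))
  if (abs(profile_voltage(profile)) > 1e-12) {
    abort("`profile` must be an equilibrium (0 V) profile")
  }
  shift <- (ew$a_ew * voltage^2 + ew$mu_ew * voltage) * profile$xi
  filling_profile(profile$xi, profile$free_energy - shift,
    voltage = voltage, metadata = attr(profile, "metadata") %||% ""
  )
}

#' Locate wet/dry states and barriers
#'
#' Finds the two minima (dry at small xi, wet at large xi) and the
#' intervening saddle of a tabulated double-well profile using discrete local
#' extrema; plateaus collapse to their smallest-xi point. Endpoints count as
#' candidate minima, which matters for capillarity profiles whose minima sit
#' exactly at xi = 0 and 1. With more than two minima the two deepest are
#' kept.
#'
#' @param profile A [filling_profile()].
#' @return An object of class `hymn_states`: filling fractions `xi_dry`,
#'   `xi_saddle`, `xi_wet`; barriers `barrier_wetting` (saddle minus dry
#'   minimum) and `barrier_drying` (saddle minus wet minimum), kBT; `gap`
#'   (wet minus dry minimum, so positive when the dry state is globally
#'   stable); and `global_state` ("dry" or "wet").
#' @section Errors: a profile with fewer than two minima raises a
#'   `hymn_single_state` error carrying the single minimum (`xi_min`,
#'   `f_min`).
#' @export
locate_states <- function(profile) {
  stopifnot(inherits(profile, "hymn_profile"))
  f <- profile$free_energy
  xi <- profile$xi
  runs <- rle(f)
  idx <- cumsum(c(1, head(runs$lengths, -1))) # first index of each plateau
  v <- runs$values
  m <- length(v)
  if (m < 2) {
    abort("profile is flat: no states to locate",
      class = "hymn_single_state", xi_min = xi[1], f_min = f[1]
    )
  }
  # strict local minima on the plateau-collapsed sequence; endpoints qualify
  # against their single neighbour
  is_min <- c(v[1] < v[2], rep(FALSE, m - 1)) |
    c(rep(FALSE, m - 1), v[m] < v[m - 1]) |
    (c(FALSE, diff(v) < 0) & c(diff(v) > 0, FALSE))
  mins <- which(is_min)
  if (length(mins) < 2) {
    j <- if (length(mins) == 1) mins else which.min(v)
    abort("profile has a single state (monostable)",
      class = "hymn_single_state", xi_min = xi[idx[j]], f_min = v[j]
    )
  }
  if (length(mins) > 2) {
    # several minima (e.g. a tilted well whose edge point becomes a shallow
    # extra minimum): split the landscape at the most prominent interior
    # maximum and keep the deepest minimum on each side
    maxs <- which(c(FALSE, diff(v) > 0) & c(diff(v) < 0, FALSE))
    best <- NULL
    best_prom <- -Inf
    for (x in maxs) {
      left <- mins[mins < x]
      right <- mins[mins > x]
      if (length(left) == 0 || length(right) == 0) next
      prom <- v[x] - max(min(v[left]), min(v[right]))
      if (prom > best_prom) {
        best_prom <- prom
        best <- list(
          dry = left[which.min(v[left])],
          wet = right[which.min(v[right])]
        )
      }
    }
    if (is.null(best)) {
      j <- which.min(v)
      abort("profile has a single state (monostable)",
        class = "hymn_single_state", xi_min = xi[idx[j]], f_min = v[j]
      )
    }
    mins <- c(best$dry, best$wet)
  }
  i_dry <- mins[1]
  i_wet <- mins[2]
  between <- seq(i_dry, i_wet)
  i_sad <- between[which.max(v[between])]
  f_dry <- v[i_dry]
  f_wet <- v[i_wet]
  f_sad <- v[i_sad]
  structure(
    list(
      xi_dry = xi[idx[i_dry]], xi_saddle = xi[idx[i_sad]], xi_wet = xi[idx[i_wet]],
      barrier_wetting = f_sad - f_dry, barrier_drying = f_sad - f_wet,
      gap = f_wet - f_dry,
      global_state = if (f_wet < f_dry) "wet" else "dry",
      f_dry = f_dry, f_saddle = f_sad, f_wet = f_wet,
      voltage = profile_voltage(profile)
    ),
    class = "hymn_states"
  )
}

#' @export
print.hymn_states <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Two-state summary (V = %g V)\n",
      "  dry min    xi = %.3f   F = %8.3f kBT\n",
      "  saddle     xi = %.3f   F = %8.3f kBT\n",
      "  wet min    xi = %.3f   F = %8.3f kBT\n",
      "  B_wet = %.3f kBT   B_dry = %.3f kBT   gap = %.3f kBT  [%s]\n"
    ),
    x$voltage, x$xi_dry, x$f_dry, x$xi_saddle, x$f_saddle,
    x$xi_wet, x$f_wet, x$barrier_wetting, x$barrier_drying, x$gap,
    x$global_state
  ))
  invisible(x)
}

## wet-minus-dry minimum energy of the tilted profile; -Inf/+Inf when the
## respective competing state has vanished.
tilted_gap <- function(profile0, ew, voltage) {
  tilted <- apply_voltage(profile0, ew, voltage)
  tryCatch(
    locate_states(tilted)$gap,
    hymn_single_state = function(cnd) {
      st0 <- locate_states(profile0)
      if (cnd$xi_min >= st0$xi_saddle) -Inf else Inf
    }
  )
}

#' Critical (switching) voltage
#'
#' Smallest voltage at which the wet minimum of the tilted profile drops to
#' (or below) the dry minimum, found by bisection. This is the thermodynamic
#' transition voltage V_c beyond which the stable state switches from dry to
#' wet.
#'
#' @param profile0 Equilibrium (0 V) profile with a dry global minimum.
#' @param ew An [electrowetting()] model.
#' @param v_max Upper search bound, V.
#' @param tol Bisection tolerance, V (default 1 mV).
#' @return The critical voltage (V); 0 when the wet state is already global
#'   at 0 V.
#' @section Errors: if no switching occurs below `v_max`, an error of class
#'   `hymn_no_switch` is raised ("no switching below v_max").
#' @export
critical_voltage <- function(profile0, ew, v_max = 5, tol = 1e-3) {
  stopifnot(inherits(profile0, "hymn_profile"), inherits(ew, "hymn_electrowetting"))
  if (tilted_gap(profile0, ew, 0) <= 0) {
    return(0)
  }
  if (tilted_gap(profile0, ew, v_max) > 0) {
    abort(sprintf("no switching below v_max = %g V", v_max),
      class = "hymn_no_switch"
    )
  }
  lo <- 0
  hi <- v_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (tilted_gap(profile0, ew, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Calibrate the quadratic coupling to a target critical voltage
#'
#' Finds `a_ew` (with `mu_ew = 0`) such that the two minima of the tilted
#' profile are degenerate exactly at `target_vc`. Used to anchor the model to
#' an observed switching voltage.
#'
#' @inheritParams critical_voltage
#' @param target_vc Target critical voltage, V (> 0).
#' @return An [electrowetting()] model with `v_c_reference = target_vc`.
#' @export
calibrate_coupling <- function(profile0, target_vc) {
  stopifnot(inherits(profile0, "hymn_profile"))
  if (target_vc <= 0) abort("`target_vc` must be > 0")
  st0 <- locate_states(profile0)
  if (st0$gap < 0) {
    abort("profile is degenerate for calibration: wet already below dry at 0 V")
  }
  if (st0$gap == 0) {
    return(electrowetting(a_ew = 0, mu_ew = 0, v_c_reference = target_vc))
  }
  a0 <- st0$gap / (target_vc^2 * (st0$xi_wet - st0$xi_dry)) # frozen-position guess
  gap_at <- function(a) tilted_gap(profile0, electrowetting(a_ew = a), target_vc)
  lo <- a0 / 4
  hi <- a0 * 4
  root <- uniroot(gap_at, lower = lo, upper = hi, tol = a0 * 1e-10)$root
  electrowetting(a_ew = root, mu_ew = 0, v_c_reference = target_vc)
}
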