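#' Memristor design criteria
#'
#' The four requirements for a pore to function as a hydrophobically gated
#' memristor: (1) preferentially dry at 0 V; (2) able to wet below the
#' maximum sustainable voltage `v_max`; (3) drying at 0 V faster than
#' `tau_dry_max`; (4) wetting at `v_max` faster than `tau_wet_max`.
#'
#' Under this package's electrowetting surrogate (a tilt linear in the
#' filling fraction, with the saddle adjacent to the wet state) the
#' thermodynamic switching voltage always exceeds the kinetic wetting
#' threshold wherever drying is fast, so a thermodynamic reading of
#' criterion (2) would be strictly stronger than the kinetic criterion (4)
#' and the two regions could never both appear. Criterion (2) is therefore
#' judged against the separate bound `v_thermo_max` on the thermodynamic
#' switching voltage (default `Inf`, i.e. inactive); the kinetic wetting
#' test (4) carries the wetting requirement. See the methods vignette.
#'
#' @param v_max Maximum sustainable voltage Delta-V*, V.
#' @param tau_dry_max Slowest acceptable drying time at 0 V, s.
#' @param tau_wet_max Slowest acceptable wetting time at `v_max`, s.
#' @param v_thermo_max Optional bound on the thermodynamic switching
#'   voltage, V.
#' @return An object of class `hymn_criteria`.
#' @export
design_criteria <- function(v_max = 0.2, tau_dry_max = 10, tau_wet_max = 10,
                            v_thermo_max = Inf) {
  if (v_max <= 0 || tau_dry_max <= 0 || tau_wet_max <= 0) {
    abort("criteria must all be positive")
  }
  structure(
    list(
      v_max = v_max, tau_dry_max = tau_dry_max, tau_wet_max = tau_wet_max,
      v_thermo_max = v_thermo_max
    ),
    class = "hymn_criteria"
  )
}

#' Region labels
#'
#' Verdicts for a pore geometry against the design criteria, with precedence
#' red > green > blue > gray:
#' * `wet_stable` (red) - the wet state is already the global minimum at 0 V;
#' * `needs_too_much_voltage` (green) - thermodynamic switching voltage above
#'   `v_thermo_max`;
#' * `slow_dryer` (blue) - drying at 0 V slower than `tau_dry_max`;
#' * `slow_wetter` (gray) - wetting at `v_max` slower than `tau_wet_max`;
#' * `allowed` - passes everything.
#' @name region_labels
#' @keywords internal
NULL

region_label_levels <- c(
  "allowed", "wet_stable", "needs_too_much_voltage", "slow_dryer", "slow_wetter"
)

## Closed-form design evaluation under the capillarity + capacitive-tilt
## surrogate. All energies kBT:
##   wall  = 2 pi R L gamma |cos theta| (+ dP term), the wetting barrier at 0 V
##   menisc = c_m gamma pi R^2, the (voltage-independent) drying barrier
##   s(V)  = a_ew V^2, the tilt reaching the wet/saddle end
design_terms <- function(geometry, liquid, alpha) {
  terms <- cnt_terms(geometry, liquid)
  ew <- ew_from_geometry(geometry, liquid, alpha)
  list(
    wall = -terms$slope, # > 0 when the dry state is favoured locally
    menisc = terms$meniscus,
    a_ew = ew$a_ew
  )
}

#' Evaluate a pore geometry against the design criteria
#'
#' Builds the capillarity description of the pore, derives the electrowetting
#' coupling from the capacitor estimate, and computes Arrhenius switching
#' times: `tau_dry(0) = 1/k_dry(0)` and `tau_wet(v_max) = 1/k_wet(v_max)`.
#' The label applies the precedence red > green > blue > gray.
#'
#' @inheritParams ew_from_geometry
#' @param criteria A [design_criteria()].
#' @param model A [rate_model()] supplying the attempt frequency.
#' @return An object of class `hymn_design_eval`: `tau_dry_at_0`,
#'   `tau_wet_at_vmax` (s), `dry_preferred_at_0`, `v_wet_thermo` (V, the
#'   thermodynamic switching voltage), `label`.
#' @examples
#' evaluate_design(pore_geometry(1.04, 2.8, 104), liquid_params(),
#'   criteria = design_criteria(v_max = 0.2)
#' )
#' @export
evaluate_design <- function(geometry, liquid = liquid_params(),
                            criteria = design_criteria(),
                            model = rate_model(), alpha = 0.30) {
  stopifnot(inherits(geometry, "hymn_geometry"), inherits(criteria, "hymn_criteria"))
  dt <- design_terms(geometry, liquid, alpha)
  nu0 <- model$prefactor
  dry_pref <- dt$wall > dt$menisc
  s_star <- dt$a_ew * criteria$v_max^2
  b_wet_at_vmax <- max(dt$wall - s_star, 0)
  tau_dry <- exp(max(dt$menisc, 0)) / nu0
  tau_wet <- exp(b_wet_at_vmax) / nu0
  v_thermo <- if (dt$wall <= dt$menisc) 0 else sqrt((dt$wall - dt$menisc) / dt$a_ew)
  label <- if (!dry_pref) {
    "wet_stable"
  } else if (v_thermo > criteria$v_thermo_max) {
    "needs_too_much_voltage"
  } else if (tau_dry > criteria$tau_dry_max) {
    "slow_dryer"
  } else if (tau_wet > criteria$tau_wet_max) {
    "slow_wetter"
  } else {
    "allowed"
  }
  structure(
    list(
      tau_dry_at_0 = tau_dry, tau_wet_at_vmax = tau_wet,
      dry_preferred_at_0 = dry_pref, v_wet_thermo = v_thermo,
      label = factor(label, levels = region_label_levels),
      geometry = geometry, criteria = criteria
    ),
    class = "hymn_design_eval"
  )
}

#' @export
print.hymn_design_eval <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Design evaluation (d = %g nm, AR = %.2f, theta = %g deg)\n",
      "  dry preferred at 0 V : %s\n",
      "  tau_dry(0)           : %.3g s\n",
      "  tau_wet(v_max)       : %.3g s\n",
      "  V_thermo             : %.3g V\n",
      "  label                : %s\n"
    ),
    x$geometry$diameter, x$geometry$aspect_ratio, x$geometry$contact_angle,
    x$dry_preferred_at_0, x$tau_dry_at_0, x$tau_wet_at_vmax, x$v_wet_thermo,
    as.character(x$label)
  ))
  invisible(x)
}

#' Design-space region map
#'
#' Classifies every (diameter, aspect-ratio) grid point against the design
#' criteria, producing the long-format map behind the diameter-vs-aspect-ratio
#' design diagrams.
#'
#' @param d_grid Diameters, nm.
#' @param ar_grid Aspect ratios (length/diameter).
#' @param theta Contact angle, degrees.
#' @inheritParams evaluate_design
#' @return A tibble of class `hymn_region_map` with columns `diameter`,
#'   `aspect_ratio`, `label` and a `params` attribute.
#' @examples
#' rm <- region_map(
#'   d_grid = seq(0.5, 3, length.out = 40),
#'   ar_grid = seq(0.5, 5, length.out = 40), theta = 104
#' )
#' allowed_fraction(rm)
#' @export
region_map <- function(d_grid = seq(0.5, 3, length.out = 100),
                       ar_grid = seq(0.5, 5, length.out = 100),
                       theta = 104, criteria = design_criteria(),
                       liquid = liquid_params(), model = rate_model(),
                       alpha = 0.30) {
  if (length(d_grid) < 1 || length(ar_grid) < 1) abort("grids must be non-empty")
  grid <- tidyr::expand_grid(diameter = d_grid, aspect_ratio = ar_grid)
  # vectorised closed forms (kBT units), identical to evaluate_design()
  r <- grid$diameter / 2 * 1e-9
  l <- grid$aspect_ratio * grid$diameter * 1e-9
  kbt <- kbt_joule(liquid$temperature)
  wall <- -(2 * pi * r * l * liquid$surface_tension * cos(theta * pi / 180) +
    liquid$pressure_difference * pi * r^2 * l) / kbt
  menisc <- liquid$meniscus_count * liquid$surface_tension * pi * r^2 / kbt
  a_ew <- alpha * 0.5 * .eps0 * (liquid$water_permittivity - 1) * pi * r^2 /
    (l * kbt)
  nu0 <- model$prefactor
  ln_dry <- log(nu0 * criteria$tau_dry_max)
  ln_wet <- log(nu0 * criteria$tau_wet_max)
  b_wet <- pmax(wall - a_ew * criteria$v_max^2, 0)
  v_thermo <- ifelse(wall <= menisc, 0, sqrt(pmax(wall - menisc, 0) / a_ew))
  label <- rep("allowed", nrow(grid))
  label[b_wet > ln_wet] <- "slow_wetter"
  label[menisc > ln_dry] <- "slow_dryer"
  label[v_thermo > criteria$v_thermo_max] <- "needs_too_much_voltage"
  label[wall <= menisc] <- "wet_stable"
  out <- grid
  out$label <- factor(label, levels = region_label_levels)
  new_tibble(as.list(out),
    nrow = nrow(out), class = "hymn_region_map",
    params = list(
      theta = theta, criteria = criteria, liquid = liquid,
      prefactor = nu0, alpha = alpha
    )
  )
}

#' Fraction of allowed design-space cells
#'
#' @param map A [region_map()].
#' @return Fraction in [0, 1] of grid cells labelled `allowed`.
#' @export
allowed_fraction <- function(map) {
  stopifnot(inherits(map, "hymn_region_map"))
  if (nrow(map) == 0) abort("empty region map")
  mean(map$label == "allowed")
}
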