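#' Tidy a two-state summary
#'
#' @param x A `hymn_states` from [locate_states()].
#' @param ... Unused.
#' @return One row per state (`dry`, `saddle`, `wet`) with `xi` and
#'   `free_energy`.
#' @method tidy hymn_states
#' @export
tidy.hymn_states <- function(x, ...) {
  tibble(
    state = c("dry", "saddle", "wet"),
    xi = c(x$xi_dry, x$xi_saddle, x$xi_wet),
    free_energy = c(x$f_dry, x$f_saddle, x$f_wet)
  )
}

#' @rdname tidy.hymn_states
#' @return `glance()`: a one-row tibble with the barriers (kBT), gap and
#'   global state.
#' @method glance hymn_states
#' @export
glance.hymn_states <- function(x, ...) {
  tibble(
    barrier_wetting = x$barrier_wetting, barrier_drying = x$barrier_drying,
    gap = x$gap, global_state = x$global_state, voltage = x$voltage
  )
}

#' Tidy a design evaluation
#'
#' @param x A `hymn_design_eval` from [evaluate_design()].
#' @param ... Unused.
#' @return A one-row tibble with the geometry, switching times and label.
#' @method tidy hymn_design_eval
#' @export
tidy.hymn_design_eval <- function(x, ...) {
  tibble(
    diameter = x$geometry$diameter, aspect_ratio = x$geometry$aspect_ratio,
    contact_angle = x$geometry$contact_angle,
    dry_preferred_at_0 = x$dry_preferred_at_0,
    tau_dry_at_0 = x$tau_dry_at_0, tau_wet_at_vmax = x$tau_wet_at_vmax,
    v_wet_thermo = x$v_wet_thermo, label = as.character(x$label)
  )
}

#' Summarise a region map
#'
#' @param x A `hymn_region_map`.
#' @param ... Unused.
#' @return A one-row tibble with the fraction of cells carrying each label.
#' @method glance hymn_region_map
#' @export
glance.hymn_region_map <- function(x, ...) {
  out <- as.list(table(x$label) / nrow(x))
  as_tibble(out)
}

#' Summarise a capacitance fit
#'
#' @param x A `hymn_capacitance_fit` from [subtract_capacitance()].
#' @param ... Unused.
#' @return A one-row tibble with `capacitance_pf`, `leak_ns`, `sigma`.
#' @method glance hymn_capacitance_fit
#' @export
glance.hymn_capacitance_fit <- function(x, ...) {
  tibble(capacitance_pf = x$capacitance_pf, leak_ns = x$leak_ns, sigma = x$sigma)
}

#' Summarise loop metrics
#'
#' @param x A `hymn_loop_metrics` from [loop_metrics()].
#' @param ... Unused.
#' @return A one-row tibble of the lobe areas, pinch flag and polarity.
#' @method glance hymn_loop_metrics
#' @export
glance.hymn_loop_metrics <- function(x, ...) {
  tibble(
    area_positive_lobe = x$area_positive_lobe,
    area_negative_lobe = x$area_negative_lobe,
    total_area = x$total_area, pinched_at_origin = x$pinched_at_origin,
    polarity = x$polarity
  )
}

#' Summarise telegraph statistics
#'
#' @param x A `hymn_telegraph` from [telegraph_stats()].
#' @param ... Unused.
#' @return A one-row tibble of levels, occupancy, dwells, rates and the
#'   two-peak conductance fraction.
#' @method glance hymn_telegraph
#' @export
glance.hymn_telegraph <- function(x, ...) {
  tibble(
    level_low = x$level_low, level_high = x$level_high,
    occupancy_high = x$occupancy_high,
    mean_dwell_low = x$mean_dwell_low, mean_dwell_high = x$mean_dwell_high,
    rate_lowhigh = x$rate_lowhigh, rate_highlow = x$rate_highlow,
    two_peak_fraction = x$two_peak_fraction, n_dwells = x$n_dwells
  )
}
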