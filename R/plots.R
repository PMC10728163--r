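#' @export
ggplot2::autoplot

#' Plot a filling free-energy profile
#'
#' @param object A [filling_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hymn_profile
#' @export
autoplot.hymn_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$xi, y = .data$free_energy)) +
    geom_line() +
    labs(
      x = expression(xi[w] ~ "(filling fraction)"),
      y = expression(F ~ (k[B] * T)),
      title = sprintf("Filling free energy at %g V", profile_voltage(object))
    )
}

#' Plot wetting/drying rate curves
#'
#' @param object A `hymn_rate_curves`.
#' @param ... Unused.
#' @return A ggplot with log10 rates versus voltage.
#' @method autoplot hymn_rate_curves
#' @export
autoplot.hymn_rate_curves <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble(
      voltage = object$voltage, wetting = object$k_wet,
      drying = object$k_dry
    ),
    c("wetting", "drying"),
    names_to = "transition", values_to = "rate"
  )
  ggplot(df, aes(x = .data$voltage, y = .data$rate, colour = .data$transition)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "Voltage (V)", y = "Rate (1/s)", colour = NULL)
}

#' Plot an ensemble trace
#'
#' @param object A `hymn_trace`.
#' @param type "iv" for the current-voltage loop (requires `I`), "time" for
#'   V(t) and n(t) panels.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hymn_trace
#' @export
autoplot.hymn_trace <- function(object, type = c("iv", "time"), ...) {
  type <- match.arg(type)
  if (type == "iv") {
    if (is.null(object$I)) abort("trace has no current; call trace_current()")
    ggplot(object, aes(x = .data$V, y = .data$I)) +
      geom_path() +
      labs(x = "Voltage (V)", y = "Current (nA)")
  } else {
    df <- tidyr::pivot_longer(
      tibble(t = object$t, `V (V)` = object$V, `wet fraction` = object$n),
      -"t",
      names_to = "signal", values_to = "value"
    )
    ggplot(df, aes(x = .data$t, y = .data$value)) +
      geom_line() +
      facet_wrap(~ .data$signal, ncol = 1, scales = "free_y") +
      labs(x = "Time (s)", y = NULL)
  }
}

#' Plot a cycle-averaged IV loop
#'
#' @param object A `hymn_iv_loop`.
#' @param ... Unused.
#' @return A ggplot with forward and backward branches.
#' @method autoplot hymn_iv_loop
#' @export
autoplot.hymn_iv_loop <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble(
      V = object$V, forward = object$I_forward,
      backward = object$I_backward
    ),
    c("forward", "backward"),
    names_to = "branch", values_to = "I"
  )
  ggplot(df, aes(x = .data$V, y = .data$I, colour = .data$branch)) +
    geom_line(na.rm = TRUE) +
    labs(x = "Voltage (V)", y = "Current (nA)", colour = NULL)
}

#' Plot a design-space region map
#'
#' Fill colours follow the conventional region palette: white allowed, red
#' wet-stable, green needs-too-much-voltage, blue slow dryer, gray slow
#' wetter.
#'
#' @param object A [region_map()].
#' @param ... Unused.
#' @return A ggplot raster of labels over diameter x aspect ratio.
#' @method autoplot hymn_region_map
#' @export
autoplot.hymn_region_map <- function(object, ...) {
  pal <- c(
    allowed = "white", wet_stable = "#d62728",
    needs_too_much_voltage = "#2ca02c", slow_dryer = "#1f77b4",
    slow_wetter = "gray60"
  )
  ggplot(object, aes(x = .data$diameter, y = .data$aspect_ratio, fill = .data$label)) +
    geom_raster() +
    scale_fill_manual(values = pal, drop = FALSE) +
    labs(x = "Diameter (nm)", y = "Aspect ratio L/d", fill = NULL)
}

#' Plot a hysteresis-area spectrum
#'
#' @param object A `hymn_area_spectrum` from [area_vs_frequency()].
#' @param ... Unused.
#' @return A ggplot of loop area versus cycling frequency (log x).
#' @method autoplot hymn_area_spectrum
#' @export
autoplot.hymn_area_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$frequency, y = .data$area)) +
    geom_line() +
    geom_point() +
    scale_x_log10() +
    labs(x = "Cycling frequency (Hz)", y = "Loop area (nA V)")
}
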