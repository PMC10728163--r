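#' Read and write filling-profile TSV files
#'
#' Two tab-separated columns `xi` and `free_energy_kbt` with a header comment
#' line `# voltage=<V> temperature=<K>`. The reader tolerates extra comment
#' and blank lines.
#'
#' @param profile A [filling_profile()].
#' @param path File path.
#' @param temperature Temperature recorded in the header, K.
#' @return `write_profile_tsv()` returns `path` invisibly;
#'   `read_profile_tsv()` returns a [filling_profile()].
#' @export
write_profile_tsv <- function(profile, path, temperature = 310) {
  stopifnot(inherits(profile, "hymn_profile"))
  header <- sprintf("# voltage=%.17g temperature=%.17g", profile_voltage(profile), temperature)
  body <- sprintf("%.17g\t%.17g", profile$xi, profile$free_energy)
  writeLines(c(header, "xi\tfree_energy_kbt", body), path)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  voltage <- 0
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    m <- regmatches(h, regexec("voltage=([-+0-9.eE]+)", h))[[1]]
    if (length(m) == 2) voltage <- as.numeric(m[2])
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) > 0 && grepl("^xi", lines[1])) lines <- lines[-1]
  parts <- strsplit(lines, "\t|[[:space:]]+")
  xi <- as.numeric(map_chr(parts, 1))
  fe <- as.numeric(map_chr(parts, 2))
  filling_profile(xi, fe, voltage = voltage, metadata = sprintf("read from %s", path))
}

#' Read and write rate-curve CSV files
#'
#' Columns `voltage,k_wet,k_dry` preceded by a units comment; values are
#' written at full double precision so the file round-trips exactly.
#'
#' @param rates A `hymn_rate_curves`.
#' @param path File path.
#' @return `write_rates_csv()` returns `path` invisibly; `read_rates_csv()`
#'   a `hymn_rate_curves`.
#' @export
write_rates_csv <- function(rates, path) {
  stopifnot(inherits(rates, "hymn_rate_curves"))
  lines <- c(
    "# units: voltage=V, k_wet=1/s, k_dry=1/s; interpolation=log-linear",
    sprintf("# prefactor=%.17g", attr(rates, "prefactor") %||% NA_real_),
    "voltage,k_wet,k_dry,capped",
    sprintf(
      "%.17g,%.17g,%.17g,%d", rates$voltage, rates$k_wet, rates$k_dry,
      as.integer(rates$capped)
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rates_csv
#' @export
read_rates_csv <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))][-1] # drop the header row
  parts <- strsplit(body, ",", fixed = TRUE)
  # base-R numeric conversion is correctly rounded, so %.17g round-trips
  df <- list(
    voltage = as.numeric(map_chr(parts, 1)),
    k_wet = as.numeric(map_chr(parts, 2)),
    k_dry = as.numeric(map_chr(parts, 3)),
    capped = as.integer(map_chr(parts, 4))
  )
  df <- as_tibble(df)
  pref <- NA_real_
  for (h in grep("^#", readLines(path, n = 5), value = TRUE)) {
    m <- regmatches(h, regexec("prefactor=([-+0-9.eE]+)", h))[[1]]
    if (length(m) == 2) pref <- as.numeric(m[2])
  }
  new_tibble(
    list(
      voltage = df$voltage, k_wet = df$k_wet, k_dry = df$k_dry,
      capped = as.logical(df$capped)
    ),
    nrow = nrow(df), class = "hymn_rate_curves",
    prefactor = pref, interpolation = "log-linear"
  )
}

#' Read and write simulated traces
#'
#' The trace CSV holds columns `t,V,n,I` (columns absent from the trace are
#' written as NA); a JSON sidecar `<path>.json` stores the mode, seed and
#' waveform specification.
#'
#' @param trace A `hymn_trace`.
#' @param path CSV file path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   a `hymn_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "hymn_trace"))
  df <- tibble(
    t = trace$t, V = trace$V, n = trace$n,
    I = trace$I %||% rep(NA_real_, nrow(trace))
  )
  readr::write_csv(df, path)
  wf <- attr(trace, "params")$waveform
  side <- list(
    mode = attr(trace, "mode"), seed = attr(trace, "seed"),
    waveform = if (!is.null(wf)) unclass(wf[c("kind", "amplitude", "frequency", "n_cycles", "offset")])
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  side_path <- paste0(path, ".json")
  mode <- "deterministic"
  seed <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path)
    mode <- side$mode %||% mode
    seed <- side$seed
  }
  tr <- new_ensemble_trace(df$t, df$V, df$n, mode = mode, seed = seed)
  if (!all(is.na(df$I))) tr$I <- df$I
  tr
}

#' Read and write recorded traces
#'
#' Recording CSV with columns `t,V,I`; the sampling rate is recovered from
#' the time base.
#'
#' @param trace A [recorded_trace()].
#' @param path CSV file path.
#' @return `write_recording_csv()` returns `path` invisibly;
#'   `read_recording_csv()` a [recorded_trace()].
#' @export
write_recording_csv <- function(trace, path) {
  stopifnot(inherits(trace, "hymn_recording"))
  readr::write_csv(tibble(t = trace$t, V = trace$V, I = trace$I), path)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  recorded_trace(df$t, df$V, df$I,
    sampling_rate = 1 / median(diff(df$t)),
    meta = list(source = path)
  )
}

#' Export a region map
#'
#' Long-format CSV `diameter,aspect_ratio,label` plus a `<path>.json` sidecar
#' with the map parameters.
#'
#' @param map A [region_map()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_region_map_csv <- function(map, path) {
  stopifnot(inherits(map, "hymn_region_map"))
  readr::write_csv(
    tibble(
      diameter = map$diameter, aspect_ratio = map$aspect_ratio,
      label = as.character(map$label)
    ),
    path
  )
  p <- attr(map, "params")
  jsonlite::write_json(
    list(
      theta = p$theta, v_max = p$criteria$v_max,
      tau_dry_max = p$criteria$tau_dry_max, tau_wet_max = p$criteria$tau_wet_max,
      surface_tension = p$liquid$surface_tension, temperature = p$liquid$temperature,
      meniscus_count = p$liquid$meniscus_count, prefactor = p$prefactor,
      alpha = p$alpha
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a declarative model configuration
#'
#' YAML file with blocks `geometry` (`diameter_nm`, `length_nm`,
#' `contact_angle_deg`), `liquid` (`surface_tension`, `temperature`,
#' `pressure_difference`, `meniscus_count`, `water_permittivity`) and
#' `electrowetting` (`a_ew`, `mu_ew`, `alpha`). Missing liquid entries take
#' the [liquid_params()] defaults; `electrowetting` may give `a_ew`/`mu_ew`
#' directly or just `alpha` for the geometric estimate.
#'
#' @param path YAML file path.
#' @return A list with `geometry`, `liquid` and `ew` objects.
#' @export
read_hymn_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$geometry
  if (is.null(g)) abort("config lacks a `geometry` block")
  geometry <- pore_geometry(g$diameter_nm, g$length_nm, g$contact_angle_deg)
  lq <- cfg$liquid %||% list()
  defaults <- list(
    surface_tension = 0.070, temperature = 310, pressure_difference = 0,
    meniscus_count = 1, water_permittivity = 78
  )
  lq <- modifyList(defaults, lq)
  liquid <- liquid_params(
    surface_tension = lq$surface_tension, temperature = lq$temperature,
    pressure_difference = lq$pressure_difference,
    water_permittivity = lq$water_permittivity,
    meniscus_count = lq$meniscus_count
  )
  e <- cfg$electrowetting %||% list()
  ew <- if (!is.null(e$a_ew)) {
    electrowetting(a_ew = e$a_ew, mu_ew = e$mu_ew %||% 0, alpha = e$alpha %||% NA_real_)
  } else {
    ew_from_geometry(geometry, liquid, alpha = e$alpha %||% 0.30)
  }
  list(geometry = geometry, liquid = liquid, ew = ew)
}
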