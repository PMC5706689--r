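# Configuration files, CSV output of sweeps / metrics / maps, run manifests
# and the probability-map figure.

#' Read a simulation configuration from YAML or JSON
#'
#' The file mirrors the arguments of [simulation_config()],
#' [flight_path_params()] and [animal_params()]:
#'
#' ```yaml
#' flight: {period: 8, mean_depth: 7, water_depth: 20,
#'          fig8_height: 3, fig8_width: 10, tether_length: 25}
#' animal: {length: 1.41, speed: 1.8}
#' z_grid: {from: 0, by: 1, to: 20}
#' y_grid: {from: -7, by: 1, to: 7}
#' n_delays: 50
#' dt: 0.1
#' collision_threshold: 0.001
#' kite: {span: 3, chord: 0.75, thickness: 0.15}
#' tether_radius: 0.02
#' ```
#'
#' Grids may be given either as explicit lists or as `{from, by, to}` ranges.
#' Missing fields fall back to the baseline defaults; invalid values are
#' rejected with the offending field named.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [simulation_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config_from_list(raw)
}

parse_grid <- function(g, name) {
  if (is.null(g)) return(NULL)
  if (is.list(g) && all(c("from", "by", "to") %in% names(g))) {
    return(seq(g$from, g$to, by = g$by))
  }
  if (is.numeric(g)) return(as.numeric(g))
  stop(sprintf("field '%s' must be a numeric list or {from, by, to}", name),
       call. = FALSE)
}

take <- function(lst, name, default) {
  if (is.null(lst[[name]])) default else lst[[name]]
}

config_from_list <- function(raw) {
  fl <- take(raw, "flight", list())
  an <- take(raw, "animal", list())
  ki <- take(raw, "kite", list())
  wrap <- function(field, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("config field '%s': %s", field, conditionMessage(e)),
           call. = FALSE)
    })
  }
  flight <- wrap("flight", flight_path_params(
    period = take(fl, "period", 8), mean_depth = take(fl, "mean_depth", 7),
    water_depth = take(fl, "water_depth", 20),
    fig8_height = take(fl, "fig8_height", 3),
    fig8_width = take(fl, "fig8_width", 10),
    tether_length = take(fl, "tether_length", 25)))
  animal <- wrap("animal", animal_params(
    length = take(an, "length", 1.41), speed = take(an, "speed", 1.8)))
  wrap("simulation", simulation_config(
    flight = flight, animal = animal,
    z_grid = parse_grid(raw$z_grid, "z_grid") %||% 0:20,
    y_grid = parse_grid(raw$y_grid, "y_grid") %||% -7:7,
    n_delays = take(raw, "n_delays", 50), dt = take(raw, "dt", 0.1),
    collision_threshold = take(raw, "collision_threshold", 0.001),
    kite_span = take(ki, "span", 3), kite_chord = take(ki, "chord", 0.75),
    kite_thickness = take(ki, "thickness", 0.15),
    tether_radius = take(raw, "tether_radius", 0.02),
    include_kite = take(raw, "include_kite", TRUE),
    include_tether = take(raw, "include_tether", TRUE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read sweep trials as CSV
#'
#' One row per trial with the canonical columns
#' `(z0, y0, delta, collided, component, t_collision, x, y, z,
#' relative_speed)`. Reruns of the same configuration produce byte-identical
#' files.
#'
#' @param sweep a [run_sweep()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  tr <- sweep_trials(sweep)
  tr <- tr[, c("z0", "y0", "delta", "collided", "component", "t_collision",
               "x", "y", "z", "relative_speed")]
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("z0", "y0", "delta", "collided", "component", "t_collision",
            "x", "y", "z", "relative_speed")
  missing <- setdiff(need, names(tr))
  if (length(missing) > 0) {
    stop("sweep CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tr$collided <- as.logical(tr$collided)
  tibble::as_tibble(tr)
}

#' Write summary metrics as a key-value CSV
#'
#' @param metrics a [component_probabilities()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  stopifnot(inherits(metrics, "metrics_summary"))
  df <- data.frame(metric = names(unclass(metrics)),
                   value = unlist(unclass(metrics), use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a probability map as long-format CSV
#'
#' @param map a [probability_map()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest (JSON)
#'
#' Snapshot of the configuration, code version, timestamps and trial counts
#' for reproducibility audits.
#'
#' @param sweep a [run_sweep()] result.
#' @param path output file.
#' @param failures optional character vector of trial failure descriptions.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(sweep, path, failures = character()) {
  stopifnot(inherits(sweep, "kite_sweep"))
  cfg <- sweep$config
  manifest <- list(
    package = sweep$provenance$package,
    version = sweep$provenance$version,
    timestamp = sweep$provenance$timestamp,
    n_trials = nrow(sweep$trials),
    n_positions = length(cfg$z_grid) * length(cfg$y_grid),
    n_delays = cfg$n_delays,
    n_collisions = sum(sweep$trials$collided),
    failures = failures,
    config = list(
      flight = unclass(cfg$flight),
      animal = unclass(cfg$animal)[c("length", "speed")],
      z_grid = cfg$z_grid, y_grid = cfg$y_grid, n_delays = cfg$n_delays,
      dt = cfg$dt, collision_threshold = cfg$collision_threshold,
      kite = list(span = cfg$kite$span, chord = cfg$kite$chord,
                  thickness = cfg$kite$thickness),
      tether_radius = cfg$tether_radius,
      include_kite = cfg$include_kite,
      include_tether = cfg$include_tether))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Probability-map figure
#'
#' Renders the cross-section collision-probability map as coloured, scaled
#' circles at each grid position.
#'
#' @param map a [probability_map()] result.
#' @param component which probability to plot: total, per component
#'   (both-inclusive) or exclusive.
#' @return A ggplot object.
#' @export
plot_probability_map <- function(map, component = c("p", "p_kite", "p_tether",
                                                    "p_kite_only",
                                                    "p_tether_only")) {
  component <- match.arg(component)
  map$value <- map[[component]]
  ggplot2::ggplot(map, ggplot2::aes(x = .data$y, y = .data$z)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$value,
                                     colour = .data$value)) +
    ggplot2::scale_size_area(max_size = 8, limits = c(0, 1),
                             labels = scales_percent) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1),
                                    labels = scales_percent) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "y [m]", y = "height above seabed [m]",
                  size = "P(collision)", colour = "P(collision)") +
    ggplot2::theme_minimal()
}

scales_percent <- function(x) paste0(round(100 * x), "%")
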