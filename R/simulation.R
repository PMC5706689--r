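# Time-stepped trajectory simulation and the grid x phase-lag sweep.
#
# Every trial is a pure, deterministic function of (y0, z0, delta) and the
# configuration: per step the kite is posed first, the animal translated next,
# then the minimum distances to kite surface and tether capsule are tested
# against the collision threshold. Results are assembled in the canonical
# order z-major, then y, then delta, so repeated sweeps are bit-identical.

#' Simulation configuration
#'
#' Defaults are the baseline operating conditions: a 21 x 15 cross-section
#' grid at 1 m spacing spanning the water column and the flight-path width,
#' 50 phase lags evenly spaced over the kite period, a 0.1 s time step and a
#' 1 mm collision threshold.
#'
#' @param flight a [flight_path_params()].
#' @param animal an [animal_params()].
#' @param z_grid animal start heights above the seabed, m.
#' @param y_grid animal start lateral positions, m.
#' @param n_delays number of phase lags, evenly spaced over one kite period.
#' @param dt time step, s.
#' @param collision_threshold minimum distance scored as a collision, m.
#' @param kite_span,kite_chord,kite_thickness kite plate dimensions, m.
#' @param tether_radius tether capsule radius, m.
#' @param include_kite,include_tether logical; drop a component to study the
#'   other in isolation.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(flight = flight_path_params(),
                              animal = animal_params(),
                              z_grid = 0:20, y_grid = -7:7,
                              n_delays = 50, dt = 0.1,
                              collision_threshold = 0.001,
                              kite_span = 3, kite_chord = 0.75,
                              kite_thickness = 0.15,
                              tether_radius = 0.02,
                              include_kite = TRUE, include_tether = TRUE) {
  stopifnot(inherits(flight, "flight_path_params"),
            inherits(animal, "animal_params"))
  fail <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)
  if (length(z_grid) < 1 || length(y_grid) < 1) fail("grids must be non-empty")
  assert_finite(z_grid, "z_grid"); assert_finite(y_grid, "y_grid")
  if (anyDuplicated(z_grid) || anyDuplicated(y_grid)) {
    fail("grid positions must be unique")
  }
  if (!is.numeric(n_delays) || n_delays < 1 || n_delays != round(n_delays)) {
    fail("'n_delays' must be a positive integer")
  }
  if (dt <= 0) fail("'dt' must be > 0")
  if (collision_threshold <= 0) fail("'collision_threshold' must be > 0")
  if (tether_radius < 0) fail("'tether_radius' must be >= 0")
  kite <- build_kite_surface(kite_span, kite_chord, kite_thickness)
  if (!include_kite && !include_tether) {
    fail("at least one device component must be included")
  }
  structure(list(flight = flight, animal = animal,
                 z_grid = as.numeric(z_grid), y_grid = as.numeric(y_grid),
                 n_delays = as.integer(n_delays), dt = dt,
                 collision_threshold = collision_threshold,
                 kite = kite, tether_radius = tether_radius,
                 include_kite = include_kite,
                 include_tether = include_tether),
            class = "simulation_config")
}

#' Phase lags of a configuration
#'
#' `n_delays` values evenly spaced over the kite period: `k T / n_delays`,
#' `k = 0, ..., n_delays - 1`.
#'
#' @param cfg a [simulation_config()].
#' @return Numeric vector of phase lags, s.
#' @export
phase_lags <- function(cfg) {
  (seq_len(cfg$n_delays) - 1) * cfg$flight$period / cfg$n_delays
}

#' Trial design of a sweep
#'
#' One row per (z0, y0, delta) combination in canonical order (z-major, then
#' y, then delta).
#'
#' @param cfg a [simulation_config()].
#' @return Tibble with columns `z0`, `y0`, `delta`.
#' @export
trial_grid <- function(cfg) {
  deltas <- phase_lags(cfg)
  grid <- expand.grid(delta = deltas, y0 = cfg$y_grid, z0 = cfg$z_grid,
                      KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(z0 = grid$z0, y0 = grid$y0, delta = grid$delta)
}

# downstream stop position: the animal centre must clear the furthest point
# the device can reach, plus the animal's own semi-major axis so the tail
# clears too
stop_position <- function(cfg) {
  cfg$flight$tether_length + kite_bounding_radius(cfg$kite) +
    cfg$animal$semi_major
}

component_labels <- c("none", "kite", "tether", "both")

run_trials <- function(trials, cfg) {
  fp <- cfg$flight
  raw <- .run_trials_cpp(trials$y0, trials$z0, trials$delta,
                         fp$period, fp$mean_depth, fp$water_depth,
                         fp$fig8_height, fp$fig8_width, fp$tether_length,
                         cfg$kite$vertices, cfg$kite$faces, cfg$tether_radius,
                         cfg$animal$semi_major, cfg$animal$semi_minor,
                         cfg$animal$speed, cfg$dt, cfg$collision_threshold,
                         stop_position(cfg),
                         cfg$include_kite, cfg$include_tether)
  tibble::tibble(
    z0 = trials$z0, y0 = trials$y0, delta = trials$delta,
    collided = raw[, "collided"] > 0,
    component = component_labels[raw[, "component"] + 1],
    t_collision = raw[, "t_collision"],
    x = raw[, "x"], y = raw[, "y"], z = raw[, "z"],
    relative_speed = raw[, "relative_speed"])
}

#' Simulate a single transit trial
#'
#' Steps time from 0 in increments of `dt`; at each step the kite is posed,
#' the animal advanced, and the minimum distances to the kite surface and the
#' tether capsule evaluated. The first step at which either distance falls
#' below the collision threshold stops the trial and records the component
#' (or `"both"` if the animal touches kite and tether simultaneously);
#' otherwise the trial ends with `component = "none"` once the animal centre
#' passes the maximum downstream device position.
#'
#' @param y0,z0 animal start position in the cross-section, m.
#' @param delta phase lag between animal and kite motion, s.
#' @param cfg a [simulation_config()].
#' @return One-row tibble: `z0`, `y0`, `delta`, `collided`, `component`,
#'   `t_collision`, collision location `x`, `y`, `z` (midpoint of the closest
#'   point pair) and `relative_speed` at impact (m/s, recorded for future
#'   severity weighting).
#' @export
run_trajectory <- function(y0, z0, delta, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  assert_finite(c(y0, z0, delta), "trial coordinates")
  run_trials(tibble::tibble(z0 = z0, y0 = y0, delta = delta), cfg)
}

#' Run the full grid x phase-lag sweep
#'
#' One trial per (z0, y0, delta) combination, in canonical order. The sweep
#' is deterministic: repeated calls give bit-identical trial tables.
#'
#' @param cfg a [simulation_config()].
#' @param prune_dead_positions if `TRUE`, grid positions whose transit
#'   corridor provably stays clear of every device pose over one kite period
#'   are not simulated and recorded directly as non-collisions. The pruning
#'   bound is conservative, so results are unchanged; it only saves time.
#' @return Object of class `kite_sweep`: list with `trials` (tibble, one row
#'   per trial), `config`, and `provenance` (package version, timestamp).
#' @export
run_sweep <- function(cfg, prune_dead_positions = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  trials <- trial_grid(cfg)
  if (prune_dead_positions) {
    dead <- dead_positions(cfg)
    is_dead <- paste(trials$z0, trials$y0) %in% paste(dead$z0, dead$y0)
    live <- run_trials(trials[!is_dead, , drop = FALSE], cfg)
    skipped <- tibble::tibble(
      z0 = trials$z0[is_dead], y0 = trials$y0[is_dead],
      delta = trials$delta[is_dead], collided = FALSE, component = "none",
      t_collision = NA_real_, x = NA_real_, y = NA_real_, z = NA_real_,
      relative_speed = NA_real_)
    out <- rbind(live, skipped)
    ord <- order(match(paste(out$z0, out$y0, out$delta),
                       paste(trials$z0, trials$y0, trials$delta)))
    out <- out[ord, , drop = FALSE]
  } else {
    out <- run_trials(trials, cfg)
  }
  structure(list(trials = out, config = cfg,
                 provenance = list(
                   package = "kitecollide",
                   version = as.character(utils::packageVersion("kitecollide")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))),
            class = "kite_sweep")
}

# Conservative dead-position detection: a start position (y0, z0) is dead when
# the infinite cylinder of radius semi_minor swept by the animal along x
# clears every device pose over one kite period by more than the collision
# threshold plus a motion margin covering the phase discretisation.
dead_positions <- function(cfg) {
  fp <- cfg$flight
  n_phi <- max(1000L, ceiling(fp$period / (cfg$dt / 5)))
  phi <- (seq_len(n_phi) - 1) * fp$period / n_phi
  att <- attachment_point(phi, 0, fp)
  # bound on device point speed: attachment speed scaled to the kite extremity
  att_speed <- sqrt(rowSums((rbind(att[-1, ], att[1, ]) - att)^2)) /
    (fp$period / n_phi)
  v_dev <- max(att_speed) *
    (1 + kite_bounding_radius(cfg$kite) / fp$tether_length)
  margin <- cfg$collision_threshold + 2 * v_dev * (fp$period / n_phi)

  kite_r <- kite_bounding_radius(cfg$kite)
  grid <- expand.grid(y0 = cfg$y_grid, z0 = cfg$z_grid)
  dead <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    y0 <- grid$y0[i]; z0 <- grid$z0[i]
    # distance from the transit line to the tether segment [0, A(phi)]
    ay <- att[, 2]; az <- att[, 3]
    s <- pmin(1, pmax(0, (ay * y0 + az * z0) / (ay^2 + az^2)))
    d_teth <- sqrt((s * ay - y0)^2 + (s * az - z0)^2) - cfg$tether_radius
    d_kite <- sqrt((ay - y0)^2 + (az - z0)^2) - kite_r
    clear_t <- if (cfg$include_tether) min(d_teth) else Inf
    clear_k <- if (cfg$include_kite) min(d_kite) else Inf
    dead[i] <- (min(clear_t, clear_k) - cfg$animal$semi_minor) > margin
  }
  tibble::tibble(y0 = grid$y0[dead], z0 = grid$z0[dead])
}

#' Time-step convergence study
#'
#' Repeats the full sweep for a decreasing sequence of time steps and reports
#' the per-component collision counts and probabilities for each, the basis
#' for choosing a time step whose counts have stabilised.
#'
#' @param cfg a [simulation_config()]; its `dt` is ignored.
#' @param dts time steps to run, s; sorted into decreasing order and
#'   deduplicated (with a warning) if needed.
#' @return Tibble with one row per time step: `dt`, `n_coll_kite`,
#'   `n_coll_tether`, `n_coll_both`, `n_coll`, `p_a_kite`, `p_a_tether`,
#'   `p_a_device` (probabilities in percent; "both" collisions are credited
#'   to both components).
#' @export
convergence_study <- function(cfg, dts) {
  stopifnot(inherits(cfg, "simulation_config"))
  assert_finite(dts, "dts")
  if (any(dts <= 0)) stop("'dts' must be > 0", call. = FALSE)
  if (anyDuplicated(dts)) {
    warning("duplicate time steps removed")
    dts <- unique(dts)
  }
  dts <- sort(dts, decreasing = TRUE)
  rows <- lapply(dts, function(step) {
    cfg_i <- cfg
    cfg_i$dt <- step
    m <- component_probabilities(run_sweep(cfg_i))
    tibble::tibble(dt = step,
                   n_coll_kite = m$n_coll_kite,
                   n_coll_tether = m$n_coll_tether,
                   n_coll_both = m$n_coll_both,
                   n_coll = m$n_coll,
                   p_a_kite = m$p_a_kite,
                   p_a_tether = m$p_a_tether,
                   p_a_device = m$p_a)
  })
  do.call(rbind, rows)
}
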