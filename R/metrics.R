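# Probability metrics over sweep results: the cross-section probability P_A,
# the swept-area probability P_SweptA, per-component bookkeeping, the
# per-position probability map, and the classic rotor-disc formula for
# horizontal-axis turbines (for comparison).

sweep_trials <- function(sweep) {
  if (inherits(sweep, "kite_sweep")) return(sweep$trials)
  if (is.data.frame(sweep)) return(sweep)
  stop("expected a 'kite_sweep' or a trials data frame", call. = FALSE)
}

sweep_n_delays <- function(sweep) {
  if (inherits(sweep, "kite_sweep")) return(sweep$config$n_delays)
  length(unique(sweep_trials(sweep)$delta))
}

#' Cross-section collision probability P_A
#'
#' `P_A = 100 NColl / NSim` (percent): the collision probability averaged over
#' every trial launched from the investigated cross-section.
#'
#' @param n_coll total number of collisions.
#' @param n_sim total number of simulations.
#' @return Probability in percent.
#' @export
p_a <- function(n_coll, n_sim) {
  stopifnot(n_sim > 0, n_coll >= 0, n_coll <= n_sim)
  100 * n_coll / n_sim
}

#' Swept-area collision probability P_SweptA
#'
#' `P_SweptA = 100 NColl / (NCollPos * n_delays)` (percent): the collision
#' probability averaged only over trials launched from collision-prone
#' positions (positions with at least one collision across the tested phase
#' lags). Directly comparable to the rotor-disc probability of
#' [classic_rotor_probability()]. With no collisions at all the probability
#' is 0.
#'
#' @param n_coll total number of collisions.
#' @param n_coll_pos number of grid positions with at least one collision.
#' @param n_delays number of phase lags per position.
#' @return Probability in percent.
#' @export
p_swept_a <- function(n_coll, n_coll_pos, n_delays) {
  stopifnot(n_coll >= 0, n_coll_pos >= 0, n_delays >= 1)
  if (n_coll_pos == 0) {
    if (n_coll > 0) stop("collisions recorded but no collision-prone positions",
                         call. = FALSE)
    return(0)
  }
  stopifnot(n_coll <= n_coll_pos * n_delays)
  100 * n_coll / (n_coll_pos * n_delays)
}

#' Summary metrics of a sweep
#'
#' Counts collisions per component and computes the probability metrics.
#' Trials that touch kite and tether simultaneously are counted once in
#' `n_coll` but credited to both components in the per-component
#' probabilities; the raw kite-only / tether-only / both counts are reported
#' alongside. The tether/kite ratio uses the exclusive counts, rounded to one
#' decimal.
#'
#' @param sweep a [run_sweep()] result (or its trials tibble).
#' @return Object of class `metrics_summary`: a list with `n_sim`,
#'   `n_coll_kite`, `n_coll_tether`, `n_coll_both`, `n_coll`, `n_coll_pos`,
#'   `p_a`, `p_a_kite`, `p_a_tether`, `p_swept_a` (percent) and
#'   `tether_kite_ratio` (NA when no kite-only collisions occurred).
#' @export
component_probabilities <- function(sweep) {
  tr <- sweep_trials(sweep)
  n_delays <- sweep_n_delays(sweep)
  n_sim <- nrow(tr)
  n_kite <- sum(tr$component == "kite")
  n_teth <- sum(tr$component == "tether")
  n_both <- sum(tr$component == "both")
  n_coll <- sum(tr$collided)
  stopifnot(n_coll == n_kite + n_teth + n_both)
  pos <- paste(tr$z0, tr$y0)
  n_coll_pos <- length(unique(pos[tr$collided]))
  structure(list(
    n_sim = n_sim,
    n_coll_kite = n_kite, n_coll_tether = n_teth, n_coll_both = n_both,
    n_coll = n_coll, n_coll_pos = n_coll_pos,
    p_a = p_a(n_coll, n_sim),
    p_a_kite = p_a(n_kite + n_both, n_sim),
    p_a_tether = p_a(n_teth + n_both, n_sim),
    p_swept_a = p_swept_a(n_coll, n_coll_pos, n_delays),
    tether_kite_ratio = if (n_kite > 0) round(n_teth / n_kite, 1) else NA_real_),
    class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat("Collision metrics over", x$n_sim, "trials\n")
  cat(sprintf("  collisions: %d (kite-only %d, tether-only %d, both %d)\n",
              x$n_coll, x$n_coll_kite, x$n_coll_tether, x$n_coll_both))
  cat(sprintf("  collision-prone positions: %d\n", x$n_coll_pos))
  cat(sprintf("  P_A = %.2f%%  (kite %.2f%%, tether %.2f%%)\n",
              x$p_a, x$p_a_kite, x$p_a_tether))
  cat(sprintf("  P_SweptA = %.2f%%\n", x$p_swept_a))
  cat(sprintf("  tether/kite ratio = %s\n",
              ifelse(is.na(x$tether_kite_ratio), "n/a",
                     format(x$tether_kite_ratio))))
  invisible(x)
}

#' Per-position collision probability map
#'
#' Collision probability at each cross-section grid position: the fraction of
#' phase lags that produced a collision, so every value is a multiple of
#' `1 / n_delays`. Per-component probabilities are given both crediting
#' simultaneous ("both") collisions to each component (`p_kite`, `p_tether`)
#' and exclusively (`p_kite_only`, `p_tether_only`).
#'
#' @param sweep a [run_sweep()] result (or its trials tibble).
#' @return Tibble ordered z-major then y, columns `y`, `z`, `n_delays`, `p`,
#'   `p_kite`, `p_tether`, `p_kite_only`, `p_tether_only` (probabilities in
#'   `[0, 1]`).
#' @export
probability_map <- function(sweep) {
  tr <- sweep_trials(sweep)
  n_delays <- sweep_n_delays(sweep)
  key <- interaction(tr$z0, tr$y0, drop = TRUE, lex.order = TRUE)
  agg <- function(x) as.vector(tapply(x, key, sum))
  first <- function(x) as.vector(tapply(x, key, `[`, 1L))
  out <- tibble::tibble(
    y = first(tr$y0), z = first(tr$z0), n_delays = n_delays,
    p = agg(tr$collided) / n_delays,
    p_kite = agg(tr$component %in% c("kite", "both")) / n_delays,
    p_tether = agg(tr$component %in% c("tether", "both")) / n_delays,
    p_kite_only = agg(tr$component == "kite") / n_delays,
    p_tether_only = agg(tr$component == "tether") / n_delays)
  out[order(out$z, out$y), , drop = FALSE]
}

#' Classic rotor-disc collision probability
#'
#' The conventional estimate for a horizontal-axis turbine:
#' `P_C = N omega L cos(alpha) / v`, the fraction of the rotor disc swept by
#' the `N` blades during the time an animal of length `L` takes to pass at
#' speed `v` under angle `alpha` to the flow. `omega` is the rotational
#' velocity in revolutions per second (use `omega_unit` to pass rad/s or
#' rpm). Raw values above 1 are clamped with a warning.
#'
#' @param n_blades number of blades.
#' @param omega rotational velocity.
#' @param length animal length, m.
#' @param alpha angle of the animal to the flow direction, rad, in
#'   `[0, pi/2]`.
#' @param speed animal speed, m/s.
#' @param omega_unit unit of `omega`.
#' @return Probability in `[0, 1]`.
#' @export
classic_rotor_probability <- function(n_blades, omega, length, alpha, speed,
                                      omega_unit = c("rev_per_s", "rad_per_s",
                                                     "rpm")) {
  omega_unit <- match.arg(omega_unit)
  stopifnot(n_blades > 0, omega >= 0, length >= 0, speed > 0,
            alpha >= 0, alpha <= pi / 2)
  omega_rev <- switch(omega_unit,
                      rev_per_s = omega,
                      rad_per_s = omega / (2 * pi),
                      rpm = omega / 60)
  raw <- n_blades * omega_rev * length * cos(alpha) / speed
  if (raw > 1) {
    warning("raw rotor-disc probability exceeds 1; clamped")
    return(1)
  }
  raw
}
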