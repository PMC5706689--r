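# Kite pose as a function of time and phase lag, and animal translation.
#
# The kite hangs on a straight tether of length L anchored at the origin and
# is positioned by a sequence of three rotations about that bottom joint:
#   beta  — polar angle from the vertical; the kite centre depth oscillates
#           around the mean depth D with period T/2,
#   gamma — azimuthal angle; the lateral position oscillates around the
#           centre plane y = 0 with period T (the 2:1 Lissajous ratio that
#           traces a figure-of-eight),
#   alpha — spin about the tether axis, chosen from the two most recent
#           attachment points so the kite chord points along the flight path.
# Heights are measured above the seabed, so "depth D" maps to height H - D.

#' Flight-path parameters of the tidal kite
#'
#' @param period time for one full figure-of-eight, s (`T`).
#' @param mean_depth mean kite depth below the surface, m (`D`).
#' @param water_depth water depth, m (`H`).
#' @param fig8_height vertical extent of the figure-of-eight, m (`h`).
#' @param fig8_width lateral extent of the figure-of-eight, m (`w`).
#' @param tether_length tether length, m.
#' @return Object of class `flight_path_params`.
#' @export
flight_path_params <- function(period = 8, mean_depth = 7, water_depth = 20,
                               fig8_height = 3, fig8_width = 10,
                               tether_length = 25) {
  p <- list(period = period, mean_depth = mean_depth, water_depth = water_depth,
            fig8_height = fig8_height, fig8_width = fig8_width,
            tether_length = tether_length)
  for (nm in names(p)) assert_finite(p[[nm]], nm)
  fail <- function(msg) stop("invalid flight path: ", msg, call. = FALSE)
  if (period <= 0) fail("'period' must be > 0")
  if (mean_depth <= 0 || mean_depth >= water_depth) {
    fail("'mean_depth' must satisfy 0 < D < H")
  }
  if (fig8_height < 0 || fig8_width < 0) {
    fail("'fig8_height' and 'fig8_width' must be >= 0")
  }
  if (tether_length <= 0) fail("'tether_length' must be > 0")
  if (fig8_height / 2 >= min(mean_depth, water_depth - mean_depth) &&
      fig8_height > 0) {
    fail("figure-of-eight height exceeds the clearance around the mean depth")
  }
  cos_hi <- (water_depth - mean_depth + fig8_height / 2) / tether_length
  cos_lo <- (water_depth - mean_depth - fig8_height / 2) / tether_length
  if (cos_hi > 1 || cos_lo < -1) {
    fail("kite depth excursion is unreachable on this tether (arccos domain)")
  }
  if (fig8_width > 0) {
    sin_min <- sqrt(1 - max(abs(cos_hi), abs(cos_lo))^2)
    if (sin_min <= 0 || fig8_width / 2 > tether_length * sin_min) {
      fail("figure-of-eight width is unreachable on this tether (arcsin domain)")
    }
  }
  structure(p, class = "flight_path_params")
}

#' Animal parameters
#'
#' The animal is a prolate ellipsoid with major radius `length / 2` and minor
#' radii `length / 3`, translating at constant speed in the +x direction.
#'
#' @param length animal length, m.
#' @param speed animal speed, m/s.
#' @return Object of class `animal_params` with derived `semi_major` and
#'   `semi_minor`.
#' @export
animal_params <- function(length = 1.41, speed = 1.8) {
  assert_finite(length, "length"); assert_finite(speed, "speed")
  if (length <= 0 || speed <= 0) {
    stop("animal 'length' and 'speed' must be > 0", call. = FALSE)
  }
  structure(list(length = length, speed = speed,
                 semi_major = length / 2, semi_minor = length / 3),
            class = "animal_params")
}

#' Kite polar angle beta
#'
#' `beta = arccos((H - D + (h/2) sin(4 pi / T (t - delta))) / L_tether)`.
#' The vertical angular frequency `4 pi / T` gives the kite-centre depth a
#' period of `T / 2`; the height above seabed is `L_tether * cos(beta)`.
#'
#' @param t time, s (vectorised).
#' @param delta phase lag, s.
#' @param params a [flight_path_params()].
#' @return Angle(s) in radians.
#' @export
beta_angle <- function(t, delta, params) {
  arg <- (params$water_depth - params$mean_depth +
            params$fig8_height / 2 *
              sin(4 * pi / params$period * (t - delta))) / params$tether_length
  if (any(arg < -1 | arg > 1)) {
    stop("arccos argument outside [-1, 1]: unreachable kite depth",
         call. = FALSE)
  }
  acos(arg)
}

#' Kite azimuthal angle gamma
#'
#' `gamma = arcsin((w/2) sin(2 pi / T (t - delta)) / (L_tether sin(beta)))`.
#' The lateral attachment position `L_tether sin(beta) sin(gamma)` then
#' oscillates exactly in `[-w/2, w/2]` with period `T`.
#'
#' @inheritParams beta_angle
#' @param beta polar angle(s) from [beta_angle()]; recomputed when missing.
#' @return Angle(s) in radians.
#' @export
gamma_angle <- function(t, delta, params, beta = beta_angle(t, delta, params)) {
  if (params$fig8_width == 0) return(rep(0, length(t)))
  sb <- sin(beta)
  if (any(sb <= 0)) stop("gamma undefined for sin(beta) = 0", call. = FALSE)
  arg <- params$fig8_width / 2 * sin(2 * pi / params$period * (t - delta)) /
    (params$tether_length * sb)
  if (any(arg < -1 | arg > 1)) {
    stop("arcsin argument outside [-1, 1]: unreachable lateral excursion",
         call. = FALSE)
  }
  asin(arg)
}

#' Tether attachment point on the flight path
#'
#' @inheritParams beta_angle
#' @return An n x 3 matrix (or length-3 vector for scalar `t`) of world
#'   coordinates; the norm of every row equals the tether length.
#' @export
attachment_point <- function(t, delta, params) {
  beta <- beta_angle(t, delta, params)
  gamma <- gamma_angle(t, delta, params, beta)
  out <- params$tether_length *
    cbind(sin(beta) * cos(gamma), sin(beta) * sin(gamma), cos(beta))
  if (length(t) == 1L) drop(out) else out
}

#' Kite heading from the two most recent positions
#'
#' Returns the spin angle `alpha` about the tether axis that aligns the kite
#' chord axis (body x) with the finite-difference direction of attachment
#' point motion from `state_prev2` to `state_prev1`, expressed in the
#' (beta, gamma) frame of `state_prev1`. Coincident positions reuse the
#' previous heading.
#'
#' @param state_prev2,state_prev1 two `kite_state` objects at distinct times
#'   (`state_prev1` the more recent).
#' @return Angle in radians.
#' @export
alpha_heading <- function(state_prev2, state_prev1) {
  m <- state_prev1$attachment - state_prev2$attachment
  if (sqrt(sum(m^2)) < 1e-12) return(state_prev1$alpha)
  base <- rot_z(state_prev1$gamma) %*% rot_y(state_prev1$beta)
  u <- drop(t(base) %*% m)
  atan2(u[2], u[1])
}

#' Kite state (pose) at a time instant
#'
#' Composes the three rotations about the bottom joint. The heading `alpha`
#' is taken from the attachment points at `t - dt` and `t` (when no explicit
#' history is given the parametric path itself provides them, which also
#' bootstraps the first step of a simulation).
#'
#' @inheritParams beta_angle
#' @param history optional list of the two previous `kite_state` objects
#'   (`list(prev2, prev1)`) from which to derive the heading.
#' @param dt finite-difference step for the bootstrap heading, s.
#' @return Object of class `kite_state`: time, the three angles, the
#'   attachment point and a [rigid_transform()] pose whose translation is the
#'   attachment point.
#' @export
kite_pose <- function(t, delta, params, history = NULL, dt = 0.1) {
  beta <- beta_angle(t, delta, params)
  gamma <- gamma_angle(t, delta, params, beta)
  attachment <- attachment_point(t, delta, params)
  base <- rot_z(gamma) %*% rot_y(beta)
  if (is.null(history)) {
    a_prev <- attachment_point(t - dt, delta, params)
    m <- attachment - a_prev
  } else {
    m <- history[[2]]$attachment - history[[1]]$attachment
  }
  if (sqrt(sum(m^2)) < 1e-12) {
    alpha <- if (is.null(history)) 0 else history[[2]]$alpha
  } else {
    u <- drop(t(base) %*% m)
    alpha <- atan2(u[2], u[1])
  }
  rotation <- base %*% rot_z(alpha)
  structure(list(t = t, alpha = alpha, beta = beta, gamma = gamma,
                 attachment = attachment,
                 pose = rigid_transform(rotation, attachment)),
            class = "kite_state")
}

#' Animal position at time t
#'
#' Linear translation `(v t, y0, z0)` from the initial cross-section position;
#' the orientation is fixed with the major axis along +x.
#'
#' @param t time, s (vectorised).
#' @param animal an [animal_params()].
#' @param y0,z0 initial cross-section position, m (z measured above seabed).
#' @return Length-3 vector (scalar `t`) or n x 3 matrix of centre positions.
#' @export
animal_position <- function(t, animal, y0 = 0, z0 = 0) {
  stopifnot(inherits(animal, "animal_params"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  out <- cbind(animal$speed * t, rep(y0, length(t)), rep(z0, length(t)))
  if (length(t) == 1L) drop(out) else out
}
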