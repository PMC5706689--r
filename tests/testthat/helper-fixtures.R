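# Shared fixtures: all inputs are generated in code.

cross3_r <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# uniform random proper rotation (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_pose <- function(translation_sd = 2) {
  rigid_transform(random_rotation(), rnorm(3, sd = translation_sd))
}

baseline_flight <- function() flight_path_params()

# reduced sweep used by the property-based acceptance checks: 7 heights
# (including the mooring point and positions above the reachable volume),
# a symmetric lateral grid, 10 phase lags, coarse 0.2 s step
reduced_config <- function(...) {
  simulation_config(z_grid = c(0, 3, 6, 10, 14, 17, 20),
                    y_grid = c(-4, -2, 0, 2, 4),
                    n_delays = 10, dt = 0.2, ...)
}

# tiny sweep for fast structural tests
tiny_config <- function(...) {
  simulation_config(z_grid = c(0, 6, 13), y_grid = c(-2, 0, 2),
                    n_delays = 3, dt = 0.2, ...)
}

# highest start position that can still produce a collision: top of the
# flight envelope plus kite reach plus animal radius
reachable_height <- function(cfg) {
  fp <- cfg$flight
  (fp$water_depth - fp$mean_depth) + fp$fig8_height / 2 +
    sqrt((cfg$kite$span / 2)^2 + (cfg$kite$chord / 2)^2 +
           (cfg$kite$thickness / 2)^2) +
    cfg$animal$semi_major
}
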