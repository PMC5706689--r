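test_that("trial bookkeeping follows the grid and delay specification", {
  cfg <- simulation_config()
  expect_equal(nrow(trial_grid(cfg)), 21 * 15 * 50)

  single <- simulation_config(z_grid = 5, y_grid = 0, n_delays = 1)
  expect_equal(nrow(trial_grid(single)), 1)

  base <- simulation_config(z_grid = c(0, 5), y_grid = c(-1, 0, 1),
                            n_delays = 4)
  doubled <- simulation_config(z_grid = c(0, 5),
                               y_grid = c(-1, 0, 1, 2, 3, 4), n_delays = 4)
  expect_equal(nrow(trial_grid(doubled)), 2 * nrow(trial_grid(base)))

  expect_equal(phase_lags(simulation_config(n_delays = 4)), c(0, 2, 4, 6))
})

test_that("a transit over the mooring point always hits the tether", {
  cfg <- simulation_config(z_grid = 0, y_grid = 0, n_delays = 5)
  sw <- run_sweep(cfg)
  expect_true(all(sw$trials$collided))
  expect_true(all(sw$trials$component == "tether"))
  expect_equal(sw$trials$t_collision, rep(0, 5))
})

test_that("starts above the reachable volume never collide", {
  cfg <- simulation_config(n_delays = 5, dt = 0.2)
  high <- reachable_height(cfg) + 0.2
  sw <- run_sweep(simulation_config(z_grid = c(high, high + 2), y_grid = 0,
                                    n_delays = 5, dt = 0.2))
  expect_false(any(sw$trials$collided))
  expect_true(all(sw$trials$component == "none"))
})

test_that("a static vertical tether reproduces the closed-form swept-tube test", {
  # h = w = 0 and H - D = L_tether: the tether stands fixed and vertical, so
  # a collision occurs iff the animal's swept tube (radius = minor semi-axis)
  # reaches the capsule
  fp <- flight_path_params(period = 8, mean_depth = 5, water_depth = 30,
                           fig8_height = 0, fig8_width = 0,
                           tether_length = 25)
  cfg <- simulation_config(flight = fp,
                           z_grid = c(0, 5, 15, 24.5, 25.3, 25.8, 27),
                           y_grid = c(0, 0.3, 0.45, 0.6, 1.5),
                           n_delays = 1, dt = 0.05, include_kite = FALSE,
                           tether_radius = 0.02)
  sw <- run_sweep(cfg)
  reach <- cfg$animal$semi_minor + cfg$tether_radius + cfg$collision_threshold
  predicted <- mapply(function(y0, z0) {
    u <- min(25, max(0, z0))
    sqrt(y0^2 + (z0 - u)^2) < reach
  }, sw$trials$y0, sw$trials$z0)
  expect_equal(sw$trials$collided, unname(predicted))
})

test_that("sweeps are deterministic and account components consistently", {
  cfg <- tiny_config()
  sw1 <- run_sweep(cfg)
  sw2 <- run_sweep(cfg)
  expect_identical(sw1$trials, sw2$trials)

  tr <- sw1$trials
  expect_equal(sum(tr$collided),
               sum(tr$component %in% c("kite", "tether", "both")))
  expect_true(all(tr$component[!tr$collided] == "none"))
  expect_true(all(tr$t_collision[tr$collided] >= 0))
  expect_true(all(is.na(tr$t_collision[!tr$collided])))
  # collision locations and relative speeds recorded for every collision
  expect_false(any(is.na(tr$x[tr$collided])))
  expect_true(all(tr$relative_speed[tr$collided] > 0))
})

test_that("removing the kite never creates collisions (trial-wise subset)", {
  full <- run_sweep(reduced_config())$trials
  tether_only <- run_sweep(reduced_config(include_kite = FALSE))$trials
  expect_true(all(!tether_only$collided | full$collided))
  # and the tether-only collision count is bounded by the full device count
  expect_lte(sum(tether_only$collided), sum(full$collided))
})

test_that("single trials match their row of the sweep", {
  cfg <- tiny_config()
  sw <- run_sweep(cfg)
  row <- sw$trials[17, ]
  single <- run_trajectory(row$y0, row$z0, row$delta, cfg)
  expect_equal(single, row, ignore_attr = TRUE)
})

test_that("time-step convergence study stabilizes and is reproducible", {
  cfg <- simulation_config(z_grid = c(0, 2, 4, 8, 12, 13, 14, 16),
                           y_grid = c(-3, -1, 0, 1, 3), n_delays = 10)
  tab <- convergence_study(cfg, c(0.2, 0.1, 0.05, 0.01))
  expect_equal(tab$dt, c(0.2, 0.1, 0.05, 0.01))
  expect_equal(tab$n_coll,
               tab$n_coll_kite + tab$n_coll_tether + tab$n_coll_both)
  # refinements stabilize: the late difference is bounded by the coarse one
  expect_lte(abs(tab$n_coll[3] - tab$n_coll[4]),
             max(1, abs(tab$n_coll[1] - tab$n_coll[4])))
  expect_lt(abs(tab$p_a_device[3] - tab$p_a_device[4]), 1)

  # identical time steps give identical counts; duplicates are removed
  expect_warning(tab2 <- convergence_study(cfg, c(0.2, 0.2, 0.1, 0.05, 0.01)),
                 "duplicate")
  expect_equal(tab2, tab)

  # a time step longer than the transit allows at most one step: the kite
  # can only be met if it already blocks the start position
  coarse <- convergence_study(simulation_config(z_grid = c(6, 10),
                                                y_grid = c(-2, 2),
                                                n_delays = 3), 60)
  expect_lte(coarse$n_coll, 12)
})

test_that("dead-position pruning never changes sweep outcomes", {
  cfg <- reduced_config()
  plain <- run_sweep(cfg)
  pruned <- run_sweep(cfg, prune_dead_positions = TRUE)
  expect_identical(plain$trials$collided, pruned$trials$collided)
  expect_identical(plain$trials$component, pruned$trials$component)
})

test_that("configuration validation rejects impossible setups", {
  expect_error(flight_path_params(mean_depth = 25, water_depth = 20),
               "0 < D < H")
  expect_error(simulation_config(dt = 0), "dt")
  expect_error(simulation_config(n_delays = 0), "n_delays")
  expect_error(simulation_config(collision_threshold = -1), "threshold")
  expect_error(simulation_config(z_grid = numeric()), "non-empty")
  expect_error(simulation_config(include_kite = FALSE,
                                 include_tether = FALSE), "component")
})
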