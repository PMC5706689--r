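test_that("beta angle reproduces the flight-path depth law", {
  fp <- baseline_flight()
  # sin term zero: arccos((H - D)/L_tether) = arccos(13/25)
  expect_equal(beta_angle(0, 0, fp), acos(13 / 25))
  expect_equal(beta_angle(3, 3, fp), acos(13 / 25))

  # flat path: beta constant in t
  flat <- flight_path_params(fig8_height = 0)
  tt <- seq(0, 16, by = 0.1)
  expect_equal(diff(range(beta_angle(tt, 0, flat))), 0)

  # vertical period T/2
  expect_equal(beta_angle(tt, 0.3, fp), beta_angle(tt + fp$period / 2, 0.3, fp))

  # unreachable depth excursion is rejected at construction
  expect_error(flight_path_params(water_depth = 40, mean_depth = 5),
               "arccos|unreachable")
})

test_that("gamma angle gives the lateral oscillation with period T", {
  fp <- baseline_flight()
  expect_equal(gamma_angle(0, 0, fp), 0)
  tt <- seq(0, 16, by = 0.05)
  expect_equal(gamma_angle(tt, 0.7, fp), gamma_angle(tt + fp$period, 0.7, fp))

  # extreme lateral excursion of the attachment point is w/2 = 5 m
  att <- attachment_point(seq(0, 8, by = 1e-3), 0, fp)
  expect_equal(max(att[, 2]), 5, tolerance = 1e-6)
  expect_equal(min(att[, 2]), -5, tolerance = 1e-6)
})

test_that("attachment path traces a closed figure-of-eight inside its envelope", {
  fp <- baseline_flight()
  tt <- seq(0, fp$period, length.out = 4001)[-4001]
  att <- attachment_point(tt, 0, fp)

  # tether length is preserved everywhere
  expect_equal(sqrt(rowSums(att^2)), rep(25, nrow(att)), tolerance = 1e-9)

  # depth extremes of the kite centre height are (H - D) +/- h/2
  expect_equal(max(att[, 3]), 13 + 1.5, tolerance = 1e-5)
  expect_equal(min(att[, 3]), 13 - 1.5, tolerance = 1e-5)

  # figure-of-eight: two mirror-image lobes joined at a single
  # self-intersection on the centre plane, crossed twice per period
  tt_off <- tt + 0.0137  # avoid sampling the crossing exactly
  att_off <- attachment_point(tt_off, 0, fp)
  y <- att_off[, 2]
  crossings <- which(y * c(y[-1], y[1]) < 0)
  expect_equal(length(crossings), 2)
  expect_equal(att_off[crossings, 3], c(13, 13), tolerance = 1e-2)
  expect_gt(max(y), 4.9)
  expect_lt(min(y), -4.9)

  # path is invariant under (y -> -y, t -> t + T/2)
  shifted <- attachment_point(tt + fp$period / 2, 0, fp)
  expect_equal(shifted[, 1], att[, 1], tolerance = 1e-9)
  expect_equal(shifted[, 2], -att[, 2], tolerance = 1e-9)
  expect_equal(shifted[, 3], att[, 3], tolerance = 1e-9)
})

test_that("heading follows the attachment motion and is stable on a circle", {
  fp <- baseline_flight()
  mk <- function(beta, gamma, att) {
    structure(list(alpha = 0.3, beta = beta, gamma = gamma, attachment = att),
              class = "kite_state")
  }
  # uniform circular attachment motion: equal heading increments
  beta <- 1
  g <- seq(0, 0.5, by = 0.05)
  att <- t(sapply(g, function(gg) {
    25 * c(sin(beta) * cos(gg), sin(beta) * sin(gg), cos(beta))
  }))
  alphas <- sapply(2:length(g), function(i) {
    alpha_heading(mk(beta, g[i - 1], att[i - 1, ]),
                  mk(beta, g[i], att[i, ]))
  })
  expect_equal(diff(alphas), rep(0, length(alphas) - 1), tolerance = 1e-9)

  # coincident positions reuse the previous heading
  s <- mk(1, 0, c(1, 2, 3))
  expect_equal(alpha_heading(s, s), 0.3)

  # stationary parametric path (h = 0, w = 0) keeps the initial heading
  flat <- flight_path_params(fig8_height = 0, fig8_width = 0)
  st <- kite_pose(1, 0, flat)
  expect_equal(st$alpha, 0)
})

test_that("kite pose composes the three rotations about the bottom joint", {
  fp <- baseline_flight()
  st <- kite_pose(0, 0, fp)
  # t - delta = 0: laterally centred at height H - D = 13 m
  expect_equal(st$gamma, 0)
  expect_equal(st$attachment, c(25 * sin(acos(13 / 25)), 0, 13),
               tolerance = 1e-12)
  expect_equal(sqrt(sum(st$attachment^2)), 25, tolerance = 1e-9)
  expect_equal(st$pose$translation, st$attachment)
  expect_equal(crossprod(st$pose$rotation), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)

  # pose is T-periodic once the heading history has warmed up
  for (t0 in c(0.3, 2.1, 5.7)) {
    a <- kite_pose(t0, 0.4, fp)
    b <- kite_pose(t0 + fp$period, 0.4, fp)
    expect_equal(a$attachment, b$attachment, tolerance = 1e-6)
    expect_equal(a$pose$rotation, b$pose$rotation, tolerance = 1e-6)
  }
})

test_that("animal translation is linear from the start position", {
  a <- animal_params()
  expect_equal(animal_position(0, a, y0 = -3, z0 = 7), c(0, -3, 7))
  expect_equal(animal_position(10, a)[1], 18)
  xs <- animal_position(seq(0, 5, by = 0.5), a, 1, 2)
  expect_equal(diff(xs[, 1]), rep(0.9, 10))
  expect_error(animal_position(-1, a), ">= 0")
})

test_that("R and compiled kinematics agree", {
  fp <- baseline_flight()
  for (t in seq(-2, 17, by = 0.37)) {
    cpp <- kitecollide:::.attach_cpp(t, 0.53, fp$period, fp$mean_depth,
                                     fp$water_depth, fp$fig8_height,
                                     fp$fig8_width, fp$tether_length)
    expect_equal(unname(cpp[c("x", "y", "z")]),
                 attachment_point(t, 0.53, fp), tolerance = 1e-12)
    expect_equal(unname(cpp["beta"]), beta_angle(t, 0.53, fp),
                 tolerance = 1e-12)
  }
})
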