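test_that("point-to-ellipsoid distance handles spheres, containment and a generic point", {
  sphere <- ellipsoid_shape(2, 2)
  res <- point_to_ellipsoid_distance(c(5, 0, 0), sphere)
  expect_equal(res$distance, 3)
  expect_false(res$contained)

  centre <- point_to_ellipsoid_distance(c(0, 0, 0), sphere)
  expect_equal(centre$distance, 0)
  expect_true(centre$contained)

  # off-axis sphere point: radius arithmetic
  res <- point_to_ellipsoid_distance(c(3, 4, 0), ellipsoid_shape(1, 1))
  expect_equal(res$distance, 4)

  # frozen value from dense surface-sampling minimisation (4e6 samples)
  res <- point_to_ellipsoid_distance(c(3, 1, 0.5), ellipsoid_shape(2, 1))
  expect_equal(res$distance, 1.362938, tolerance = 1e-4)

  expect_error(point_to_ellipsoid_distance(c(Inf, 0, 0), sphere), "finite")
  expect_error(ellipsoid_shape(-1, 1), "> 0")
})

test_that("segment-to-ellipsoid distance matches trivial and grid-search oracles", {
  unit <- ellipsoid_shape(1, 1)
  expect_equal(
    segment_to_ellipsoid_distance(capsule_shape(c(4, 0, 0), c(9, 0, 0), 0), unit),
    3)
  expect_equal(
    segment_to_ellipsoid_distance(capsule_shape(c(-3, 0, 0), c(3, 0, 0), 0.2),
                                  ellipsoid_shape(2, 0.7)),
    0)
  # frozen value from a 2D grid search (600 segment stations x 1.4e6 surface
  # samples) for an oblique segment
  d <- segment_to_ellipsoid_distance(capsule_shape(c(3, -2, 1), c(1, 2, 2), 0),
                                     ellipsoid_shape(2, 0.94))
  expect_equal(d, 1.010061, tolerance = 2e-4)
  # capsule radius is subtracted and clamped at zero
  d_r <- segment_to_ellipsoid_distance(
    capsule_shape(c(3, -2, 1), c(1, 2, 2), 0.25), ellipsoid_shape(2, 0.94))
  expect_equal(d_r, d - 0.25, tolerance = 1e-9)
  d_big <- segment_to_ellipsoid_distance(
    capsule_shape(c(3, -2, 1), c(1, 2, 2), 5), ellipsoid_shape(2, 0.94))
  expect_equal(d_big, 0)
})

test_that("sphere specialization equals the closed-form point-segment distance", {
  set.seed(42)
  for (i in 1:25) {
    r <- runif(1, 0.3, 2)
    rc <- runif(1, 0, 0.5)
    ctr <- rnorm(3)
    p0 <- rnorm(3, sd = 4)
    p1 <- rnorm(3, sd = 4)
    d <- segment_to_ellipsoid_distance(
      capsule_shape(p0, p1, rc),
      ellipsoid_shape(r, r, rigid_transform(diag(3), ctr)))
    ab <- p1 - p0
    tt <- min(1, max(0, sum((ctr - p0) * ab) / sum(ab^2)))
    closed <- max(0, sqrt(sum((ctr - p0 - tt * ab)^2)) - r - rc)
    expect_equal(d, closed, tolerance = 1e-9)
  }
})

test_that("kite surface construction honours its contract", {
  k <- build_kite_surface(3, 0.75, 0.15)
  extents <- apply(k$vertices, 2, function(col) diff(range(col)))
  expect_equal(extents, c(0.75, 3, 0.15))  # chord x, span y, thickness z
  expect_equal(nrow(k$faces), 12)

  cube <- build_kite_surface(1, 1, 1)
  # closed, consistently oriented surface: every directed edge appears once
  edges <- do.call(rbind, lapply(seq_len(nrow(cube$faces)), function(f) {
    tri <- cube$faces[f, ]
    rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
  }))
  directed <- paste(edges[, 1], edges[, 2])
  reversed <- paste(edges[, 2], edges[, 1])
  expect_false(any(duplicated(directed)))
  expect_true(all(directed %in% reversed))

  # plate lower bound on surface area
  k <- build_kite_surface(3, 0.75, 0.15)
  area <- sum(sapply(seq_len(nrow(k$faces)), function(f) {
    v <- k$vertices[k$faces[f, ], ]
    0.5 * sqrt(sum((cross3_r(v[2, ] - v[1, ], v[3, ] - v[1, ]))^2))
  }))
  expect_gte(area, 2 * 3 * 0.75)

  expect_error(build_kite_surface(0, 1, 1), "> 0")
})

test_that("mesh-to-ellipsoid distance handles plates, intersection and random poses", {
  # unit sphere centred 5 m from the nearest face of a flat plate
  plate <- build_kite_surface(3, 0.75, 0.15)
  e <- ellipsoid_shape(1, 1, rigid_transform(diag(3), c(0, 0, 5.075)))
  expect_equal(as.numeric(mesh_to_ellipsoid_distance(plate, e)), 4,
               tolerance = 1e-9)

  # intersecting pair scores zero
  e0 <- ellipsoid_shape(1, 0.5)
  expect_equal(as.numeric(mesh_to_ellipsoid_distance(plate, e0)), 0)

  # ellipsoid fully inside a closed box: containment means distance zero
  box <- build_kite_surface(5, 5, 5)
  tiny <- ellipsoid_shape(0.2, 0.1)
  expect_equal(as.numeric(mesh_to_ellipsoid_distance(box, tiny)), 0)

  # random pose pairs agree with the sampling oracle
  set.seed(7)
  checked <- 0
  while (checked < 10) {
    kite <- build_kite_surface(1.5, 0.6, 0.2, pose = random_pose())
    e <- ellipsoid_shape(runif(1, 0.5, 1.2), runif(1, 0.2, 0.5),
                         random_pose())
    d <- as.numeric(mesh_to_ellipsoid_distance(kite, e))
    if (d < 0.05) next  # overlap handled by the dedicated case above
    oracle <- brute_force_distance_oracle(e, kite, n_samples = 4e4)
    expect_lt(abs(d - oracle), 1e-3)  # absolute agreement in metres
    checked <- checked + 1
  }
})

test_that("distances are rigid-transform invariant", {
  set.seed(11)
  for (i in 1:10) {
    g <- random_pose()
    e <- ellipsoid_shape(1.5, 0.6, random_pose())
    cap <- capsule_shape(rnorm(3, sd = 3), rnorm(3, sd = 3), 0.1)
    kite <- build_kite_surface(2, 0.8, 0.2, pose = random_pose())

    compose <- function(outer, inner) {
      rigid_transform(outer$rotation %*% inner$rotation,
                      drop(outer$rotation %*% inner$translation) +
                        outer$translation)
    }
    e_g <- e; e_g$pose <- compose(g, e$pose)
    cap_g <- capsule_shape(transform_points(g, cap$endpoint_a),
                           transform_points(g, cap$endpoint_b), cap$radius)
    kite_g <- kite; kite_g$pose <- compose(g, kite$pose)

    expect_equal(segment_to_ellipsoid_distance(cap_g, e_g),
                 segment_to_ellipsoid_distance(cap, e), tolerance = 1e-9)
    expect_equal(as.numeric(mesh_to_ellipsoid_distance(kite_g, e_g)),
                 as.numeric(mesh_to_ellipsoid_distance(kite, e)),
                 tolerance = 1e-9)
  }
})

test_that("rigid transforms are validated", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "determinant")
})
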