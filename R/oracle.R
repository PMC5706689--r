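# Brute-force distance oracles: dense surface sampling with closed-form
# point-to-segment / point-to-triangle distances. Deliberately independent of
# the numerical minimisation used by the distance operations, so the two can
# cross-check each other. Sampled minima upper-bound the true distance and
# converge to it with sample density.

# n-point parametric sampling of a posed ellipsoid surface
sample_ellipsoid_surface <- function(e, n_samples) {
  n_u <- max(8L, ceiling(sqrt(n_samples)))
  n_v <- max(8L, ceiling(n_samples / n_u))
  u <- seq(0, pi, length.out = n_u)              # polar (includes the tips)
  v <- seq(0, 2 * pi, length.out = n_v + 1)[-1]  # azimuth
  g <- expand.grid(u = u, v = v)
  pts <- cbind(e$axes[1] * cos(g$u),
               e$axes[2] * sin(g$u) * cos(g$v),
               e$axes[3] * sin(g$u) * sin(g$v))
  transform_points(e$pose, pts)
}

# exact distances from points (n x 3) to a segment
points_to_segment <- function(pts, a, b) {
  ab <- b - a
  tt <- pmin(1, pmax(0, (sweep(pts, 2, a, "-") %*% ab) / sum(ab^2)))
  diff <- pts - (rep(1, nrow(pts)) %*% t(a) + tt %*% t(ab))
  sqrt(rowSums(diff^2))
}

cross_vec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# exact distances from points (n x 3) to a triangle, via edge/face regions
points_to_triangle <- function(pts, v1, v2, v3) {
  n <- cross_vec(v2 - v1, v3 - v1)
  nn <- sum(n^2)
  if (nn < 1e-24) {  # degenerate: fall back to the longest edge
    return(points_to_segment(pts, v1, v2))
  }
  # distance to the supporting plane, valid where the projection is inside
  rel <- sweep(pts, 2, v1, "-")
  dist_plane <- as.vector(abs(rel %*% n)) / sqrt(nn)
  proj <- pts - (rel %*% n) %*% t(n) / nn
  w1 <- cross_vec(v3 - v2, n); c1 <- as.vector(sweep(proj, 2, v2, "-") %*% w1)
  w2 <- cross_vec(v1 - v3, n); c2 <- as.vector(sweep(proj, 2, v3, "-") %*% w2)
  w3 <- cross_vec(v2 - v1, n); c3 <- as.vector(sweep(proj, 2, v1, "-") %*% w3)
  inside <- c1 <= 0 & c2 <= 0 & c3 <= 0
  d_edges <- pmin(points_to_segment(pts, v1, v2),
                  points_to_segment(pts, v2, v3),
                  points_to_segment(pts, v3, v1))
  ifelse(inside, dist_plane, d_edges)
}

inside_ellipsoid <- function(pts, e) {
  body <- invert_points(e$pose, pts)
  rowSums(sweep(body, 2, e$axes, "/")^2) <= 1
}

#' Brute-force minimum-distance oracle
#'
#' Dense-sampling estimate of the minimum distance between two shapes, used
#' as an independent check of the exact distance operations. Supported pairs:
#' ellipsoid--ellipsoid, ellipsoid--capsule and ellipsoid--kite surface (in
#' either argument order). The ellipsoid surface is sampled densely; against
#' a capsule or mesh the distance from each sample to the other shape is
#' closed-form, and overlap is detected by containment tests of the samples.
#'
#' @param shape_a,shape_b shapes ([ellipsoid_shape()], [capsule_shape()] or
#'   [build_kite_surface()]); at least one must be an ellipsoid.
#' @param n_samples approximate number of surface samples (>= 1e4 recommended
#'   for test use).
#' @return Estimated minimum distance, m (0 on detected overlap).
#' @export
brute_force_distance_oracle <- function(shape_a, shape_b, n_samples = 1e4) {
  if (!inherits(shape_a, "ellipsoid_shape") &&
      inherits(shape_b, "ellipsoid_shape")) {
    return(brute_force_distance_oracle(shape_b, shape_a, n_samples))
  }
  stopifnot(inherits(shape_a, "ellipsoid_shape"), n_samples >= 1)
  pts <- sample_ellipsoid_surface(shape_a, n_samples)

  if (inherits(shape_b, "capsule_shape")) {
    d <- points_to_segment(pts, shape_b$endpoint_a, shape_b$endpoint_b) -
      shape_b$radius
    seg_samples <- outer(seq(0, 1, length.out = 200),
                         shape_b$endpoint_b - shape_b$endpoint_a) +
      rep(1, 200) %*% t(shape_b$endpoint_a)
    if (any(d <= 0) || any(inside_ellipsoid(seg_samples, shape_a))) return(0)
    return(min(d))
  }
  if (inherits(shape_b, "ellipsoid_shape")) {
    pts_b <- sample_ellipsoid_surface(shape_b, n_samples)
    if (any(inside_ellipsoid(pts, shape_b)) ||
        any(inside_ellipsoid(pts_b, shape_a))) return(0)
    best <- Inf
    for (i in seq(1, nrow(pts), by = 500)) {
      chunk <- pts[i:min(i + 499, nrow(pts)), , drop = FALSE]
      d2 <- outer(rowSums(chunk^2), rowSums(pts_b^2), "+") -
        2 * chunk %*% t(pts_b)
      best <- min(best, min(d2))
    }
    return(sqrt(max(0, best)))
  }
  if (inherits(shape_b, "kite_surface")) {
    verts <- kite_world_vertices(shape_b)
    if (any(inside_ellipsoid(verts, shape_a))) return(0)
    d <- rep(Inf, nrow(pts))
    for (f in seq_len(nrow(shape_b$faces))) {
      tri <- shape_b$faces[f, ]
      d <- pmin(d, points_to_triangle(pts, verts[tri[1], ], verts[tri[2], ],
                                      verts[tri[3], ]))
    }
    # mesh samples inside the ellipsoid flag overlap the vertex test misses
    mesh_pts <- do.call(rbind, lapply(seq_len(nrow(shape_b$faces)), function(f) {
      tri <- shape_b$faces[f, ]
      bary <- expand.grid(u = seq(0, 1, length.out = 12),
                          v = seq(0, 1, length.out = 12))
      bary <- bary[bary$u + bary$v <= 1, ]
      as.matrix(bary$u) %*% t(verts[tri[2], ] - verts[tri[1], ]) +
        as.matrix(bary$v) %*% t(verts[tri[3], ] - verts[tri[1], ]) +
        rep(1, nrow(bary)) %*% t(verts[tri[1], ])
    }))
    if (any(inside_ellipsoid(mesh_pts, shape_a))) return(0)
    return(min(d))
  }
  stop("unsupported shape pair for the oracle", call. = FALSE)
}
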