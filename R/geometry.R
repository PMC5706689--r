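# Geometric primitives: rigid transforms, the animal ellipsoid, the tether
# capsule and the parametric kite surface, plus exact minimum-distance
# computations between the ellipsoid and the device shapes.

assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}

vec3 <- function(x, y = NULL, z = NULL) {
  v <- if (is.null(y)) x else c(x, y, z)
  assert_finite(v, "vec3")
  if (length(v) != 3L) stop("a 3-vector is required", call. = FALSE)
  as.numeric(v)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric, metres.
#' @param tol tolerance for the orthonormality check.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- vec3(translation)
  assert_finite(rotation, "rotation")
  if (max(abs(crossprod(rotation) - diag(3))) > tol) {
    stop("rotation must be orthonormal", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > tol) {
    stop("rotation must be proper (determinant +1)", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points length-3 vector or n x 3 matrix of points.
#' @return Transformed points with the same shape as the input.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.null(dim(points))) {
    return(drop(transform$rotation %*% vec3(points)) + transform$translation)
  }
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

# world -> body coordinates
invert_points <- function(transform, points) {
  if (is.null(dim(points))) {
    return(drop(t(transform$rotation) %*% (vec3(points) - transform$translation)))
  }
  sweep(points, 2, transform$translation, "-") %*% transform$rotation
}

#' Prolate ellipsoid shape
#'
#' The animal body: semi-major axis along body x (the direction of motion),
#' two equal minor semi-axes.
#'
#' @param semi_major major semi-axis, m.
#' @param semi_minor minor semi-axis (both minor radii), m.
#' @param pose a [rigid_transform()] placing the body frame in the world.
#' @return Object of class `ellipsoid_shape`.
#' @export
ellipsoid_shape <- function(semi_major, semi_minor, pose = rigid_transform()) {
  assert_finite(semi_major, "semi_major")
  assert_finite(semi_minor, "semi_minor")
  if (semi_major <= 0 || semi_minor <= 0) {
    stop("ellipsoid semi-axes must be > 0", call. = FALSE)
  }
  structure(list(semi_major = semi_major, semi_minor = semi_minor,
                 axes = c(semi_major, semi_minor, semi_minor), pose = pose),
            class = "ellipsoid_shape")
}

#' Capsule shape (segment with radius)
#'
#' Models the tether: a straight segment from the seabed foundation to the
#' kite attachment point, thickened by a radius.
#'
#' @param endpoint_a,endpoint_b segment endpoints, world coordinates, m.
#' @param radius capsule radius, m (>= 0).
#' @return Object of class `capsule_shape`.
#' @export
capsule_shape <- function(endpoint_a, endpoint_b, radius) {
  endpoint_a <- vec3(endpoint_a)
  endpoint_b <- vec3(endpoint_b)
  assert_finite(radius, "radius")
  if (radius < 0) stop("capsule radius must be >= 0", call. = FALSE)
  if (sqrt(sum((endpoint_a - endpoint_b)^2)) < 1e-12) {
    stop("capsule endpoints must be distinct", call. = FALSE)
  }
  structure(list(endpoint_a = endpoint_a, endpoint_b = endpoint_b,
                 radius = radius), class = "capsule_shape")
}

#' Build the parametric kite surface
#'
#' A watertight rectangular-planform plate triangulated into 12 faces, in body
#' coordinates centred on the tether attachment point: span along body y,
#' chord along body x, thickness along body z.
#'
#' @param span wing span, m.
#' @param chord chord length, m.
#' @param thickness plate thickness, m.
#' @param pose a [rigid_transform()]; defaults to identity (body frame).
#' @return Object of class `kite_surface` with fields `vertices` (8 x 3, body
#'   frame), `faces` (12 x 3, 1-based, outward-oriented), the dimensions and
#'   the pose.
#' @export
build_kite_surface <- function(span = 3, chord = 0.75, thickness = 0.15,
                               pose = rigid_transform()) {
  for (nm in c("span", "chord", "thickness")) {
    val <- get(nm)
    assert_finite(val, nm)
    if (val <= 0) stop(sprintf("'%s' must be > 0", nm), call. = FALSE)
  }
  hx <- chord / 2; hy <- span / 2; hz <- thickness / 2
  vertices <- as.matrix(expand.grid(x = c(-hx, hx), y = c(-hy, hy),
                                    z = c(-hz, hz)))
  dimnames(vertices) <- NULL
  # outward-oriented triangulation of the box (vertex order: x fastest)
  faces <- rbind(
    c(1, 7, 3), c(1, 5, 7),   # -x
    c(2, 4, 8), c(2, 8, 6),   # +x
    c(1, 2, 6), c(1, 6, 5),   # -y
    c(3, 8, 4), c(3, 7, 8),   # +y
    c(1, 4, 2), c(1, 3, 4),   # -z
    c(5, 6, 8), c(5, 8, 7))   # +z
  structure(list(span = span, chord = chord, thickness = thickness,
                 vertices = vertices, faces = faces, pose = pose),
            class = "kite_surface")
}

# maximum reach of the kite from its attachment point
kite_bounding_radius <- function(kite) {
  sqrt((kite$span / 2)^2 + (kite$chord / 2)^2 + (kite$thickness / 2)^2)
}

# kite vertices in world coordinates
kite_world_vertices <- function(kite) {
  transform_points(kite$pose, kite$vertices)
}

#' Distance from a point to an ellipsoid surface
#'
#' Euclidean distance from a point to the surface of a posed ellipsoid.
#' Interior points report distance 0 with the containment flag set.
#'
#' @param point length-3 numeric, world coordinates, m.
#' @param e an [ellipsoid_shape()].
#' @return List with `distance` (m) and `contained` (logical).
#' @export
point_to_ellipsoid_distance <- function(point, e) {
  stopifnot(inherits(e, "ellipsoid_shape"))
  q <- invert_points(e$pose, vec3(point))
  res <- .pt_ellipsoid_cpp(q, e$axes)
  list(distance = res$distance, contained = res$contained)
}

#' Minimum distance between a capsule and an ellipsoid
#'
#' Minimum over the capsule axis of the point-to-ellipsoid distance, minus the
#' capsule radius, clamped at 0 (overlap scores 0).
#'
#' @param capsule a [capsule_shape()].
#' @param e an [ellipsoid_shape()].
#' @return Distance in metres (>= 0).
#' @export
segment_to_ellipsoid_distance <- function(capsule, e) {
  stopifnot(inherits(capsule, "capsule_shape"), inherits(e, "ellipsoid_shape"))
  p0 <- invert_points(e$pose, capsule$endpoint_a)
  p1 <- invert_points(e$pose, capsule$endpoint_b)
  res <- .seg_ellipsoid_cpp(p0, p1, e$axes)
  max(0, res$distance - capsule$radius)
}

#' Minimum distance between a triangulated surface and an ellipsoid
#'
#' Minimum over the posed triangles of the triangle-to-ellipsoid distance;
#' 0 on intersection or containment (either shape inside the other).
#' Degenerate (zero-area) triangles are skipped; their count is attached as
#' attribute `n_degenerate` and triggers a warning.
#'
#' @param k a [build_kite_surface()] result (or any object with `vertices`,
#'   `faces` and `pose`).
#' @param e an [ellipsoid_shape()].
#' @return Distance in metres (>= 0), with attribute `n_degenerate`.
#' @export
mesh_to_ellipsoid_distance <- function(k, e) {
  stopifnot(inherits(e, "ellipsoid_shape"))
  world <- transform_points(k$pose, k$vertices)
  body <- invert_points(e$pose, world)
  res <- .mesh_ellipsoid_cpp(body, k$faces, e$axes)
  if (res$n_degenerate > 0) {
    warning(sprintf("%d degenerate triangle(s) skipped", res$n_degenerate))
  }
  structure(res$distance, n_degenerate = res$n_degenerate)
}

# rotation about the z axis
rot_z <- function(angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

# rotation about the y axis
rot_y <- function(angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}
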