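# Geometry primitives underlying all planning computations.
# Conventions: world coordinates in mm, right-handed, LPS orientation for
# image volumes; points are length-3 numeric vectors or n x 3 matrices.

#' Coerce to an n x 3 coordinate matrix
#'
#' Accepts a length-3 numeric vector (one point) or an n x 3 matrix /
#' data.frame of points and returns an n x 3 numeric matrix.
#'
#' @param x points as a length-3 vector or n x 3 matrix-like object.
#' @return numeric matrix with 3 columns.
#' @keywords internal
as_points3 <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("a point must have exactly 3 coordinates")
    x <- matrix(as.numeric(x), 1L, 3L)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("points must be given as an n x 3 matrix")
  if (!all(is.finite(x))) stop("point coordinates must be finite")
  x
}

vnorm <- function(v) sqrt(sum(v * v))

#' Normalize a direction vector to unit length
#'
#' @param v length-3 numeric vector; must be nonzero.
#' @return unit vector.
#' @export
unit_vector <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 3L || !all(is.finite(v))) stop("direction must be a finite length-3 vector")
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

assert_unit <- function(v, what = "direction", tol = 1e-9) {
  if (abs(vnorm(v) - 1) > tol) stop(sprintf("%s must be a unit vector", what))
  invisible(v)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Rigid transform (rotation + translation)
#'
#' Constructs a rigid (proper orthogonal) transform mapping points `p` to
#' `rotation %*% p + translation`. Reflections are rejected.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector, mm.
#' @return object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "double"
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (length(translation) != 3L) stop("translation must have length 3")
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("transform components must be finite")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal (R'R = I within 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1); reflections are not rigid")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation (mm):", paste(signif(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points length-3 vector or n x 3 matrix of points (mm).
#' @return transformed points with the same shape semantics (always n x 3
#'   matrix; a single input point yields a 1 x 3 matrix unless `drop = TRUE`).
#' @param drop if `TRUE` and a single point was given, return a length-3 vector.
#' @export
transform_points <- function(transform, points, drop = FALSE) {
  stopifnot(inherits(transform, "rigid_transform"))
  p <- as_points3(points)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3L, byrow = TRUE)
  if (drop && nrow(out) == 1L) out <- out[1L, ]
  out
}

#' Apply a rigid transform to direction vectors (rotation only)
#'
#' @inheritParams transform_points
#' @param directions length-3 vector or n x 3 matrix of directions.
#' @export
transform_directions <- function(transform, directions, drop = FALSE) {
  stopifnot(inherits(transform, "rigid_transform"))
  d <- as_points3(directions)
  out <- d %*% t(transform$rotation)
  if (drop && nrow(out) == 1L) out <- out[1L, ]
  out
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `second` after `first`:
#' `compose_transforms(second, first)` maps `p` to `second(first(p))`.
#'
#' @param second,first [rigid_transform()] objects.
#' @export
compose_transforms <- function(second, first) {
  stopifnot(inherits(second, "rigid_transform"), inherits(first, "rigid_transform"))
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) + second$translation)
}

#' Rotation angle of a rigid transform, degrees
#'
#' The magnitude of the axis-angle rotation; useful to quantify the rotational
#' discrepancy between a recovered and a ground-truth registration.
#'
#' @param transform a [rigid_transform()].
#' @return angle in degrees, in `[0, 180]`.
#' @export
rotation_angle_deg <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  tr <- sum(diag(transform$rotation))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Line segment in 3-D
#'
#' @param a,b endpoints (mm); must be distinct.
#' @return object of class `segment3`.
#' @export
segment3 <- function(a, b) {
  a <- as.numeric(as_points3(a))
  b <- as.numeric(as_points3(b))
  if (vnorm(b - a) < 1e-12) stop("degenerate segment: endpoints coincide")
  structure(list(a = a, b = b), class = "segment3")
}

#' Capsule chain: a polyline thickened by a fixed radius
#'
#' Models tubular anatomy (facial-nerve canal, chorda tympani, canal walls)
#' as the set of points within `radius` of the centerline polyline.
#'
#' @param vertices n x 3 matrix (n >= 2) of centerline vertices, mm.
#' @param radius tube radius, mm, > 0.
#' @return object of class `capsule_chain`.
#' @export
capsule_chain <- function(vertices, radius) {
  v <- as_points3(vertices)
  if (nrow(v) < 2L) stop("a capsule chain needs at least 2 vertices")
  seglen <- sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  if (any(seglen < 1e-12)) stop("consecutive capsule vertices must be distinct")
  radius <- as.numeric(radius)
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0)
    stop("capsule radius must be a single positive number")
  structure(list(vertices = v, radius = radius), class = "capsule_chain")
}

#' Minimum distance between two line segments
#'
#' Closed-form clamped closest-point computation (the standard quadratic
#' minimization over the two segment parameters with clamping to `[0, 1]`).
#' Parallel ties are resolved by clamping the first parameter to 0; the
#' distance value is unaffected.
#'
#' @param s1,s2 [segment3()] objects.
#' @return minimum Euclidean distance in mm.
#' @export
segment_segment_distance <- function(s1, s2) {
  stopifnot(inherits(s1, "segment3"), inherits(s2, "segment3"))
  seg_seg_dist(s1$a, s1$b, s2$a, s2$b)
}

# Core segment-segment distance on raw endpoint vectors (Ericson-style).
seg_seg_dist <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1
  d2 <- q2 - p2
  r <- p1 - p2
  a <- sum(d1 * d1)
  e <- sum(d2 * d2)
  f <- sum(d2 * r)
  c_ <- sum(d1 * r)
  b <- sum(d1 * d2)
  denom <- a * e - b * b
  # s on segment 1, t on segment 2
  s <- if (denom > 1e-14 * a * e) min(1, max(0, (b * f - c_ * e) / denom)) else 0
  t <- (b * s + f) / e
  if (t < 0) {
    t <- 0
    s <- min(1, max(0, -c_ / a))
  } else if (t > 1) {
    t <- 1
    s <- min(1, max(0, (b - c_) / a))
  }
  cp1 <- p1 + s * d1
  cp2 <- p2 + t * d2
  vnorm(cp1 - cp2)
}

#' Distance from a path axis to a capsule surface
#'
#' The planning-relevant clearance: the minimum distance from the drill-path
#' centerline (a segment) to the *surface* of a tubular risk structure,
#' i.e. centerline-to-centerline distance minus the capsule radius. Negative
#' values mean the axis penetrates the structure and flag an invalid plan;
#' they are returned unclamped so callers can distinguish touching from
#' penetration.
#'
#' @param axis a [segment3()]: the drill-path centerline.
#' @param capsule a [capsule_chain()].
#' @return signed surface distance in mm.
#' @export
axis_to_capsule_surface_distance <- function(axis, capsule) {
  stopifnot(inherits(axis, "segment3"), inherits(capsule, "capsule_chain"))
  v <- capsule$vertices
  n <- nrow(v)
  dmin <- Inf
  for (i in seq_len(n - 1L)) {
    d <- seg_seg_dist(axis$a, axis$b, v[i, ], v[i + 1L, ])
    if (d < dmin) dmin <- d
  }
  dmin - capsule$radius
}

#' Least-squares rigid registration of corresponding point sets
#'
#' Fits the rigid transform (rotation + translation, no scaling, no
#' reflection) minimizing the sum of squared distances between
#' `transform(source)` and `target`, by the SVD of the cross-covariance with
#' a determinant guard forcing a proper rotation. Also reports the fiducial
#' registration error (FRE), the root-mean-square residual after alignment.
#'
#' @param source,target n x 3 matrices of corresponding points (n >= 3,
#'   non-collinear), mm.
#' @return list with `transform` ([rigid_transform()]), `fre` (mm),
#'   `residuals` (per-point residual norms, mm) and `n` (number of points).
#' @export
fit_rigid_transform <- function(source, target) {
  S <- as_points3(source)
  T_ <- as_points3(target)
  if (nrow(S) != nrow(T_)) stop("source and target must have equal point counts")
  n <- nrow(S)
  if (n < 3L) stop("rigid registration needs at least 3 point pairs")
  cs <- colMeans(S)
  ct <- colMeans(T_)
  Sc <- sweep(S, 2L, cs)
  Tc <- sweep(T_, 2L, ct)
  # collinearity check: rank of the centered source configuration
  sv_rank <- svd(Sc, nu = 0, nv = 0)$d
  if (sv_rank[2L] < 1e-9 * max(sv_rank[1L], 1))
    stop("point configuration is collinear; rigid transform is not unique")
  H <- crossprod(Sc, Tc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - as.numeric(R %*% cs)
  transform <- rigid_transform(R, tr)
  res <- T_ - transform_points(transform, S)
  rn <- sqrt(rowSums(res^2))
  list(transform = transform, fre = sqrt(mean(rn^2)), residuals = rn, n = n)
}
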