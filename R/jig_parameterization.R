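# Conversion of a planned access path into a jig through-hole pose in frame
# coordinates, reachability checks against the jig envelope, and projection
# of manufacturing deviations to the target depth.

#' Jig through-hole pose in frame coordinates
#'
#' The hole axis is anchored where it crosses the jig reference plane; its
#' orientation plus the depth to the target fully encode the planned
#' trajectory once the jig is mounted on the frame.
#'
#' @param point hole axis reference point on the jig reference plane, frame
#'   coordinates, mm.
#' @param axis unit direction of the hole axis (toward the target).
#' @param depth_to_target distance L from the reference plane to the target
#'   along the axis, mm, > 0.
#' @return object of class `hole_pose`.
#' @export
hole_pose <- function(point, axis, depth_to_target) {
  point <- as.numeric(as_points3(point))
  axis <- as.numeric(axis)
  assert_unit(axis, "hole axis")
  if (!is.finite(depth_to_target) || depth_to_target <= 0)
    stop("depth_to_target must be positive")
  structure(list(point = point, axis = axis, depth_to_target = depth_to_target),
            class = "hole_pose")
}

#' Jig envelope: reference plane and reachable boundary
#'
#' The clinical jig's true reachable limits are unpublished; the defaults
#' (5 mm boundary disc, 30 degree tilt limit) are configurable placeholders.
#'
#' @param plane_origin origin of the jig reference plane, frame coordinates,
#'   mm.
#' @param plane_normal unit normal of the reference plane.
#' @param radius boundary disc radius around `plane_origin`, mm.
#' @param tilt_limit maximum hole-axis tilt from the plane normal, degrees,
#'   in (0, 90).
#' @return object of class `jig_envelope`.
#' @export
jig_envelope <- function(plane_origin = c(0, 0, 0), plane_normal = c(0, 0, 1),
                         radius = 5, tilt_limit = 30) {
  plane_origin <- as.numeric(as_points3(plane_origin))
  plane_normal <- unit_vector(plane_normal)
  if (!is.finite(radius) || radius <= 0) stop("boundary radius must be positive")
  if (!is.finite(tilt_limit) || tilt_limit <= 0 || tilt_limit >= 90)
    stop("tilt limit must lie in (0, 90) degrees")
  structure(list(plane_origin = plane_origin, plane_normal = plane_normal,
                 radius = radius, tilt_limit = tilt_limit),
            class = "jig_envelope")
}

#' Convert a planned path to a jig through-hole pose
#'
#' Transforms the path into frame coordinates via the image-to-frame
#' registration, intersects its axis with the jig reference plane to anchor
#' the hole point, and checks the pose against the envelope boundary
#' (hole point within the boundary disc, axis tilt within the limit). A
#' registration whose fiducial registration error exceeds `fre_gate` is
#' rejected: transferring a plan through a bad registration is unsafe.
#'
#' @param path an [access_path()] in image/world coordinates.
#' @param image_to_frame [rigid_transform()] from the registration step.
#' @param envelope a [jig_envelope()].
#' @param fre fiducial registration error of the registration, mm; `NULL`
#'   skips the gate.
#' @param fre_gate maximum acceptable FRE, mm.
#' @return list with `hole` ([hole_pose()]), `in_bounds` (logical), `tilt`
#'   (degrees) and `radial_offset` (mm from the plane origin).
#' @export
path_to_hole <- function(path, image_to_frame, envelope = jig_envelope(),
                         fre = NULL, fre_gate = 0.3) {
  stopifnot(inherits(path, "access_path"),
            inherits(image_to_frame, "rigid_transform"),
            inherits(envelope, "jig_envelope"))
  if (!is.null(fre) && fre > fre_gate)
    stop(sprintf("registration FRE %.3f mm exceeds the %.3f mm gate", fre, fre_gate))
  target_f <- transform_points(image_to_frame, path$target, drop = TRUE)
  dir_f <- transform_directions(image_to_frame, path$direction, drop = TRUE)
  n <- envelope$plane_normal
  denom <- sum(dir_f * n)
  if (abs(denom) < 1e-9)
    stop("path is parallel to the jig reference plane; no through-hole pose exists")
  # intersection of the (infinite) hole axis with the reference plane
  t <- sum((envelope$plane_origin - target_f) * n) / denom
  point <- target_f + t * dir_f
  L <- sum((target_f - point) * dir_f)  # signed depth along the hole axis
  if (L <= 0)
    stop("jig reference plane lies beyond the target along the drill axis")
  hole <- hole_pose(point, dir_f, L)
  tilt <- acos(min(1, abs(sum(dir_f * n)))) * 180 / pi
  radial <- vnorm((point - envelope$plane_origin) -
                  sum((point - envelope$plane_origin) * n) * n)
  list(hole = hole,
       in_bounds = (radial <= envelope$radius) && (tilt <= envelope$tilt_limit),
       tilt = tilt, radial_offset = radial)
}

#' Convert a hole pose back to a world-coordinate path
#'
#' Inverse of [path_to_hole()]: reconstructs the access path in image/world
#' coordinates from a hole pose and the frame-to-image transform.
#'
#' @param hole a [hole_pose()].
#' @param frame_to_image [rigid_transform()] (the inverse of the
#'   registration).
#' @param diameter drill diameter for the reconstructed path, mm.
#' @param length path length; defaults to the hole depth.
#' @return an [access_path()].
#' @export
hole_to_path <- function(hole, frame_to_image, diameter = 1.5, length = NULL) {
  stopifnot(inherits(hole, "hole_pose"), inherits(frame_to_image, "rigid_transform"))
  target_f <- hole$point + hole$depth_to_target * hole$axis
  target_w <- transform_points(frame_to_image, target_f, drop = TRUE)
  dir_w <- unit_vector(transform_directions(frame_to_image, hole$axis, drop = TRUE))
  if (is.null(length)) length <- hole$depth_to_target
  access_path(target_w, dir_w, length, diameter)
}

#' Manufacturing deviation projected to the target depth
#'
#' Given the nominal (planned) and measured (coordinate-measurement-machine)
#' through-hole poses, returns the lateral offset between the two hole axes
#' evaluated at the nominal depth of the target:
#' `|| (p_m + L a_m) - (p_n + L a_n) ||` with `L` from the nominal pose.
#' A purely axial manufacturing offset does not displace the drill axis and
#' therefore does not contribute at fixed depth.
#'
#' @param nominal,measured [hole_pose()] objects in the same frame.
#' @return deviation in mm.
#' @export
deviation_at_target <- function(nominal, measured) {
  stopifnot(inherits(nominal, "hole_pose"), inherits(measured, "hole_pose"))
  L <- nominal$depth_to_target
  vnorm((measured$point + L * measured$axis) - (nominal$point + L * nominal$axis))
}

#' Quality-control gate on the projected deviation
#'
#' @param deviation measured deviation at target depth, mm, >= 0.
#' @param tolerance maximum acceptable deviation, mm. The 0.3 mm default is
#'   chosen to stay below the facial-nerve safety margin, so a passing jig
#'   cannot by itself consume the planned nerve clearance.
#' @return `TRUE` (pass) iff `deviation <= tolerance`.
#' @export
qc_gate <- function(deviation, tolerance = 0.3) {
  if (!is.finite(deviation) || deviation < 0) stop("deviation must be >= 0")
  deviation <= tolerance
}
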