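# Straight access-path planning through the facial recess: clearances to
# the facial nerve (FN), chorda tympani (CT) and external auditory canal
# (EAC) wall, drill-diameter margins and feasibility, insertion angles,
# and screw-site bone thickness.
#
# All clearances are measured from the path CENTERLINE to the structure
# SURFACE: these are the numbers directly comparable to a drill radius,
# and the published margin arithmetic (margin = distance - D/2) only works
# under this reading.

#' Planned straight access path
#'
#' @param target round-window target point, mm (world coordinates).
#' @param direction unit vector pointing from the entry toward the target.
#' @param length path length from skull-surface entry to target, mm.
#' @param diameter drill diameter D, mm, in (0, 3].
#' @return object of class `access_path`.
#' @export
access_path <- function(target, direction, length, diameter = 1.5) {
  target <- as.numeric(as_points3(target))
  direction <- as.numeric(direction)
  assert_unit(direction, "path direction")
  if (!is.finite(length) || length <= 0) stop("path length must be positive")
  if (!is.finite(diameter) || diameter <= 0 || diameter > 3)
    stop("drill diameter must lie in (0, 3] mm")
  structure(list(target = target, direction = direction,
                 length = length, diameter = diameter),
            class = "access_path")
}

#' @export
print.access_path <- function(x, ...) {
  cat("<access_path> target:", paste(signif(x$target, 6), collapse = " "),
      "mm; D =", x$diameter, "mm; length =", x$length, "mm\n")
  invisible(x)
}

#' Entry point of an access path
#'
#' @param path an [access_path()].
#' @return entry point (skull surface end), mm.
#' @export
path_entry <- function(path) {
  stopifnot(inherits(path, "access_path"))
  path$target - path$length * path$direction
}

#' Path centerline as a segment
#'
#' @param path an [access_path()].
#' @return a [segment3()] from entry to target.
#' @export
path_axis <- function(path) segment3(path_entry(path), path$target)

#' Scene model: risk structures, target and optional reference geometry
#'
#' @param structures named list of [capsule_chain()] risk structures; must
#'   contain `FN` and `CT` for clearance evaluation, optionally `EAC`.
#' @param target round-window target point, mm.
#' @param cochlear_frame optional list with unit vectors `axis1` (reference
#'   direction in the basal-turn plane), `normal` (plane normal).
#' @param screw_site optional list with `point` and unit `normal` for the
#'   frame fixation screw.
#' @return object of class `scene_model`.
#' @export
scene_model <- function(structures, target, cochlear_frame = NULL,
                        screw_site = NULL) {
  if (is.null(names(structures)) || any(names(structures) == "") ||
      anyDuplicated(names(structures)))
    stop("structures must be a uniquely named list")
  for (s in structures)
    if (!inherits(s, "capsule_chain")) stop("each structure must be a capsule_chain")
  target <- as.numeric(as_points3(target))
  if (!is.null(cochlear_frame)) {
    cochlear_frame$axis1 <- unit_vector(cochlear_frame$axis1)
    cochlear_frame$normal <- unit_vector(cochlear_frame$normal)
    if (abs(sum(cochlear_frame$axis1 * cochlear_frame$normal)) > 1e-6)
      stop("cochlear_frame axis1 must be orthogonal to the plane normal")
  }
  if (!is.null(screw_site)) {
    screw_site$point <- as.numeric(as_points3(screw_site$point))
    screw_site$normal <- unit_vector(screw_site$normal)
  }
  structure(list(structures = structures, target = target,
                 cochlear_frame = cochlear_frame, screw_site = screw_site),
            class = "scene_model")
}

#' Evaluate clearances and drill-diameter feasibility for a path
#'
#' Measures the shortest distance from the path centerline to the surface of
#' each named risk structure, derives the margin `m_S(D) = d_S - D/2` for
#' each tested drill diameter, the effective facial-recess width
#' `w = d_FN + d_CT`, and a per-diameter feasibility verdict. A diameter D
#' fits when both nerve margins are non-negative, i.e.
#' `min(d_FN, d_CT) >= D/2` (inclusive: a drill surface exactly touching the
#' bony boundary still counts as fitting); the strict variant
#' `min(d_FN, d_CT) > D/2` ("passes freely", no contact at all) is reported
#' alongside. The 0.3 mm facial-nerve safety margin is a separate soft rule,
#' see [check_fn_constraint()].
#'
#' @param path an [access_path()].
#' @param scene a [scene_model()] containing `FN` and `CT`.
#' @param diameters drill diameters to test, mm; the default set
#'   `c(1.5, 1.8, 2.2, 2.6)` is the sham-drill series used clinically.
#' @return object of class `clearance_report`: list with `d` (named surface
#'   distances, mm), `margins` (structures x diameters matrix),
#'   `recess_width`, `feasible` / `feasible_strict` (named logical per
#'   diameter), `largest_feasible` (mm or `NA`), `valid` (no structure
#'   penetrated) and `path`.
#' @export
evaluate_clearance <- function(path, scene, diameters = c(1.5, 1.8, 2.2, 2.6)) {
  stopifnot(inherits(path, "access_path"), inherits(scene, "scene_model"))
  if (!all(c("FN", "CT") %in% names(scene$structures)))
    stop("scene must contain FN and CT structures for clearance evaluation")
  if (length(diameters) < 1L || any(diameters <= 0))
    stop("diameters must be positive")
  diameters <- sort(unique(as.numeric(diameters)))
  axis <- path_axis(path)
  d <- vapply(scene$structures, function(s)
    axis_to_capsule_surface_distance(axis, s), numeric(1))
  margins <- outer(d, diameters / 2, "-")
  colnames(margins) <- format(diameters, trim = TRUE)
  d_nerve_min <- min(d[["FN"]], d[["CT"]])
  feasible <- d_nerve_min >= diameters / 2
  feasible_strict <- d_nerve_min > diameters / 2
  names(feasible) <- names(feasible_strict) <- colnames(margins)
  largest <- if (any(feasible)) max(diameters[feasible]) else NA_real_
  structure(list(
    d = d,
    margins = margins,
    diameters = diameters,
    recess_width = d[["FN"]] + d[["CT"]],
    feasible = feasible,
    feasible_strict = feasible_strict,
    largest_feasible = largest,
    valid = all(d >= 0),
    path = path), class = "clearance_report")
}

#' @export
print.clearance_report <- function(x, ...) {
  cat("<clearance_report>\n")
  cat("  axis-to-surface distances (mm):",
      paste(sprintf("%s=%.2f", names(x$d), x$d), collapse = ", "), "\n")
  cat("  facial recess width (d_FN + d_CT):", sprintf("%.2f", x$recess_width), "mm\n")
  for (j in seq_along(x$diameters))
    cat(sprintf("  D = %.1f mm: m_FN = %.2f, m_CT = %.2f, fits: %s\n",
                x$diameters[j], x$margins["FN", j], x$margins["CT", j],
                ifelse(x$feasible[j], "yes", "no")))
  if (!x$valid) cat("  WARNING: path penetrates a risk structure\n")
  invisible(x)
}

#' Facial-nerve safety-margin check (soft constraint)
#'
#' The planning rule aims for at least `min_margin` (default 0.3 mm) between
#' the drill surface and the facial-nerve canal. The rule is soft: anatomy
#' (typically the EAC wall) can force a smaller margin, which is reported as
#' a warning note rather than an error, as long as the margin is still
#' non-negative.
#'
#' @param report a [clearance_report()].
#' @param D drill diameter, mm; must be one of the report's tested diameters.
#' @param min_margin required FN margin, mm (inclusive).
#' @return list with `ok` (logical) and `note` (character or `NULL`; a
#'   soft-violation note when `0 <= m_FN(D) < min_margin`).
#' @export
check_fn_constraint <- function(report, D = 1.5, min_margin = 0.3) {
  stopifnot(inherits(report, "clearance_report"))
  j <- match(TRUE, abs(report$diameters - D) < 1e-9)
  if (is.na(j)) stop("diameter D was not evaluated in this report")
  m_fn <- report$margins["FN", j]
  ok <- m_fn >= min_margin
  note <- NULL
  if (!ok && m_fn >= 0)
    note <- sprintf(paste0("soft violation: FN margin %.2f mm below the ",
                           "%.2f mm target at D = %.1f mm; acceptable only if ",
                           "anatomy (e.g. the EAC wall) allows no alternative"),
                    m_fn, min_margin, D)
  if (m_fn < 0)
    note <- sprintf("FN margin negative (%.2f mm): drill would breach the canal", m_fn)
  list(ok = ok, margin = unname(m_fn), note = note)
}

#' Clearance of the drill shaft to the EAC wall
#'
#' The guided sham drill widens stepwise up to a `shaft_diameter` (3 mm)
#' shaft; this check verifies the shaft does not touch the posterior EAC
#' wall. The published per-case "distance to EAC wall" does not state its
#' reference (axis or drill surface), so the convention is explicit:
#' `axis_to_wall` reports the centerline-to-wall distance and flags a touch
#' when it is below the shaft radius; `drill_surface_to_wall` reports the
#' distance from the drill surface (axis distance minus D/2) and flags a
#' touch when the *shaft* surface reaches the wall. Touching is strict:
#' a distance exactly equal to the shaft radius counts as not touching.
#'
#' @param path an [access_path()].
#' @param scene a [scene_model()] with an `EAC` structure.
#' @param shaft_diameter shaft diameter, mm.
#' @param convention `"axis_to_wall"` or `"drill_surface_to_wall"`.
#' @return list with `distance` (mm, under the chosen convention),
#'   `axis_distance` (mm), `touches` (logical) and `convention`.
#' @export
check_shaft_eac <- function(path, scene, shaft_diameter = 3.0,
                            convention = c("axis_to_wall", "drill_surface_to_wall")) {
  stopifnot(inherits(path, "access_path"), inherits(scene, "scene_model"))
  convention <- match.arg(convention)
  if (!"EAC" %in% names(scene$structures))
    stop("scene has no EAC structure; cannot check shaft clearance")
  ax <- axis_to_capsule_surface_distance(path_axis(path), scene$structures[["EAC"]])
  distance <- switch(convention,
                     axis_to_wall = ax,
                     drill_surface_to_wall = ax - path$diameter / 2)
  touches <- switch(convention,
                    axis_to_wall = ax < shaft_diameter / 2,
                    drill_surface_to_wall = distance < 0)
  list(distance = distance, axis_distance = ax, touches = touches,
       convention = convention, shaft_diameter = shaft_diameter)
}

#' In-plane and off-plane insertion angles into the cochlea
#'
#' Decomposes the path direction relative to a cochlear reference frame
#' (basal-turn plane): `off_plane` is the elevation of the direction out of
#' the plane (90 degrees minus the angle to the plane normal, signed by the
#' normal side); `in_plane` is the signed azimuth of the in-plane projection
#' measured from `axis1` (positive toward `normal x axis1`). Both in degrees
#' in (-180, 180]. When the direction is parallel to the normal the in-plane
#' angle is undefined and returned as `NA` with a note.
#'
#' @param path an [access_path()].
#' @param cochlear_frame list with unit vectors `axis1` and `normal`.
#' @return list with `in_plane`, `off_plane` (degrees) and `note`.
#' @export
insertion_angles <- function(path, cochlear_frame) {
  stopifnot(inherits(path, "access_path"))
  a1 <- unit_vector(cochlear_frame$axis1)
  n <- unit_vector(cochlear_frame$normal)
  a2 <- cross3(n, a1)
  dirv <- path$direction
  s <- sum(dirv * n)                      # out-of-plane component
  proj <- dirv - s * n                    # in-plane projection
  off_plane <- asin(max(-1, min(1, s))) * 180 / pi
  if (vnorm(proj) < 1e-9) {
    return(list(in_plane = NA_real_, off_plane = off_plane,
                note = "direction is parallel to the plane normal; in-plane angle undefined"))
  }
  in_plane <- atan2(sum(proj * a2), sum(proj * a1)) * 180 / pi
  if (in_plane <= -180) in_plane <- in_plane + 360
  list(in_plane = in_plane, off_plane = off_plane, note = NULL)
}

#' Bone thickness along a ray
#'
#' Samples the volume at half-voxel steps along `direction` from `point` and
#' returns the length of the first contiguous above-threshold run — the
#' outer bone table down to the first sub-threshold void (air-filled mastoid
#' cells terminate the run, as they do on the clinical thickness readout).
#'
#' @param vol an [image_volume()].
#' @param point ray start, mm (on or just outside the outer bone surface).
#' @param direction unit ray direction (into the bone).
#' @param bone_threshold intensity above which a sample counts as bone.
#' @param max_depth maximum search depth along the ray, mm.
#' @return thickness in mm (0 with a warning if no bone is found at entry).
#' @export
bone_thickness <- function(vol, point, direction, bone_threshold = 300,
                           max_depth = 25) {
  stopifnot(inherits(vol, "image_volume"))
  point <- as.numeric(as_points3(point))
  direction <- unit_vector(direction)
  step <- min(vol$spacing) / 2
  t <- seq(0, max_depth, by = step)
  pts <- matrix(point, length(t), 3L, byrow = TRUE) + outer(t, direction)
  v <- sample_volume(vol, pts, outside_value = -Inf)
  above <- v >= bone_threshold
  first <- match(TRUE, above)
  if (is.na(first)) {
    warning("no bone found along the ray")
    return(0)
  }
  runend <- match(FALSE, above[first:length(above)])
  nrun <- if (is.na(runend)) length(above) - first + 1L else runend - 1L
  nrun * step
}

#' Screw-site thickness check
#'
#' The frame's fixation screw engages a fixed depth of bone; the site is
#' acceptable when the local bone thickness is at least that reach.
#'
#' @param thickness measured bone thickness, mm.
#' @param screw_reach design engagement depth of the bone screw, mm.
#' @return `TRUE` iff `thickness >= screw_reach` (inclusive).
#' @export
check_screw_site <- function(thickness, screw_reach = 3.6) {
  if (!is.finite(thickness) || thickness < 0) stop("thickness must be >= 0")
  thickness >= screw_reach
}

#' Optimize the entry point over a reachable disc
#'
#' Searches entry candidates on a disc (the region the jig can reach) for
#' the straight path to the scene target that maximizes the smaller of the
#' two nerve margins at diameter `D`, subject to the facial-nerve soft rule
#' (reported if unattainable) and to the EAC shaft check when an EAC
#' structure is present. Search is a regular grid at `pitch` over the disc
#' followed by a refined grid around the incumbent; ties are broken by the
#' smaller distance to the disc center, then lexicographically.
#'
#' @param scene a [scene_model()].
#' @param disc list with `center` (mm), unit `normal`, `radius` (mm):
#'   candidate entries lie on this disc.
#' @param D drill diameter to optimize for, mm.
#' @param pitch coarse grid pitch, mm.
#' @param min_fn_margin facial-nerve margin target, mm (soft).
#' @param shaft_diameter shaft diameter for the EAC check, mm.
#' @return list with `path` ([access_path()]), `report`
#'   ([clearance_report()]), `objective` (the achieved min nerve margin, mm)
#'   and `notes` (character vector of soft-rule messages).
#' @export
optimize_entry <- function(scene, disc, D = 1.5, pitch = 0.25,
                           min_fn_margin = 0.3, shaft_diameter = 3.0) {
  stopifnot(inherits(scene, "scene_model"))
  center <- as.numeric(as_points3(disc$center))
  normal <- unit_vector(disc$normal)
  radius <- disc$radius
  if (!is.finite(radius) || radius <= 0) stop("disc radius must be positive")
  # in-plane basis, deterministic
  ref <- if (abs(normal[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit_vector(cross3(normal, ref))
  v <- cross3(normal, u)
  target <- scene$target
  has_eac <- "EAC" %in% names(scene$structures)

  eval_entry <- function(entry) {
    len <- vnorm(target - entry)
    if (len < 1e-6) return(NULL)
    p <- access_path(target, unit_vector(target - entry), len, D)
    rep_ <- evaluate_clearance(p, scene, diameters = D)
    obj <- min(rep_$margins["FN", 1L], rep_$margins["CT", 1L])
    if (has_eac) {
      eac <- check_shaft_eac(p, scene, shaft_diameter)
      if (eac$touches) return(list(obj = -Inf, path = p, report = rep_))
    }
    list(obj = obj, path = p, report = rep_)
  }

  grid_offsets <- function(p) {
    k <- ceiling(radius / p)
    g <- expand.grid(i = -k:k, j = -k:k)
    g <- g[g$i^2 + g$j^2 <= (radius / p)^2 + 1e-12, , drop = FALSE]
    cbind(g$i * p, g$j * p)
  }

  search <- function(offsets, origin2 = c(0, 0)) {
    best <- NULL
    for (r in seq_len(nrow(offsets))) {
      off <- origin2 + offsets[r, ]
      if (sum(off^2) > radius^2 + 1e-12) next
      entry <- center + off[1L] * u + off[2L] * v
      cand <- eval_entry(entry)
      if (is.null(cand)) next
      if (is.null(best) || cand$obj > best$obj + 1e-12 ||
          (abs(cand$obj - best$obj) <= 1e-12 &&
           (sum(off^2) < best$r2 - 1e-12 ||
            (abs(sum(off^2) - best$r2) <= 1e-12 &&
             (off[1L] < best$off[1L] - 1e-12 ||
              (abs(off[1L] - best$off[1L]) <= 1e-12 && off[2L] < best$off[2L])))))) {
        best <- cand
        best$off <- off
        best$r2 <- sum(off^2)
      }
    }
    best
  }

  best <- search(grid_offsets(pitch))
  if (!is.null(best) && is.finite(best$obj)) {
    for (fine in c(pitch / 10, pitch / 100)) {
      g <- as.matrix(expand.grid(i = -10:10, j = -10:10)) * fine
      ref_best <- search(g, origin2 = best$off)
      if (!is.null(ref_best) && ref_best$obj >= best$obj) best <- ref_best
    }
  }
  if (is.null(best) || !is.finite(best$obj) || best$obj <= 0) {
    binding <- if (is.null(best) || !is.finite(best$obj)) "EAC" else {
      m <- best$report$margins[c("FN", "CT"), 1L]
      names(m)[which.min(m)]
    }
    stop(sprintf("no feasible path: no candidate entry achieves positive margins (binding structure: %s)",
                 binding))
  }
  notes <- character()
  fn <- check_fn_constraint(best$report, D, min_fn_margin)
  if (!fn$ok && !is.null(fn$note)) notes <- c(notes, fn$note)
  list(path = best$path, report = best$report, objective = best$obj,
       entry_offset = best$off, notes = notes)
}
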