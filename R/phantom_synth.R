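# Synthetic temporal-bone phantom: analytic scenes with exact geometric
# ground truth, plus CT-like rasterization for end-to-end validation of
# detection, registration, clearance measurement and bone-thickness probing.
#
# Geometry of the canonical scene (all in mm, world = phantom coordinates):
# the round-window target sits at the origin and the canonical drill path
# runs along -z from the entry at (0, 0, path_length). The facial nerve and
# chorda tympani are straight capsules crossing the path corridor
# perpendicular to the axis (curvature of the canals is irrelevant over the
# 3-4 mm scale of the facial recess), offset in -y and +y so that the
# axis-to-surface distances equal the configured d_FN and d_CT exactly.
# The EAC lumen is an air capsule parallel to the path on the +x side at a
# configurable axis-to-wall distance, and a bone slab of configurable
# thickness (backed by an air cell layer) occupies the screw-site corner.

#' Phantom specification
#'
#' Defaults describe a typical case in the middle of the clinically observed
#' range: nerve clearances a little over 1 mm each, an EAC wall about 1 mm
#' from the axis, and a 5.6 mm bone table at the screw site.
#'
#' @param d_fn,d_ct target axis-to-surface distances to the facial nerve and
#'   chorda tympani, mm.
#' @param r_fn,r_ct canal radii, mm (facial-nerve canal about 0.7 mm, chorda
#'   canal about 0.3 mm).
#' @param d_eac axis-to-surface distance to the EAC wall, mm.
#' @param r_eac EAC lumen radius, mm.
#' @param slab_thickness bone thickness at the screw site, mm.
#' @param path_length canonical path length from entry to target, mm.
#' @param marker optional [marker_model()] rasterized into its own volume by
#'   [rasterize_marker_volume()].
#' @param marker_pose [rigid_transform()] placing the marker in world
#'   coordinates.
#' @param noise additive Gaussian image noise, as a fraction of the titanium
#'   intensity (0.02 = 2% of ball intensity).
#' @param seed integer seed fixing all randomness of rasterization.
#' @param spacing isotropic voxel size, mm.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(d_fn = 1.1, d_ct = 1.45, r_fn = 0.7, r_ct = 0.3,
                         d_eac = 1.1, r_eac = 3.0, slab_thickness = 5.6,
                         path_length = 35, marker = default_marker_model(),
                         marker_pose = rigid_transform(),
                         noise = 0.02, seed = 0L, spacing = 0.3) {
  if (!is.finite(d_fn) || !is.finite(d_ct) || d_fn <= 0 || d_ct <= 0)
    stop("inconsistent phantom: d_fn and d_ct must be positive (zero recess gap rejected)")
  if (r_fn <= 0 || r_ct <= 0 || r_eac <= 0) stop("structure radii must be positive")
  if (d_eac <= 0) stop("d_eac must be positive")
  if (slab_thickness <= 0) stop("slab thickness must be positive")
  if (path_length <= 5) stop("path length too short for the scene")
  if (noise < 0) stop("noise must be >= 0")
  if (spacing <= 0) stop("spacing must be positive")
  structure(list(d_fn = d_fn, d_ct = d_ct, r_fn = r_fn, r_ct = r_ct,
                 d_eac = d_eac, r_eac = r_eac,
                 slab_thickness = slab_thickness, path_length = path_length,
                 marker = marker, marker_pose = marker_pose,
                 noise = noise, seed = as.integer(seed), spacing = spacing),
            class = "phantom_spec")
}

#' Material intensities of the phantom (CT-like arbitrary units)
#'
#' Only the ordering air < soft tissue < bone < titanium matters to the
#' algorithms.
#' @export
phantom_materials <- function() {
  c(air = -1000, soft = 0, bone = 1000, titanium = 3000)
}

#' Build the analytic phantom scene with exact ground truth
#'
#' Places the risk-structure capsules in closed form so that the
#' axis-to-surface distances of the canonical path equal the configured
#' values exactly, and returns the scene together with a ground-truth
#' record.
#'
#' @param spec a [phantom_spec()].
#' @return list with `scene` ([scene_model()]), `path` (the canonical
#'   [access_path()]) and `truth` (configured distances, screw site, slab
#'   thickness).
#' @export
build_scene <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  target <- c(0, 0, 0)
  # nerves cross the corridor perpendicular to the axis; the closest
  # centerline point to the axis is the x = 0 chain endpoint, at exactly
  # (d + r) lateral offset, so axis-to-surface distance is d by construction
  z_fn <- 3.0
  z_ct <- 4.5
  fn <- capsule_chain(rbind(c(-5, -(spec$d_fn + spec$r_fn), z_fn),
                            c(0, -(spec$d_fn + spec$r_fn), z_fn)),
                      radius = spec$r_fn)
  ct <- capsule_chain(rbind(c(-5, spec$d_ct + spec$r_ct, z_ct),
                            c(0, spec$d_ct + spec$r_ct, z_ct)),
                      radius = spec$r_ct)
  # FN and CT canals must not intersect each other
  gap <- segment_segment_distance(segment3(fn$vertices[1, ], fn$vertices[2, ]),
                                  segment3(ct$vertices[1, ], ct$vertices[2, ])) -
    spec$r_fn - spec$r_ct
  if (gap <= 0) stop("inconsistent phantom: nerve canals would overlap")
  eac <- capsule_chain(rbind(c(spec$d_eac + spec$r_eac, 0, -2),
                             c(spec$d_eac + spec$r_eac, 0, 20)),
                       radius = spec$r_eac)
  screw_site <- list(point = c(-6.5, 0, 11.8), normal = c(0, 0, -1))
  cochlear_frame <- list(axis1 = c(0, 0, -1), normal = c(0, 1, 0))
  scene <- scene_model(list(FN = fn, CT = ct, EAC = eac), target = target,
                       cochlear_frame = cochlear_frame, screw_site = screw_site)
  path <- access_path(target, c(0, 0, -1), spec$path_length, 1.5)
  truth <- list(d = c(FN = spec$d_fn, CT = spec$d_ct, EAC = spec$d_eac),
                slab_thickness = spec$slab_thickness,
                screw_site = screw_site, path = path)
  list(scene = scene, path = path, truth = truth)
}

# Minimum distance from each of n points to a segment.
points_to_segment_distance <- function(pts, seg) {
  ab <- seg$b - seg$a
  t <- pmin(1, pmax(0, (sweep(pts, 2L, seg$a) %*% ab) / sum(ab * ab)))
  cp <- matrix(seg$a, nrow(pts), 3L, byrow = TRUE) + t %*% matrix(ab, 1L, 3L)
  sqrt(rowSums((pts - cp)^2))
}

# Minimum distance from each of n points to a capsule chain's centerline.
points_to_chain_distance <- function(pts, chain) {
  v <- chain$vertices
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(v) - 1L)) {
    a <- v[i, ]; b <- v[i + 1L, ]
    ab <- b - a
    t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L] +
          (pts[, 3L] - a[3L]) * ab[3L]) / sum(ab * ab)
    t <- pmin(1, pmax(0, t))
    dx <- pts[, 1L] - (a[1L] + t * ab[1L])
    dy <- pts[, 2L] - (a[2L] + t * ab[2L])
    dz <- pts[, 3L] - (a[3L] + t * ab[3L])
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy + dz * dz))
  }
  dmin
}

# Partial-volume coverage weight from a signed surface distance: full
# coverage half a voxel inside the surface, zero half a voxel outside.
pv_weight <- function(signed_dist, h) pmin(1, pmax(0, 0.5 - signed_dist / h))

#' Rasterize the anatomy scene into a CT-like volume
#'
#' Voxelizes bone background, the nerve canals (soft tissue), the EAC lumen
#' (air), and the screw-site bone slab backed by an air-cell layer, with
#' linear partial-volume blending at material boundaries, then adds seeded
#' Gaussian noise. The volume covers the recess corridor and the screw-site
#' corner (x in [-8, 8], y in [-6, 6], z in [-3, 12] mm).
#'
#' @param built result of [build_scene()].
#' @param spec the [phantom_spec()] used to build it.
#' @param max_voxels guard against accidentally huge volumes.
#' @return an [image_volume()].
#' @export
rasterize_scene <- function(built, spec, max_voxels = 2e7) {
  stopifnot(inherits(spec, "phantom_spec"))
  mat <- phantom_materials()
  h <- spec$spacing
  lo <- c(-8, -6, -3)
  hi <- c(8, 6, 12)
  dm <- floor((hi - lo) / h) + 1L
  if (prod(dm) > max_voxels) stop("volume would exceed the voxel budget")
  vol <- image_volume(array(mat[["bone"]], dim = dm), spacing = h, origin = lo)
  dmv <- dim(vol$array)
  # voxel center world coordinates, one axis at a time (axis-aligned grid)
  xs <- lo[1L] + h * (seq_len(dmv[1L]) - 1)
  ys <- lo[2L] + h * (seq_len(dmv[2L]) - 1)
  zs <- lo[3L] + h * (seq_len(dmv[3L]) - 1)

  paint_capsule <- function(arr, chain, value) {
    v <- chain$vertices
    r <- chain$radius
    bb_lo <- apply(v, 2L, min) - r - h
    bb_hi <- apply(v, 2L, max) + r + h
    ii <- which(xs >= bb_lo[1L] & xs <= bb_hi[1L])
    jj <- which(ys >= bb_lo[2L] & ys <= bb_hi[2L])
    kk <- which(zs >= bb_lo[3L] & zs <= bb_hi[3L])
    if (!length(ii) || !length(jj) || !length(kk)) return(arr)
    g <- as.matrix(expand.grid(x = xs[ii], y = ys[jj], z = zs[kk]))
    w <- pv_weight(points_to_chain_distance(g, chain) - r, h)
    idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    lin <- idx[, 1L] + dmv[1L] * (idx[, 2L] - 1) + dmv[1L] * dmv[2L] * (idx[, 3L] - 1)
    arr[lin] <- (1 - w) * arr[lin] + w * value
    arr
  }

  a <- vol$array
  a <- paint_capsule(a, built$scene$structures$FN, mat[["soft"]])
  a <- paint_capsule(a, built$scene$structures$CT, mat[["soft"]])
  a <- paint_capsule(a, built$scene$structures$EAC, mat[["air"]])

  # screw-site slab: bone down to slab_thickness below the top face for
  # x <= -6 (clear of the nerve corridor, which stays at x >= -5), then a
  # 2 mm air-cell layer (terminates the thickness probe)
  ss <- built$truth$screw_site
  z_top <- ss$point[3L]
  gap_hi <- z_top - spec$slab_thickness
  gap_lo <- gap_hi - 2.0
  ii <- which(xs <= -6)
  kk <- which(zs > gap_lo - h & zs < gap_hi + h)
  if (length(ii) && length(kk)) {
    for (k in kk) {
      # partial volume on the two z faces of the air layer
      cov <- min(1, max(0, (min(gap_hi, zs[k] + h / 2) - max(gap_lo, zs[k] - h / 2)) / h))
      if (cov <= 0) next
      a[ii, , k] <- (1 - cov) * a[ii, , k] + cov * mat[["air"]]
    }
  }
  if (spec$noise > 0) {
    set.seed(spec$seed)
    a <- a + stats::rnorm(length(a), 0, spec$noise * mat[["titanium"]])
  }
  image_volume(a, spacing = h, origin = lo)
}

#' Rasterize a marker into its own volume
#'
#' Places the marker's titanium balls (transformed by `pose`) in a uniform
#' soft-tissue background with partial-volume ball surfaces and seeded
#' Gaussian noise. The volume is sized to the transformed ball bounding box
#' plus `margin`.
#'
#' @param model a [marker_model()].
#' @param pose [rigid_transform()] mapping marker/frame coordinates to world.
#' @param spacing isotropic voxel size, mm.
#' @param noise Gaussian noise s.d. as a fraction of the ball intensity.
#' @param seed integer seed.
#' @param margin padding around the balls, mm.
#' @param max_voxels voxel budget guard.
#' @return an [image_volume()].
#' @export
rasterize_marker_volume <- function(model, pose = rigid_transform(),
                                    spacing = 0.3, noise = 0, seed = 0L,
                                    margin = 4, max_voxels = 2e7) {
  stopifnot(inherits(model, "marker_model"), inherits(pose, "rigid_transform"))
  centers <- transform_points(pose, model$ball_centers)
  r <- model$ball_radius
  mat <- phantom_materials()
  lo <- apply(centers, 2L, min) - r - margin
  hi <- apply(centers, 2L, max) + r + margin
  dm <- floor((hi - lo) / spacing) + 1L
  if (prod(dm) > max_voxels) stop("volume would exceed the voxel budget")
  a <- array(mat[["soft"]], dim = dm)
  xs <- lo[1L] + spacing * (seq_len(dm[1L]) - 1)
  ys <- lo[2L] + spacing * (seq_len(dm[2L]) - 1)
  zs <- lo[3L] + spacing * (seq_len(dm[3L]) - 1)
  for (b in seq_len(nrow(centers))) {
    cb <- centers[b, ]
    ii <- which(abs(xs - cb[1L]) <= r + spacing)
    jj <- which(abs(ys - cb[2L]) <= r + spacing)
    kk <- which(abs(zs - cb[3L]) <= r + spacing)
    g <- as.matrix(expand.grid(x = xs[ii], y = ys[jj], z = zs[kk]))
    d <- sqrt(rowSums(sweep(g, 2L, cb)^2))
    w <- pv_weight(d - r, spacing)
    idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    lin <- idx[, 1L] + dm[1L] * (idx[, 2L] - 1) + dm[1L] * dm[2L] * (idx[, 3L] - 1)
    a[lin] <- (1 - w) * a[lin] + w * model$intensity
  }
  if (noise > 0) {
    set.seed(seed)
    a <- a + stats::rnorm(length(a), 0, noise * model$intensity)
  }
  image_volume(a, spacing = spacing, origin = lo)
}

#' Re-measure nerve clearances from a rasterized volume
#'
#' Validation counterpart of [evaluate_clearance()] that does not use the
#' analytic scene geometry for the measurement itself: soft-tissue voxels
#' (the rasterized nerve canals) are segmented by an intensity window,
#' grouped into connected components, each component is attributed to the
#' structure whose centerline is nearest to its centroid, and the
#' axis-to-surface distance is estimated as the minimum distance from the
#' path axis to any voxel center of the component.
#'
#' @param vol rasterized [image_volume()].
#' @param path the [access_path()] to measure against.
#' @param scene the [scene_model()] (used only to attribute components to
#'   structure names).
#' @param window intensity window (length 2) classifying soft tissue.
#' @return named numeric vector of estimated axis-to-surface distances, mm.
#' @export
measure_clearance_from_volume <- function(vol, path, scene,
                                          window = c(-500, 500)) {
  stopifnot(inherits(vol, "image_volume"), inherits(path, "access_path"),
            inherits(scene, "scene_model"))
  a <- vol$array
  sel <- which(a > window[1L] & a < window[2L])
  if (!length(sel)) stop("no soft-tissue voxels found in the window")
  dm <- dim(a)
  comp <- label_components_26(sel, dm)
  world <- voxel_to_world(vol, arrayInd(sel, dm))
  axis <- path_axis(path)
  nerves <- scene$structures[names(scene$structures) %in% c("FN", "CT")]
  out <- rep(Inf, length(nerves))
  names(out) <- names(nerves)
  for (cid in unique(comp)) {
    pts <- world[comp == cid, , drop = FALSE]
    if (nrow(pts) < 5L) next  # noise specks
    centroid <- colMeans(pts)
    dc <- vapply(nerves, function(s)
      points_to_chain_distance(matrix(centroid, 1L, 3L), s), numeric(1))
    who <- names(nerves)[which.min(dc)]
    # guard against thin partial-volume shells of other interfaces (e.g. the
    # air-bone boundary of the EAC lumen falls into the soft-tissue window):
    # keep only voxels in the vicinity of the attributed canal
    near <- points_to_chain_distance(pts, nerves[[who]]) <=
      nerves[[who]]$radius + 2 * max(vol$spacing)
    if (!any(near)) next
    out[who] <- min(out[who],
                    min(points_to_segment_distance(pts[near, , drop = FALSE], axis)))
  }
  out
}

#' Bundled per-case planning table of the first-in-man trial
#'
#' Machine-readable copy of the published per-patient planning and outcome
#' table (six patients): demographics, recorded sham-drill outcomes, planned
#' distance to the EAC wall, the two nerve clearances d_FN and d_CT, the
#' planned margins at 1.5 mm drill diameter, the jig manufacturing deviation
#' projected to target depth, and the bone thickness at the screw site.
#'
#' @return data.frame with one row per patient.
#' @export
trial_fixture <- function() {
  path <- system.file("extdata", "table1_trial.csv", package = "jigplan",
                      mustWork = TRUE)
  utils::read.csv(path, colClasses = c(patient = "character"))
}
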