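# Fiducial marker localization and image-to-frame registration.
#
# The bone-anchored frame carries an X-ray marker with several titanium
# balls at known positions. Registration proceeds in three steps:
# detect bright ball-like components in the volume (sub-voxel centroids),
# match them to the marker model by comparing inter-ball distances, and
# fit the least-squares rigid transform.

#' Marker model: known ball layout in frame coordinates
#'
#' @param ball_centers n x 3 matrix (n >= 4) of ball centers in marker/frame
#'   coordinates, mm.
#' @param ball_radius ball radius, mm.
#' @param intensity expected scalar level of titanium in the image (arbitrary
#'   CT-like units; only the ordering bone < titanium matters).
#' @return object of class `marker_model`.
#' @export
marker_model <- function(ball_centers, ball_radius = 1.0, intensity = 3000) {
  centers <- as_points3(ball_centers)
  if (nrow(centers) < 4L) stop("a marker model needs at least 4 balls")
  if (ball_radius <= 0) stop("ball_radius must be positive")
  d <- as.numeric(stats::dist(centers))
  # the pairwise-distance multiset must be non-degenerate for unambiguous
  # matching: no two inter-ball distances closer than the matching tolerance
  if (min(diff(sort(d))) < 1e-6)
    warning("marker has repeated inter-ball distances; matching may be ambiguous")
  structure(list(ball_centers = centers, ball_radius = ball_radius,
                 intensity = intensity),
            class = "marker_model")
}

#' Default five-ball marker layout
#'
#' A non-symmetric 3-D configuration of five balls spanning roughly 35 mm,
#' chosen so that all ten inter-ball distances are pairwise distinct (no
#' ambiguity under any rigid motion). The clinical marker's layout is not
#' published; this stand-in is user-replaceable via [marker_model()] /
#' [read_marker_model()].
#'
#' @inheritParams marker_model
#' @export
default_marker_model <- function(ball_radius = 1.0, intensity = 3000) {
  marker_model(rbind(
    c(0, 0, 0),
    c(24, 2, 1),
    c(5, 21, -2),
    c(19, 16, 9),
    c(9, 7, 17)), ball_radius = ball_radius, intensity = intensity)
}

#' Read / write a marker model as JSON
#'
#' Schema: `{"balls_mm": [[x,y,z], ...], "radius_mm": r, "intensity": i}`.
#'
#' @param path JSON file path.
#' @export
read_marker_model <- function(path) {
  j <- jsonlite::fromJSON(path)
  marker_model(as.matrix(j$balls_mm),
               ball_radius = j$radius_mm,
               intensity = if (!is.null(j$intensity)) j$intensity else 3000)
}

#' @rdname read_marker_model
#' @param model a [marker_model()].
#' @export
write_marker_model <- function(model, path) {
  stopifnot(inherits(model, "marker_model"))
  jsonlite::write_json(list(balls_mm = model$ball_centers,
                            radius_mm = model$ball_radius,
                            intensity = model$intensity),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Otsu threshold over the upper tail of the intensity distribution.
# Titanium is the brightest material in the scan; restricting Otsu to the
# top quantile separates metal from bone without modelling the full
# histogram.
upper_tail_otsu <- function(values, tail = 0.01, nbins = 256L) {
  lo <- stats::quantile(values, 1 - tail, names = FALSE)
  v <- values[values >= lo]
  if (length(unique(v)) < 2L) return(lo)
  h <- graphics::hist(v, breaks = nbins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Detect marker balls in a volume
#'
#' Thresholds the volume, labels 26-connected bright components, and keeps
#' components whose equivalent-sphere radius lies within `radius_range`.
#' Centers are intensity-weighted sub-voxel centroids in world mm, sorted
#' lexicographically by (x, y, z) for determinism. Components touching the
#' volume border are kept but flagged, since their centroids are unreliable.
#'
#' @param vol an [image_volume()].
#' @param intensity_threshold scalar threshold; `NULL` (default) uses Otsu on
#'   the upper 1% intensity tail.
#' @param radius_range length-2 range of acceptable equivalent-sphere radii,
#'   mm.
#' @return data.frame with columns `x`, `y`, `z` (mm), `radius_mm`
#'   (equivalent-sphere), `n_voxels`, `on_border`.
#' @export
detect_balls <- function(vol, intensity_threshold = NULL,
                         radius_range = c(0.5, 2.0)) {
  stopifnot(inherits(vol, "image_volume"))
  a <- vol$array
  if (is.null(intensity_threshold)) intensity_threshold <- upper_tail_otsu(a)
  sel <- which(a >= intensity_threshold)
  if (length(sel) == 0L) stop("marker not found: no voxels above threshold")
  dm <- dim(a)
  comp <- label_components_26(sel, dm)
  vox_mm3 <- prod(vol$spacing)
  ijk <- arrayInd(sel, dm)
  w <- a[sel] - intensity_threshold  # intensity weighting above threshold
  w[w <= 0] <- 1e-12
  res <- lapply(split(seq_along(sel), comp), function(ii) {
    sub <- ijk[ii, , drop = FALSE]
    wi <- w[ii]
    centroid_ijk <- colSums(sub * wi) / sum(wi)
    nvox <- length(ii)
    r_eq <- (3 * nvox * vox_mm3 / (4 * pi))^(1 / 3)
    border <- any(sub == 1L) || any(sweep(sub, 2L, dm, "==") )
    c(centroid_ijk, r_eq, nvox, as.numeric(border))
  })
  m <- do.call(rbind, res)
  keep <- m[, 4L] >= radius_range[1L] & m[, 4L] <= radius_range[2L]
  if (!any(keep)) stop("marker not found: no component in the ball radius range")
  m <- m[keep, , drop = FALSE]
  world <- voxel_to_world(vol, m[, 1:3, drop = FALSE])
  out <- data.frame(x = world[, 1L], y = world[, 2L], z = world[, 3L],
                    radius_mm = m[, 4L], n_voxels = as.integer(m[, 5L]),
                    on_border = m[, 6L] > 0)
  if (any(out$on_border))
    warning("some detected components touch the volume border; centroids may be biased")
  out <- out[order(out$x, out$y, out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 26-connected component labelling on a sparse voxel index set.
# Only the above-threshold voxels (a few thousand for marker balls) are
# touched, so a label-propagation over the sorted linear indices is cheap.
label_components_26 <- function(lin_idx, dm) {
  n <- length(lin_idx)
  ijk <- arrayInd(lin_idx, dm)
  ord <- order(lin_idx)
  sorted_lin <- lin_idx[ord]
  # offsets of the 13 "previous" neighbours in linear index space are not
  # contiguous; use full 26-neighbourhood membership lookups via match()
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2L, offs[k, ], "+")
    ok <- nb[, 1L] >= 1 & nb[, 1L] <= dm[1L] &
          nb[, 2L] >= 1 & nb[, 2L] <= dm[2L] &
          nb[, 3L] >= 1 & nb[, 3L] <= dm[3L]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1L] + dm[1L] * (nb[ok, 2L] - 1) + dm[1L] * dm[2L] * (nb[ok, 3L] - 1)
    pos <- findInterval(nb_lin, sorted_lin)
    hit <- pos > 0 & sorted_lin[pmax(pos, 1L)] == nb_lin
    ia <- which(ok)[hit]
    ib <- ord[pos[hit]]
    for (m in seq_along(ia)) {
      ra <- find(ia[m]); rb <- find(ib[m])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Match detected balls to a marker model
#'
#' Exhaustive correspondence search over inter-point distances: for every
#' injective assignment of model balls to detected points (models have <= 10
#' balls, so the search is small), counts how many model inter-ball distances
#' are reproduced within `tol` and returns the assignment maximizing that
#' count; ties are broken by the lower total absolute distance residual.
#' Spurious detections are excluded automatically; the map must cover at
#' least 4 balls.
#'
#' @param detected data.frame from [detect_balls()] or an n x 3 point matrix.
#' @param model a [marker_model()].
#' @param tol distance-match tolerance, mm.
#' @return integer vector `map` of length `nrow(model$ball_centers)`;
#'   `map[i]` is the row of `detected` matched to model ball `i` (`NA` if
#'   unmatched), with attribute `n_matched`.
#' @export
match_balls <- function(detected, model, tol = 0.3) {
  stopifnot(inherits(model, "marker_model"))
  if (is.data.frame(detected)) detected <- as.matrix(detected[, c("x", "y", "z")])
  P <- as_points3(detected)
  if (nrow(P) < 4L) stop("need at least 4 detected points to match a marker")
  M <- model$ball_centers
  nm <- nrow(M)
  np <- nrow(P)
  dM <- as.matrix(stats::dist(M))
  dP <- as.matrix(stats::dist(P))

  best <- list(score = -1L, resid = Inf, map = NULL)
  map <- rep(NA_integer_, nm)
  used <- rep(FALSE, np)

  score_pairs <- function(map) {
    idx <- which(!is.na(map))
    if (length(idx) < 2L) return(c(0, 0))
    s <- 0L; r <- 0
    for (i in seq_along(idx)[-length(idx)]) for (j in (i + 1L):length(idx)) {
      a <- idx[i]; b <- idx[j]
      dd <- abs(dM[a, b] - dP[map[a], map[b]])
      if (dd <= tol) { s <- s + 1L; r <- r + dd }
    }
    c(s, r)
  }

  recurse <- function(i, map, used, nmatched) {
    # bound: even matching all remaining balls cannot beat the best score
    if (nmatched + (nm - i + 1L) < 4L) return()
    if (i > nm) {
      if (nmatched < 4L) return()
      sc <- score_pairs(map)
      npairs <- nmatched * (nmatched - 1L) / 2L
      if (sc[1L] < npairs) return()  # all matched pairs must be consistent
      if (sc[1L] > best$score || (sc[1L] == best$score && sc[2L] < best$resid)) {
        best <<- list(score = sc[1L], resid = sc[2L], map = map)
      }
      return()
    }
    for (p in seq_len(np)) {
      if (used[p]) next
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (!is.na(map[j]) && abs(dM[j, i] - dP[map[j], p]) > tol) { ok <- FALSE; break }
      }
      if (ok) {
        map[i] <- p; used[p] <- TRUE
        recurse(i + 1L, map, used, nmatched + 1L)
        map[i] <- NA_integer_; used[p] <- FALSE
      }
    }
    recurse(i + 1L, map, used, nmatched)  # leave model ball i unmatched
  }
  recurse(1L, map, used, 0L)
  if (is.null(best$map) || best$score < 1L)
    stop("ambiguous or missing marker: no consistent correspondence covering >= 4 balls")
  structure(best$map, n_matched = sum(!is.na(best$map)))
}

#' Register a volume to the frame via the X-ray marker
#'
#' Composition of [detect_balls()], [match_balls()] and
#' [fit_rigid_transform()]: detects ball centroids, establishes
#' correspondence with the marker model, and returns the image-to-frame
#' rigid transform together with the fiducial registration error.
#'
#' @inheritParams detect_balls
#' @param model a [marker_model()].
#' @param match_tol distance-match tolerance for correspondence, mm.
#' @return list with `transform` (image -> frame [rigid_transform()]),
#'   `fre` (mm), `n_used` (balls used), `detected` (the detection table) and
#'   `map` (model-to-detection correspondence).
#' @export
register_marker <- function(vol, model = default_marker_model(),
                            intensity_threshold = NULL,
                            radius_range = c(0.5, 2.0), match_tol = 0.3) {
  det <- detect_balls(vol, intensity_threshold, radius_range)
  map <- match_balls(det, model, tol = match_tol)
  idx <- which(!is.na(map))
  fit <- fit_rigid_transform(as.matrix(det[map[idx], c("x", "y", "z")]),
                             model$ball_centers[idx, , drop = FALSE])
  list(transform = fit$transform, fre = fit$fre, n_used = fit$n,
       detected = det, map = map)
}
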