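# JSON serialization of planning objects (scene, path, transform, hole).
# Schemas are flat and explicit so that other tools (the manufacturing
# system, a CMM export) can produce or consume them.

#' Read / write a scene model as JSON
#'
#' Schema: `{"structures": [{"name", "centerline_mm": [[x,y,z],...],
#' "radius_mm"}], "target_mm", "cochlear_frame": {"axis1","normal"},
#' "screw_site": {"point_mm","normal"}}`; the frame and screw site are
#' optional.
#'
#' @param path JSON file path.
#' @export
read_scene <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  structures <- list()
  for (s in j$structures) {
    cl <- s$centerline_mm
    if (is.list(cl)) cl <- do.call(rbind, cl)
    structures[[s$name]] <- capsule_chain(cl, radius = s$radius_mm)
  }
  cf <- if (!is.null(j$cochlear_frame))
    list(axis1 = as.numeric(j$cochlear_frame$axis1),
         normal = as.numeric(j$cochlear_frame$normal))
  ss <- if (!is.null(j$screw_site))
    list(point = as.numeric(j$screw_site$point_mm),
         normal = as.numeric(j$screw_site$normal))
  scene_model(structures, as.numeric(j$target_mm),
              cochlear_frame = cf, screw_site = ss)
}

#' @rdname read_scene
#' @param scene a [scene_model()].
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene_model"))
  j <- list(
    structures = lapply(names(scene$structures), function(nm) {
      s <- scene$structures[[nm]]
      list(name = nm, centerline_mm = s$vertices, radius_mm = s$radius)
    }),
    target_mm = scene$target)
  if (!is.null(scene$cochlear_frame))
    j$cochlear_frame <- list(axis1 = scene$cochlear_frame$axis1,
                             normal = scene$cochlear_frame$normal)
  if (!is.null(scene$screw_site))
    j$screw_site <- list(point_mm = scene$screw_site$point,
                         normal = scene$screw_site$normal)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write an access path as JSON
#'
#' Schema: `{"target_mm", "direction", "length_mm", "diameter_mm"}`.
#' @param path JSON file path.
#' @export
read_path <- function(path) {
  j <- jsonlite::fromJSON(path)
  access_path(as.numeric(j$target_mm), as.numeric(j$direction),
              j$length_mm, j$diameter_mm)
}

#' @rdname read_path
#' @param x an [access_path()].
#' @export
write_path <- function(x, path) {
  stopifnot(inherits(x, "access_path"))
  jsonlite::write_json(list(target_mm = x$target, direction = x$direction,
                            length_mm = x$length, diameter_mm = x$diameter),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a rigid transform as JSON
#'
#' Schema: `{"rotation": [[...],[...],[...]], "translation_mm", "fre_mm",
#' "n_used"}` (the last two optional, written by the registration step).
#' @param path JSON file path.
#' @export
read_transform <- function(path) {
  j <- jsonlite::fromJSON(path)
  out <- rigid_transform(as.matrix(j$rotation), as.numeric(j$translation_mm))
  attr(out, "fre") <- j$fre_mm
  attr(out, "n_used") <- j$n_used
  out
}

#' @rdname read_transform
#' @param transform a [rigid_transform()]; `fre`/`n_used` optional metadata.
#' @param fre,n_used optional registration metadata to embed.
#' @export
write_transform <- function(transform, path, fre = NULL, n_used = NULL) {
  stopifnot(inherits(transform, "rigid_transform"))
  j <- list(rotation = transform$rotation, translation_mm = transform$translation)
  if (!is.null(fre)) j$fre_mm <- fre
  if (!is.null(n_used)) j$n_used <- n_used
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a jig hole pose as JSON
#'
#' Schema: `{"point_mm", "axis", "depth_mm"}`.
#' @param path JSON file path.
#' @export
read_hole <- function(path) {
  j <- jsonlite::fromJSON(path)
  hole_pose(as.numeric(j$point_mm), as.numeric(j$axis), j$depth_mm)
}

#' @rdname read_hole
#' @param hole a [hole_pose()].
#' @export
write_hole <- function(hole, path) {
  stopifnot(inherits(hole, "hole_pose"))
  jsonlite::write_json(list(point_mm = hole$point, axis = hole$axis,
                            depth_mm = hole$depth_to_target),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
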