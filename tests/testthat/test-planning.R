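# Clearance evaluation, margins, feasibility, angles, bone thickness and
# entry optimization.

test_that("clearance report reproduces the published margin arithmetic", {
  # case with d_FN = 1.16, d_CT = 1.29 at D = 1.5 mm
  b <- build_scene(phantom_spec(d_fn = 1.16, d_ct = 1.29))
  r <- evaluate_clearance(b$path, b$scene)
  expect_equal(r$d[["FN"]], 1.16, tolerance = 1e-12)
  expect_equal(r$d[["CT"]], 1.29, tolerance = 1e-12)
  expect_equal(r$margins["FN", "1.5"], 0.41, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(r$margins["CT", "1.5"], 0.54, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(r$recess_width, 2.45, tolerance = 1e-12)

  # wide chorda case: d_CT = 2.28 gives margin 1.53 at 1.5 mm
  b2 <- build_scene(phantom_spec(d_fn = 1.06, d_ct = 2.28))
  r2 <- evaluate_clearance(b2$path, b2$scene)
  expect_equal(r2$margins["CT", "1.5"], 1.53, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("feasibility is inclusive at the touching boundary", {
  b <- build_scene(phantom_spec(d_fn = 0.75, d_ct = 0.75, r_ct = 0.7))
  r <- evaluate_clearance(b$path, b$scene)
  expect_equal(r$margins["FN", "1.5"], 0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(r$margins["CT", "1.5"], 0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(r$feasible[["1.5"]])          # touching still fits under >=
  expect_false(r$feasible_strict[["1.5"]])  # but does not pass freely
})

test_that("largest feasible diameter follows the tested series", {
  b <- build_scene(phantom_spec(d_fn = 1.08, d_ct = 1.60))
  r <- evaluate_clearance(b$path, b$scene)
  expect_equal(r$largest_feasible, 1.8)  # 0.9 <= 1.08 < 1.1
})

test_that("feasibility is nested and margins shrink with structure radius", {
  set.seed(2)
  for (i in 1:20) {
    b <- build_scene(phantom_spec(d_fn = runif(1, 0.4, 2), d_ct = runif(1, 0.4, 2.5)))
    r <- evaluate_clearance(b$path, b$scene)
    f <- r$feasible
    expect_true(all(f == cummin(f)))  # once infeasible, larger D stays infeasible
  }
  b <- build_scene(phantom_spec(d_fn = 1.2, d_ct = 1.4))
  r1 <- evaluate_clearance(b$path, b$scene)
  grown <- b$scene
  grown$structures$FN <- capsule_chain(grown$structures$FN$vertices,
                                       grown$structures$FN$radius + 0.3)
  r2 <- evaluate_clearance(b$path, grown)
  expect_true(all(r2$margins <= r1$margins + 1e-12))
})

test_that("a penetrating axis is flagged invalid with negative clearance", {
  b <- build_scene(phantom_spec(d_fn = 1.0, d_ct = 1.0))
  # aim straight at the FN canal center
  fnv <- b$scene$structures$FN$vertices
  hit <- colMeans(fnv)
  p <- access_path(hit, c(0, 0, -1), 20, 1.5)
  r <- evaluate_clearance(p, b$scene)
  expect_lt(r$d[["FN"]], 0)
  expect_false(r$valid)
})

test_that("the facial-nerve rule is inclusive and soft below target", {
  b <- build_scene(phantom_spec(d_fn = 1.16, d_ct = 1.29))
  r <- evaluate_clearance(b$path, b$scene)
  expect_true(check_fn_constraint(r, 1.5, 0.3)$ok)  # margin 0.41

  b2 <- build_scene(phantom_spec(d_fn = 1.04, d_ct = 1.61))
  r2 <- evaluate_clearance(b2$path, b2$scene)
  chk <- check_fn_constraint(r2, 1.5, 0.3)          # margin 0.29
  expect_false(chk$ok)
  expect_match(chk$note, "soft violation")

  b3 <- build_scene(phantom_spec(d_fn = 1.05, d_ct = 1.5))
  r3 <- evaluate_clearance(b3$path, b3$scene)
  expect_true(check_fn_constraint(r3, 1.5, 0.3)$ok) # margin exactly 0.30
})

test_that("EAC shaft check honours convention and strict touching", {
  b <- build_scene(phantom_spec(d_eac = 1.9))
  chk <- check_shaft_eac(b$path, b$scene, convention = "axis_to_wall")
  expect_equal(chk$distance, 1.9, tolerance = 1e-12)
  expect_false(chk$touches)  # 1.9 mm axis clearance > 1.5 mm shaft radius
  chk2 <- check_shaft_eac(b$path, b$scene, convention = "drill_surface_to_wall")
  expect_equal(chk2$distance, 1.9 - 0.75, tolerance = 1e-12)

  far <- build_scene(phantom_spec(d_eac = 10))
  expect_false(check_shaft_eac(far$path, far$scene)$touches)

  boundary <- build_scene(phantom_spec(d_eac = 1.5))
  expect_false(check_shaft_eac(boundary$path, boundary$scene)$touches)

  no_eac <- scene_model(b$scene$structures[c("FN", "CT")], b$scene$target)
  expect_error(check_shaft_eac(b$path, no_eac), "no EAC")
})

test_that("insertion angles follow the documented convention", {
  frame <- list(axis1 = c(1, 0, 0), normal = c(0, 0, 1))
  p_in <- access_path(c(0, 0, 0), c(1, 0, 0), 30)
  a <- insertion_angles(p_in, frame)
  expect_equal(a$in_plane, 0)
  expect_equal(a$off_plane, 0)

  p_norm <- access_path(c(0, 0, 0), c(0, 0, 1), 30)
  a2 <- insertion_angles(p_norm, frame)
  expect_true(is.na(a2$in_plane))
  expect_equal(a2$off_plane, 90)
  expect_match(a2$note, "undefined")

  # 30 deg elevation, 45 deg azimuth
  d <- c(cos(pi / 6) * cos(pi / 4), cos(pi / 6) * sin(pi / 4), sin(pi / 6))
  a3 <- insertion_angles(access_path(c(0, 0, 0), d, 30), frame)
  expect_equal(a3$in_plane, 45, tolerance = 1e-9)
  expect_equal(a3$off_plane, 30, tolerance = 1e-9)
})

test_that("bone thickness is read off rasterized slabs within one voxel", {
  for (thick in c(6.9, 5.0)) {
    spec <- phantom_spec(slab_thickness = thick, noise = 0)
    b <- build_scene(spec)
    vol <- rasterize_scene(b, spec)
    th <- bone_thickness(vol, b$truth$screw_site$point, b$truth$screw_site$normal)
    expect_equal(th, thick, tolerance = 0.3)
  }
  spec <- phantom_spec(noise = 0)
  b <- build_scene(spec)
  vol <- rasterize_scene(b, spec)
  # start the ray inside the EAC air lumen: no bone at entry
  expect_warning(th0 <- bone_thickness(vol, c(4.1, 0, 5), c(0, 0, -1),
                                       max_depth = 2), "no bone")
  expect_equal(th0, 0)
})

test_that("screw-site check is inclusive at the design reach", {
  expect_true(check_screw_site(3.7))
  expect_true(check_screw_site(3.6))
  expect_false(check_screw_site(3.5))
})

test_that("entry optimization respects symmetry and beats random search", {
  # scene mirror-symmetric in y: optimum must lie on the symmetry plane
  fn <- capsule_chain(rbind(c(-5, -1.8, 3), c(5, -1.8, 3)), 0.6)
  ct <- capsule_chain(rbind(c(-5, 1.8, 3), c(5, 1.8, 3)), 0.6)
  scene <- scene_model(list(FN = fn, CT = ct), target = c(0, 0, 0))
  disc <- list(center = c(0, 0, 30), normal = c(0, 0, 1), radius = 4)
  opt <- optimize_entry(scene, disc, D = 1.5)
  entry <- path_entry(opt$path)
  expect_lt(abs(entry[2]), 0.25 + 1e-9)  # on the plane within grid pitch

  set.seed(77)
  rand_best <- -Inf
  for (i in 1:3000) {
    ang <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * disc$radius
    entry_i <- disc$center + c(rr * cos(ang), rr * sin(ang), 0)
    dirv <- unit_vector(scene$target - entry_i)
    p <- access_path(scene$target, dirv, sqrt(sum((scene$target - entry_i)^2)), 1.5)
    r <- evaluate_clearance(p, scene, 1.5)
    rand_best <- max(rand_best, min(r$margins[c("FN", "CT"), 1]))
  }
  expect_gte(opt$objective, rand_best - 1e-6)
})

test_that("an everywhere-blocked scene reports no feasible path", {
  fn <- capsule_chain(rbind(c(-10, -0.4, 3), c(10, -0.4, 3)), 0.6)
  ct <- capsule_chain(rbind(c(-10, 0.4, 3), c(10, 0.4, 3)), 0.6)
  scene <- scene_model(list(FN = fn, CT = ct), target = c(0, 0, 0))
  disc <- list(center = c(0, 0, 30), normal = c(0, 0, 1), radius = 2)
  expect_error(optimize_entry(scene, disc, D = 1.5), "no feasible path")
})
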