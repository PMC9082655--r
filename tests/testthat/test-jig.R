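# Through-hole parameterization and manufacturing-deviation projection.

test_that("an axial path through the plane origin yields the trivial hole", {
  p <- access_path(c(0, 0, 0), c(0, 0, -1), 40, 1.5)
  env <- jig_envelope(plane_origin = c(0, 0, 20), plane_normal = c(0, 0, 1))
  h <- path_to_hole(p, rigid_transform(), env)
  expect_equal(h$hole$point, c(0, 0, 20), tolerance = 1e-12)
  expect_equal(h$tilt, 0, tolerance = 1e-9)
  expect_equal(h$hole$depth_to_target, 20, tolerance = 1e-12)
  expect_true(h$in_bounds)
})

test_that("a hole outside the boundary disc is out of bounds", {
  p <- access_path(c(6, 0, 0), c(0, 0, -1), 40, 1.5)
  env <- jig_envelope(plane_origin = c(0, 0, 20), plane_normal = c(0, 0, 1),
                      radius = 5)
  h <- path_to_hole(p, rigid_transform(), env)
  expect_equal(h$radial_offset, 6, tolerance = 1e-12)
  expect_false(h$in_bounds)
})

test_that("hole conversion round-trips through an arbitrary registration", {
  set.seed(19)
  env <- jig_envelope(plane_origin = c(0, 0, 15), plane_normal = c(0, 0, 1),
                      radius = 50, tilt_limit = 89)
  for (i in 1:10) {
    T_ <- random_rigid()
    # a frame-coordinate path crossing the reference plane toward its target
    target_f <- c(runif(2, -5, 5), runif(1, -10, 5))
    entry_f <- c(runif(2, -10, 10), runif(1, 25, 40))
    dir_f <- unit_vector(target_f - entry_f)
    frame_to_image <- invert_transform(T_)
    p <- access_path(transform_points(frame_to_image, target_f, drop = TRUE),
                     transform_directions(frame_to_image, dir_f, drop = TRUE),
                     sqrt(sum((target_f - entry_f)^2)), 1.5)
    h <- path_to_hole(p, T_, env)
    back <- hole_to_path(h$hole, frame_to_image, diameter = p$diameter)
    expect_equal(back$target, p$target, tolerance = 1e-9)
    expect_equal(sum(back$direction * p$direction), 1, tolerance = 1e-9)
  }
})

test_that("a path parallel to the reference plane is rejected", {
  p <- access_path(c(0, 0, 0), c(1, 0, 0), 40, 1.5)
  env <- jig_envelope(plane_origin = c(0, 0, 20), plane_normal = c(0, 0, 1))
  expect_error(path_to_hole(p, rigid_transform(), env), "parallel")
})

test_that("a bad registration is stopped at the FRE gate", {
  p <- access_path(c(0, 0, 0), c(0, 0, -1), 40, 1.5)
  env <- jig_envelope(plane_origin = c(0, 0, 20), plane_normal = c(0, 0, 1))
  expect_error(path_to_hole(p, rigid_transform(), env, fre = 0.5, fre_gate = 0.3),
               "FRE")
  expect_silent(path_to_hole(p, rigid_transform(), env, fre = 0.2, fre_gate = 0.3))
})

test_that("deviation projection matches closed forms", {
  L <- 40
  nom <- hole_pose(c(0, 0, 0), c(0, 0, 1), L)
  expect_equal(deviation_at_target(nom, nom), 0)

  # pure angular error of 0.1 degrees
  th <- 0.1 * pi / 180
  rot <- hole_pose(c(0, 0, 0), c(sin(th), 0, cos(th)), L)
  dev <- deviation_at_target(nom, rot)
  # chord at depth L: 2 L sin(theta/2); equals L tan(theta) to first order
  expect_equal(dev, 2 * L * sin(th / 2), tolerance = 1e-12)
  expect_lt(abs(dev - L * tan(th)), 1.5e-7)

  # pure translation is depth-invariant
  sh <- hole_pose(c(0.1, 0, 0), c(0, 0, 1), L)
  expect_equal(deviation_at_target(nom, sh), 0.1, tolerance = 1e-12)
  nom2 <- hole_pose(c(0, 0, 0), c(0, 0, 1), 123)
  sh2 <- hole_pose(c(0.1, 0, 0), c(0, 0, 1), 123)
  expect_equal(deviation_at_target(nom2, sh2), 0.1, tolerance = 1e-12)
})

test_that("deviation is symmetric and grows linearly with depth for tilt", {
  set.seed(29)
  a <- hole_pose(runif(3), unit_vector(rnorm(3)), 40)
  b <- hole_pose(a$point + rnorm(3, 0, 0.1), unit_vector(a$axis + rnorm(3, 0, 0.01)), 40)
  expect_equal(deviation_at_target(a, b), deviation_at_target(b, a),
               tolerance = 1e-12)

  th <- 0.2 * pi / 180
  tilted_axis <- c(sin(th), 0, cos(th))
  devs <- vapply(c(10, 20, 40, 80), function(L)
    deviation_at_target(hole_pose(c(0, 0, 0), c(0, 0, 1), L),
                        hole_pose(c(0, 0, 0), tilted_axis, L)), numeric(1))
  slopes <- devs / c(10, 20, 40, 80)
  expect_lt(diff(range(slopes)), 1e-9)
  expect_equal(slopes[1], 2 * sin(th / 2), tolerance = 1e-12)
})

test_that("the QC gate passes the measured deviation range and is inclusive", {
  expect_true(qc_gate(0.24, 0.3))   # largest deviation seen in manufacturing
  expect_true(qc_gate(0.05, 0.3))
  expect_true(qc_gate(0.3, 0.3))
  expect_false(qc_gate(0.31, 0.3))
  expect_error(qc_gate(-0.1), ">= 0")
})
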