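# Geometry primitives: segment/capsule distances and the rigid fit.

test_that("segment distance handles parallel, identical and degenerate cases", {
  s1 <- segment3(c(0, 0, 0), c(1, 0, 0))
  s2 <- segment3(c(0, 2, 0), c(1, 2, 0))
  expect_equal(segment_segment_distance(s1, s2), 2.0)
  expect_equal(segment_segment_distance(s1, s1), 0.0)
  expect_equal(segment_segment_distance(s1, s2),
               segment_segment_distance(s2, s1))
  expect_error(segment3(c(1, 1, 1), c(1, 1, 1)), "degenerate")
})

test_that("segment distance matches the dense-sampling oracle on random pairs", {
  set.seed(42)
  worst <- 0
  for (i in 1:200) {
    s1 <- random_segment(5)
    s2 <- random_segment(5)
    got <- segment_segment_distance(s1, s2)
    want <- oracle_segment_distance(s1$a, s1$b, s2$a, s2$b)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-3)
})

test_that("segment distance never exceeds any endpoint-pair distance", {
  set.seed(7)
  for (i in 1:50) {
    s1 <- random_segment(5)
    s2 <- random_segment(5)
    d <- segment_segment_distance(s1, s2)
    ep <- c(sqrt(sum((s1$a - s2$a)^2)), sqrt(sum((s1$a - s2$b)^2)),
            sqrt(sum((s1$b - s2$a)^2)), sqrt(sum((s1$b - s2$b)^2)))
    expect_lte(d, min(ep) + 1e-12)
  }
})

test_that("axis-to-capsule distance is surface-referenced and signed", {
  axis <- segment3(c(0, 0, 0), c(1, 0, 0))
  cap <- capsule_chain(rbind(c(0, 1.5, 0), c(1, 1.5, 0)), radius = 0.5)
  expect_equal(axis_to_capsule_surface_distance(axis, cap), 1.0)
  through <- capsule_chain(rbind(c(0.5, -1, 0), c(0.5, 1, 0)), radius = 0.5)
  expect_equal(axis_to_capsule_surface_distance(axis, through), -0.5)
})

test_that("capsule surface distance decreases with radius at slope -1", {
  set.seed(11)
  axis <- random_segment(5)
  verts <- rbind(runif(3, -5, 5), runif(3, -5, 5), runif(3, -5, 5))
  radii <- c(0.2, 0.5, 0.9, 1.4)
  d <- vapply(radii, function(r)
    axis_to_capsule_surface_distance(axis, capsule_chain(verts, r)), numeric(1))
  expect_equal(diff(d), -diff(radii))
})

test_that("rigid fit recovers identity and known transforms", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  fit <- fit_rigid_transform(pts, pts)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(fit$fre, 1e-12)

  th <- 30 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  truth <- rigid_transform(Rz, c(1, 2, 3))
  fit2 <- fit_rigid_transform(pts, transform_points(truth, pts))
  expect_lt(max(abs(fit2$transform$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(fit2$transform$translation - truth$translation)), 1e-9)
  expect_lt(fit2$fre, 1e-9)
})

test_that("rigid fit is invariant to consistent relabeling and rejects bad input", {
  set.seed(5)
  src <- matrix(runif(18, -20, 20), 6, 3)
  tgt <- transform_points(random_rigid(), src) + matrix(rnorm(18, 0, 0.1), 6, 3)
  fit <- fit_rigid_transform(src, tgt)
  perm <- sample(6)
  fit_p <- fit_rigid_transform(src[perm, ], tgt[perm, ])
  expect_equal(fit_p$transform$rotation, fit$transform$rotation, tolerance = 1e-9)
  expect_equal(fit_p$transform$translation, fit$transform$translation, tolerance = 1e-9)

  expect_error(fit_rigid_transform(src[1:2, ], tgt[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(fit_rigid_transform(line, line), "collinear")
  expect_error(fit_rigid_transform(src[1:4, ], tgt), "equal point counts")
})

test_that("rigid fit never produces a reflection", {
  # near-planar configurations are where an unguarded SVD flips
  set.seed(9)
  for (i in 1:20) {
    src <- cbind(runif(5, -10, 10), runif(5, -10, 10), rnorm(5, 0, 1e-4))
    tgt <- transform_points(random_rigid(), src) + matrix(rnorm(15, 0, 0.5), 5, 3)
    fit <- fit_rigid_transform(src, tgt)
    expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
  }
})

test_that("transform composition and inversion are exact", {
  set.seed(13)
  for (i in 1:20) {
    T1 <- random_rigid()
    p <- runif(3, -50, 50)
    back <- transform_points(invert_transform(T1),
                             transform_points(T1, p, drop = TRUE), drop = TRUE)
    expect_equal(back, p, tolerance = 1e-9)
    T2 <- random_rigid()
    via_compose <- transform_points(compose_transforms(T2, T1), p, drop = TRUE)
    stepwise <- transform_points(T2, transform_points(T1, p, drop = TRUE), drop = TRUE)
    expect_equal(via_compose, stepwise, tolerance = 1e-9)
  }
})

test_that("Monte-Carlo FRE agrees with the closed-form expectation", {
  set.seed(21)
  N <- 6
  sigma <- 0.05
  fid <- matrix(runif(N * 3, 0, 40), N, 3)
  fres <- replicate(200, {
    fit_rigid_transform(fid, fid + matrix(rnorm(N * 3, 0, sigma), N, 3))$fre
  })
  expected <- sigma * sqrt(3 * (1 - 2 / N))
  expect_lt(abs(mean(fres) - expected) / expected, 0.2)
})
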