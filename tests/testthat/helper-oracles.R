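# Independent oracles and small generators shared across tests.

# Brute-force segment-segment minimum distance by dense parameter sampling:
# a coarse grid over both parameters, then two rounds of dense re-sampling
# in a shrinking window around the incumbent minimizer. Purely sampling
# based; shares no code with the closed-form implementation.
oracle_segment_distance <- function(p1, q1, p2, q2,
                                    n_coarse = 60L, n_fine = 200L) {
  d1 <- q1 - p1
  d2 <- q2 - p2
  pair_min <- function(t1, t2) {
    P1 <- matrix(p1, length(t1), 3L, byrow = TRUE) + t1 %*% matrix(d1, 1L, 3L)
    P2 <- matrix(p2, length(t2), 3L, byrow = TRUE) + t2 %*% matrix(d2, 1L, 3L)
    sq <- outer(rowSums(P1^2), rowSums(P2^2), "+") - 2 * P1 %*% t(P2)
    k <- arrayInd(which.min(sq), dim(sq))
    list(d = sqrt(max(0, sq[k])), i = k[1L], j = k[2L])
  }
  t1 <- seq(0, 1, length.out = n_coarse)
  t2 <- seq(0, 1, length.out = n_coarse)
  res <- pair_min(t1, t2)
  w1 <- 1 / (n_coarse - 1)
  for (r in 1:2) {
    c1 <- t1[res$i]; c2 <- t2[res$j]
    t1 <- seq(max(0, c1 - w1), min(1, c1 + w1), length.out = n_fine)
    t2 <- seq(max(0, c2 - w1), min(1, c2 + w1), length.out = n_fine)
    res <- pair_min(t1, t2)
    w1 <- 2 * w1 / (n_fine - 1)
  }
  res$d
}

# Random segment inside a cube of the given half-width, endpoints distinct.
random_segment <- function(halfwidth = 5) {
  repeat {
    a <- stats::runif(3, -halfwidth, halfwidth)
    b <- stats::runif(3, -halfwidth, halfwidth)
    if (sqrt(sum((a - b)^2)) > 0.1) return(segment3(a, b))
  }
}

# Random rigid transform with rotation drawn uniformly via QR of a Gaussian
# matrix (sign-fixed to a proper rotation) and bounded translation.
random_rigid <- function(max_translation = 10) {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  rigid_transform(Q, stats::runif(3, -max_translation, max_translation))
}

# Angle (deg) and translation norm (mm) separating two rigid transforms.
transform_discrepancy <- function(t1, t2) {
  delta <- compose_transforms(t1, invert_transform(t2))
  list(angle = rotation_angle_deg(delta),
       translation = sqrt(sum(delta$translation^2)))
}

expect_gate_status <- function(result, gate_pattern, status) {
  g <- result$gates[grepl(gate_pattern, result$gates$gate), ]
  expect_equal(nrow(g), 1L)
  expect_identical(g$status, status)
}
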