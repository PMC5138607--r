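test_that("cone projection solves the constrained least-squares problem", {
  # interior point: projection is the identity
  B <- matrix(c(1, 0, 1, 1, 0, 1), 3, 2)
  v <- as.numeric(B %*% c(1, 1))
  pr <- project_onto_cone(v, B)
  expect_equal(pr$p, v, tolerance = 1e-10)
  expect_equal(pr$angle_deg, 0, tolerance = 1e-6)

  # orthant projection clamps the negative coordinate
  pr <- project_onto_cone(c(-1, 2), diag(2))
  expect_equal(pr$p, c(0, 2), tolerance = 1e-12)
  expect_equal(pr$angle_deg, acos(2 / sqrt(5)) * 180 / pi, tolerance = 1e-9)

  # fully outside the dual cone: image collapses to the origin
  pr <- project_onto_cone(c(-1, -1), diag(2))
  expect_equal(pr$p, c(0, 0))
  expect_identical(pr$angle_deg, 180)

  # empty generator set degenerates to the origin
  pr <- project_onto_cone(c(1, 2), matrix(numeric(0), 2, 0))
  expect_identical(pr$angle_deg, 180)

  expect_true(all(project_onto_cone(c(-1, 2), diag(2))$alpha >= 0))
})

test_that("projection optimality beats random non-negative coefficient probes", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      M <- sample(2:4, 1)
      Q <- sample(2:6, 1)
      B <- matrix(abs(rnorm(M * Q)), M, Q)
      v <- rnorm(M)
      if (all(v == 0)) v[1] <- 1
      pr <- project_onto_cone(v, B)
      res <- sqrt(sum((v - pr$p)^2))
      probes <- matrix(rexp(2000 * Q), Q, 2000)
      vals <- sqrt(colSums((v - B %*% probes)^2))
      expect_true(all(res <= vals + 1e-9))
    }
  })
})

test_that("lateral edge detection removes exactly the conic combinations", {
  # orthant plus an interior ray
  R <- cbind(diag(3), c(1, 1, 1) / sqrt(3))
  ed <- detect_lateral_edges(R)
  expect_equal(ed$edge_idx, 1:3)
  expect_equal(ed$J_star, 3L)

  # a 2-D fan: only the angular extremes are edges
  R <- rays_2d(c(10, 40, 80))
  expect_equal(detect_lateral_edges(R)$edge_idx, c(1L, 3L))

  # single ray is trivially an edge
  expect_equal(detect_lateral_edges(matrix(c(1, 0), 2, 1))$edge_idx, 1L)
})

test_that("sequential detection matches the brute-force edge oracle", {
  withr::with_seed(11, {
    n_done <- 0
    while (n_done < 60) {
      M <- sample(2:4, 1)
      J <- sample(3:8, 1)
      R <- vapply(seq_len(J), function(i) rand_orthant_dir(M),
                  numeric(M))
      # skip near-degenerate instances (the oracle equivalence is only
      # claimed away from ties)
      angs <- outer(seq_len(J), seq_len(J),
                    Vectorize(function(i, j) {
                      if (i >= j) 90 else angle_deg(R[, i], R[, j])
                    }))
      if (min(angs[upper.tri(angs)]) < 1) next
      n_done <- n_done + 1
      expect_equal(detect_lateral_edges(R)$edge_idx, brute_force_edges(R))
    }
  })
})

test_that("edge sets are invariant to the scan order of well-separated rays", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      repeat {
        R <- vapply(1:6, function(i) rand_orthant_dir(3), numeric(3))
        angs <- combn(6, 2, function(ij) angle_deg(R[, ij[1]], R[, ij[2]]))
        if (min(angs) > 5) break
      }
      base <- sort(detect_lateral_edges(R)$edge_idx)
      perm <- sample(6)
      shuffled <- detect_lateral_edges(R[, perm])$edge_idx
      expect_equal(sort(perm[shuffled]), base)
    }
  })
})
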