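test_that("point-to-ray distance handles both projection regimes", {
  # point on its own ray
  expect_equal(point_ray_distance(c(3, 4), c(3, 4) / 5), 0)
  # orthogonal point: nearest ray point is the origin
  expect_equal(point_ray_distance(c(1, 0), c(0, 1)), 1)
  # perpendicular foot inside the ray
  expect_equal(point_ray_distance(c(1, 1), c(1, 0)), 1)
  # negative inner product: distance is the point norm
  expect_equal(point_ray_distance(c(-2, 0), c(1, 0)), 2)
})

test_that("central ray is the principal axis of the sector autocorrelation", {
  # single point
  expect_equal(central_ray(matrix(c(3, 4), 2, 1)), c(0.6, 0.8))
  # diagonal autocorrelation: dominant coordinate wins
  expect_equal(central_ray(cbind(c(2, 0), c(0, 1))), c(1, 0))
  # closed-form 2x2 case: C = [[2,1],[1,1]], eigenvector (1, (sqrt(5)-1)/2)
  r <- central_ray(cbind(c(1, 1), c(1, 0)))
  phi <- (sqrt(5) - 1) / 2
  expect_equal(r, c(1, phi) / sqrt(1 + phi^2), tolerance = 1e-12)
  expect_error(central_ray(matrix(0, 2, 3)), "zero")
})

test_that("central ray maximizes the quadratic form over random unit probes", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      P <- matrix(rnorm(3 * 8), 3, 8)
      r <- central_ray(P)
      qf <- function(u) sum(crossprod(P, u)^2)
      probes <- matrix(rnorm(3 * 2000), 3, 2000)
      probes <- sweep(probes, 2, sqrt(colSums(probes^2)), "/")
      expect_true(all(qf(r) >= apply(probes, 2, qf) - 1e-9))
    }
  })
})

test_that("sector clustering converges with non-increasing distortion", {
  withr::with_seed(21, {
    X <- vapply(1:80, function(i) rand_orthant_dir(3) * runif(1, 0.5, 2),
                numeric(3))
    part <- cluster_sectors(X, J = 6, n_restarts = 5, seed = 99)
    expect_s3_class(part, "cam_sectors")
    expect_equal(sum(part$counts), 80)
    expect_equal(sqrt(colSums(part$R^2)), rep(1, 6), tolerance = 1e-9)
    expect_true(all(diff(part$distortion_trace) <= 1e-12))
    expect_gte(part$distortion, 0)
    # reported distortion is reproducible from the partition itself
    expect_equal(
      clustering_distortion(X, part$R, part$assignment),
      part$distortion, tolerance = 1e-9
    )
    # determinism under a fixed seed
    part2 <- cluster_sectors(X, J = 6, n_restarts = 5, seed = 99)
    expect_identical(part$assignment, part2$assignment)
    expect_equal(part$R, part2$R)
  })
})

test_that("one sector per point reaches zero distortion", {
  withr::with_seed(3, {
    X <- vapply(1:8, function(i) rand_orthant_dir(3), numeric(3))
    part <- cluster_sectors(X, J = 8, n_restarts = 3, seed = 1)
    expect_lt(part$distortion, 1e-12)
  })
})

test_that("two well-separated bundles are recovered as two sectors", {
  withr::with_seed(17, {
    # tight bundles around orthogonal directions
    b1 <- replicate(5, c(1, 0, 0) + abs(rnorm(3, sd = 0.01)))
    b2 <- replicate(5, c(0, 0, 1) + abs(rnorm(3, sd = 0.01)))
    X <- cbind(b1, b2)
    part <- cluster_sectors(X, J = 2, n_restarts = 10, seed = 5)
    g <- part$assignment
    expect_true(all(g[1:5] == g[1]) && all(g[6:10] == g[6]) && g[1] != g[6])
    # distortion equals the exhaustive-minimum assignment over 2^N splits
    best <- Inf
    for (mask in 0:(2^10 - 1)) {
      grp <- as.logical(bitwAnd(mask, 2^(0:9)))
      if (!any(grp) || all(grp)) next
      d <- 0
      for (side in c(TRUE, FALSE)) {
        P <- X[, grp == side, drop = FALSE]
        r <- central_ray(P)
        d <- d + sum(apply(P, 2, point_ray_distance, r = r)^2)
      }
      best <- min(best, d)
    }
    expect_equal(part$distortion, best, tolerance = 1e-9)
  })
})
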