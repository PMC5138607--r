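#' Distance between a data point and a ray
#'
#' The distance from a point to a ray from the origin is the minimum distance
#' to any point on the ray. When the point projects onto the positive half of
#' the ray (`x' r >= 0`) this is the orthogonal distance
#' `sqrt(|x|^2 - (x'r)^2)`; otherwise the closest ray point is the origin and
#' the distance is `|x|`.
#'
#' @param x Numeric data vector.
#' @param r Unit-norm direction vector of the ray.
#' @return Non-negative scalar distance.
#' @export
point_ray_distance <- function(x, r) {
  x <- as.numeric(x)
  r <- as.numeric(r)
  xr <- sum(x * r)
  if (xr >= 0) {
    sqrt(max(0, sum(x^2) - xr^2))
  } else {
    sqrt(sum(x^2))
  }
}

#' Central ray of a set of points
#'
#' The sector central ray minimizes the summed squared point-to-ray distances
#' over all unit rays; it is the principal eigenvector of the sector
#' autocorrelation matrix `C = sum_x x x'`. The eigenvector sign is chosen so
#' the ray points into the data (`sum_x x'r >= 0`).
#'
#' @param points Numeric matrix with points as columns (M x n), at least one
#'   of them non-zero.
#' @return Unit-norm numeric vector of length M.
#' @export
central_ray <- function(points) {
  P <- as.matrix(points)
  if (all(P == 0)) stop("central_ray(): all points are zero")
  C <- tcrossprod(P)
  r <- eigen(C, symmetric = TRUE)$vectors[, 1]
  if (sum(crossprod(P, r)) < 0) r <- -r
  r
}

#' Total sector clustering distortion
#'
#' Sum over sectors of the squared point-to-ray distances between the member
#' points and their sector central ray.
#'
#' @param X Data matrix (M x N, samples as columns).
#' @param R Matrix of unit central rays (M x J).
#' @param assignment Integer vector of length N mapping each sample to a
#'   sector in `1..J`.
#' @return Non-negative scalar.
#' @export
clustering_distortion <- function(X, R, assignment) {
  X <- as.matrix(X)
  R <- as.matrix(R)
  N <- ncol(X)
  if (length(assignment) != N) {
    stop("clustering_distortion(): 'assignment' must have one entry per sample")
  }
  P <- pmax(crossprod(X, R), 0)
  d2 <- colSums(X^2) - P[cbind(seq_len(N), assignment)]^2
  sum(pmax(d2, 0))
}

# One Lloyd-style run from a given initialization. Alternates (i) assignment
# of each point to the nearest ray and (ii) ray update as the principal
# eigenvector of each sector's autocorrelation matrix, until the distortion
# is exactly unchanged (finite termination) or max_iter is hit. Empty sectors
# are re-seeded to the point with the largest current distance contribution,
# which cannot increase the distortion.
lloyd_sectors <- function(X, J, init_idx, max_iter = 500) {
  N <- ncol(X)
  norm2 <- colSums(X^2)
  R <- X[, init_idx, drop = FALSE]
  cn <- sqrt(colSums(R^2))
  cn[cn == 0] <- 1
  R <- sweep(R, 2, cn, "/")
  prev <- Inf
  trace <- numeric(0)
  assignment <- rep(1L, N)
  for (it in seq_len(max_iter)) {
    P <- pmax(crossprod(X, R), 0)
    assignment <- max.col(P, ties.method = "first")
    # empty-sector repair: re-seed to the worst-fit point, then re-partition
    for (rep_round in seq_len(J)) {
      empty <- which(tabulate(assignment, J) == 0L)
      if (!length(empty)) break
      d2 <- pmax(norm2 - P[cbind(seq_len(N), assignment)]^2, 0)
      for (j in empty) {
        idx <- which.max(d2)
        if (norm2[idx] > 0) R[, j] <- X[, idx] / sqrt(norm2[idx])
        d2[idx] <- -Inf
      }
      P <- pmax(crossprod(X, R), 0)
      assignment <- max.col(P, ties.method = "first")
    }
    for (j in seq_len(J)) {
      members <- X[, assignment == j, drop = FALSE]
      if (any(colSums(members^2) > 0)) R[, j] <- central_ray(members)
    }
    P2 <- pmax(crossprod(X, R), 0)
    cur <- sum(pmax(norm2 - P2[cbind(seq_len(N), assignment)]^2, 0))
    trace <- c(trace, cur)
    if (cur == prev) break
    prev <- cur
  }
  list(
    R = R, assignment = assignment, counts = tabulate(assignment, J),
    distortion = trace[length(trace)], n_iter = length(trace),
    distortion_trace = trace
  )
}

#' Sector-based clustering of mixture samples
#'
#' Groups the sample columns of `X` into `J` sectors, each represented by a
#' unit central ray, by a Lloyd-style alternation of nearest-ray assignment
#' and principal-eigenvector ray updates. Central rays are initialized at
#' randomly chosen data points; the algorithm is restarted `n_restarts` times
#' and the partition with minimum total distortion is returned. Assignment
#' ties go to the lowest sector index, which together with a fixed seed makes
#' the result deterministic.
#'
#' @param X Data matrix (M x N, samples as columns) with at least `J`
#'   columns.
#' @param J Number of sectors (default 30).
#' @param n_restarts Number of independent random initializations
#'   (default 20).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param max_iter Iteration cap per restart; the usual stop is exact
#'   equality of successive distortions.
#' @return An object of class `cam_sectors`: list with `R` (M x J unit rays),
#'   `assignment`, `counts`, `distortion`, `n_iter` and `distortion_trace`
#'   (per-iteration distortions of the winning restart).
#' @export
cluster_sectors <- function(X, J = 30, n_restarts = 20, seed = NULL,
                            max_iter = 500) {
  X <- as.matrix(X)
  N <- ncol(X)
  if (J < 1) stop("cluster_sectors(): 'J' must be at least 1")
  if (J > N) {
    stop("cluster_sectors(): 'J' exceeds the number of samples (", N, ")")
  }
  run <- function() {
    best <- NULL
    for (rs in seq_len(n_restarts)) {
      init <- sample.int(N, J)
      res <- lloyd_sectors(X, J, init, max_iter)
      if (is.null(best) || res$distortion < best$distortion) best <- res
    }
    best
  }
  best <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(best) <- "cam_sectors"
  best
}

#' @export
print.cam_sectors <- function(x, ...) {
  cat("Sector-based clustering: J =", ncol(x$R), "sectors,",
      sum(x$counts), "samples\n")
  cat("  distortion:", format(x$distortion), "after", x$n_iter,
      "iterations\n")
  invisible(x)
}
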