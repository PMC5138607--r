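# Shared fixtures and independent oracles, all built in code.

# random unit direction in the non-negative orthant
rand_orthant_dir <- function(M) {
  v <- abs(rnorm(M))
  v / sqrt(sum(v^2))
}

# matrix of 2-D unit rays at the given angles (degrees) from e1
rays_2d <- function(angles_deg) {
  a <- angles_deg * pi / 180
  rbind(cos(a), sin(a))
}

# Independent edge oracle: column j is an edge iff the NNLS projection of
# r_j onto the cone of ALL other columns leaves a positive angle. No
# sequential removal, computed directly from the definition.
brute_force_edges <- function(R, tol_deg = 0.001) {
  J <- ncol(R)
  which(vapply(seq_len(J), function(j) {
    a <- pracma::lsqnonneg(R[, -j, drop = FALSE], R[, j])$x
    p <- R[, -j, drop = FALSE] %*% a
    if (sqrt(sum(p^2)) < 1e-12) return(TRUE)
    ang <- acos(min(1, max(-1, sum(R[, j] * p) /
                             sqrt(sum(R[, j]^2) * sum(p^2))))) * 180 / pi
    ang > tol_deg
  }, logical(1)))
}

# Exhaustive permutation oracle for the minimum average column angle
brute_force_min_avg_angle <- function(U, W) {
  K <- ncol(U)
  perms <- permutations_of(K)
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    ang <- mean(vapply(seq_len(K), function(k) angle_deg(U[, k], W[, p[k]]),
                       numeric(1)))
    if (ang < best) best <- ang
  }
  best
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  out
}

# Ground-truth system with exact well-grounded points: per source,
# `n_wgp` columns proportional to a basis vector (varied scales), the rest
# random non-negative interior columns.
make_wgp_system <- function(M, K, n_wgp = 6, n_interior = 24, seed = 1,
                            noise_snr_db = Inf) {
  withr::with_seed(seed, {
    A <- make_simplicial_mixing(M, K, seed = NULL)
    S_wgp <- matrix(0, K, K * n_wgp)
    for (k in seq_len(K)) {
      cols <- (k - 1) * n_wgp + seq_len(n_wgp)
      S_wgp[k, cols] <- seq(0.5, 2.5, length.out = n_wgp)
    }
    S_int <- matrix(runif(K * n_interior, 0.2, 1), K, n_interior)
    S <- cbind(S_wgp, S_int)
    X <- A %*% S
    if (is.finite(noise_snr_db)) {
      X <- add_noise_at_snr(X, noise_snr_db, seed = NULL)$X
    }
    list(A = A, S = S, X = X)
  })
}
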