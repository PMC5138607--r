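#' Configuration for the synthetic mixture simulator
#'
#' Describes a ground-truthed simulation in which K non-negative sources are
#' mixed into M observed signals and corrupted with Gaussian noise at a
#' prescribed SNR. Half of the sample columns (by default) are drawn from
#' independent exponential distributions, whose heavy mass near the origin
#' guarantees near well-grounded points on every source axis; the remaining
#' columns are absolute values of correlated Gaussians, which makes the
#' sources mutually correlated, as real expression or imaging sources tend to
#' be.
#'
#' @param M Number of mixtures (rows of X), at least 2.
#' @param K Number of sources, at least 2.
#' @param N Number of sample columns.
#' @param exp_fraction Fraction of samples drawn from the exponential block,
#'   in (0, 1].
#' @param exp_rates Positive exponential rates, one per source.
#' @param gauss_mean Non-negative mean vector of the Gaussian block, length K.
#' @param gauss_cov Symmetric positive-definite K x K covariance of the
#'   Gaussian block; the default has unit variances and 0.5 off-diagonal
#'   correlation.
#' @param snr_db Target signal-to-noise ratio in decibels
#'   (`10 log10(|AS|_F^2 / |E|_F^2)`); may be `Inf` for noise-free data.
#' @param seed Integer RNG seed; the simulation is fully determined by it.
#' @param min_pairwise_angle_deg Minimum pairwise angle between mixing-matrix
#'   columns, enforced by [make_simplicial_mixing()].
#' @param mixing_spread Off-axis perturbation weight of the mixing-matrix
#'   construction (see [make_simplicial_mixing()]).
#' @param noise_cov Optional M x M noise covariance; defaults to isotropic
#'   (iid) noise.
#' @return An object of class `cam_sim_config`.
#' @export
cam_sim_config <- function(M = 3, K = 3, N = 1600, exp_fraction = 0.5,
                           exp_rates = rep(1, K), gauss_mean = rep(1, K),
                           gauss_cov = NULL, snr_db = 12.4, seed = 1,
                           min_pairwise_angle_deg = 30, mixing_spread = 0.25,
                           noise_cov = NULL) {
  if (M < 2 || K < 2) stop("cam_sim_config(): need M >= 2 and K >= 2")
  if (N < 2) stop("cam_sim_config(): need N >= 2")
  if (!(exp_fraction > 0 && exp_fraction <= 1)) {
    stop("cam_sim_config(): 'exp_fraction' must be in (0, 1]")
  }
  if (length(exp_rates) != K || any(exp_rates <= 0)) {
    stop("cam_sim_config(): 'exp_rates' must be K positive rates")
  }
  if (length(gauss_mean) != K || any(gauss_mean < 0)) {
    stop("cam_sim_config(): 'gauss_mean' must be a non-negative K-vector")
  }
  if (is.null(gauss_cov)) {
    gauss_cov <- matrix(0.5, K, K)
    diag(gauss_cov) <- 1
  }
  gauss_cov <- as.matrix(gauss_cov)
  if (!all(dim(gauss_cov) == c(K, K)) ||
      max(abs(gauss_cov - t(gauss_cov))) > 1e-12) {
    stop("cam_sim_config(): 'gauss_cov' must be a symmetric K x K matrix")
  }
  ok <- tryCatch({chol(gauss_cov); TRUE}, error = function(e) FALSE)
  if (!ok) stop("cam_sim_config(): 'gauss_cov' must be positive definite")
  if (is.na(snr_db) || (is.infinite(snr_db) && snr_db < 0)) {
    stop("cam_sim_config(): 'snr_db' must be finite or +Inf")
  }
  if (!is.null(noise_cov)) {
    noise_cov <- as.matrix(noise_cov)
    if (!all(dim(noise_cov) == c(M, M))) {
      stop("cam_sim_config(): 'noise_cov' must be M x M")
    }
  }
  structure(
    list(M = M, K = K, N = N, exp_fraction = exp_fraction,
         exp_rates = exp_rates, gauss_mean = gauss_mean,
         gauss_cov = gauss_cov, snr_db = snr_db, seed = seed,
         min_pairwise_angle_deg = min_pairwise_angle_deg,
         mixing_spread = mixing_spread, noise_cov = noise_cov),
    class = "cam_sim_config"
  )
}

#' Sample a simplicial, unit-row-sum mixing matrix
#'
#' Draws K non-negative columns in M dimensions, rescales the rows to unit
#' sums (so the entries read as mixing proportions), and accepts the draw
#' only when every pairwise column angle is at least
#' `min_pairwise_angle_deg`, every column is simplicial per
#' [check_simplicial()] (no column is a non-negative or non-positive
#' combination of the others), and, when `M >= K`, the matrix has full
#' column rank.
#'
#' In the exact- and over-determined cases (`K <= M`) each column is a
#' perturbation of a distinct coordinate axis: column k is
#' `(1 - spread) e_k + spread d_k` with `d_k` a random direction in the unit
#' simplex. This yields the diagonally dominant, well-separated mixing
#' geometry typical of compartment- and cell-type-mixing studies, where each
#' mixture channel is driven mainly by one source; `spread` controls how far
#' the columns move off the axes (0 gives the identity pattern, 1 a fully
#' random column-stochastic matrix). In the under-determined case (`K > M`)
#' columns are rejection-sampled random orthant directions, since no axis
#' anchoring is possible; geometric infeasibility (e.g. more than two
#' cone-extreme columns in two dimensions) then surfaces as an error after
#' `max_attempts` rejections.
#'
#' @param M,K Matrix dimensions.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param min_pairwise_angle_deg Minimum angular separation of columns, in
#'   degrees (a validity constraint, enforced by rejection).
#' @param spread Off-axis perturbation weight in `[0, 1)` for the `K <= M`
#'   construction (default 0.25).
#' @param max_attempts Number of rejection-sampling attempts before giving
#'   up.
#' @return An M x K non-negative matrix with unit row sums.
#' @export
make_simplicial_mixing <- function(M, K, seed = NULL,
                                   min_pairwise_angle_deg = 30,
                                   spread = 0.25, max_attempts = 1000) {
  if (M < 2 || K < 2) stop("make_simplicial_mixing(): need M >= 2 and K >= 2")
  if (spread < 0 || spread >= 1) {
    stop("make_simplicial_mixing(): 'spread' must be in [0, 1)")
  }
  draw <- function() {
    for (att in seq_len(max_attempts)) {
      if (K <= M) {
        D <- matrix(stats::runif(M * K), M, K)
        D <- sweep(D, 2, colSums(D), "/")
        A0 <- (1 - spread) * diag(M)[, seq_len(K), drop = FALSE] + spread * D
      } else {
        A0 <- matrix(abs(stats::rnorm(M * K)), M, K)
      }
      A0 <- sweep(A0, 2, sqrt(colSums(A0^2)), "/")
      rs <- rowSums(A0)
      if (any(rs <= 0)) next
      A <- A0 / rs
      ok <- TRUE
      for (i in seq_len(K - 1)) {
        for (j in (i + 1):K) {
          if (angle_deg(A[, i], A[, j]) < min_pairwise_angle_deg) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (!ok) next
      if (M >= K && qr(A)$rank < K) next
      if (!all(check_simplicial(A))) next
      return(A)
    }
    stop("make_simplicial_mixing(): no simplicial matrix with pairwise ",
         "column angle >= ", min_pairwise_angle_deg, " deg found in ",
         max_attempts, " attempts (M = ", M, ", K = ", K, ")")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Draw the ground-truth source matrix
#'
#' The first `ceiling(exp_fraction * N)` sample columns are drawn with
#' independent exponential coordinates (rate `exp_rates[k]` for source k);
#' the remaining columns are absolute values of draws from the correlated
#' Gaussian `N(gauss_mean, gauss_cov)`. All entries are non-negative.
#'
#' @param cfg A [cam_sim_config()] object.
#' @param seed Optional seed overriding `cfg$seed`; `NULL` uses the current
#'   RNG stream.
#' @return A K x N non-negative matrix.
#' @export
draw_sources <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "cam_sim_config"))
  draw <- function() {
    n_exp <- ceiling(cfg$exp_fraction * cfg$N)
    S_exp <- matrix(
      stats::rexp(cfg$K * n_exp, rate = rep(cfg$exp_rates, n_exp)),
      cfg$K, n_exp
    )
    n_g <- cfg$N - n_exp
    if (n_g > 0) {
      G <- MASS::mvrnorm(n_g, mu = cfg$gauss_mean, Sigma = cfg$gauss_cov)
      S_g <- t(abs(matrix(G, nrow = n_g)))
      cbind(S_exp, S_g)
    } else {
      S_exp
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Add Gaussian noise at an exact SNR
#'
#' Draws Gaussian noise (isotropic by default, or with covariance
#' `noise_cov`) and rescales it after drawing so that the realized
#' whole-dataset SNR, `10 log10(|signal|_F^2 / |E|_F^2)`, equals `snr_db`
#' exactly. With `snr_db = Inf` the noise is identically zero.
#'
#' @param signal Finite numeric M x N matrix (the noise-free mixtures A S).
#' @param snr_db Target SNR in decibels.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param noise_cov Optional M x M noise covariance.
#' @return A list with `X = signal + E` and the noise matrix `E`.
#' @export
add_noise_at_snr <- function(signal, snr_db, seed = NULL, noise_cov = NULL) {
  signal <- as.matrix(signal)
  if (!all(is.finite(signal))) {
    stop("add_noise_at_snr(): 'signal' must be finite")
  }
  if (is.infinite(snr_db)) {
    E <- matrix(0, nrow(signal), ncol(signal))
    return(list(X = signal, E = E))
  }
  M <- nrow(signal)
  N <- ncol(signal)
  draw <- function() {
    if (is.null(noise_cov)) {
      matrix(stats::rnorm(M * N), M, N)
    } else {
      t(matrix(MASS::mvrnorm(N, mu = rep(0, M), Sigma = noise_cov), nrow = N))
    }
  }
  E0 <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  scale <- sqrt(sum(signal^2) / (10^(snr_db / 10) * sum(E0^2)))
  E <- scale * E0
  list(X = signal + E, E = E)
}

#' Realized whole-dataset SNR in decibels
#'
#' @param signal Noise-free signal matrix.
#' @param E Noise matrix of the same dimension.
#' @return `10 log10(|signal|_F^2 / |E|_F^2)`; `Inf` when `E` is zero.
#' @export
compute_snr_db <- function(signal, E) {
  10 * log10(sum(signal^2) / sum(E^2))
}

#' Simulate a ground-truthed noisy mixture dataset
#'
#' Composes [make_simplicial_mixing()], [draw_sources()] and
#' [add_noise_at_snr()] under the single seed in `cfg`, so two calls with the
#' same configuration return identical data.
#'
#' @param cfg A [cam_sim_config()] object.
#' @return An object of class `cam_sim`: list with `A_true` (M x K, unit row
#'   sums), `S_true` (K x N, non-negative), `E`, `X = A_true S_true + E`, and
#'   `config`. `X` is not clipped: noise may push entries slightly negative,
#'   and downstream preprocessing and cone projection tolerate that.
#' @export
cam_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "cam_sim_config"))
  withr::with_seed(cfg$seed, {
    A <- make_simplicial_mixing(
      cfg$M, cfg$K, seed = NULL,
      min_pairwise_angle_deg = cfg$min_pairwise_angle_deg,
      spread = cfg$mixing_spread
    )
    S <- draw_sources(cfg, seed = NULL)
    noisy <- add_noise_at_snr(A %*% S, cfg$snr_db, seed = NULL,
                              noise_cov = cfg$noise_cov)
    dimnames(noisy$X) <- list(
      paste0("m", seq_len(cfg$M)), paste0("s", seq_len(cfg$N))
    )
    structure(
      list(A_true = A, S_true = S, E = noisy$E, X = noisy$X, config = cfg),
      class = "cam_sim"
    )
  })
}

#' @export
print.cam_sim <- function(x, ...) {
  cfg <- x$config
  snr <- if (is.infinite(cfg$snr_db)) Inf else compute_snr_db(
    x$A_true %*% x$S_true, x$E
  )
  cat("Simulated mixture dataset: M =", cfg$M, "mixtures, K =", cfg$K,
      "sources, N =", cfg$N, "samples\n")
  cat("  realized SNR:", format(snr, digits = 6), "dB; seed:", cfg$seed, "\n")
  invisible(x)
}
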