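#' Angle between two vectors
#'
#' Computes the angle between `v` and `w` in degrees. By convention the angle
#' between a non-zero vector and the zero vector is 180 degrees, so that a
#' point whose cone projection collapses to the origin is treated as maximally
#' far from the cone.
#'
#' @param v,w Numeric vectors of equal length. `v` must be non-zero.
#' @return The angle in degrees, a scalar in \[0, 180\].
#' @examples
#' angle_deg(c(1, 0), c(0, 1)) # 90
#' angle_deg(c(1, 0), c(3, 0)) # 0
#' angle_deg(c(1, 1), c(0, 0)) # 180 by convention
#' @export
angle_deg <- function(v, w) {
  v <- as.numeric(v)
  w <- as.numeric(w)
  if (length(v) != length(w)) {
    stop("angle_deg(): 'v' and 'w' must have the same length")
  }
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("angle_deg(): 'v' must be a non-zero vector")
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(180)
  ct <- sum(v * w) / (nv * nw)
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Minimum average angle between the columns of two matrices
#'
#' The column correspondence between two mixing-matrix estimates is unknown,
#' so the mean per-column angle is minimized over all permutations of the
#' columns of `W`. The minimization is solved as a linear assignment problem
#' on the K x K matrix of pairwise column angles (Hungarian method), which is
#' exact and runs in O(K^3).
#'
#' @param U,W Numeric matrices of identical dimension M x K with non-zero
#'   columns.
#' @return A list with `angle_deg`, the minimal mean column angle in degrees,
#'   and `permutation`, an integer vector p such that column k of `U` is
#'   matched to column `p[k]` of `W`.
#' @examples
#' U <- diag(3)
#' min_average_angle(U, U[, c(2, 3, 1)])$angle_deg # 0
#' @export
min_average_angle <- function(U, W) {
  U <- as.matrix(U)
  W <- as.matrix(W)
  if (!all(dim(U) == dim(W))) {
    stop("min_average_angle(): 'U' and 'W' must have identical dimensions")
  }
  K <- ncol(U)
  cost <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      cost[i, j] <- angle_deg(U[, i], W[, j])
    }
  }
  perm <- as.integer(clue::solve_LSAP(cost))
  list(
    angle_deg = mean(cost[cbind(seq_len(K), perm)]),
    permutation = perm
  )
}
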