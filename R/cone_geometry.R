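#' Project a vector onto a convex cone
#'
#' The convex cone C\{B\} is the set of non-negative linear combinations of
#' the columns of `B`. The projection of `v` onto C\{B\} is the cone member
#' closest to `v` in Euclidean distance. Although the projection can be posed
#' as a second-order cone program, it is solved here as a non-negative least
#' squares problem (Lawson-Hanson active set), which attains the same optimum
#' exactly.
#'
#' @param v Non-zero numeric vector to project.
#' @param B Numeric matrix whose columns generate the cone; may have zero
#'   columns, in which case the cone degenerates to the origin.
#' @param zero_tol Relative norm below which the projection image is treated
#'   as the zero vector, triggering the 180-degree angle convention.
#' @return A list with `p` (the projection image), `alpha` (the non-negative
#'   coefficients, `p = B %*% alpha`), and `angle_deg` (the projection angle,
#'   180 when `p` vanishes).
#' @examples
#' project_onto_cone(c(-1, 2), diag(2))$angle_deg # about 26.57
#' project_onto_cone(c(-1, -1), diag(2))$angle_deg # 180
#' @export
project_onto_cone <- function(v, B, zero_tol = 1e-12) {
  v <- as.numeric(v)
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("project_onto_cone(): 'v' must be a non-zero vector")
  if (is.null(B) || NCOL(B) == 0) {
    return(list(p = rep(0, length(v)), alpha = numeric(0), angle_deg = 180))
  }
  B <- as.matrix(B)
  if (nrow(B) != length(v)) {
    stop("project_onto_cone(): 'v' and columns of 'B' must have the same length")
  }
  alpha <- pracma::lsqnonneg(B, v)$x
  p <- as.numeric(B %*% alpha)
  if (sqrt(sum(p^2)) < zero_tol * nv) {
    list(p = rep(0, length(v)), alpha = alpha, angle_deg = 180)
  } else {
    list(p = p, alpha = alpha, angle_deg = angle_deg(v, p))
  }
}

#' Detect the lateral edges of the cone spanned by a set of rays
#'
#' A generator is a lateral edge of the cone when it cannot be expressed as a
#' non-negative combination of the remaining generators; equivalently, its
#' projection onto the cone of the others makes a strictly positive angle
#' with it. The columns of `R` are scanned sequentially: column j is projected
#' onto the cone of the other currently retained columns; if the projection
#' angle exceeds `tau_deg` the column is kept and the scan advances, otherwise
#' it is removed (the cone is unchanged, since a removed column is a conic
#' combination of the rest) and the test repeats at the current position.
#'
#' `tau_deg` defaults to 0.001 degrees; any sufficiently small positive value
#' yields the same edge set because true edges of a clustered representation
#' deviate from the cone of the remaining rays by far more than the threshold.
#'
#' @param R Numeric matrix whose columns are rays (unit norm recommended)
#'   with pairwise distinct directions.
#' @param tau_deg Positive angular threshold in degrees.
#' @return An object of class `cam_edges`: a list with `edge_idx` (retained
#'   column indices, in original order), `J_star` (their number) and
#'   `tau_deg`.
#' @examples
#' R <- cbind(diag(3), c(1, 1, 1) / sqrt(3))
#' detect_lateral_edges(R)$edge_idx # 1 2 3 (interior ray removed)
#' @export
detect_lateral_edges <- function(R, tau_deg = 0.001) {
  R <- as.matrix(R)
  if (tau_deg <= 0) stop("detect_lateral_edges(): 'tau_deg' must be positive")
  keep <- seq_len(ncol(R))
  j <- 1L
  while (j <= length(keep)) {
    others <- R[, keep[-j], drop = FALSE]
    ang <- project_onto_cone(R[, keep[j]], others)$angle_deg
    if (ang > tau_deg) {
      j <- j + 1L
    } else {
      keep <- keep[-j]
    }
  }
  structure(
    list(edge_idx = keep, J_star = length(keep), tau_deg = tau_deg),
    class = "cam_edges"
  )
}

#' @export
print.cam_edges <- function(x, ...) {
  cat("Lateral edge detection: ", x$J_star, " edge(s) retained (tau = ",
      x$tau_deg, " deg)\n", sep = "")
  cat("  indices:", x$edge_idx, "\n")
  invisible(x)
}
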