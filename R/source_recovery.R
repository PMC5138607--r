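#' Columnwise simplicial test of a mixing matrix
#'
#' A matrix is simplicial when no column is a non-negative or non-positive
#' linear combination of the other columns, the condition under which the
#' columns are exactly the lateral edges of their cone and the mixing matrix
#' is identifiable from edge detection. Column k passes when the non-negative
#' least-squares residuals of both `a_k` and `-a_k` against the remaining
#' columns are positive.
#'
#' @param A Numeric matrix with non-degenerate columns.
#' @param tol Relative residual-norm tolerance.
#' @return Logical vector, one entry per column.
#' @examples
#' check_simplicial(diag(3)) # all TRUE
#' A <- cbind(diag(2), c(1, 1)) # third column = a1 + a2
#' check_simplicial(A) # FALSE in position 3
#' @export
check_simplicial <- function(A, tol = 1e-8) {
  A <- as.matrix(A)
  K <- ncol(A)
  out <- logical(K)
  for (k in seq_len(K)) {
    a <- A[, k]
    na <- sqrt(sum(a^2))
    rest <- A[, -k, drop = FALSE]
    r_pos <- pracma::lsqnonneg(rest, a)$resid.norm
    r_neg <- pracma::lsqnonneg(rest, -a)$resid.norm
    out[k] <- sqrt(r_pos) > tol * na && sqrt(r_neg) > tol * na
  }
  out
}

#' Recover non-negative sources by column-wise NNLS
#'
#' Given the estimated mixing matrix, each sample column is fitted by
#' non-negative least squares: `s_n = argmin_{s >= 0} |x_n - A s|`. This is
#' equivalent to projecting the sample onto the cone of the mixing-matrix
#' columns and applying the generalized inverse, so the projected data
#' `X_proj = A S_hat` is non-negative in source space and noise outside the
#' cone is suppressed. All samples are fitted, including any that were
#' filtered out when estimating the mixing matrix.
#'
#' @param X Scaled mixture matrix (M x N), all samples.
#' @param A_hat Estimated mixing matrix (M x K) with full column rank.
#' @param zero_tol Entries of `S_hat` below this are zeroed for sparsity.
#' @param check_rank Refuse rank-deficient `A_hat` (default). Disabling the
#'   check returns one of the (non-unique) NNLS minimizers, which is only
#'   meaningful when explicitly forcing recovery in the under-determined
#'   case.
#' @return A list with `S_hat` (K x N, non-negative) and
#'   `X_proj = A_hat %*% S_hat`.
#' @export
recover_sources <- function(X, A_hat, zero_tol = 1e-12, check_rank = TRUE) {
  X <- as.matrix(X)
  A_hat <- as.matrix(A_hat)
  K <- ncol(A_hat)
  if (nrow(A_hat) != nrow(X)) {
    stop("recover_sources(): 'X' and 'A_hat' must have the same number of rows")
  }
  if (check_rank && qr(A_hat)$rank < K) {
    stop("recover_sources(): 'A_hat' is rank-deficient; without a full ",
         "column rank mixing matrix the sources are not recoverable")
  }
  N <- ncol(X)
  S <- matrix(0, K, N)
  for (n in seq_len(N)) {
    S[, n] <- pracma::lsqnonneg(A_hat, X[, n])$x
  }
  S[S < zero_tol] <- 0
  list(S_hat = S, X_proj = A_hat %*% S)
}

# Rescale the columns of a ray-direction mixing matrix so that its rows sum
# to one (the proportion convention of row-scaled data), and rescale the
# recovered sources compatibly so A %*% S is unchanged. The column scales
# solve A c = 1 (exactly in the exact-determined full-rank case, least
# squares otherwise); non-positive scales, which can only arise in badly
# misestimated fits, are left at one with a warning.
unit_row_sum_rescale <- function(A_ray, S_ray = NULL) {
  M <- nrow(A_ray)
  K <- ncol(A_ray)
  ones <- rep(1, M)
  cvec <- if (M == K) {
    tryCatch(as.numeric(solve(A_ray, ones)), error = function(e) NULL)
  } else {
    as.numeric(qr.coef(qr(A_ray), ones))
  }
  if (is.null(cvec) || anyNA(cvec) || any(cvec <= 0)) {
    cvec <- pracma::lsqnonneg(A_ray, ones)$x
  }
  bad <- cvec <= 1e-12
  if (any(bad)) {
    warning("unit row-sum rescaling failed for ", sum(bad),
            " column(s); leaving their scale at 1")
    cvec[bad] <- 1
  }
  A <- A_ray * rep(cvec, each = M)
  out <- list(A_hat = A, scales = cvec)
  if (!is.null(S_ray)) out$S_hat <- S_ray / cvec
  out
}
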