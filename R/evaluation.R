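#' Mixing-matrix recovery accuracy
#'
#' One minus the permutation-matched mean column angle between the estimated
#' and true mixing matrices, normalized by 90 degrees and clipped to
#' `[0, 1]`. The measure is 1 for a perfect estimate and is invariant to
#' column permutation and positive column rescaling of either argument --
#' exactly the ambiguities left open by edge-detection identifiability.
#'
#' @param A_hat,A_true Matrices of identical dimension M x K.
#' @return A list with `accuracy`, `mean_angle_deg` and `permutation` (the
#'   matching of `A_hat` columns to `A_true` columns).
#' @export
mixing_recovery_accuracy <- function(A_hat, A_true) {
  maa <- min_average_angle(A_hat, A_true)
  list(
    accuracy = min(1, max(0, 1 - maa$angle_deg / 90)),
    mean_angle_deg = maa$angle_deg,
    permutation = maa$permutation
  )
}

#' Source recovery accuracy
#'
#' Mean Pearson correlation between each recovered source and its matched
#' true source, with negative correlations clipped to zero so the score
#' stays in `[0, 1]`. The match must be the permutation produced by
#' [mixing_recovery_accuracy()], so both scores refer to the same source
#' labelling.
#'
#' @param S_hat Recovered sources (K x N).
#' @param S_true True sources (K x N).
#' @param permutation Integer vector mapping row k of `S_hat` to row
#'   `permutation[k]` of `S_true`.
#' @return Scalar in `[0, 1]`.
#' @export
source_recovery_accuracy <- function(S_hat, S_true, permutation) {
  S_hat <- as.matrix(S_hat)
  S_true <- as.matrix(S_true)
  K <- nrow(S_hat)
  if (length(permutation) != K) {
    stop("source_recovery_accuracy(): 'permutation' must have one entry per source")
  }
  cors <- numeric(K)
  for (k in seq_len(K)) {
    a <- S_hat[k, ]
    b <- S_true[permutation[k], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop("source_recovery_accuracy(): source ", k,
           " has zero variance; correlation undefined")
    }
    cors[k] <- max(0, stats::cor(a, b))
  }
  mean(cors)
}

#' Per-sample source dominance
#'
#' The dominance of source k in sample n is its share of the sample's total
#' source loading, `s_kn / sum_k' s_k'n`. Valid columns sum to one; an
#' all-zero column has undefined dominance and is returned as `NA` with a
#' warning.
#'
#' @param S Non-negative source matrix (K x N).
#' @return K x N matrix of dominance values.
#' @export
source_dominance <- function(S) {
  S <- as.matrix(S)
  if (any(S < 0)) stop("source_dominance(): 'S' must be non-negative")
  cs <- colSums(S)
  zero <- cs == 0
  if (any(zero)) {
    warning("source_dominance(): ", sum(zero),
            " all-zero column(s) have undefined dominance (returned as NA)")
    cs[zero] <- NA_real_
  }
  sweep(S, 2, cs, "/")
}

#' Rank samples by dominance of one source
#'
#' Returns the `m` samples in which source `k` is most dominant, in
#' descending dominance order (near well-grounded points first). Used to
#' pick source-specific marker genes from a recovered expression
#' decomposition; around 200 markers per source is a practical starting
#' point for downstream enrichment analysis.
#'
#' @param S_hat Recovered non-negative source matrix (K x N).
#' @param k Source index.
#' @param m Number of samples to return, `1 <= m <= N`.
#' @return Integer vector of `m` sample indices; ties broken by lower index.
#' @export
select_markers <- function(S_hat, k, m) {
  S_hat <- as.matrix(S_hat)
  N <- ncol(S_hat)
  if (m < 1 || m > N) stop("select_markers(): 'm' must be in 1..N")
  if (k < 1 || k > nrow(S_hat)) stop("select_markers(): invalid source index")
  d <- suppressWarnings(source_dominance(S_hat))[k, ]
  ord <- order(-d, seq_len(N), na.last = TRUE)
  ord[seq_len(m)]
}
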