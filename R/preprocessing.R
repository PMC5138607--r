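#' Scale mixture rows to unit sums
#'
#' Rescales every row (mixture) of `X` to sum to one. Under the latent model
#' X = A S with unit-row-sum sources, this makes the mixing matrix rows sum
#' to one as well, so its entries read directly as mixing proportions. The
#' operation is idempotent. Negative entries introduced by noise are kept;
#' only a row with non-positive total sum is an error, since its scaling is
#' undefined.
#'
#' @param X Numeric matrix (M x N, mixtures in rows).
#' @return The row-rescaled matrix.
#' @export
unit_sum_scale <- function(X) {
  X <- as.matrix(X)
  rs <- rowSums(X)
  bad <- which(rs <= 0)
  if (length(bad)) {
    stop("unit_sum_scale(): row(s) ", paste(bad, collapse = ", "),
         " have non-positive sums and cannot be scaled")
  }
  X / rs
}

#' Remove the samples with smallest vector norms
#'
#' Since the expected noise level is the same for all samples, samples with
#' small Euclidean norms have the lowest local SNR; removing a fraction of
#' them before estimating the mixing matrix suppresses their influence.
#' Exactly `floor(remove_fraction * N)` columns with the smallest norms are
#' removed; among tied norms the lower-index sample is kept.
#'
#' @param X_scaled Row-scaled data matrix (M x N).
#' @param remove_fraction Fraction of samples to remove, in `[0, 1)`. The
#'   sensitivity of downstream results to values in the 0.3-0.5 range is
#'   usually mild; 0.3 is a reasonable starting point.
#' @return A list with `X_kept`, `kept_idx`, `removed_idx` (both ascending),
#'   and `norm_threshold` (the smallest kept norm; `-Inf` when nothing is
#'   removed).
#' @export
filter_small_norm <- function(X_scaled, remove_fraction) {
  X_scaled <- as.matrix(X_scaled)
  if (remove_fraction < 0 || remove_fraction >= 1) {
    stop("filter_small_norm(): 'remove_fraction' must be in [0, 1)")
  }
  N <- ncol(X_scaled)
  n_remove <- floor(remove_fraction * N)
  norms <- sqrt(colSums(X_scaled^2))
  # ascending norm; among ties the higher index is removed first
  ord <- order(norms, -seq_len(N))
  removed_idx <- sort(ord[seq_len(n_remove)])
  kept_idx <- sort(setdiff(seq_len(N), removed_idx))
  list(
    X_kept = X_scaled[, kept_idx, drop = FALSE],
    kept_idx = kept_idx,
    removed_idx = removed_idx,
    norm_threshold = if (n_remove > 0) min(norms[kept_idx]) else -Inf
  )
}

#' Collapse samples lying in the same direction
#'
#' Edge detection assumes no two data vectors share a direction. Columns
#' whose pairwise angle is within `angle_tol_deg` are grouped and only the
#' largest-norm representative of each group is retained (greedy scan in
#' descending norm order; ties by lower index). Zero-norm columns have no
#' direction and are dropped with a warning.
#'
#' @param X Data matrix (M x n, samples as columns).
#' @param angle_tol_deg Non-negative angular tolerance in degrees; the tiny
#'   default only collapses numerically identical directions.
#' @return A list with `X_kept`, `kept_idx` (ascending original indices) and
#'   `collapsed_groups` (a list, one element per representative, of the
#'   column indices it absorbed, itself included).
#' @export
deduplicate_directions <- function(X, angle_tol_deg = 1e-6) {
  X <- as.matrix(X)
  if (angle_tol_deg < 0) {
    stop("deduplicate_directions(): 'angle_tol_deg' must be non-negative")
  }
  n <- ncol(X)
  norms <- sqrt(colSums(X^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    warning("deduplicate_directions(): dropping ", length(zero),
            " zero-norm column(s) with undefined direction")
  }
  live <- setdiff(seq_len(n), zero)
  U <- X[, live, drop = FALSE] / rep(norms[live], each = nrow(X))
  ord <- live[order(-norms[live], live)]
  cos_tol <- cos(angle_tol_deg * pi / 180)
  kept <- integer(0)
  groups <- list()
  pos <- match(ord, live)
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    u <- U[, pos[ii]]
    matched <- FALSE
    for (g in seq_along(kept)) {
      ck <- sum(u * U[, match(kept[g], live)])
      if (ck >= cos_tol) {
        groups[[g]] <- c(groups[[g]], i)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      kept <- c(kept, i)
      groups[[length(kept)]] <- i
    }
  }
  o <- order(kept)
  list(
    X_kept = X[, sort(kept), drop = FALSE],
    kept_idx = sort(kept),
    collapsed_groups = lapply(groups[o], sort)
  )
}

#' Full preprocessing: scale, filter, deduplicate
#'
#' Applies [unit_sum_scale()], [filter_small_norm()] and (optionally)
#' [deduplicate_directions()] in sequence.
#'
#' @param X Raw mixture matrix (M x N).
#' @param remove_fraction Fraction of small-norm samples to drop
#'   (default 0.3).
#' @param dedup Whether to collapse duplicate directions (default TRUE).
#' @param dedup_angle_tol Angular tolerance for deduplication, degrees.
#' @return An object of class `cam_preprocess`: list with `X_scaled` (all N
#'   scaled columns), `X_kept` (columns surviving filtering and
#'   deduplication), `kept_idx`, `removed_idx`, `collapsed_groups`, and
#'   `norm_threshold`.
#' @export
cam_preprocess <- function(X, remove_fraction = 0.3, dedup = TRUE,
                           dedup_angle_tol = 1e-6) {
  X_scaled <- unit_sum_scale(X)
  flt <- filter_small_norm(X_scaled, remove_fraction)
  kept_idx <- flt$kept_idx
  collapsed <- list()
  X_kept <- flt$X_kept
  if (dedup) {
    dd <- deduplicate_directions(X_kept, dedup_angle_tol)
    collapsed <- lapply(dd$collapsed_groups, function(g) kept_idx[g])
    kept_idx <- kept_idx[dd$kept_idx]
    X_kept <- dd$X_kept
  }
  structure(
    list(
      X_scaled = X_scaled,
      X_kept = X_kept,
      kept_idx = kept_idx,
      removed_idx = sort(setdiff(seq_len(ncol(X_scaled)), kept_idx)),
      collapsed_groups = collapsed,
      norm_threshold = flt$norm_threshold
    ),
    class = "cam_preprocess"
  )
}
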