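# Fit the mixing matrix (as ray directions) on one set of sample columns:
# sector clustering, lateral edge detection, and K-edge selection by
# fitting-error minimization. Uses the current RNG stream. Internal; the
# user-facing pipeline is cam_run().
fit_mixing_rays <- function(Xc, K, J = 30, n_restarts = 20, tau_deg = 0.001,
                            search = "branch_bound") {
  J_eff <- min(J, ncol(Xc))
  if (J_eff < J) {
    warning("fit_mixing_rays(): J reduced to ", J_eff,
            " (only ", ncol(Xc), " samples)")
  }
  part <- cluster_sectors(Xc, J = J_eff, n_restarts = n_restarts, seed = NULL)
  edges <- detect_lateral_edges(part$R, tau_deg)
  cand <- edges$edge_idx
  if (length(cand) < K) {
    warning("fit_mixing_rays(): only ", length(cand), " edges detected; ",
            "augmenting the candidate pool greedily to reach K = ", K)
    cand <- augment_candidates(part$R, part$counts, cand, K)
  }
  sel <- select_k_edges(part$R, part$counts, K, candidate_idx = cand,
                        method = search)
  list(A_ray = sel$A_hat, selection = sel, partition = part, edges = edges)
}

# Shared engine for the stability analysis: L two-fold cross-validation
# trials; per trial the folds are clustered once (the clustering does not
# depend on K) and then, for each candidate K, per-fold mixing estimates are
# compared by the minimum average inter-fold angle, against a baseline of K
# randomly chosen sector rays per fold.
stability_trials <- function(X_pre, K_grid, L, J, n_restarts, tau_deg,
                             search) {
  N <- ncol(X_pre)
  if (N < 4) stop("stability analysis needs at least 4 samples")
  nK <- length(K_grid)
  matched <- matrix(NA_real_, L, nK)
  baseline <- matrix(NA_real_, L, nK)
  for (l in seq_len(L)) {
    idx <- sample.int(N)
    n1 <- floor(N / 2)
    f1 <- X_pre[, idx[seq_len(n1)], drop = FALSE]
    f2 <- X_pre[, idx[(n1 + 1):N], drop = FALSE]
    prep_fold <- function(f) {
      J_eff <- min(J, ncol(f))
      part <- cluster_sectors(f, J = J_eff, n_restarts = n_restarts,
                              seed = NULL)
      edges <- detect_lateral_edges(part$R, tau_deg)
      list(part = part, cand = edges$edge_idx)
    }
    p1 <- prep_fold(f1)
    p2 <- prep_fold(f2)
    fold_A <- function(p, K) {
      cand <- p$cand
      if (length(cand) < K) {
        cand <- augment_candidates(p$part$R, p$part$counts, cand, K)
      }
      select_k_edges(p$part$R, p$part$counts, K, candidate_idx = cand,
                     method = search)$A_hat
    }
    for (ki in seq_len(nK)) {
      K <- K_grid[ki]
      A1 <- fold_A(p1, K)
      A2 <- fold_A(p2, K)
      matched[l, ki] <- min_average_angle(A1, A2)$angle_deg
      R1 <- p1$part$R
      R2 <- p2$part$R
      Ar1 <- R1[, sample.int(ncol(R1), K), drop = FALSE]
      Ar2 <- R2[, sample.int(ncol(R2), K), drop = FALSE]
      baseline[l, ki] <- min_average_angle(Ar1, Ar2)$angle_deg
    }
  }
  list(matched = matched, baseline = baseline)
}

#' Normalized model instability for one candidate source number
#'
#' Runs `L` two-fold cross-validation trials on the preprocessed data. In
#' each trial the data are split at random into equal folds, the mixing
#' matrix is estimated independently on each fold (sector clustering, edge
#' detection, K-edge selection), and the two estimates are compared by their
#' minimum average column angle. The disagreement is normalized by the
#' corresponding angle between matrices of K randomly selected sector rays,
#' one draw per fold and trial, so that the index is comparable across model
#' orders. The default aggregation is the ratio of the summed matched angles
#' to the summed baseline angles over the L trials; the mean of per-trial
#' ratios is available as an alternative.
#'
#' @param X_pre Preprocessed (scaled and filtered) data matrix.
#' @param K Candidate source number, at least 2.
#' @param L Number of cross-validation trials (default 30).
#' @param J Sector count per fold (reduced with a warning when a fold is
#'   smaller).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param n_restarts Clustering restarts per fold (default 5; smaller than
#'   the full-data default because each of the 2 L fold fits repeats the
#'   whole clustering).
#' @param tau_deg Edge-detection threshold, degrees.
#' @param search Subset search method for the K-edge selection.
#' @param aggregate `"sum_ratio"` (default) or `"mean_ratio"`.
#' @return Scalar NMI index (non-negative; 0 means the two fold estimates
#'   always agree perfectly).
#' @export
nmi_index <- function(X_pre, K, L = 30, J = 30, seed = NULL, n_restarts = 5,
                      tau_deg = 0.001, search = "branch_bound",
                      aggregate = c("sum_ratio", "mean_ratio")) {
  rep <- select_source_number(
    X_pre, K_grid = K, L = L, J = J, seed = seed, n_restarts = n_restarts,
    tau_deg = tau_deg, search = search, aggregate = aggregate
  )
  rep$nmi[[1]]
}

#' Select the source number by stability analysis
#'
#' Computes the normalized model instability (see [nmi_index()]) for every
#' candidate source number and selects the minimizer: too few sources force
#' arbitrary merges of true sources and too many fit noise, and both inflate
#' the cross-validated disagreement between independently fitted mixing
#' matrices. Ties go to the smaller K. The cross-validation splits and fold
#' clusterings are shared across the candidate grid, as the clustering does
#' not depend on K.
#'
#' @param X_pre Preprocessed (scaled and filtered) data matrix.
#' @param K_grid Candidate source numbers (default `2:K_max`).
#' @param K_max Largest candidate when `K_grid` is not given (default 9).
#' @param L,J,seed,n_restarts,tau_deg,search,aggregate See [nmi_index()].
#' @return An object of class `cam_stability`: list with `K_grid`, `nmi`
#'   (named per K), `K_selected`, `L`, and the per-trial `matched_angles`
#'   and `baseline_angles` matrices (L x length(K_grid)).
#' @export
select_source_number <- function(X_pre, K_grid = NULL, K_max = 9, L = 30,
                                 J = 30, seed = NULL, n_restarts = 5,
                                 tau_deg = 0.001, search = "branch_bound",
                                 aggregate = c("sum_ratio", "mean_ratio")) {
  aggregate <- match.arg(aggregate)
  if (is.null(K_grid)) K_grid <- 2:K_max
  if (any(K_grid < 2)) {
    stop("select_source_number(): candidate source numbers must be >= 2")
  }
  X_pre <- as.matrix(X_pre)
  run <- function() stability_trials(X_pre, K_grid, L, J, n_restarts,
                                     tau_deg, search)
  tr <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  nmi <- switch(
    aggregate,
    sum_ratio = colSums(tr$matched) / colSums(tr$baseline),
    mean_ratio = colMeans(tr$matched / tr$baseline)
  )
  names(nmi) <- as.character(K_grid)
  structure(
    list(
      K_grid = K_grid,
      nmi = nmi,
      K_selected = K_grid[which.min(nmi)],
      L = L,
      matched_angles = tr$matched,
      baseline_angles = tr$baseline
    ),
    class = "cam_stability"
  )
}

#' @export
print.cam_stability <- function(x, ...) {
  cat("Stability analysis over", x$L, "two-fold cross-validations\n")
  tab <- data.frame(K = x$K_grid, NMI = round(unname(x$nmi), 4))
  print(tab, row.names = FALSE)
  cat("Selected source number:", x$K_selected, "\n")
  invisible(x)
}
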