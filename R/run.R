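#' Run the full CAM pipeline
#'
#' Executes the complete convex analysis of mixtures on an observed mixture
#' matrix: (1) unit-row-sum scaling, small-norm sample filtering and
#' duplicate-direction removal; (2) sector-based clustering of the retained
#' samples (best of `n_restarts` random initializations); (3) lateral edge
#' detection on the sector central rays followed by branch-and-bound
#' selection of the K edges minimizing the weighted angular model fitting
#' error; and (4) non-negative least-squares recovery of the sources from
#' all samples (including the filtered ones). When `K` is not given, a
#' stability analysis over `K_grid` selects it first. All randomness
#' (clustering initializations, cross-validation splits, baseline draws)
#' derives from the single `seed`.
#'
#' The reported mixing matrix has its columns rescaled so that its rows sum
#' to one, matching the row-scaled data, with the sources rescaled
#' compatibly; for exact-determined full-rank fits this is exact.
#'
#' @param X Non-negative mixture matrix, mixtures in rows (M x N).
#' @param K Number of sources; `NULL` triggers stability-based selection.
#' @param J Number of sectors (default 30).
#' @param n_restarts Clustering restarts on the full data (default 20).
#' @param remove_fraction Fraction of small-norm samples excluded from
#'   mixing-matrix estimation (default 0.3).
#' @param tau_deg Edge-detection angular threshold in degrees
#'   (default 0.001).
#' @param K_grid Candidate source numbers for stability analysis
#'   (default `2:9`).
#' @param L Cross-validation trials for stability analysis (default 30).
#' @param stability_restarts Clustering restarts per cross-validation fold
#'   (default 5).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param search `"branch_bound"` or `"exhaustive"` edge-subset search.
#' @param dedup,dedup_angle_tol Duplicate-direction collapsing (see
#'   [deduplicate_directions()]).
#' @param force_sources In the under-determined case (`M < K`) the sources
#'   are not uniquely determined and are withheld by default; set TRUE to
#'   compute the NNLS estimate anyway.
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `cam_fit`: list with `A_hat` (M x K, unit row
#'   sums, in the row-scaled convention), `A_hat_raw` (the same columns
#'   mapped back to the units of the input data, for comparison against a
#'   ground-truth mixing matrix), `S_hat` (K x N or NULL when withheld),
#'   `X_proj`,
#'   `fitting_error`, `edge_idx` (sector indices of the selected edges),
#'   `detected_edges`, `partition`, `preprocess`, `stability` (NULL when K
#'   was given), `source_status`, and `config`.
#' @export
cam_run <- function(X, K = NULL, J = 30, n_restarts = 20,
                    remove_fraction = 0.3, tau_deg = 0.001, K_grid = 2:9,
                    L = 30, stability_restarts = 5, seed = NULL,
                    search = c("branch_bound", "exhaustive"), dedup = TRUE,
                    dedup_angle_tol = 1e-6, force_sources = FALSE,
                    verbose = FALSE) {
  search <- match.arg(search)
  X <- as.matrix(X)
  say <- function(...) if (verbose) message(...)
  run <- function() {
    say("[preprocess] scaling rows, removing ",
        round(100 * remove_fraction), "% smallest-norm samples")
    pre <- cam_preprocess(X, remove_fraction = remove_fraction,
                          dedup = dedup, dedup_angle_tol = dedup_angle_tol)
    say("[preprocess] kept ", length(pre$kept_idx), " of ", ncol(X),
        " samples")
    stability <- NULL
    K_use <- K
    if (is.null(K_use)) {
      say("[stability] selecting K over {", paste(K_grid, collapse = ", "),
          "} with L = ", L, " trials")
      stability <- select_source_number(
        pre$X_kept, K_grid = K_grid, L = L, J = J,
        n_restarts = stability_restarts, tau_deg = tau_deg, search = search
      )
      K_use <- stability$K_selected
      say("[stability] selected K = ", K_use)
    }
    say("[cluster] J = ", J, ", best of ", n_restarts, " restarts")
    fit <- fit_mixing_rays(pre$X_kept, K_use, J = J,
                           n_restarts = n_restarts, tau_deg = tau_deg,
                           search = search)
    say("[cluster] distortion ", format(fit$partition$distortion),
        "; [edges] ", fit$edges$J_star, " detected; [select] error ",
        format(fit$selection$error))
    M <- nrow(X)
    under <- M < K_use
    if (under && !force_sources) {
      resc <- unit_row_sum_rescale(fit$A_ray)
      S_hat <- NULL
      X_proj <- NULL
      status <- paste0(
        "under-determined (M = ", M, " < K = ", K_use, "): the mixing ",
        "matrix is identifiable but the sources are not uniquely ",
        "determined; set force_sources = TRUE for the (non-unique) NNLS ",
        "estimate"
      )
    } else {
      say("[recover] NNLS on all ", ncol(X), " samples")
      rec <- recover_sources(pre$X_scaled, fit$A_ray, check_rank = !under)
      resc <- unit_row_sum_rescale(fit$A_ray, rec$S_hat)
      S_hat <- resc$S_hat
      dimnames(S_hat) <- list(paste0("source", seq_len(K_use)), colnames(X))
      X_proj <- rec$X_proj
      dimnames(X_proj) <- dimnames(X)
      status <- if (under) "forced NNLS estimate (non-unique)" else "ok"
    }
    A_hat <- resc$A_hat
    dimnames(A_hat) <- list(rownames(X), paste0("source", seq_len(K_use)))
    # the fit lives in the row-scaled convention; undo the row scaling so
    # A_hat_raw is comparable to a mixing matrix in the input units
    A_hat_raw <- A_hat * rowSums(X)
    dimnames(A_hat_raw) <- dimnames(A_hat)
    structure(
      list(
        A_hat = A_hat,
        A_hat_raw = A_hat_raw,
        S_hat = S_hat,
        X_proj = X_proj,
        fitting_error = fit$selection$error,
        edge_idx = fit$selection$subset_idx,
        detected_edges = fit$edges,
        partition = fit$partition,
        preprocess = pre,
        stability = stability,
        source_status = status,
        config = list(
          K = K_use, J = J, n_restarts = n_restarts,
          remove_fraction = remove_fraction, tau_deg = tau_deg,
          K_grid = K_grid, L = L, stability_restarts = stability_restarts,
          seed = seed, search = search, dedup = dedup,
          dedup_angle_tol = dedup_angle_tol, force_sources = force_sources
        )
      ),
      class = "cam_fit"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.cam_fit <- function(x, ...) {
  cat("Convex analysis of mixtures fit\n")
  cat("  mixtures M =", nrow(x$A_hat), "; sources K =", ncol(x$A_hat), "\n")
  cat("  detected edges:", x$detected_edges$J_star,
      "; selected sector rays:", paste(x$edge_idx, collapse = ", "), "\n")
  cat("  model fitting error:", format(x$fitting_error), "\n")
  if (!is.null(x$stability)) {
    cat("  stability-selected K =", x$stability$K_selected, "\n")
  }
  if (is.null(x$S_hat)) cat("  sources:", x$source_status, "\n")
  invisible(x)
}
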