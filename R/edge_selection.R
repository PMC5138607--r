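#' Weighted angular model fitting error of an edge subset
#'
#' For a candidate set of mixing-matrix columns (a subset of the sector
#' central rays), the model fitting error is the sector-population-weighted
#' sum of the angles between every sector central ray and its projection onto
#' the cone generated by the subset. Rays inside the subset cone (including
#' the subset members themselves) contribute zero, so the sum is effectively
#' over the "exterior" rays. The error is monotone non-increasing as the
#' subset is enlarged, which is what makes branch-and-bound pruning sound.
#'
#' @param R Matrix of unit sector central rays (M x J).
#' @param counts Sector population sizes N_j, length J.
#' @param subset_idx Non-empty integer vector of candidate column indices.
#' @return Non-negative scalar (degrees, weighted).
#' @export
model_fitting_error <- function(R, counts, subset_idx) {
  R <- as.matrix(R)
  if (length(subset_idx) < 1) {
    stop("model_fitting_error(): 'subset_idx' must be non-empty")
  }
  if (length(counts) != ncol(R)) {
    stop("model_fitting_error(): 'counts' must have one entry per column of 'R'")
  }
  B <- R[, subset_idx, drop = FALSE]
  err <- 0
  for (j in seq_len(ncol(R))) {
    if (j %in% subset_idx) next
    if (counts[j] == 0) next
    err <- err + counts[j] * project_onto_cone(R[, j], B)$angle_deg
  }
  err
}

#' Select the K edges minimizing the model fitting error
#'
#' Chooses, among the detected lateral edges, the size-K subset with globally
#' minimal [model_fitting_error()]. The default search enumerates removals
#' from the full candidate pool in a branch-and-bound tree
#' (Narendra-Fukunaga style): since the error can only grow as candidates are
#' removed, the error of a partially removed node lower-bounds all of its
#' descendants and the branch is pruned once it meets the incumbent. The
#' result is guaranteed identical to exhaustive enumeration; ties in the
#' minimal error are broken by the lexicographically smallest index subset.
#'
#' @param R Matrix of all sector central rays (M x J); the fitting error is
#'   accumulated over every sector, not only the candidates.
#' @param counts Sector population sizes, length J.
#' @param K Number of edges to select.
#' @param candidate_idx Indices of the candidate pool (typically the detected
#'   edge set); defaults to all columns.
#' @param method `"branch_bound"` (default) or `"exhaustive"`.
#' @return A list with `subset_idx` (sorted selected indices), `error`,
#'   `A_hat` (the selected ray columns), and `nodes_explored`.
#' @export
select_k_edges <- function(R, counts, K,
                           candidate_idx = seq_len(ncol(R)),
                           method = c("branch_bound", "exhaustive")) {
  method <- match.arg(method)
  R <- as.matrix(R)
  candidate_idx <- sort(as.integer(candidate_idx))
  J_star <- length(candidate_idx)
  if (K > J_star) {
    stop("select_k_edges(): K = ", K, " exceeds the candidate pool size ",
         J_star)
  }
  fe <- function(sub) model_fitting_error(R, counts, sub)
  tie_tol <- 1e-9
  nodes <- 0L

  if (J_star == K) {
    best_sub <- candidate_idx
    best_err <- fe(best_sub)
    nodes <- 1L
  } else if (method == "exhaustive") {
    subs <- utils::combn(candidate_idx, K)
    best_err <- Inf
    best_sub <- NULL
    for (i in seq_len(ncol(subs))) {
      e <- fe(subs[, i])
      nodes <- nodes + 1L
      if (e < best_err - tie_tol) {
        best_err <- e
        best_sub <- subs[, i]
      }
    }
  } else {
    m <- J_star - K
    # order candidates by ascending error increase when removed alone, so the
    # leftmost (greedy) leaf gives a strong incumbent early
    solo <- vapply(
      seq_len(J_star),
      function(i) fe(candidate_idx[-i]),
      numeric(1)
    )
    ord <- order(solo, seq_len(J_star))
    cand <- candidate_idx[ord]
    best_err <- Inf
    best_sub <- NULL
    env <- environment()
    recurse <- function(kept_pos, start, nrem) {
      sub <- cand[kept_pos]
      err <- fe(sub)
      assign("nodes", nodes + 1L, envir = env)
      # lower bound: descendants only remove more, never reducing the error
      if (err > best_err + tie_tol) return(invisible(NULL))
      if (nrem == m) {
        s <- sort(sub)
        better <- err < best_err - tie_tol ||
          (abs(err - best_err) <= tie_tol && !is.null(best_sub) &&
             lex_less(s, sort(best_sub)))
        if (is.null(best_sub) || better) {
          assign("best_err", min(err, best_err), envir = env)
          assign("best_sub", s, envir = env)
        }
        return(invisible(NULL))
      }
      for (i in start:J_star) {
        if (!(i %in% kept_pos)) next
        if (J_star - i < m - nrem - 1) break
        recurse(setdiff(kept_pos, i), i + 1L, nrem + 1L)
      }
      invisible(NULL)
    }
    recurse(seq_len(J_star), 1L, 0L)
  }

  best_sub <- sort(best_sub)
  list(
    subset_idx = best_sub,
    error = best_err,
    A_hat = R[, best_sub, drop = FALSE],
    nodes_explored = nodes
  )
}

# TRUE when integer vector a precedes b lexicographically
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# Expand an undersized candidate pool greedily: add, one at a time, the ray
# that minimizes the fitting error of the enlarged set. Used only in the
# degenerate case where edge detection returned fewer than K edges.
augment_candidates <- function(R, counts, candidate_idx, K) {
  pool <- sort(as.integer(candidate_idx))
  all_idx <- seq_len(ncol(R))
  while (length(pool) < K) {
    rest <- setdiff(all_idx, pool)
    if (!length(rest)) {
      stop("fewer sector rays (", ncol(R), ") than requested sources (", K, ")")
    }
    errs <- vapply(
      rest,
      function(j) model_fitting_error(R, counts, c(pool, j)),
      numeric(1)
    )
    pool <- sort(c(pool, rest[which.min(errs)]))
  }
  pool
}
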