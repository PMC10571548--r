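#' Minimum-cost one-to-one assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear assignment problem by the Hungarian
#' algorithm in its shortest-augmenting-path form with dual potentials
#' (O(n^2 m)). All `min(n, m)` rows (or columns, whichever is fewer) are
#' assigned; the total cost is the minimum over all injective assignments.
#' The implementation is fully deterministic: given the same matrix it
#' always returns the same optimum, scanning columns in index order.
#'
#' @param cost A numeric matrix of finite costs (possibly rectangular,
#'   possibly empty).
#' @return A list with `rows`, `cols` (parallel integer vectors giving the
#'   matched pairs) and `total` (the summed cost of the matching).
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L)
    return(list(rows = integer(0), cols = integer(0), total = 0))
  if (any(!is.finite(cost)))
    pt_validation_error("assignment costs must be finite")
  if (n > m) {
    res <- solve_assignment(t(cost))
    return(list(rows = res$cols, cols = res$rows, total = res$total))
  }
  col_of <- hungarian_core(cost)
  rows <- seq_len(n)
  list(rows = rows, cols = col_of,
       total = sum(cost[cbind(rows, col_of)]))
}

# Shortest augmenting path Hungarian with potentials; requires n <= m.
# Index shift: the classic formulation uses a virtual column 0 and virtual
# row 0, stored here at offset +1.
hungarian_core <- function(a) {
  n <- nrow(a); m <- ncol(a)
  U <- numeric(n + 1L)            # row potentials, U[i + 1]
  V <- numeric(m + 1L)            # column potentials, V[j + 1]
  P <- integer(m + 1L)            # P[j + 1] = row matched to column j
  WAY <- integer(m + 1L)
  for (i in seq_len(n)) {
    P[1L] <- i
    j0 <- 0L
    MINV <- rep(Inf, m + 1L)
    USED <- rep(FALSE, m + 1L)
    repeat {
      USED[j0 + 1L] <- TRUE
      i0 <- P[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!USED[j + 1L]) {
          cur <- a[i0, j] - U[i0 + 1L] - V[j + 1L]
          if (cur < MINV[j + 1L]) {
            MINV[j + 1L] <- cur
            WAY[j + 1L] <- j0
          }
          if (MINV[j + 1L] < delta) {
            delta <- MINV[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (USED[j + 1L]) {
          U[P[j + 1L] + 1L] <- U[P[j + 1L] + 1L] + delta
          V[j + 1L] <- V[j + 1L] - delta
        } else {
          MINV[j + 1L] <- MINV[j + 1L] - delta
        }
      }
      j0 <- j1
      if (P[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- WAY[j0 + 1L]
      P[j0 + 1L] <- P[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  col_of <- integer(n)
  for (j in seq_len(m)) if (P[j + 1L] > 0L) col_of[P[j + 1L]] <- j
  col_of
}

#' Gated assignment for track-detection matching
#'
#' Runs [solve_assignment()] on an IoU-distance matrix (`cost = 1 - IoU`)
#' and then dissolves any matched pair whose cost exceeds `max_cost` back
#' into the unmatched sets. Gating after the global optimum (rather than
#' masking before) is the convention of IoU-based trackers: the optimum is
#' computed once, then implausible pairs are rejected.
#'
#' @param cost Numeric matrix of finite non-negative costs; rows are
#'   tracks, columns are detections.
#' @param max_cost Pairs costing strictly more than this are dissolved.
#' @return A list with `matches` (two-column integer matrix of row/col
#'   pairs), `unmatched_rows` and `unmatched_cols`.
#' @examples
#' linear_assignment(matrix(c(1, 2, 2, 4), 2, byrow = TRUE), max_cost = 10)
#' @export
linear_assignment <- function(cost, max_cost = 1) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L)
    return(list(matches = matrix(integer(0), 0L, 2L),
                unmatched_rows = seq_len(n), unmatched_cols = seq_len(m)))
  sol <- solve_assignment(cost)
  keep <- cost[cbind(sol$rows, sol$cols)] <= max_cost
  matches <- cbind(row = sol$rows[keep], col = sol$cols[keep])
  list(matches = matches,
       unmatched_rows = setdiff(seq_len(n), matches[, 1L]),
       unmatched_cols = setdiff(seq_len(m), matches[, 2L]))
}
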