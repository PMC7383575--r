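#' Optimal assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for a rectangular score matrix with
#' `nrow <= ncol`: selects one column per row, all distinct, maximising the
#' total score. Implemented as the O(n^2 m) potentials / shortest-augmenting-
#' path form of the Kuhn-Munkres algorithm.
#'
#' @param score numeric matrix of pair scores. When there are more rows than
#'   columns the problem is solved on the transpose.
#' @return integer vector `a` of length `nrow(score)`: row `i` is assigned to
#'   column `a[i]`; `NA` for rows left unmatched when `nrow > ncol`.
#' @export
hungarian_assignment <- function(score) {
  stopifnot(is.matrix(score), all(is.finite(score)))
  transposed <- FALSE
  if (nrow(score) > ncol(score)) {
    score <- t(score)
    transposed <- TRUE
  }
  cost <- max(score) - score            # maximisation -> minimisation
  n <- nrow(cost); m <- ncol(cost)
  u <- numeric(n + 1L)                  # row potentials (+ dummy slot)
  v <- numeric(m + 1L)                  # column potentials (+ virtual col)
  p <- integer(m + 1L)                  # p[j]: row matched to column j (0 = free)
  way <- integer(m + 1L)
  J0 <- m + 1L                          # virtual starting column
  for (i in seq_len(n)) {
    p[J0] <- i
    j0 <- J0
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          ip <- p[j]; if (ip == 0L) ip <- n + 1L
          u[ip] <- u[ip] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {                            # augment along the alternating path
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == J0) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assign[p[j]] <- j
  if (transposed) {
    # solved on the transpose: assign[k] is the original row matched to
    # original column k; re-express as original row -> column (NA = unmatched)
    out <- rep(NA_integer_, m)
    out[assign] <- seq_len(n)
    return(out)
  }
  assign
}
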