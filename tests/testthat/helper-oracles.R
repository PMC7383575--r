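# Independent oracles: deliberately brute-force / direct implementations,
# kept free of the package's own algorithmic code paths.

# maximum total score over all injections of rows into columns (rows <= cols)
brute_force_assignment <- function(score) {
  n <- nrow(score)
  m <- ncol(score)
  stopifnot(n <= m)
  best <- -Inf
  best_p <- NULL
  rec <- function(cur, used) {
    if (length(cur) == n) {
      v <- sum(score[cbind(seq_len(n), cur)])
      if (v > best) {
        best <<- v
        best_p <<- cur
      }
      return(invisible())
    }
    for (j in setdiff(seq_len(m), used)) rec(c(cur, j), c(used, j))
  }
  rec(integer(0), integer(0))
  list(score = best, assignment = best_p)
}

# minimum number of state changes over all 0/1 labelings of internal nodes
exhaustive_parsimony <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  s <- states[tree$tip.label]
  best <- Inf
  for (code in 0:(2^nint - 1)) {
    lab <- c(s, as.integer(intToBits(code))[seq_len(nint)])
    changes <- sum(lab[tree$edge[, 1L]] != lab[tree$edge[, 2L]])
    if (changes < best) best <- changes
  }
  best
}

# P(X >= k) by direct combinatorial summation (independent of phyper)
hyper_tail_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# global affine-gap alignment score (Gotoh), gap of length L costs
# open + ext * L, matching the pairwiseAlignment convention
gotoh_score <- function(a, b, submat, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (A aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- submat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# all monophyletic leaf groups of a rooted tree (for conservative_k checks)
monophyletic_groups <- function(tree) {
  ntip <- length(tree$tip.label)
  groups <- as.list(tree$tip.label)
  # descendants per internal node
  po <- ape::reorder.phylo(tree, "postorder")$edge
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po))) {
    desc[[po[e, 1]]] <- c(desc[[po[e, 1]]], desc[[po[e, 2]]])
  }
  c(groups, desc[(ntip + 1):(ntip + tree$Nnode)])
}

# conservative k by exhaustive enumeration of monophyletic groups:
# greedily take maximal all-positive groups from the largest down
conservative_k_oracle <- function(tree, counts) {
  groups <- monophyletic_groups(tree)
  positive <- names(counts)[counts > 0]
  all_pos <- Filter(function(g) all(g %in% positive), groups)
  covered <- character(0)
  total <- 0
  for (g in all_pos[order(-vapply(all_pos, length, 0L))]) {
    if (!any(g %in% covered)) {
      total <- total + max(counts[g])
      covered <- c(covered, g)
    }
  }
  total
}
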