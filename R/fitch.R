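#' Maximum-parsimony ancestral states for a binary trait
#'
#' Fitch parsimony on a rooted tree for a 0/1 character: the bottom-up pass
#' builds preliminary state sets by intersection (or union, counting one
#' change) of the child sets, and the parsimony score is the number of union
#' events. Node state sets are then refined to the full most-parsimonious-
#' reconstruction (MPR) sets — the states a node can take in at least one
#' reconstruction of minimal cost — via a unit-cost dynamic program up and
#' down the tree. Nodes whose MPR set contains both states are ambiguous.
#'
#' Multifurcating trees are resolved arbitrarily to binary with zero-length
#' branches before the calculation (with a message), since the two-set Fitch
#' recurrence assumes a binary tree.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param states named 0/1 vector over all tips of `tree`.
#' @return list of class `fitch_parsimony`: `score` (integer), `tree` (the
#'   binary tree used), `prelim` (list of bottom-up Fitch state sets, indexed
#'   by node number), `mpr` (list of MPR state sets), `ambiguous` (logical
#'   per node).
#' @export
fitch_parsimony <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("fitch_parsimony requires a rooted tree")
  if (!ape::is.binary(tree)) {
    message("resolving multifurcations arbitrarily with zero-length branches")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (is.null(names(states))) stop("states must be named by tip label")
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing) > 0L) {
    stop("states missing for tips: ", paste(missing, collapse = ", "))
  }
  s <- states[tree$tip.label]
  if (!all(s %in% c(0, 1))) stop("states must be binary 0/1")

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")$edge
  kids <- vector("list", nnode)
  for (e in seq_len(nrow(po))) kids[[po[e, 1L]]] <- c(kids[[po[e, 1L]]], po[e, 2L])

  # bottom-up Fitch sets; sets encoded as logical length-2 (state 0, state 1)
  prelim <- matrix(FALSE, nnode, 2L)
  prelim[cbind(seq_len(ntip), s + 1L)] <- TRUE
  score <- 0L
  up <- matrix(Inf, nnode, 2L)          # unit-cost Sankoff, same pass
  up[cbind(seq_len(ntip), s + 1L)] <- 0
  internal_po <- unique(po[, 1L])       # children precede parents
  for (nd in internal_po) {
    ch <- kids[[nd]]
    inter <- prelim[ch[1L], ] & prelim[ch[2L], ]
    if (any(inter)) {
      prelim[nd, ] <- inter
    } else {
      prelim[nd, ] <- prelim[ch[1L], ] | prelim[ch[2L], ]
      score <- score + 1L
    }
    for (st in 1:2) {
      up[nd, st] <- sum(vapply(ch, function(c2) {
        min(up[c2, st], min(up[c2, ]) + 1)
      }, 0))
    }
  }
  stopifnot(score == min(up[root, ]))

  # downward pass: cost of the rest of the tree given each node state
  down <- matrix(Inf, nnode, 2L)
  down[root, ] <- 0
  for (nd in rev(internal_po)) {
    ch <- kids[[nd]]
    for (ci in seq_along(ch)) {
      c1 <- ch[ci]; sib <- ch[-ci]
      for (st in 1:2) {
        best <- Inf
        for (sp in 1:2) {
          v <- down[nd, sp] + (if (sp != st) 1 else 0) +
            sum(vapply(sib, function(b) min(up[b, sp], min(up[b, ]) + 1), 0))
          if (v < best) best <- v
        }
        down[c1, st] <- best
      }
    }
  }
  total <- up + down
  mpr <- total == min(up[root, ])
  structure(list(
    score = score,
    tree = tree,
    prelim = apply(prelim, 1L, function(r) which(r) - 1L, simplify = FALSE),
    mpr = apply(mpr, 1L, function(r) which(r) - 1L, simplify = FALSE),
    ambiguous = rowSums(mpr) > 1L), class = "fitch_parsimony")
}

#' @export
print.fitch_parsimony <- function(x, ...) {
  cat(sprintf("<fitch_parsimony> %d-leaf tree, score %d, %d ambiguous node(s)\n",
              length(x$tree$tip.label), x$score, sum(x$ambiguous)))
  invisible(x)
}

#' Map parsimony state changes onto branches
#'
#' Converts a [fitch_parsimony()] reconstruction into per-branch events. A
#' branch is a gain (0 to 1) or a loss (1 to 0) when the parent and child MPR
#' state sets are disjoint singletons; when either endpoint is ambiguous the
#' branch is flagged ambiguous rather than forced by an acceleration or
#' delay heuristic; otherwise the branch carries no event. The number of
#' unambiguous gains plus losses never exceeds the parsimony score.
#'
#' @param fit a `fitch_parsimony` object.
#' @return list with `events` (data.frame: `parent`, `child` node numbers,
#'   `child_label` for tip children, `state_parent`, `state_child` — `"0/1"`
#'   when ambiguous — and `event` in gain/loss/none/ambiguous) and `totals`
#'   (named numeric: `gains`, `losses`, `ambiguous`, `score`).
#' @export
map_events <- function(fit) {
  stopifnot(inherits(fit, "fitch_parsimony"))
  tree <- fit$tree
  ntip <- length(tree$tip.label)
  set_chr <- function(ss) paste(ss, collapse = "/")
  ev <- character(nrow(tree$edge))
  sp <- character(nrow(tree$edge)); sc <- character(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    ps <- fit$mpr[[p]]; cs <- fit$mpr[[ch]]
    sp[e] <- set_chr(ps); sc[e] <- set_chr(cs)
    ev[e] <- if (length(ps) > 1L || length(cs) > 1L) {
      "ambiguous"
    } else if (ps == cs) {
      "none"
    } else if (ps == 0L) "gain" else "loss"
  }
  child_label <- ifelse(tree$edge[, 2L] <= ntip,
                        tree$tip.label[tree$edge[, 2L]], NA_character_)
  events <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                       child_label = child_label, state_parent = sp,
                       state_child = sc, event = ev, stringsAsFactors = FALSE)
  totals <- c(gains = sum(ev == "gain"), losses = sum(ev == "loss"),
              ambiguous = sum(ev == "ambiguous"), score = fit$score)
  list(events = events, totals = totals)
}

#' Parsimony reconstruction for every domain of a trait matrix
#'
#' @param tree rooted [ape::phylo] tree.
#' @param traits 0/1 matrix, rows named by tip label, columns by domain.
#' @return list: per domain, `fit` ([fitch_parsimony()]) and `events`
#'   ([map_events()]).
#' @export
reconstruct_all_domains <- function(tree, traits) {
  stopifnot(is.matrix(traits), !is.null(rownames(traits)),
            !is.null(colnames(traits)))
  out <- lapply(colnames(traits), function(d) {
    fit <- fitch_parsimony(tree, stats::setNames(traits[, d], rownames(traits)))
    list(fit = fit, events = map_events(fit))
  })
  names(out) <- colnames(traits)
  out
}
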