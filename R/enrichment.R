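#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` marked genes when drawing `n` genes
#' without replacement from a universe of `N` genes of which `K` are marked
#' — the one-tailed exact Fisher / hypergeometric enrichment test. Evaluated
#' through the numerically stable distribution routines of R (log-space
#' internally), not by naive summation.
#'
#' @param k observed successes (marked genes inside the neighbourhood set).
#' @param K marked genes in the universe.
#' @param n genes drawn (neighbourhood-set size).
#' @param N universe size.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`; 1 when `k <= 0`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop("invalid hypergeometric parameters: k=", k, " K=", K, " n=", n, " N=", N)
  }
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p_raw raw p-value(s) in `[0, 1]`.
#' @param m number of tests in the family (>= 1).
#' @return `min(1, m * p_raw)`, vectorised over `p_raw`.
#' @export
bonferroni <- function(p_raw, m) {
  stopifnot(m >= 1, all(p_raw >= 0 & p_raw <= 1))
  pmin(1, m * p_raw)
}

#' Phylogeny-conservative success count
#'
#' Related species inherit neighbourhood content vertically, so counting every
#' leaf of a clade that shares a domain inflates the hypergeometric success
#' count `k` with non-independent observations. The conservative correction
#' partitions the trait-positive leaves of the tested clade into maximal
#' monophyletic groups (on the tree induced by the clade's leaves) in which
#' *every* leaf carries the domain, and counts each group once, at the count
#' of its best leaf: the corrected `k` is the sum over groups of the maximum
#' per-leaf domain count. Leaves with count 0 contribute nothing and break
#' monophyletic runs.
#'
#' @param tree an [ape::phylo] tree containing all clade leaves.
#' @param clade_leaves leaf names of the tested clade.
#' @param leaf_counts named integer vector, domain-copy count in each leaf's
#'   neighbourhood; leaves missing from it are treated as 0 (with a message).
#' @return the conservative success count (integer-valued numeric).
#' @export
conservative_k <- function(tree, clade_leaves, leaf_counts) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(clade_leaves, tree$tip.label)
  if (length(missing) > 0L) {
    stop("clade leaves absent from tree: ", paste(missing, collapse = ", "))
  }
  absent <- setdiff(clade_leaves, names(leaf_counts))
  if (length(absent) > 0L) {
    message("leaves without counts treated as 0: ", paste(absent, collapse = ", "))
  }
  counts <- stats::setNames(rep(0, length(clade_leaves)), clade_leaves)
  common <- intersect(clade_leaves, names(leaf_counts))
  counts[common] <- leaf_counts[common]
  if (any(counts < 0)) stop("negative leaf counts")
  sub <- induced_subtree(tree, clade_leaves)
  conservative_k_on_subtree(sub, counts)
}

# Restrict a tree to a leaf subset; handles the 1- and 2-leaf degenerate cases
# that ape::keep.tip cannot represent as a proper phylo.
induced_subtree <- function(tree, leaves) {
  if (length(leaves) <= 1L) return(list(degenerate = TRUE, tips = leaves))
  sub <- ape::keep.tip(tree, leaves)
  list(degenerate = FALSE, tree = sub)
}

conservative_k_on_subtree <- function(sub, counts) {
  if (sub$degenerate) {
    return(sum(counts[sub$tips]))
  }
  tr <- sub$tree
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  po <- ape::reorder.phylo(tr, "postorder")$edge
  all_pos <- logical(nnode)
  grp_max <- numeric(nnode)     # max leaf count within all-positive subtree
  tipc <- counts[tr$tip.label]
  all_pos[seq_len(ntip)] <- tipc > 0
  grp_max[seq_len(ntip)] <- tipc
  kids <- vector("list", nnode)
  for (e in seq_len(nrow(po))) {
    kids[[po[e, 1L]]] <- c(kids[[po[e, 1L]]], po[e, 2L])
  }
  for (nd in unique(po[, 1L])) {
    ch <- kids[[nd]]
    all_pos[nd] <- all(all_pos[ch])
    grp_max[nd] <- max(grp_max[ch])
  }
  parent <- integer(nnode)
  parent[tr$edge[, 2L]] <- tr$edge[, 1L]
  root <- ntip + 1L
  total <- 0
  # maximal all-positive nodes: all_pos and (root or parent not all_pos)
  for (nd in seq_len(nnode)) {
    if (!all_pos[nd]) next
    if (nd == root || !all_pos[parent[nd]]) total <- total + grp_max[nd]
  }
  total
}

#' Run the domain-enrichment analysis
#'
#' For each clade of target genes and each domain observed at least once in
#' that clade's neighbourhoods, tests whether the domain is over-represented
#' among neighbourhood genes relative to the pooled genome background, with a
#' one-tailed hypergeometric test and Bonferroni correction over the domains
#' tested within the clade. Counting is at the gene level: a gene carrying one
#' or more hits of a domain counts once. In `"conservative"` mode the success
#' count is reduced by monophyletic collapsing (see [conservative_k()]);
#' the neighbourhood-set size `n` is never reduced, which is strictly
#' conservative.
#'
#' @param genomes list of [annotated_genome()] objects (the universe).
#' @param gns_by_clade named list: clade name -> list of neighbourhoods of
#'   that clade's target genes.
#' @param tree target-gene tree (required for conservative mode).
#' @param leaf_to_gn named character vector mapping tree leaves to `gn_id`s
#'   (required for conservative mode; leaves sharing a neighbourhood should
#'   first be reduced to a representative, see
#'   [select_representative_leaves()]).
#' @param level `"family"` or `"subfamily"` domain labelling
#'   (see [domain_label()]).
#' @param mode `"naive"` or `"conservative"`.
#' @param threshold significance threshold on the adjusted p-value
#'   (default 0.01).
#' @param include_targets keep the target genes themselves in the universe and
#'   neighbourhood gene sets (default `TRUE`).
#' @return data.frame with one row per (clade, domain): columns `clade`,
#'   `domain`, `level`, `mode`, `k`, `K`, `n`, `N`, `m`, `p_raw`, `p_adj`,
#'   `significant`, sorted by `p_adj` within clade.
#' @export
run_enrichment <- function(genomes, gns_by_clade, tree = NULL,
                           leaf_to_gn = NULL,
                           level = c("family", "subfamily"),
                           mode = c("naive", "conservative"),
                           threshold = 0.01, include_targets = TRUE) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  if (mode == "conservative" && (is.null(tree) || is.null(leaf_to_gn))) {
    stop("conservative mode requires a tree and a leaf_to_gn mapping")
  }
  genes <- pooled_gene_table(genomes)
  hits <- pooled_hit_table(genomes)
  all_targets <- unique(unlist(lapply(unlist(gns_by_clade, recursive = FALSE),
                                      `[[`, "center_gene_ids")))
  if (!include_targets) {
    genes <- genes[!genes$gene_id %in% all_targets, , drop = FALSE]
    hits <- hits[!hits$gene_id %in% all_targets, , drop = FALSE]
  }
  N <- nrow(genes)
  hits$label <- domain_label(hits, level)
  gene_dom <- unique(hits[, c("gene_id", "label")])
  K_all <- table(gene_dom$label)

  rows <- list()
  for (clade in names(gns_by_clade)) {
    gns <- gns_by_clade[[clade]]
    if (length(gns) == 0L) {
      warning("clade ", clade, " has no neighbourhoods; skipped")
      next
    }
    member_sets <- lapply(gns, `[[`, "member_gene_ids")
    members <- unlist(member_sets)
    if (!include_targets) members <- setdiff(members, all_targets)
    if (anyDuplicated(members)) {
      stop("neighbourhoods of clade ", clade, " share member genes; ",
           "merge or deduplicate before enrichment")
    }
    n <- length(members)
    in_gn <- gene_dom[gene_dom$gene_id %in% members, , drop = FALSE]
    doms <- sort(unique(in_gn$label))
    m <- length(doms)
    if (m == 0L) next
    k_naive <- table(factor(in_gn$label, levels = doms))

    k_use <- as.numeric(k_naive)
    if (mode == "conservative") {
      gn_ids <- vapply(gns, `[[`, "", "gn_id")
      clade_leaves <- names(leaf_to_gn)[leaf_to_gn %in% gn_ids]
      if (length(clade_leaves) == 0L) {
        stop("no tree leaves map to the neighbourhoods of clade ", clade)
      }
      sub <- induced_subtree(tree, clade_leaves)
      # per-leaf gene sets once, then per-domain counts
      leaf_members <- lapply(leaf_to_gn[clade_leaves], function(id) {
        member_sets[[match(id, gn_ids)]]
      })
      for (d in seq_along(doms)) {
        dom_genes <- gene_dom$gene_id[gene_dom$label == doms[d]]
        cnts <- vapply(leaf_members, function(mm) sum(mm %in% dom_genes), 0)
        names(cnts) <- clade_leaves
        k_use[d] <- conservative_k_on_subtree(sub, cnts)
      }
    }
    p_raw <- vapply(seq_along(doms), function(d) {
      hypergeom_upper_tail(k_use[d], as.numeric(K_all[doms[d]]), n, N)
    }, 0)
    p_adj <- bonferroni(p_raw, m)
    rows[[length(rows) + 1L]] <- data.frame(
      clade = clade, domain = doms, level = level, mode = mode,
      k = k_use, K = as.numeric(K_all[doms]), n = n, N = N, m = m,
      p_raw = p_raw, p_adj = p_adj,
      significant = p_adj < threshold,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(clade = character(), domain = character(),
                      level = character(), mode = character(), k = numeric(),
                      K = numeric(), n = numeric(), N = numeric(),
                      m = numeric(), p_raw = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$clade, out$p_adj, out$domain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-genome enrichment reruns
#'
#' Repeats [run_enrichment()] with each genome in turn as its own universe,
#' restricting every clade's neighbourhood set to that genome. Useful for
#' checking that a pooled association is not driven by a single genome.
#'
#' @inheritParams run_enrichment
#' @return data.frame as [run_enrichment()] with a `genome_id` column
#'   prepended.
#' @export
run_enrichment_per_genome <- function(genomes, gns_by_clade, tree = NULL,
                                      leaf_to_gn = NULL,
                                      level = c("family", "subfamily"),
                                      mode = c("naive", "conservative"),
                                      threshold = 0.01,
                                      include_targets = TRUE) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  out <- list()
  for (g in genomes) {
    sub_gns <- lapply(gns_by_clade, function(gns) {
      Filter(function(gn) gn$genome_id == g$genome_id, gns)
    })
    sub_gns <- sub_gns[vapply(sub_gns, length, 0L) > 0L]
    if (length(sub_gns) == 0L) next
    res <- run_enrichment(list(g), sub_gns, tree = tree,
                          leaf_to_gn = leaf_to_gn, level = level, mode = mode,
                          threshold = threshold,
                          include_targets = include_targets)
    if (nrow(res) > 0L) {
      out[[length(out) + 1L]] <- cbind(genome_id = g$genome_id, res,
                                       stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
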