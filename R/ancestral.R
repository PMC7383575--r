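#' Root a gene tree for ancestral reconstruction
#'
#' The parsimony score is invariant to rooting, but event polarity (gain vs
#' loss) is not, so reconstructions are reported for an explicit rooting:
#' at a user-named outgroup leaf when one is given, otherwise by midpoint
#' rooting on the branch-length metric.
#'
#' @param tree an [ape::phylo] tree.
#' @param outgroup optional tip label to root on.
#' @return a rooted tree.
#' @export
root_tree <- function(tree, outgroup = NULL) {
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) stop("outgroup not in tree: ", outgroup)
    return(ape::root(tree, outgroup = outgroup, resolve.root = TRUE))
  }
  if (ape::is.rooted(tree)) return(tree)
  phangorn::midpoint(tree)
}

#' Remove leaves whose neighbourhood is undersized
#'
#' Leaves mapping to neighbourhoods with fewer than `min_genes` genes (edge-
#' truncated windows) are pruned before ancestral reconstruction; the implied
#' unary nodes are suppressed and their branch lengths summed, so the retained
#' leaves keep their patristic distances.
#'
#' @param tree an [ape::phylo] tree.
#' @param leaf_to_gn named character vector mapping every tip to a `gn_id`.
#' @param gns list of `genome_neighbourhood` covering the mapped ids.
#' @param min_genes minimum neighbourhood size (default 11).
#' @return the pruned tree.
#' @export
prune_for_reconstruction <- function(tree, leaf_to_gn, gns, min_genes = 11L) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(tree$tip.label, names(leaf_to_gn))
  if (length(missing) > 0L) {
    stop("tips without a neighbourhood mapping: ", paste(missing, collapse = ", "))
  }
  gn_ids <- vapply(gns, `[[`, "", "gn_id")
  sizes <- vapply(gns, function(g) length(g$member_gene_ids), 0L)
  leaf_sizes <- sizes[match(leaf_to_gn[tree$tip.label], gn_ids)]
  if (anyNA(leaf_sizes)) {
    stop("leaves map to unknown neighbourhoods: ",
         paste(tree$tip.label[is.na(leaf_sizes)], collapse = ", "))
  }
  drop <- tree$tip.label[leaf_sizes < min_genes]
  if (length(tree$tip.label) - length(drop) < 2L) {
    stop("pruning would leave fewer than 2 leaves")
  }
  if (length(drop) == 0L) return(tree)
  ape::drop.tip(tree, drop)
}

#' Choose one representative leaf per neighbourhood
#'
#' Merged neighbourhoods containing several target genes appear as several
#' leaves in the gene tree; keeping them all would overweight those loci.
#' For each neighbourhood mapped by more than one leaf, the leaf maximising
#' the mean DSS between its neighbourhood and the neighbourhoods of the
#' surrounding leaves is retained and the others are dropped. "Surrounding"
#' is, by default, all retained leaves of other neighbourhoods; the
#' `"nearest"` method restricts the mean to the `k` closest leaves by
#' patristic distance, under which co-resident leaves can genuinely differ.
#' Ties are broken by leaf name.
#'
#' @param tree an [ape::phylo] tree.
#' @param leaf_to_gn named character vector mapping tips to `gn_id`s.
#' @param dss symmetric numeric matrix of DSS values with `gn_id` dimnames
#'   (see [pairs_to_matrix()]).
#' @param method `"all"` (mean over all other-neighbourhood leaves) or
#'   `"nearest"` (mean over the `k` nearest such leaves).
#' @param k neighbourhood size for `method = "nearest"`.
#' @return character vector of retained leaf names.
#' @export
select_representative_leaves <- function(tree, leaf_to_gn, dss,
                                         method = c("all", "nearest"), k = 5L) {
  method <- match.arg(method)
  tips <- tree$tip.label
  stopifnot(all(tips %in% names(leaf_to_gn)))
  gn_of <- leaf_to_gn[tips]
  patr <- if (method == "nearest") stats::as.dist(ape::cophenetic.phylo(tree)) else NULL
  patrm <- if (method == "nearest") as.matrix(ape::cophenetic.phylo(tree)) else NULL
  score <- function(leaf) {
    others <- tips[gn_of[tips] != gn_of[leaf]]
    if (method == "nearest" && length(others) > k) {
      others <- others[order(patrm[leaf, others], others)][seq_len(k)]
    }
    if (length(others) == 0L) return(0)
    mean(dss[gn_of[leaf], gn_of[others]])
  }
  keep <- character()
  for (gid in unique(gn_of)) {
    cand <- sort(tips[gn_of == gid])
    if (length(cand) == 1L) {
      keep <- c(keep, cand)
    } else {
      sc <- vapply(cand, score, 0)
      keep <- c(keep, cand[which.max(sc)])   # ties: first in sorted order
    }
  }
  keep[order(match(keep, tips))]
}

#' Square matrix from a pairwise comparison table
#'
#' @param pairs data.frame as `all_vs_all()$pairs`.
#' @param value which column to spread (default `"dss"`).
#' @param diag value on the diagonal (default 1 for similarity indices).
#' @return symmetric matrix with `gn_id` dimnames.
#' @export
pairs_to_matrix <- function(pairs, value = "dss", diag = 1) {
  ids <- sort(unique(c(pairs$gn_a, pairs$gn_b)))
  m <- matrix(diag, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(pairs))) {
    m[pairs$gn_a[r], pairs$gn_b[r]] <- pairs[[value]][r]
    m[pairs$gn_b[r], pairs$gn_a[r]] <- pairs[[value]][r]
  }
  m
}

#' Binary trait matrix from neighbourhood domain content
#'
#' For each retained leaf and each domain of interest, records whether the
#' leaf's neighbourhood carries at least one gene with that domain.
#'
#' @param leaves character vector of retained tips.
#' @param leaf_to_gn named mapping tip -> `gn_id`.
#' @param gns list of neighbourhoods.
#' @param genomes list of `annotated_genome`.
#' @param domains character vector of domain labels to score.
#' @param level domain labelling level.
#' @return 0/1 matrix, rows = leaves, columns = domains.
#' @export
trait_matrix <- function(leaves, leaf_to_gn, gns, genomes, domains,
                         level = c("subfamily", "family")) {
  level <- match.arg(level)
  gn_ids <- vapply(gns, `[[`, "", "gn_id")
  genome_ids <- vapply(genomes, `[[`, "", "genome_id")
  m <- matrix(0L, length(leaves), length(domains),
              dimnames = list(leaves, domains))
  for (leaf in leaves) {
    gn <- gns[[match(leaf_to_gn[[leaf]], gn_ids)]]
    g <- genomes[[match(gn$genome_id, genome_ids)]]
    hits <- g$hits[g$hits$gene_id %in% gn$member_gene_ids, , drop = FALSE]
    labels <- if (nrow(hits) > 0L) domain_label(hits, level) else character()
    m[leaf, ] <- as.integer(domains %in% labels)
  }
  m
}
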