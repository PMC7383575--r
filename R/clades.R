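#' Propagate clade labels from reference leaves across a gene tree
#'
#' Given a gene tree and clade/subfamily labels for a reference subset of its
#' leaves (typically genes of a well-annotated model species), each unlabeled
#' leaf receives the label of the smallest enclosing clade that contains at
#' least one reference leaf, provided all reference leaves inside that clade
#' agree. Where the smallest such clade mixes labels the leaf is marked
#' ambiguous. Reference labels are never overwritten.
#'
#' @param tree an [ape::phylo] tree (rooted or unrooted; unrooted trees are
#'   treated as rooted at their basal trichotomy for clade enumeration).
#' @param reference data.frame with columns `leaf_name`, `label` covering a
#'   subset of the tree's leaves.
#' @return data.frame with columns `leaf_name`, `label` (`NA` for ambiguous)
#'   and `source` (`"reference"`, `"propagated"` or `"ambiguous"`), one row
#'   per leaf of the tree.
#' @export
propagate_clade_labels <- function(tree, reference) {
  stopifnot(inherits(tree, "phylo"),
            all(c("leaf_name", "label") %in% names(reference)))
  missing <- setdiff(reference$leaf_name, tree$tip.label)
  if (length(missing) > 0L) {
    stop("reference leaves absent from tree: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(reference$leaf_name)) stop("duplicated reference leaves")
  ntip <- length(tree$tip.label)
  ref_label <- stats::setNames(reference$label, reference$leaf_name)

  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  # reference labels present in each node's subtree, computed leaf-upward
  node_labels <- vector("list", ntip + tree$Nnode)
  tip_ref <- ref_label[tree$tip.label]
  for (i in seq_len(ntip)) {
    node_labels[[i]] <- if (!is.na(tip_ref[i])) tip_ref[[i]] else character()
  }
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1L]; ch <- po[e, 2L]
    node_labels[[p]] <- unique(c(node_labels[[p]], node_labels[[ch]]))
  }

  out_label <- character(ntip)
  out_source <- character(ntip)
  for (i in seq_len(ntip)) {
    if (!is.na(tip_ref[i])) {
      out_label[i] <- tip_ref[[i]]
      out_source[i] <- "reference"
      next
    }
    node <- i
    found <- FALSE
    while (parent[node] != 0L) {
      node <- parent[node]
      labs <- node_labels[[node]]
      if (length(labs) == 1L) {
        out_label[i] <- labs
        out_source[i] <- "propagated"
        found <- TRUE
        break
      }
      if (length(labs) > 1L) {
        out_label[i] <- NA_character_
        out_source[i] <- "ambiguous"
        found <- TRUE
        break
      }
    }
    if (!found) {
      out_label[i] <- NA_character_
      out_source[i] <- "ambiguous"
    }
  }
  data.frame(leaf_name = tree$tip.label, label = out_label,
             source = out_source, stringsAsFactors = FALSE)
}
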