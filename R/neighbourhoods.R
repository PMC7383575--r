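#' Extract genome neighbourhoods around target genes
#'
#' A genome neighbourhood (GN) is the window of genes extending `flank` genes
#' either side of a target gene along its scaffold, in gene-order (rank) space.
#' Windows are clipped at scaffold edges (flagged `truncated`), and windows on
#' the same scaffold whose rank intervals overlap or touch are merged
#' transitively into one larger GN carrying all of their target genes (flagged
#' `merged`). With the default flank of 5, an interior non-overlapping target
#' therefore yields an 11-gene neighbourhood.
#'
#' @param genome an [annotated_genome()].
#' @param target_gene_ids character vector of target gene ids (all must exist
#'   in the genome).
#' @param flank number of genes kept on each side of a target (default 5).
#' @param merge_adjacent merge windows that touch without overlapping
#'   (default `TRUE`).
#' @return list of `genome_neighbourhood` objects sorted by scaffold and
#'   window start. Each has fields `gn_id`, `genome_id`, `scaffold_id`,
#'   `center_gene_ids`, `member_gene_ids` (ordered by rank), `first_rank`,
#'   `last_rank`, `flank`, `merged`, `truncated`.
#' @export
extract_neighbourhoods <- function(genome, target_gene_ids, flank = 5L,
                                   merge_adjacent = TRUE) {
  stopifnot(is_annotated_genome(genome), flank >= 0L)
  genes <- genome$genes
  unknown <- setdiff(target_gene_ids, genes$gene_id)
  if (length(unknown) > 0L) {
    stop("unknown target gene(s): ", paste(unknown, collapse = ", "))
  }
  tg <- genes[match(target_gene_ids, genes$gene_id), , drop = FALSE]
  out <- list()
  for (scaf in sort(unique(tg$scaffold_id))) {
    scaf_genes <- genes[genes$scaffold_id == scaf, , drop = FALSE]
    scaf_genes <- scaf_genes[order(scaf_genes$rank), , drop = FALSE]
    max_rank <- max(scaf_genes$rank)
    tg_scaf <- tg[tg$scaffold_id == scaf, , drop = FALSE]
    tg_scaf <- tg_scaf[order(tg_scaf$rank), , drop = FALSE]
    lo <- tg_scaf$rank - flank
    hi <- tg_scaf$rank + flank
    # transitive merge of overlapping / touching rank intervals
    gap <- if (merge_adjacent) 1L else 0L
    grp <- cumsum(c(1L, as.integer(lo[-1L] > utils::head(cummax(hi), -1L) + gap)))
    for (g in unique(grp)) {
      sel <- grp == g
      w_lo <- min(lo[sel]); w_hi <- max(hi[sel])
      truncated <- w_lo < 0L || w_hi > max_rank
      w_lo <- max(w_lo, 0L); w_hi <- min(w_hi, max_rank)
      members <- scaf_genes$gene_id[scaf_genes$rank >= w_lo & scaf_genes$rank <= w_hi]
      gn <- structure(list(
        gn_id = sprintf("%s:%s:%d-%d", genome$genome_id, scaf, w_lo, w_hi),
        genome_id = genome$genome_id,
        scaffold_id = scaf,
        center_gene_ids = tg_scaf$gene_id[sel],
        member_gene_ids = members,
        first_rank = w_lo, last_rank = w_hi,
        flank = as.integer(flank),
        merged = sum(sel) > 1L,
        truncated = truncated), class = "genome_neighbourhood")
      out[[length(out) + 1L]] <- gn
    }
  }
  out
}

#' @export
print.genome_neighbourhood <- function(x, ...) {
  cat(sprintf("<genome_neighbourhood> %s: %d genes, %d target(s)%s%s\n",
              x$gn_id, length(x$member_gene_ids), length(x$center_gene_ids),
              if (x$merged) ", merged" else "",
              if (x$truncated) ", truncated" else ""))
  invisible(x)
}

#' Keep only neighbourhoods of at least a minimum size
#'
#' Truncated neighbourhoods on short scaffolds can be smaller than the nominal
#' window; similarity and ancestral-state analyses restrict to full-size
#' windows (>= 11 genes at the default flank of 5).
#'
#' @param gns list of `genome_neighbourhood`.
#' @param min_genes minimum member-gene count (default 11).
#' @return the qualifying subset, order preserved.
#' @export
filter_by_size <- function(gns, min_genes = 11L) {
  keep <- vapply(gns, function(gn) length(gn$member_gene_ids) >= min_genes, logical(1))
  if (!any(keep) && length(gns) > 0L) {
    warning("no neighbourhoods with >= ", min_genes, " genes")
  }
  gns[keep]
}

#' Does a neighbourhood qualify as a biosynthetic gene cluster?
#'
#' A biosynthetic gene cluster (BGC) is defined operationally as a
#' neighbourhood whose genes collectively carry enzymatic domains from at
#' least three distinct enzyme classes (for example scaffold-generating,
#' oxidising and acylating). The class of each enzymatic domain family is
#' supplied by `enzyme_class_map`; families absent from the map (non-enzymatic
#' domains) are ignored.
#'
#' @param gn a `genome_neighbourhood`.
#' @param hits domain-hit data.frame covering the genome.
#' @param enzyme_class_map named character vector mapping domain family ->
#'   enzyme class name.
#' @param min_classes number of distinct classes required (default 3).
#' @return `TRUE` if the neighbourhood qualifies.
#' @export
classify_bgc <- function(gn, hits, enzyme_class_map, min_classes = 3L) {
  hits <- hits[hits$gene_id %in% gn$member_gene_ids, , drop = FALSE]
  classes <- enzyme_class_map[hits$family]
  length(unique(classes[!is.na(classes)])) >= min_classes
}

#' Tabulate a list of neighbourhoods
#'
#' @param gns list of `genome_neighbourhood`.
#' @param hits optional pooled domain-hit table; when supplied together with
#'   `enzyme_class_map`, an `is_bgc` column is added.
#' @param enzyme_class_map optional mapping family -> enzyme class.
#' @return data.frame with one row per neighbourhood.
#' @export
gn_summary_table <- function(gns, hits = NULL, enzyme_class_map = NULL) {
  df <- data.frame(
    gn_id = vapply(gns, `[[`, "", "gn_id"),
    genome_id = vapply(gns, `[[`, "", "genome_id"),
    scaffold_id = vapply(gns, `[[`, "", "scaffold_id"),
    n_genes = vapply(gns, function(g) length(g$member_gene_ids), 0L),
    centers = vapply(gns, function(g) paste(g$center_gene_ids, collapse = ","), ""),
    merged = vapply(gns, `[[`, NA, "merged"),
    truncated = vapply(gns, `[[`, NA, "truncated"),
    stringsAsFactors = FALSE)
  if (!is.null(hits) && !is.null(enzyme_class_map)) {
    df$is_bgc <- vapply(gns, classify_bgc, NA, hits = hits,
                        enzyme_class_map = enzyme_class_map)
  }
  df
}
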