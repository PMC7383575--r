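#' Parse a domain-hit table
#'
#' The hit table is a minimal tab-separated format with a mandatory header
#' `gene_id  family  subfamily  score`, one row per domain hit. It is
#' deliberately decoupled from any particular search tool's output; users
#' converting HMMER `--domtblout` files should map target name to `gene_id`,
#' query name to `family`/`subfamily` and the full-sequence bit score to
#' `score`. An empty `subfamily` field means no subfamily-level annotation.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene_id`, `family`, `subfamily`, `score`.
#' @export
parse_domain_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = FALSE,
                           blank.lines.skip = FALSE)
  expected <- c("gene_id", "family", "subfamily", "score")
  if (!identical(names(raw), expected)) {
    stop("unexpected domain-table columns: ", paste(names(raw), collapse = ", "),
         " (expected ", paste(expected, collapse = ", "), ")")
  }
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(score) | !is.finite(score))
  if (length(bad) > 0L) {
    stop("non-numeric score in domain table at line ", bad[1L] + 1L,
         " (value '", raw$score[bad[1L]], "')")
  }
  validate_domain_hits(data.frame(gene_id = raw$gene_id, family = raw$family,
                                  subfamily = raw$subfamily, score = score,
                                  stringsAsFactors = FALSE))
}

#' Write a domain-hit table
#'
#' @param hits domain-hit data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(hits, path) {
  hits <- validate_domain_hits(hits)
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces the input contracts the
#' rest of the pipeline relies on: a single tree, unique leaf names, and branch
#' lengths (missing lengths default to 1).
#'
#' @param path path to a Newick file containing one tree.
#' @return an [ape::phylo] object with `edge.length` set.
#' @export
parse_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) {
    stop("unparseable Newick file ", path, ": ", conditionMessage(e))
  })
  if (is.null(tr)) stop("unparseable Newick file: ", path)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree in ", path)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf names in tree: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

#' Export protein sequences as FASTA
#'
#' Writes the translated genes of a genome (or a subset of them) for use by
#' the sequence-similarity stage. Genes without a translation are skipped.
#'
#' @param genome an `annotated_genome`.
#' @param path output path.
#' @param gene_ids optional subset of gene ids to export.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(genome, path, gene_ids = NULL) {
  stopifnot(is_annotated_genome(genome))
  genes <- genome$genes
  if (!is.null(gene_ids)) genes <- genes[genes$gene_id %in% gene_ids, , drop = FALSE]
  genes <- genes[!is.na(genes$protein), , drop = FALSE]
  aa <- Biostrings::AAStringSet(genes$protein)
  names(aa) <- genes$gene_id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
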