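#' Construct an annotated genome
#'
#' An annotated genome bundles a gene table (one row per protein-coding gene)
#' with a table of Pfam-style domain hits on those genes. Gene order along each
#' scaffold is captured by a 0-based `rank` column, recomputed here from the
#' start coordinates, so that all neighbourhood arithmetic downstream is done
#' in gene-order space rather than nucleotide space.
#'
#' @param genome_id single string identifying the genome.
#' @param genes data.frame with columns `gene_id`, `scaffold_id`, `start`,
#'   `end`, `strand` (+1/-1) and optionally `protein` (amino-acid string, `NA`
#'   when no translation is available).
#' @param hits data.frame of domain hits with columns `gene_id`, `family`,
#'   `subfamily`, `score`; may be empty.
#' @return An object of class `annotated_genome`: a list with elements
#'   `genome_id`, `genes` (with `rank` added, sorted by scaffold and start)
#'   and `hits`.
#' @export
annotated_genome <- function(genome_id, genes, hits = empty_domain_hits()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  required <- c("gene_id", "scaffold_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("gene table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"protein" %in% names(genes)) genes$protein <- NA_character_
  genes <- genes[, c(required, "protein")]
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (any(genes$start > genes$end)) {
    bad <- genes$gene_id[genes$start > genes$end][1L]
    stop("gene with start > end: ", bad)
  }
  if (!all(genes$strand %in% c(1L, -1L))) stop("strand must be +1 or -1")
  genes <- genes[order(genes$scaffold_id, genes$start, genes$gene_id), , drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$scaffold_id,
                           FUN = seq_along) - 1L
  rownames(genes) <- NULL
  hits <- validate_domain_hits(hits)
  unknown <- setdiff(hits$gene_id, genes$gene_id)
  if (length(unknown) > 0L) {
    stop("domain hits reference unknown genes: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  structure(list(genome_id = genome_id, genes = genes, hits = hits),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d genes on %d scaffold(s), %d domain hits\n",
              x$genome_id, nrow(x$genes), length(unique(x$genes$scaffold_id)),
              nrow(x$hits)))
  invisible(x)
}

#' @rdname annotated_genome
#' @param x object to test.
#' @export
is_annotated_genome <- function(x) inherits(x, "annotated_genome")

empty_domain_hits <- function() {
  data.frame(gene_id = character(), family = character(),
              subfamily = character(), score = numeric(),
              stringsAsFactors = FALSE)
}

validate_domain_hits <- function(hits) {
  required <- c("gene_id", "family", "subfamily", "score")
  missing_cols <- setdiff(required, names(hits))
  if (length(missing_cols) > 0L) {
    stop("domain-hit table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  hits <- hits[, required, drop = FALSE]
  hits$subfamily[is.na(hits$subfamily)] <- ""
  if (nrow(hits) > 0L && any(!is.finite(hits$score))) {
    stop("non-finite domain-hit score at row ",
         which(!is.finite(hits$score))[1L])
  }
  rownames(hits) <- NULL
  hits
}

#' Attach domain hits to a genome
#'
#' @param genome an `annotated_genome`.
#' @param hits a domain-hit data.frame (see [parse_domain_table()]).
#' @return The genome with `hits` replaced.
#' @export
set_domain_hits <- function(genome, hits) {
  stopifnot(is_annotated_genome(genome))
  annotated_genome(genome$genome_id, genome$genes, hits)
}

#' Pool the gene tables of several genomes
#'
#' @param genomes list of `annotated_genome` objects.
#' @return data.frame of all genes with a `genome_id` column prepended.
#' @export
pooled_gene_table <- function(genomes) {
  stopifnot(length(genomes) > 0L)
  tabs <- lapply(genomes, function(g) {
    stopifnot(is_annotated_genome(g))
    cbind(genome_id = g$genome_id, g$genes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Pool the domain-hit tables of several genomes
#'
#' @inheritParams pooled_gene_table
#' @return data.frame of all hits with a `genome_id` column prepended.
#' @export
pooled_hit_table <- function(genomes) {
  stopifnot(length(genomes) > 0L)
  tabs <- lapply(genomes, function(g) {
    if (nrow(g$hits) == 0L) return(NULL)
    cbind(genome_id = g$genome_id, g$hits, stringsAsFactors = FALSE)
  })
  tabs <- Filter(Negate(is.null), tabs)
  if (length(tabs) == 0L) {
    return(cbind(genome_id = character(), empty_domain_hits()))
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Domain label at a chosen annotation level
#'
#' At `"family"` level the label is the Pfam-style family name; at
#' `"subfamily"` level the subfamily name is used where one is annotated and
#' the family name is kept as a fallback for hits without a subfamily, so the
#' labelling is total over all hits.
#'
#' @param hits domain-hit data.frame.
#' @param level `"family"` or `"subfamily"`.
#' @return character vector of labels, one per hit row.
#' @export
domain_label <- function(hits, level = c("family", "subfamily")) {
  level <- match.arg(level)
  if (level == "family") return(hits$family)
  ifelse(is.na(hits$subfamily) | hits$subfamily == "", hits$family, hits$subfamily)
}
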