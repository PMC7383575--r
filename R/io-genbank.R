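#' Parse a GenBank flat file into an annotated genome
#'
#' Reads the CDS features of a (possibly multi-record) GenBank flat file. Each
#' LOCUS record is treated as one scaffold; each CDS becomes one gene. Gene
#' identifiers are taken from the first of `/locus_tag`, `/gene`,
#' `/protein_id`; a CDS carrying none of these is an error. Compound
#' (`join`/`order`) locations are reduced to their minimum start and maximum
#' end, since only gene order matters downstream, and `complement(...)`
#' determines the strand. `/translation` qualifiers, when present, populate the
#' protein column.
#'
#' @param path path to a GenBank flat file.
#' @param genome_id identifier to assign; defaults to the ACCESSION (or LOCUS
#'   name) of the first record.
#' @return An [annotated_genome()] with empty domain hits.
#' @export
parse_genbank <- function(path, genome_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  recs <- split_genbank_records(lines)
  if (length(recs) == 0L) stop("no records in GenBank file: ", path)
  gene_rows <- list()
  first_id <- NULL
  for (rec in recs) {
    locus_line <- grep("^LOCUS", rec, value = TRUE)
    if (length(locus_line) == 0L) stop("GenBank record without LOCUS line")
    scaffold_id <- strsplit(trimws(sub("^LOCUS", "", locus_line[1L])), "\\s+")[[1L]][1L]
    acc_line <- grep("^ACCESSION", rec, value = TRUE)
    rec_id <- if (length(acc_line) > 0L) {
      trimws(sub("^ACCESSION", "", acc_line[1L]))
    } else scaffold_id
    if (is.null(first_id) && nzchar(rec_id)) first_id <- rec_id
    for (feat in genbank_cds_features(rec, scaffold_id)) {
      gene_rows[[length(gene_rows) + 1L]] <- feat
    }
  }
  if (length(gene_rows) == 0L) stop("no CDS features in GenBank file: ", path)
  genes <- do.call(rbind, gene_rows)
  if (is.null(genome_id)) genome_id <- first_id
  annotated_genome(genome_id, genes)
}

split_genbank_records <- function(lines) {
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) return(list())
  ends <- grep("^//\\s*$", lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  if (length(ends) == 0L) { starts <- 1L; ends <- length(lines) }
  Map(function(s, e) lines[s:e], starts, ends)
}

# Extract CDS features of one record as one-row data.frames.
genbank_cds_features <- function(rec, scaffold_id) {
  fstart <- grep("^FEATURES", rec)
  if (length(fstart) == 0L) return(list())
  body_end <- grep("^(ORIGIN|CONTIG|BASE COUNT)", rec)
  body_end <- if (length(body_end) > 0L) min(body_end) - 1L else length(rec)
  if (body_end <= fstart[1L]) return(list())
  body <- rec[(fstart[1L] + 1L):body_end]

  # feature starts: a non-blank key in columns 6-20
  is_key <- grepl("^ {5}\\S", body)
  key_idx <- which(is_key)
  if (length(key_idx) == 0L) return(list())
  keys <- vapply(body[key_idx], function(l) strsplit(trimws(l), "\\s+")[[1L]][1L], "")
  out <- list()
  for (i in seq_along(key_idx)) {
    if (keys[i] != "CDS") next
    from <- key_idx[i]
    to <- if (i < length(key_idx)) key_idx[i + 1L] - 1L else length(body)
    chunk <- body[from:to]
    feat <- parse_cds_chunk(chunk, scaffold_id)
    out[[length(out) + 1L]] <- feat
  }
  out
}

parse_cds_chunk <- function(chunk, scaffold_id) {
  txt <- trimws(chunk)
  qual_start <- grep("^/", txt[-1L])
  loc_lines <- if (length(qual_start) > 0L) {
    c(sub("^\\S+\\s+", "", txt[1L]), txt[seq_len(min(qual_start) - 1L)][-1L])
  } else {
    c(sub("^\\S+\\s+", "", txt[1L]), txt[-1L])
  }
  loc <- paste(loc_lines, collapse = "")
  strand <- if (grepl("complement", loc)) -1L else 1L
  nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
  if (length(nums) == 0L) stop("CDS with unparseable location: ", loc)
  rest <- txt[-1L]
  qual_lines <- if (length(qual_start) > 0L) {
    rest[min(qual_start):length(rest)]
  } else character()
  quals <- parse_qualifiers(qual_lines)
  gene_id <- quals[["locus_tag"]] %||% quals[["gene"]] %||% quals[["protein_id"]]
  if (is.null(gene_id)) {
    stop("CDS at ", loc, " on ", scaffold_id,
         " has no locus_tag/gene/protein_id qualifier")
  }
  protein <- quals[["translation"]] %||% NA_character_
  data.frame(gene_id = gene_id, scaffold_id = scaffold_id,
             start = as.integer(min(nums)), end = as.integer(max(nums)),
             strand = strand, protein = protein, stringsAsFactors = FALSE)
}

# Qualifier lines -> named list; multi-line quoted values are concatenated
# without separators (GenBank wraps translations mid-word).
parse_qualifiers <- function(lines) {
  quals <- list()
  cur_name <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_name) && is.null(quals[[cur_name]])) {
      quals[[cur_name]] <<- gsub("\"", "", cur_val)
    }
  }
  for (l in lines) {
    if (grepl("^/", l)) {
      flush()
      if (grepl("=", l)) {
        cur_name <- sub("^/([^=]+)=.*$", "\\1", l)
        cur_val <- sub("^/[^=]+=", "", l)
      } else {
        cur_name <- sub("^/", "", l)
        cur_val <- "TRUE"
      }
    } else if (!is.null(cur_name)) {
      cur_val <- paste0(cur_val, l)
    }
  }
  flush()
  quals
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a genome neighbourhood as a GenBank record
#'
#' Exports the member genes of one neighbourhood as a single-record GenBank
#' flat file. Coordinates are shifted so the window starts at base 1;
#' re-parsing the file with [parse_genbank()] recovers the same gene ids in
#' the same order with the same strands.
#'
#' @param gn a `genome_neighbourhood` (see [extract_neighbourhoods()]).
#' @param genome the `annotated_genome` the neighbourhood was extracted from.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_neighbourhood_genbank <- function(gn, genome, path) {
  stopifnot(inherits(gn, "genome_neighbourhood"), is_annotated_genome(genome))
  genes <- genome$genes[match(gn$member_gene_ids, genome$genes$gene_id), , drop = FALSE]
  if (anyNA(genes$gene_id)) {
    stop("neighbourhood references genes absent from genome: ",
         paste(setdiff(gn$member_gene_ids, genome$genes$gene_id), collapse = ", "))
  }
  offset <- min(genes$start) - 1L
  genes$start <- genes$start - offset
  genes$end <- genes$end - offset
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  locus_name <- gsub("[^A-Za-z0-9_.-]", "_", gn$gn_id)
  definition <- sprintf("genome neighbourhood %s from genome %s scaffold %s.",
                        gn$gn_id, gn$genome_id, gn$scaffold_id)
  write_genbank_record(con, locus_name, genes,
                       centers = gn$center_gene_ids, definition = definition)
  invisible(path)
}

#' Write a whole annotated genome as a multi-record GenBank flat file
#'
#' One LOCUS record per scaffold, one CDS feature per gene;
#' [parse_genbank()] round-trips the result.
#'
#' @param genome an [annotated_genome()].
#' @param path output file path.
#' @param centers optional gene ids to flag as target genes.
#' @return `path`, invisibly.
#' @export
write_genome_genbank <- function(genome, path, centers = character()) {
  stopifnot(is_annotated_genome(genome))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (scaf in sort(unique(genome$genes$scaffold_id))) {
    genes <- genome$genes[genome$genes$scaffold_id == scaf, , drop = FALSE]
    definition <- sprintf("scaffold %s of synthetic genome %s.",
                          scaf, genome$genome_id)
    write_genbank_record(con, scaf, genes, centers = centers,
                         definition = definition)
  }
  invisible(path)
}

write_genbank_record <- function(con, locus_name, genes, centers = character(),
                                 definition = "") {
  span <- max(genes$end)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   UNA 01-JAN-2000",
                     locus_name, span), con)
  if (nzchar(definition)) writeLines(paste0("DEFINITION  ", definition), con)
  writeLines(sprintf("ACCESSION   %s", locus_name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", span), con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    loc <- sprintf("%d..%d", g$start, g$end)
    if (g$strand == -1L) loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", g$gene_id), con)
    if (g$gene_id %in% centers) {
      writeLines("                     /note=\"neighbourhood target gene\"", con)
    }
    if (!is.na(g$protein)) {
      writeLines(wrap_qualifier("translation", g$protein), con)
    }
  }
  writeLines("ORIGIN", con)
  writeLines("//", con)
}

wrap_qualifier <- function(name, value, width = 58L) {
  first <- sprintf("                     /%s=\"", name)
  txt <- paste0(value, "\"")
  avail1 <- 79L - nchar(first)
  pieces <- character()
  take <- substr(txt, 1L, avail1)
  pieces <- paste0(first, take)
  rest <- substr(txt, avail1 + 1L, nchar(txt))
  while (nchar(rest) > 0L) {
    take <- substr(rest, 1L, width)
    pieces <- c(pieces, paste0("                     ", take))
    rest <- substr(rest, nchar(take) + 1L, nchar(rest))
  }
  pieces
}
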