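# In-code fixtures shared across test files.

# deterministic little genome: one or more scaffolds of evenly spaced genes
make_test_genome <- function(genome_id = "TG1", scaffold_sizes = c(s1 = 30),
                             protein = function(i) strrep("M", 10)) {
  rows <- list()
  for (scaf in names(scaffold_sizes)) {
    n <- scaffold_sizes[[scaf]]
    ids <- sprintf("%s_%s_g%02d", genome_id, scaf, seq_len(n))
    rows[[scaf]] <- data.frame(
      gene_id = ids, scaffold_id = scaf,
      start = (seq_len(n) - 1L) * 1000L + 1L,
      end = (seq_len(n) - 1L) * 1000L + 800L,
      strand = rep_len(c(1L, -1L), n),
      protein = vapply(seq_len(n), protein, ""),
      stringsAsFactors = FALSE)
  }
  annotated_genome(genome_id, do.call(rbind, rows))
}

# hand-written GenBank flat file, independent of the package's writer
write_handmade_genbank <- function(path) {
  lines <- c(
    "LOCUS       chr1 5200 bp    DNA     linear   PLN 01-JAN-2000",
    "DEFINITION  hand-written two-scaffold test genome.",
    "ACCESSION   ACC001",
    "FEATURES             Location/Qualifiers",
    "     source          1..5200",
    "     CDS             101..400",
    "                     /locus_tag=\"h1\"",
    "                     /translation=\"MKLV\"",
    "     CDS             complement(501..900)",
    "                     /locus_tag=\"h2\"",
    "                     /translation=\"MAACDEFGHIKLMNPQRSTVWYAACDEFGHIKLMNPQRSTVWYAACD",
    "                     EFGHIKLMNPQRSTVWY\"",
    "     CDS             join(1001..1200,1301..1500)",
    "                     /locus_tag=\"h3\"",
    "                     /note=\"compound location\"",
    "     CDS             2001..2400",
    "                     /gene=\"h4\"",
    "                     /translation=\"MSTV\"",
    "     CDS             complement(join(3001..3200,3301..3400))",
    "                     /locus_tag=\"h5\"",
    "ORIGIN",
    "//",
    "LOCUS       chr2 2600 bp    DNA     linear   PLN 01-JAN-2000",
    "ACCESSION   ACC002",
    "FEATURES             Location/Qualifiers",
    "     source          1..2600",
    "     CDS             201..400",
    "                     /locus_tag=\"h6\"",
    "     CDS             complement(801..1000)",
    "                     /locus_tag=\"h7\"",
    "     CDS             1501..1900",
    "                     /locus_tag=\"h8\"",
    "                     /translation=\"MGGA\"",
    "ORIGIN",
    "//")
  writeLines(lines, path)
  path
}

# random gene table for property tests
random_gene_table <- function(n, n_scaffolds = 2) {
  data.frame(
    gene_id = sprintf("r%03d", seq_len(n)),
    scaffold_id = sample(sprintf("sc%d", seq_len(n_scaffolds)), n, replace = TRUE),
    start = sample.int(1e6, n),
    end = integer(n),
    strand = sample(c(1L, -1L), n, replace = TRUE),
    stringsAsFactors = FALSE) -> df
  df$end <- df$start + sample.int(500, n)
  df
}

# random rooted binary tree (via ape) with named tips
random_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$tip.label <- sprintf("L%02d", seq_len(n_tips))
  tr
}

# quick domain-copy profile literal
make_profile <- function(gn_id, copies) {
  structure(list(gn_id = gn_id, families = sort(names(copies)),
                 copies = lapply(copies, function(g) {
                   data.frame(gene_id = names(g), protein = unname(g),
                              stringsAsFactors = FALSE)
                 })[sort(names(copies))]),
            class = "domain_copy_profile")
}
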