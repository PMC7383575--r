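#!/usr/bin/env Rscript
# Step 2: extract genome neighbourhoods (five genes either side of each
# target), merge overlapping windows, and classify which neighbourhoods
# qualify as biosynthetic gene clusters (>= 3 distinct enzyme classes).

suppressMessages(library(gnevol))

data_dir <- "results/data"
out_dir <- "results/analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

targets <- read.table(file.path(data_dir, "targets.tsv"), sep = "\t",
                      header = TRUE, colClasses = "character")
hits <- parse_domain_table(file.path(data_dir, "domain_hits.tsv"))
genome_paths <- list.files(file.path(data_dir, "genomes"), full.names = TRUE)
genomes <- lapply(genome_paths, function(p) {
  parse_genbank(p, genome_id = tools::file_path_sans_ext(basename(p)))
})

gns <- list()
for (g in genomes) {
  tg <- targets$gene_id[targets$genome_id == g$genome_id]
  gns <- c(gns, extract_neighbourhoods(g, tg, flank = 5))
}

enzyme_classes <- c(SQHop_cyclase = "scaffold_generating",
                    p450 = "oxidising", Transferase = "acylating",
                    CYP708A = "oxidising",
                    UDPGT = "glycosylating", Methyltransf_2 = "methylating")
summary_tab <- gn_summary_table(gns, hits = hits,
                                enzyme_class_map = enzyme_classes)
write.table(summary_tab, file.path(out_dir, "neighbourhoods.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Extracted", nrow(summary_tab), "neighbourhoods;",
    sum(summary_tab$n_genes >= 11), "with >= 11 genes;",
    sum(summary_tab$is_bgc), "meet the BGC definition",
    sprintf("(%.0f%%)\n", 100 * mean(summary_tab$is_bgc)))
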