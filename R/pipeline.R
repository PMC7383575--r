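#' Assemble a pipeline configuration
#'
#' Validates the inputs and parameters of an end-to-end run. Defaults follow
#' the standard neighbourhood analysis: flank 5 (11-gene windows), minimum
#' neighbourhood size 11, significance threshold 0.01 on Bonferroni-adjusted
#' p-values.
#'
#' @param genome_paths character vector of GenBank genome files.
#' @param domain_table path to the pooled domain-hit TSV.
#' @param tree path to the Newick target-gene tree.
#' @param targets path to a TSV with columns `genome_id`, `gene_id` (target
#'   genes) and optionally `clade`.
#' @param reference_labels optional path to a TSV with columns `leaf_name`,
#'   `label`; clade labels are propagated over the tree from these leaves
#'   when the targets file carries no `clade` column.
#' @param whitelist optional path to a text file of admissible domain labels
#'   (one per line) for the similarity stage.
#' @param out_dir output directory.
#' @param flank,min_genes,level,threshold stage parameters (see
#'   [extract_neighbourhoods()], [filter_by_size()], [run_enrichment()]).
#' @param analysis_clade clade analysed by the similarity and ancestral
#'   stages; default, the clade with most neighbourhoods.
#' @param trait_domains domains reconstructed on the tree; default, every
#'   domain significantly enriched (conservative mode) in the analysis clade.
#' @param outgroup optional outgroup leaf for rooting.
#' @param gap_opening,gap_extension alignment parameters.
#' @param seed seed for any stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_paths, domain_table, tree, targets,
                            reference_labels = NULL, whitelist = NULL,
                            out_dir = "gnevol_out", flank = 5L,
                            min_genes = 11L,
                            level = c("subfamily", "family"),
                            threshold = 0.01, analysis_clade = NULL,
                            trait_domains = NULL, outgroup = NULL,
                            gap_opening = 10, gap_extension = 0.5,
                            seed = 1L) {
  level <- match.arg(level)
  paths <- c(genome_paths, domain_table, tree, targets, reference_labels,
             whitelist)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("missing input files: ", paste(missing, collapse = ", "))
  }
  structure(as.list(environment())[setdiff(ls(), c("paths", "missing"))],
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full neighbourhood-evolution pipeline
#'
#' Executes every stage in order: genome and input loading, neighbourhood
#' extraction and merging, clade-label propagation, domain enrichment (naive
#' and conservative, both levels' counting at the configured level),
#' all-vs-all similarity of the analysis clade's full-size neighbourhoods,
#' representative-leaf selection, pruning, maximum-parsimony ancestral
#' reconstruction and gain/loss event mapping. Each stage's table is written
#' under `out_dir` along with a run manifest and a plain-text report whose
#' bookkeeping identities (total pairs = n(n-1)/2, shared + unshared = total)
#' hold exactly. A failure in any stage aborts with the stage name and leaves
#' a `FAILED` marker file.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the main in-memory results: `gns`,
#'   `labels`, `enrichment`, `similarity`, `representatives`, `pruned_tree`,
#'   `reconstruction`, `report` (named list of the report's numbers).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  stage <- "load_inputs"
  result <- tryCatch({
    set.seed(config$seed)
    genomes <- lapply(config$genome_paths, function(p) {
      parse_genbank(p, genome_id = tools::file_path_sans_ext(basename(p)))
    })
    hits <- parse_domain_table(config$domain_table)
    tree <- parse_newick(config$tree)
    targets <- utils::read.table(config$targets, sep = "\t", header = TRUE,
                                 colClasses = "character")
    gene_to_genome <- stats::setNames(
      rep(vapply(genomes, `[[`, "", "genome_id"),
          vapply(genomes, function(g) nrow(g$genes), 0L)),
      unlist(lapply(genomes, function(g) g$genes$gene_id)))
    genomes <- lapply(genomes, function(g) {
      set_domain_hits(g, hits[gene_to_genome[hits$gene_id] == g$genome_id, ,
                              drop = FALSE])
    })
    names(genomes) <- vapply(genomes, `[[`, "", "genome_id")

    stage <- "clade_labels"
    if ("clade" %in% names(targets)) {
      labels <- data.frame(leaf_name = targets$gene_id, label = targets$clade,
                           source = "reference", stringsAsFactors = FALSE)
    } else {
      if (is.null(config$reference_labels)) {
        stop("targets file has no clade column and no reference_labels given")
      }
      ref <- utils::read.table(config$reference_labels, sep = "\t",
                               header = TRUE, colClasses = "character")
      labels <- propagate_clade_labels(tree, ref)
    }
    write_tsv(labels, file.path(out, "clade_labels.tsv"))

    stage <- "extract_neighbourhoods"
    gns <- list()
    for (gid in names(genomes)) {
      tg <- targets$gene_id[targets$genome_id == gid]
      if (length(tg) == 0L) next
      gns <- c(gns, extract_neighbourhoods(genomes[[gid]], tg,
                                           flank = config$flank))
    }
    leaf_to_gn <- character()
    for (gn in gns) {
      leaf_to_gn[gn$center_gene_ids] <- gn$gn_id
    }
    clade_of_leaf <- stats::setNames(labels$label, labels$leaf_name)
    gn_ids <- vapply(gns, `[[`, "", "gn_id")
    gns_by_clade <- list()
    for (gn in gns) {
      for (cl in unique(clade_of_leaf[gn$center_gene_ids])) {
        if (is.na(cl)) next
        gns_by_clade[[cl]] <- c(gns_by_clade[[cl]], list(gn))
      }
    }
    write_tsv(gn_summary_table(gns), file.path(out, "neighbourhoods.tsv"))

    stage <- "enrichment"
    enr <- list()
    for (mode in c("naive", "conservative")) {
      enr[[mode]] <- run_enrichment(genomes, gns_by_clade, tree = tree,
                                    leaf_to_gn = leaf_to_gn,
                                    level = config$level, mode = mode,
                                    threshold = config$threshold)
    }
    enrichment <- rbind(enr$naive, enr$conservative)
    write_tsv(enrichment, file.path(out, "enrichment.tsv"))

    stage <- "similarity"
    clade_sizes <- vapply(gns_by_clade, length, 0L)
    analysis_clade <- config$analysis_clade %||%
      names(clade_sizes)[which.max(clade_sizes)]
    whitelist <- if (!is.null(config$whitelist)) {
      readLines(config$whitelist, warn = FALSE)
    } else NULL
    ava <- all_vs_all(gns_by_clade[[analysis_clade]], genomes,
                      whitelist = whitelist, min_genes = config$min_genes,
                      level = config$level,
                      gap_opening = config$gap_opening,
                      gap_extension = config$gap_extension)
    write_tsv(ava$pairs, file.path(out, "pairwise_similarity.tsv"))
    write_tsv(data.frame(metric = names(ava$summary),
                         count = as.numeric(ava$summary)),
              file.path(out, "pair_summary.tsv"))

    stage <- "ancestral"
    clade_leaves <- labels$leaf_name[!is.na(labels$label) &
                                       labels$label == analysis_clade]
    clade_tree <- if (length(clade_leaves) >= 2L &&
                        length(clade_leaves) < length(tree$tip.label)) {
      ape::keep.tip(tree, clade_leaves)
    } else tree
    clade_tree <- root_tree(clade_tree, config$outgroup)
    pruned <- prune_for_reconstruction(clade_tree, leaf_to_gn, gns,
                                       min_genes = config$min_genes)
    dss_mat <- pairs_to_matrix(ava$pairs, "dss")
    retained <- select_representative_leaves(pruned, leaf_to_gn, dss_mat)
    pruned <- if (length(retained) < length(pruned$tip.label)) {
      ape::keep.tip(pruned, retained)
    } else pruned
    trait_domains <- config$trait_domains
    if (is.null(trait_domains)) {
      # default: the most abundant non-target domains across the analysis
      # clade's neighbourhoods (by number of leaves carrying them)
      clade_gns <- gns_by_clade[[analysis_clade]]
      clade_hits <- do.call(rbind, lapply(clade_gns, function(gn) {
        g <- genomes[[gn$genome_id]]
        h <- g$hits[g$hits$gene_id %in% gn$member_gene_ids, , drop = FALSE]
        if (nrow(h) == 0L) return(NULL)
        data.frame(gn_id = gn$gn_id, label = domain_label(h, config$level),
                   stringsAsFactors = FALSE)
      }))
      cand <- table(unique(clade_hits)[["label"]])
      cand <- cand[!names(cand) %in%
                     unique(hits$family[hits$gene_id %in% targets$gene_id])]
      cand <- cand[cand >= 2L]
      cand <- cand[order(-cand, names(cand))]
      trait_domains <- utils::head(names(cand), 4L)
    }
    reconstruction <- NULL
    events_tab <- NULL
    if (length(trait_domains) > 0L) {
      traits <- trait_matrix(pruned$tip.label, leaf_to_gn, gns,
                             unname(genomes), trait_domains,
                             level = config$level)
      reconstruction <- reconstruct_all_domains(pruned, traits)
      events_tab <- do.call(rbind, lapply(names(reconstruction), function(d) {
        cbind(domain = d, reconstruction[[d]]$events$events,
              stringsAsFactors = FALSE)
      }))
      write_tsv(events_tab, file.path(out, "ancestral_events.tsv"))
    }

    stage <- "report"
    n_ret <- length(unique(leaf_to_gn[pruned$tip.label]))
    s <- ava$summary
    report <- list(
      n_genomes = length(genomes),
      n_targets = nrow(targets),
      n_neighbourhoods = length(gns),
      n_full_size = length(filter_by_size(gns, config$min_genes)),
      analysis_clade = analysis_clade,
      n_retained_leaves = length(pruned$tip.label),
      n_retained_gns = n_ret,
      total_pairs = unname(s["total_pairs"]),
      no_shared_pairs = unname(s["no_shared"]),
      shared_pairs = unname(s["shared"]),
      jaccard_ge_0.5 = unname(s["jaccard_ge_0.5"]),
      identity_lt_50 = unname(s["identity_lt_50"]),
      dss_le_0.3 = unname(s["dss_le_0.3"]),
      n_significant_conservative = sum(enr$conservative$significant),
      n_significant_naive = sum(enr$naive$significant),
      trait_domains = paste(trait_domains, collapse = ","),
      total_events = if (!is.null(reconstruction)) {
        sum(vapply(reconstruction, function(r) r$fit$score, 0L))
      } else 0L,
      seed = config$seed)
    n_compared <- length(ava$profiles)
    stopifnot(report$total_pairs == choose(n_compared, 2),
              report$no_shared_pairs + report$shared_pairs == report$total_pairs)
    report_lines <- sprintf("%s\t%s", names(report),
                            vapply(report, as.character, ""))
    writeLines(report_lines, file.path(out, "report.tsv"))

    manifest <- list(package = "gnevol",
                     version = as.character(utils::packageVersion("gnevol")),
                     parameters = config[c("flank", "min_genes", "level",
                                           "threshold", "gap_opening",
                                           "gap_extension", "seed")])
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))

    list(gns = gns, labels = labels, enrichment = enrichment,
         similarity = ava, representatives = retained, pruned_tree = pruned,
         reconstruction = reconstruction, report = report)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               failed_marker)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
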