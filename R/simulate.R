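AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a Yule gene tree
#'
#' Pure-birth (Yule) tree with unit birth rate, as a neutral scaffold for
#' trait and sequence simulation. Deterministic for a given seed.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed optional integer seed.
#' @param leaf_names optional character vector of `n_leaves` names.
#' @return an [ape::phylo] tree with branch lengths.
#' @export
simulate_tree <- function(n_leaves, seed = NULL, leaf_names = NULL) {
  if (n_leaves < 2L) stop("need at least 2 leaves")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_leaves, birth = 1, death = 0)
  if (!is.null(leaf_names)) {
    stopifnot(length(leaf_names) == n_leaves)
    tr$tip.label <- leaf_names
  }
  tr
}

#' Simulate a tree with guaranteed monophyletic clades
#'
#' One Yule subtree per clade, joined under a common root by unit-length
#' stems, so each named clade is monophyletic by construction — the structure
#' the clade-wise enrichment and conservative collapsing assume.
#'
#' @param clade_sizes named integer vector: clade name -> number of leaves
#'   (each >= 2).
#' @param seed optional integer seed.
#' @param leaf_names optional list: clade name -> leaf names.
#' @return list: `tree` ([ape::phylo]) and `clade_of` (named character,
#'   leaf -> clade).
#' @export
simulate_clade_tree <- function(clade_sizes, seed = NULL, leaf_names = NULL) {
  stopifnot(!is.null(names(clade_sizes)), all(clade_sizes >= 2L),
            length(clade_sizes) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  subtrees <- list()
  for (cl in names(clade_sizes)) {
    sub <- ape::rphylo(clade_sizes[[cl]], birth = 1, death = 0)
    nm <- if (!is.null(leaf_names)) leaf_names[[cl]] else
      sprintf("%s_t%02d", cl, seq_len(clade_sizes[[cl]]))
    stopifnot(length(nm) == clade_sizes[[cl]])
    sub$tip.label <- nm
    subtrees[[cl]] <- sub
  }
  if (length(subtrees) == 1L) {
    tree <- subtrees[[1L]]
  } else {
    # join the clade subtrees under one root with unit-length stems
    stems <- vapply(subtrees, function(s) {
      sub("; *$", "", ape::write.tree(s))
    }, "")
    tree <- ape::read.tree(text = paste0(
      "(", paste0(stems, ":1", collapse = ","), ");"))
  }
  clade_of <- rep(names(clade_sizes),
                  times = vapply(subtrees, function(s) length(s$tip.label), 0L))
  names(clade_of) <- unlist(lapply(subtrees, `[[`, "tip.label"))
  list(tree = tree, clade_of = clade_of[tree$tip.label])
}

#' Evolve a binary trait along a tree
#'
#' Two-state continuous-time Markov chain simulated branch by branch with
#' exponential waiting times, so every realised gain (0 to 1) and loss
#' (1 to 0) event is recorded. Over a branch of length `t` the transition
#' probability follows the closed form
#' `P(0 -> 1; t) = gain/(gain+loss) * (1 - exp(-(gain+loss) t))`
#' (see [trait_transition_prob()]).
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param gain_rate,loss_rate event rates per unit branch length (>= 0).
#' @param root_state state at the root (0 or 1).
#' @param seed optional integer seed.
#' @return list: `leaf_states` (named 0/1), `node_states` (0/1 per node
#'   number), `events` (data.frame `parent`, `child`, `from`, `to`, `time`)
#'   and `n_events`.
#' @export
evolve_binary_trait <- function(tree, gain_rate, loss_rate, root_state = 0L,
                                seed = NULL) {
  stopifnot(gain_rate >= 0, loss_rate >= 0, root_state %in% c(0L, 1L))
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  state <- integer(nnode)
  state[root] <- root_state
  pre <- ape::reorder.phylo(tree, "cladewise")$edge  # parents precede children
  elen <- tree$edge.length[match(paste(pre[, 1L], pre[, 2L]),
                                 paste(tree$edge[, 1L], tree$edge[, 2L]))]
  ev <- list()
  for (e in seq_len(nrow(pre))) {
    s <- state[pre[e, 1L]]
    t_left <- elen[e]
    repeat {
      rate <- if (s == 0L) gain_rate else loss_rate
      if (rate == 0) break
      w <- stats::rexp(1L, rate)
      if (w >= t_left) break
      t_left <- t_left - w
      ev[[length(ev) + 1L]] <- data.frame(
        parent = pre[e, 1L], child = pre[e, 2L], from = s, to = 1L - s,
        time = elen[e] - t_left)
      s <- 1L - s
    }
    state[pre[e, 2L]] <- s
  }
  events <- if (length(ev) > 0L) do.call(rbind, ev) else
    data.frame(parent = integer(), child = integer(), from = integer(),
               to = integer(), time = numeric())
  list(leaf_states = stats::setNames(state[seq_len(ntip)], tree$tip.label),
       node_states = state, events = events, n_events = nrow(events))
}

#' Closed-form transition probability of the binary-trait chain
#'
#' @param t branch length.
#' @param gain_rate,loss_rate chain rates.
#' @param from starting state (0 or 1).
#' @return probability of ending in the opposite state after time `t`.
#' @export
trait_transition_prob <- function(t, gain_rate, loss_rate, from = 0L) {
  s <- gain_rate + loss_rate
  if (s == 0) return(0)
  if (from == 0L) gain_rate / s * (1 - exp(-s * t))
  else loss_rate / s * (1 - exp(-s * t))
}

#' Simulate a protein family along a tree
#'
#' The root sequence is uniform over the 20 standard residues; along each
#' branch of length `t`, each site substitutes with probability
#' `1 - exp(-rate * t)` to a residue drawn uniformly from the other 19.
#' Expected leaf-pair identity follows the 20-state equal-rates closed form
#' of [expected_protein_identity()] over the patristic path.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param length protein length (>= 1).
#' @param rate expected substitutions per site per unit branch length.
#' @param seed optional integer seed.
#' @return named character vector of leaf sequences.
#' @export
simulate_protein_family <- function(tree, length, rate, seed = NULL) {
  stopifnot(length >= 1L, rate >= 0)
  nsites <- length
  rm(length)                            # unshadow base::length
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  seqs <- vector("list", nnode)
  seqs[[root]] <- sample(AA20, nsites, replace = TRUE)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- tree$edge.length[match(paste(pre[, 1L], pre[, 2L]),
                                 paste(tree$edge[, 1L], tree$edge[, 2L]))]
  for (e in seq_len(nrow(pre))) {
    sq <- seqs[[pre[e, 1L]]]
    p_sub <- 1 - exp(-rate * elen[e])
    hit <- stats::runif(nsites) < p_sub
    if (any(hit)) {
      for (i in which(hit)) {
        sq[i] <- sample(setdiff(AA20, sq[i]), 1L)
      }
    }
    seqs[[pre[e, 2L]]] <- sq
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), "")
  names(out) <- tree$tip.label
  out
}

#' Expected identity between two simulated leaves
#'
#' Under the per-branch substitution scheme of [simulate_protein_family()],
#' each branch contributes a factor `q(t) = (20 exp(-rate t) - 1) / 19` to
#' the site-level "no net change" probability, and the probability that two
#' leaves share a site's residue is `q + (1 - q)/20` with `q` the product of
#' the factors along the path joining them.
#'
#' @param tree the tree the family was simulated on.
#' @param rate the substitution rate used.
#' @param tip_a,tip_b leaf names.
#' @return expected fractional identity in `[1/20, 1]`.
#' @export
expected_protein_identity <- function(tree, rate, tip_a, tip_b) {
  ia <- match(tip_a, tree$tip.label)
  ib <- match(tip_b, tree$tip.label)
  stopifnot(!is.na(ia), !is.na(ib))
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  blen <- numeric(ntip + tree$Nnode)
  blen[tree$edge[, 2L]] <- tree$edge.length
  path_up <- function(i) {
    anc <- i; node <- i
    while (parent[node] != 0L) { node <- parent[node]; anc <- c(anc, node) }
    anc
  }
  pa <- path_up(ia); pb <- path_up(ib)
  mrca <- pa[min(which(pa %in% pb))]
  branches <- c(pa[seq_len(which(pa == mrca) - 1L)],
                pb[seq_len(which(pb == mrca) - 1L)])
  q <- prod((20 * exp(-rate * blen[branches]) - 1) / 19)
  q + (1 - q) / 20
}

random_protein <- function(length) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

#' Default domain palette of the simulator
#'
#' A small Pfam-flavoured palette mixing tailoring-enzyme families that carry
#' subfamily labels (cytochrome P450 subfamilies, acyltransferase subclades)
#' with generic background families, mirroring the annotation structure of
#' real genome neighbourhoods.
#'
#' @return data.frame with columns `family`, `subfamily` (empty when none).
#' @export
default_domain_palette <- function() {
  data.frame(
    family = c("p450", "p450", "p450", "p450",
               "Transferase", "Transferase",
               "Methyltransf_2", "UDPGT", "FAD_binding_4", "Abhydrolase_3",
               "Glyco_hydro_1", "NAD_binding_1", "PPR", "LRR_1",
               "Pkinase", "WD40", "Myb_DNA-binding", "AP2", "RRM_1", "DUF4220"),
    subfamily = c("CYP705A", "CYP708A", "CYP702A", "CYP716A",
                  "ACT_IIIa", "ACT_IIIb",
                  rep("", 14L)),
    stringsAsFactors = FALSE)
}

#' Simulate per-gene domain hits with planted window associations
#'
#' Background placement: every gene acquires each palette domain
#' independently with probability `p_background`. Foreground placement: genes
#' listed in `foreground` additionally acquire the planted labels of their
#' group with probability `p_foreground`. Scores are drawn uniformly from
#' plausible bit-score ranges and carry no signal.
#'
#' @param gene_ids character vector of all gene ids in the universe.
#' @param palette data.frame `family`, `subfamily` (see
#'   [default_domain_palette()]).
#' @param p_background per-gene, per-domain background probability.
#' @param foreground named list: planted label -> gene ids eligible for
#'   foreground placement of that label.
#' @param p_foreground per-gene probability of the planted label inside its
#'   foreground set.
#' @param seed optional integer seed.
#' @return domain-hit data.frame (`gene_id`, `family`, `subfamily`, `score`).
#' @export
simulate_domain_hits <- function(gene_ids, palette = default_domain_palette(),
                                 p_background = 0.02, foreground = list(),
                                 p_foreground = 0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- ifelse(palette$subfamily == "", palette$family, palette$subfamily)
  n <- length(gene_ids)
  rows <- list()
  for (d in seq_len(nrow(palette))) {
    hit <- stats::runif(n) < p_background
    planted <- foreground[[labels[d]]]
    if (!is.null(planted)) {
      idx <- match(planted, gene_ids)
      stopifnot(!anyNA(idx))
      hit[idx] <- hit[idx] | (stats::runif(length(idx)) < p_foreground)
    }
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_ids[hit],
        family = palette$family[d],
        subfamily = palette$subfamily[d],
        score = round(stats::runif(sum(hit), 50, 400), 1),
        stringsAsFactors = FALSE)
    }
  }
  planted_only <- setdiff(names(foreground), labels)
  for (lab in planted_only) {
    idx <- match(foreground[[lab]], gene_ids)
    stopifnot(!anyNA(idx))
    hit <- stats::runif(length(idx)) < p_foreground
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_ids[idx[hit]], family = lab, subfamily = "",
        score = round(stats::runif(sum(hit), 50, 400), 1),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_domain_hits())
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$family, out$subfamily), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic-data generator. The
#' defaults describe a small Brassicaceae-like study: 13 genomes, one target
#' (oxidosqualene-cyclase-like) gene per genome, two monophyletic target
#' clades, a CYP/acyltransferase subfamily association planted in the
#' neighbourhoods of one clade at high probability against a low genome-wide
#' background, a slowly gained and lost binary trait domain for ancestral
#' reconstruction, and moderately diverged target protein sequences.
#'
#' @param seed integer seed driving every stochastic choice.
#' @param n_genomes number of genomes.
#' @param scaffolds_per_genome scaffolds per genome.
#' @param genes_per_scaffold genes on each scaffold.
#' @param n_targets_per_genome target genes per genome (placed on scaffold 1
#'   with non-overlapping interior windows).
#' @param clade_sizes named vector partitioning the targets into monophyletic
#'   clades (must sum to `n_genomes * n_targets_per_genome`).
#' @param palette domain palette data.frame (`family`, `subfamily`).
#' @param planted named list: clade -> planted domain labels.
#' @param p_background per-gene background domain probability.
#' @param p_foreground per-gene planted probability inside foreground
#'   windows.
#' @param trait_domains domain labels whose neighbourhood presence evolves as
#'   a binary trait on the tree (kept out of the Bernoulli palette).
#' @param gain_rate,loss_rate trait gain/loss rates per unit branch length.
#' @param flank neighbourhood flank used to define foreground windows.
#' @param protein_length length of simulated proteins.
#' @param substitution_rate substitutions per site per unit branch length for
#'   the target-gene family.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genomes = 13L,
                              scaffolds_per_genome = 2L,
                              genes_per_scaffold = 60L,
                              n_targets_per_genome = 1L,
                              clade_sizes = c(cladeA = 7L, cladeB = 6L),
                              palette = default_domain_palette(),
                              planted = list(cladeA = c("CYP705A", "ACT_IIIa")),
                              p_background = 0.02,
                              p_foreground = 0.9,
                              trait_domains = "CYP708A",
                              gain_rate = 0.05,
                              loss_rate = 0.05,
                              flank = 5L,
                              protein_length = 200L,
                              substitution_rate = 0.3) {
  n_targets <- n_genomes * n_targets_per_genome
  stopifnot(sum(clade_sizes) == n_targets,
            p_background >= 0, p_background <= 1,
            p_foreground >= 0, p_foreground <= 1,
            gain_rate >= 0, loss_rate >= 0,
            genes_per_scaffold >= 2L * flank + 1L)
  # trait-domain presence is driven by the evolved trait alone, so those
  # labels are removed from the Bernoulli background palette
  palette <- palette[!(palette$family %in% trait_domains |
                         palette$subfamily %in% trait_domains), , drop = FALSE]
  stopifnot(all(unlist(planted) %in%
                  ifelse(palette$subfamily == "", palette$family,
                         palette$subfamily)))
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a complete synthetic dataset
#'
#' Produces everything the pipeline consumes — GenBank genomes with target
#' genes at known positions, a pooled domain-hit table with planted
#' clade-specific associations, the target-gene tree in Newick, the target
#' protein FASTA, a target/clade table — together with a machine-readable
#' ground-truth record (planted associations, realised trait events, the
#' seed). Byte-identical output for identical configurations.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the in-memory objects: `genomes` (list of
#'   [annotated_genome()]), `tree`, `clade_of`, `targets` (data.frame),
#'   `trait_truth` (list per trait domain), `ground_truth` (list as written
#'   to JSON) and `paths`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "genomes"), showWarnings = FALSE)
  set.seed(config$seed)

  genome_ids <- sprintf("G%02d", seq_len(config$n_genomes))
  # target ids, assigned to genomes in order, then to clades in order
  target_tab <- expand.grid(k = seq_len(config$n_targets_per_genome),
                            genome_id = genome_ids,
                            stringsAsFactors = FALSE)[, c(2L, 1L)]
  clade_names <- rep(names(config$clade_sizes), times = config$clade_sizes)

  # gene tables with targets at interior, non-overlapping ranks on scaffold 1
  flank <- config$flank
  gps <- config$genes_per_scaffold
  genomes <- list()
  target_rows <- list()
  for (gi in seq_along(genome_ids)) {
    gid <- genome_ids[gi]
    rows <- list()
    for (si in seq_len(config$scaffolds_per_genome)) {
      scaf <- sprintf("s%d", si)
      ids <- sprintf("%s_%s_g%03d", gid, scaf, seq_len(gps))
      rows[[si]] <- data.frame(
        gene_id = ids, scaffold_id = scaf,
        start = (seq_len(gps) - 1L) * 1500L + 1L,
        end = (seq_len(gps) - 1L) * 1500L + 1000L,
        strand = sample(c(1L, -1L), gps, replace = TRUE),
        protein = vapply(seq_len(gps), function(i) random_protein(60L), ""),
        stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, rows)
    # choose target ranks on scaffold 1: interior, windows disjoint
    n_t <- config$n_targets_per_genome
    candidate <- seq(flank, gps - 1L - flank)
    ranks <- integer(0)
    for (t in seq_len(n_t)) {
      ok <- candidate[vapply(candidate, function(r)
        all(abs(r - ranks) > 2L * flank + 1L), NA)]
      if (length(ok) == 0L) stop("cannot place ", n_t,
                                 " disjoint target windows on scaffold of ",
                                 gps, " genes")
      ranks <- c(ranks, if (length(ok) == 1L) ok else sample(ok, 1L))
    }
    ranks <- sort(ranks)
    sel <- genes$scaffold_id == "s1"
    target_ids <- genes$gene_id[sel][ranks + 1L]   # rank is 0-based
    target_rows[[gi]] <- data.frame(genome_id = gid, gene_id = target_ids,
                                    rank = ranks, stringsAsFactors = FALSE)
    genomes[[gi]] <- annotated_genome(gid, genes)
  }
  targets <- do.call(rbind, target_rows)
  targets$clade <- clade_names
  n_targets <- nrow(targets)

  # tree over target genes with monophyletic clades
  ct <- simulate_clade_tree(config$clade_sizes,
                            leaf_names = split(targets$gene_id, targets$clade)[
                              names(config$clade_sizes)])
  tree <- ct$tree
  clade_of <- ct$clade_of

  # target proteins evolve on the tree
  target_prot <- simulate_protein_family(tree, config$protein_length,
                                         config$substitution_rate)
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    sel <- g$genes$gene_id %in% names(target_prot)
    g$genes$protein[sel] <- target_prot[g$genes$gene_id[sel]]
    genomes[[gi]] <- g
  }

  # foreground windows: member genes of each target's flank window
  window_genes <- list()
  for (gi in seq_along(genomes)) {
    gid <- genome_ids[gi]
    tg <- targets$gene_id[targets$genome_id == gid]
    gns <- extract_neighbourhoods(genomes[[gi]], tg, flank = flank)
    for (gn in gns) {
      for (ctr in gn$center_gene_ids) {
        window_genes[[ctr]] <- gn$member_gene_ids
      }
    }
  }

  all_gene_ids <- unlist(lapply(genomes, function(g) g$genes$gene_id))
  foreground <- list()
  for (cl in names(config$planted)) {
    cl_targets <- targets$gene_id[targets$clade == cl]
    fg_genes <- unique(unlist(window_genes[cl_targets]))
    for (lab in config$planted[[cl]]) {
      foreground[[lab]] <- unique(c(foreground[[lab]], fg_genes))
    }
  }
  hits <- simulate_domain_hits(all_gene_ids, palette = config$palette,
                               p_background = config$p_background,
                               foreground = foreground,
                               p_foreground = config$p_foreground)

  # target-family hit on every target gene
  hits <- rbind(hits, data.frame(
    gene_id = targets$gene_id, family = "SQHop_cyclase", subfamily = "",
    score = round(stats::runif(n_targets, 200, 600), 1),
    stringsAsFactors = FALSE))

  # trait domains evolve on the tree; presence = one hit on a window gene
  trait_truth <- list()
  for (td in config$trait_domains) {
    sim <- evolve_binary_trait(tree, config$gain_rate, config$loss_rate,
                               root_state = 0L)
    trait_truth[[td]] <- sim
    present <- names(sim$leaf_states)[sim$leaf_states == 1L]
    for (tg in present) {
      members <- setdiff(window_genes[[tg]], targets$gene_id)
      carrier <- if (length(members) == 1L) members else sample(members, 1L)
      hits <- rbind(hits, data.frame(
        gene_id = carrier, family = td, subfamily = "",
        score = round(stats::runif(1L, 50, 400), 1), stringsAsFactors = FALSE))
    }
  }
  hits <- hits[order(hits$gene_id, hits$family, hits$subfamily), , drop = FALSE]

  # distribute hits back to their genomes
  gene_to_genome <- rep(genome_ids,
                        times = vapply(genomes, function(g) nrow(g$genes), 0L))
  names(gene_to_genome) <- all_gene_ids
  for (gi in seq_along(genomes)) {
    gh <- hits[gene_to_genome[hits$gene_id] == genome_ids[gi], , drop = FALSE]
    genomes[[gi]] <- set_domain_hits(genomes[[gi]], gh)
  }

  # write everything
  paths <- list(
    genomes = file.path(out_dir, "genomes",
                        paste0(genome_ids, ".gbk")),
    hits = file.path(out_dir, "domain_hits.tsv"),
    tree = file.path(out_dir, "tree.nwk"),
    targets = file.path(out_dir, "targets.tsv"),
    proteins = file.path(out_dir, "target_proteins.faa"),
    ground_truth = file.path(out_dir, "ground_truth.json"))
  for (gi in seq_along(genomes)) {
    write_genome_genbank(genomes[[gi]], paths$genomes[gi],
                         centers = targets$gene_id)
  }
  write_domain_table(hits, paths$hits)
  ape::write.tree(tree, paths$tree)
  utils::write.table(targets, paths$targets, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  aa <- Biostrings::AAStringSet(target_prot)
  Biostrings::writeXStringSet(aa, paths$proteins)

  ground_truth <- list(
    seed = config$seed,
    planted_associations = lapply(names(config$planted), function(cl) {
      list(clade = cl, domains = config$planted[[cl]],
           p_foreground = config$p_foreground,
           p_background = config$p_background)
    }),
    trait_events = lapply(trait_truth, function(s) {
      list(n_events = s$n_events,
           leaf_states = as.list(s$leaf_states))
    }))
  jsonlite::write_json(ground_truth, paths$ground_truth, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(genomes = genomes, tree = tree, clade_of = clade_of,
                 targets = targets, trait_truth = trait_truth,
                 ground_truth = ground_truth, paths = paths))
}
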