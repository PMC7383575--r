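#' Fixed scaffold for enrichment calibration experiments
#'
#' One synthetic genome of `n_genes` genes with `n_gns` non-overlapping
#' 11-gene neighbourhoods whose target genes form a single monophyletic clade
#' on a Yule tree — the replicated-unit layout used by the type-I-error and
#' power experiments below.
#'
#' @param n_genes genes in the universe.
#' @param n_gns neighbourhoods (= clade leaves).
#' @param flank window flank.
#' @param seed seed for the clade tree.
#' @return list: `genome`, `gns`, `tree`, `leaf_to_gn`, `foreground_genes`.
#' @export
calibration_scaffold <- function(n_genes = 5000L, n_gns = 20L, flank = 5L,
                                 seed = 1L) {
  genes <- data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
                      scaffold_id = "s1",
                      start = (seq_len(n_genes) - 1L) * 1500L + 1L,
                      end = (seq_len(n_genes) - 1L) * 1500L + 1000L,
                      strand = 1L, stringsAsFactors = FALSE)
  genome <- annotated_genome("CAL", genes)
  step <- (n_genes - 2L * flank - 2L) %/% n_gns
  stopifnot(step > 2L * flank + 1L)
  targets <- genes$gene_id[seq(flank + 1L, by = step, length.out = n_gns)]
  gns <- extract_neighbourhoods(genome, targets, flank = flank)
  ct <- simulate_clade_tree(c(clade = n_gns), seed = seed,
                            leaf_names = list(clade = targets))
  leaf_to_gn <- stats::setNames(vapply(gns, `[[`, "", "gn_id"), targets)
  list(genome = genome, gns = gns, tree = ct$tree, leaf_to_gn = leaf_to_gn,
       foreground_genes = unique(unlist(lapply(gns, `[[`, "member_gene_ids"))))
}

#' Type-I error of the enrichment test under the null
#'
#' Simulates datasets with no planted association (foreground placement equal
#' to background) and measures, across all domains tested in all replicates,
#' the fraction reaching Bonferroni-adjusted significance — separately for the
#' naive and the phylogeny-conservative test, on the same data.
#'
#' @param n_replicates number of simulated datasets.
#' @param p background (= foreground) per-gene domain probability.
#' @param threshold adjusted-p significance threshold.
#' @param scaffold a [calibration_scaffold()]; built fresh when `NULL`.
#' @param seed integer seed.
#' @return named numeric: `naive`, `conservative` (false-positive fractions),
#'   `n_tests` (tests per mode).
#' @export
enrichment_null_rate <- function(n_replicates = 500L, p = 0.02,
                                 threshold = 0.01, scaffold = NULL,
                                 seed = 1L) {
  if (is.null(scaffold)) scaffold <- calibration_scaffold(seed = seed)
  set.seed(seed)
  sig <- c(naive = 0L, conservative = 0L)
  n_tests <- c(naive = 0L, conservative = 0L)
  for (r in seq_len(n_replicates)) {
    hits <- simulate_domain_hits(scaffold$genome$genes$gene_id,
                                 p_background = p)
    g <- set_domain_hits(scaffold$genome, hits)
    for (mode in c("naive", "conservative")) {
      res <- run_enrichment(list(g), list(clade = scaffold$gns),
                            tree = scaffold$tree,
                            leaf_to_gn = scaffold$leaf_to_gn,
                            level = "subfamily", mode = mode,
                            threshold = threshold)
      sig[mode] <- sig[mode] + sum(res$significant)
      n_tests[mode] <- n_tests[mode] + nrow(res)
    }
  }
  c(naive = unname(sig["naive"] / n_tests["naive"]),
    conservative = unname(sig["conservative"] / n_tests["conservative"]),
    n_tests = unname(n_tests["naive"]))
}

#' Detection power for a planted association
#'
#' Plants one domain in every neighbourhood of the clade at `p_foreground`
#' against the background rate and measures how often it reaches adjusted
#' significance (and the top rank) in each mode.
#'
#' @inheritParams enrichment_null_rate
#' @param p_background background per-gene probability.
#' @param p_foreground planted per-gene probability inside the
#'   neighbourhoods.
#' @param domain planted domain label.
#' @return named numeric: `naive`, `conservative` (detection frequencies),
#'   `top_ranked` (fraction of replicates where the planted domain ranks
#'   first in the naive test).
#' @export
enrichment_power <- function(n_replicates = 100L, p_background = 0.02,
                             p_foreground = 0.9, domain = "CYP705A",
                             threshold = 0.01, scaffold = NULL, seed = 1L) {
  if (is.null(scaffold)) scaffold <- calibration_scaffold(seed = seed)
  set.seed(seed)
  det <- c(naive = 0L, conservative = 0L)
  top <- 0L
  for (r in seq_len(n_replicates)) {
    hits <- simulate_domain_hits(
      scaffold$genome$genes$gene_id, p_background = p_background,
      foreground = stats::setNames(list(scaffold$foreground_genes), domain),
      p_foreground = p_foreground)
    g <- set_domain_hits(scaffold$genome, hits)
    for (mode in c("naive", "conservative")) {
      res <- run_enrichment(list(g), list(clade = scaffold$gns),
                            tree = scaffold$tree,
                            leaf_to_gn = scaffold$leaf_to_gn,
                            level = "subfamily", mode = mode,
                            threshold = threshold)
      row <- res[res$domain == domain, ]
      if (nrow(row) == 1L && row$significant) det[mode] <- det[mode] + 1L
      if (mode == "naive" && nrow(res) > 0L && res$domain[1L] == domain) {
        top <- top + 1L
      }
    }
  }
  c(naive = unname(det["naive"]) / n_replicates,
    conservative = unname(det["conservative"]) / n_replicates,
    top_ranked = top / n_replicates)
}

#' Parsimony event-count recovery rate
#'
#' Simulates a binary trait under low gain/loss rates on Yule trees and asks
#' how often the Fitch parsimony score equals the number of realised events.
#' Parsimony is a lower bound on the truth, so recovery fails exactly when
#' events overlap in a way a shorter reconstruction can explain.
#'
#' @param n_replicates number of simulated tree/trait pairs.
#' @param n_leaves leaves per Yule tree.
#' @param gain_rate,loss_rate trait rates per unit branch length.
#' @param seed integer seed.
#' @return named numeric: `recovery` (fraction of exact matches),
#'   `mean_events` (mean realised event count), `n_informative` (replicates
#'   with at least one event).
#' @export
event_recovery_rate <- function(n_replicates = 200L, n_leaves = 39L,
                                gain_rate = 0.05, loss_rate = 0.05,
                                seed = 1L) {
  set.seed(seed)
  hit <- 0L
  events <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    tr <- ape::rphylo(n_leaves, birth = 1, death = 0)
    sim <- evolve_binary_trait(tr, gain_rate, loss_rate, root_state = 0L)
    fit <- fitch_parsimony(tr, sim$leaf_states)
    events[r] <- sim$n_events
    if (fit$score == sim$n_events) hit <- hit + 1L
  }
  c(recovery = hit / n_replicates, mean_events = mean(events),
    n_informative = sum(events > 0))
}
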