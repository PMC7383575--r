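test_that("Fitch parsimony resolves the canonical 4-leaf cases", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  # all absent: no change anywhere
  f0 <- fitch_parsimony(tr, c(A = 0, B = 0, C = 0, D = 0))
  expect_equal(f0$score, 0L)
  expect_true(all(vapply(f0$mpr, identical, NA, 0L)))
  # alternating states: two changes, all nodes ambiguous-free? (score only)
  f1 <- fitch_parsimony(tr, c(A = 1, B = 0, C = 1, D = 0))
  expect_equal(f1$score, 2L)
  # clean split: one change, root genuinely ambiguous
  f2 <- fitch_parsimony(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(f2$score, 1L)
  root <- length(tr$tip.label) + 1L
  expect_equal(f2$mpr[[root]], c(0L, 1L))
  expect_true(f2$ambiguous[root])
  expect_error(fitch_parsimony(tr, c(A = 2, B = 0, C = 0, D = 0)), "binary")
  expect_error(fitch_parsimony(tr, c(A = 1, B = 0, C = 0)), "missing")
})

test_that("Fitch score equals the exhaustive labeling minimum and phangorn", {
  set.seed(59)
  for (rep in 1:60) {
    tr <- random_tree(sample(4:8, 1))
    states <- setNames(sample(0:1, length(tr$tip.label), replace = TRUE),
                       tr$tip.label)
    f <- fitch_parsimony(tr, states)
    expect_equal(f$score, exhaustive_parsimony(tr, states))
    pd <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                  dimnames = list(names(states), NULL)),
                           type = "USER", levels = c("0", "1"))
    expect_equal(f$score, phangorn::fitch(tr, pd))
  }
})

test_that("Fitch score is invariant to rerooting", {
  set.seed(61)
  for (rep in 1:10) {
    tr <- random_tree(7)
    states <- setNames(sample(0:1, 7, replace = TRUE), tr$tip.label)
    base <- fitch_parsimony(tr, states)$score
    for (tip in sample(tr$tip.label, 3)) {
      rerooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
      expect_equal(fitch_parsimony(rerooted, states)$score, base)
    }
  }
})

test_that("event mapping distinguishes gains, losses and ambiguity", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  # score 0: all branches none
  ev0 <- map_events(fitch_parsimony(tr, c(A = 1, B = 1, C = 1, D = 1)))
  expect_true(all(ev0$events$event == "none"))
  expect_equal(unname(ev0$totals[c("gains", "losses")]), c(0, 0))
  # alternating: every reconstruction differs, so no branch event is forced
  ev1 <- map_events(fitch_parsimony(tr, c(A = 1, B = 0, C = 1, D = 0)))
  expect_equal(unname(ev1$totals["gains"] + ev1$totals["losses"]), 0)
  expect_gte(unname(ev1$totals["ambiguous"]), 4)
  expect_lte(unname(ev1$totals["gains"] + ev1$totals["losses"]),
             unname(ev1$totals["score"]))
  # single derived tip: an unambiguous gain on its pendant branch
  tr1 <- ape::read.tree(text = "(((A,B),C),D);")
  evg <- map_events(fitch_parsimony(tr1, c(A = 1, B = 0, C = 0, D = 0)))
  expect_equal(evg$events$event[evg$events$child_label %in% "A"], "gain")
  expect_equal(unname(evg$totals["gains"]), 1)
  # root-ambiguous split: branches incident to ambiguous nodes are ambiguous
  ev2 <- map_events(fitch_parsimony(tr, c(A = 1, B = 1, C = 0, D = 0)))
  expect_equal(unname(ev2$totals["ambiguous"]), 2)
  expect_equal(unname(ev2$totals["gains"]) + unname(ev2$totals["losses"]), 0)
  expect_lte(unname(ev2$totals["gains"] + ev2$totals["losses"]),
             unname(ev2$totals["score"]))
  # polarity: loss on a derived tip
  tr2 <- ape::read.tree(text = "(((A,B),C),D);")
  ev3 <- map_events(fitch_parsimony(tr2, c(A = 0, B = 1, C = 1, D = 1)))
  expect_equal(ev3$events$event[ev3$events$child_label %in% "A"], "loss")
})

test_that("undersized-neighbourhood leaves are pruned with lengths preserved", {
  g <- make_test_genome(scaffold_sizes = c(s1 = 30, s2 = 30, s3 = 5))
  targets <- c(g$genes$gene_id[g$genes$scaffold_id == "s1"][16],
               g$genes$gene_id[g$genes$scaffold_id == "s2"][16],
               g$genes$gene_id[g$genes$scaffold_id == "s3"][3])
  gns <- extract_neighbourhoods(g, targets)
  leaf_to_gn <- setNames(vapply(gns, `[[`, "", "gn_id"),
                         vapply(gns, function(x) x$center_gene_ids[1], ""))
  tr <- ape::read.tree(text = sprintf("((%s:0.2,%s:0.3):0.1,%s:0.5);",
                                      targets[1], targets[3], targets[2]))
  pruned <- prune_for_reconstruction(tr, leaf_to_gn, gns)
  expect_setequal(pruned$tip.label, targets[1:2])
  # sibling re-attaches with summed branch length: 0.2 + 0.1 on the path
  d <- ape::cophenetic.phylo(pruned)[targets[1], targets[2]]
  expect_equal(d, 0.2 + 0.1 + 0.5)
  # no pruning: identical topology
  tr_ok <- ape::read.tree(text = sprintf("((%s,%s),%s);", targets[1],
                                         targets[2], targets[1]))
  expect_error(prune_for_reconstruction(tr, leaf_to_gn, gns, min_genes = 12),
               "fewer than 2")
  same <- prune_for_reconstruction(tr, leaf_to_gn, gns, min_genes = 3)
  expect_equal(same$tip.label, tr$tip.label)
})

test_that("representative-leaf selection keeps the best-connected leaf", {
  # two leaves share one neighbourhood; under the nearest-leaf method their
  # local DSS means differ and the better one is kept
  tr <- ape::read.tree(
    text = "(((L1:0.1,N1:0.1):0.1,N2:0.2):0.5,(L2:0.1,N3:0.1):0.5);")
  leaf_to_gn <- c(L1 = "gnX", L2 = "gnX", N1 = "gn1", N2 = "gn2", N3 = "gn3")
  dss <- matrix(0, 4, 4, dimnames = list(c("gnX", "gn1", "gn2", "gn3"),
                                         c("gnX", "gn1", "gn2", "gn3")))
  diag(dss) <- 1
  dss["gnX", c("gn1", "gn2", "gn3")] <- c(0.6, 0.2, 0.1)
  dss[c("gn1", "gn2", "gn3"), "gnX"] <- c(0.6, 0.2, 0.1)
  # L1 is near gn1/gn2 (mean 0.4), L2 near gn3 (mean 0.1)
  keep <- select_representative_leaves(tr, leaf_to_gn, dss,
                                       method = "nearest", k = 2)
  expect_true("L1" %in% keep)
  expect_false("L2" %in% keep)
  expect_setequal(setdiff(keep, "L1"), c("N1", "N2", "N3"))
  # all-leaves method: equal means, lexicographic tie-break
  keep2 <- select_representative_leaves(tr, leaf_to_gn, dss, method = "all")
  expect_true("L1" %in% keep2 && !"L2" %in% keep2)
  # single-leaf neighbourhoods: identity
  solo <- c(L1 = "g1", N1 = "g2", N2 = "g3", N3 = "g4", L2 = "g5")
  expect_setequal(select_representative_leaves(tr, solo, dss), tr$tip.label)
})

test_that("trait matrices record binary neighbourhood domain presence", {
  g <- make_test_genome(scaffold_sizes = c(s1 = 30, s2 = 30))
  targets <- c(g$genes$gene_id[g$genes$scaffold_id == "s1"][16],
               g$genes$gene_id[g$genes$scaffold_id == "s2"][16])
  gns <- extract_neighbourhoods(g, targets)
  hits <- data.frame(
    gene_id = c(gns[[1]]$member_gene_ids[2], gns[[1]]$member_gene_ids[3]),
    family = c("p450", "Transferase"),
    subfamily = c("CYP705A", "ACT_IIIa"), score = 100, stringsAsFactors = FALSE)
  g <- set_domain_hits(g, hits)
  leaf_to_gn <- setNames(vapply(gns, `[[`, "", "gn_id"), targets)
  tm <- trait_matrix(targets, leaf_to_gn, gns, list(g),
                     domains = c("CYP705A", "ACT_IIIa", "CYP708A"))
  expect_equal(dim(tm), c(2L, 3L))
  expect_equal(unname(tm[targets[1], ]), c(1L, 1L, 0L))
  expect_equal(unname(tm[targets[2], ]), c(0L, 0L, 0L))
})
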