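test_that("window extraction yields 11-gene neighbourhoods for interior targets", {
  g <- make_test_genome(scaffold_sizes = c(s1 = 30))
  target <- g$genes$gene_id[g$genes$rank == 15]
  gns <- extract_neighbourhoods(g, target)
  expect_length(gns, 1L)
  gn <- gns[[1]]
  expect_length(gn$member_gene_ids, 11L)
  expect_equal(c(gn$first_rank, gn$last_rank), c(10L, 20L))
  expect_false(gn$truncated)
  expect_false(gn$merged)
  expect_true(target %in% gn$member_gene_ids)
})

test_that("windows clip at scaffold edges and flag truncation", {
  g <- make_test_genome(scaffold_sizes = c(tiny = 3))
  target <- g$genes$gene_id[g$genes$rank == 1]
  gn <- extract_neighbourhoods(g, target)[[1]]
  expect_length(gn$member_gene_ids, 3L)
  expect_true(gn$truncated)
})

test_that("overlapping windows merge transitively with all centers kept", {
  g <- make_test_genome(scaffold_sizes = c(s1 = 30))
  targets <- g$genes$gene_id[g$genes$rank %in% c(10, 14)]
  gns <- extract_neighbourhoods(g, targets)
  expect_length(gns, 1L)
  gn <- gns[[1]]
  expect_length(gn$member_gene_ids, 15L)          # ranks 5..19
  expect_equal(c(gn$first_rank, gn$last_rank), c(5L, 19L))
  expect_setequal(gn$center_gene_ids, targets)
  expect_true(gn$merged)
})

test_that("adjacent (touching) windows merge by default but not when disabled", {
  g <- make_test_genome(scaffold_sizes = c(s1 = 40))
  targets <- g$genes$gene_id[g$genes$rank %in% c(10, 21)]  # windows 5-15, 16-26
  merged <- extract_neighbourhoods(g, targets)
  expect_length(merged, 1L)
  expect_length(merged[[1]]$member_gene_ids, 22L)
  apart <- extract_neighbourhoods(g, targets, merge_adjacent = FALSE)
  expect_length(apart, 2L)
  expect_equal(vapply(apart, function(x) length(x$member_gene_ids), 0L),
               c(11L, 11L))
})

test_that("unknown targets are rejected by name", {
  g <- make_test_genome()
  expect_error(extract_neighbourhoods(g, "nope"), "nope")
})

test_that("merging is invariant to target input order and members are disjoint", {
  set.seed(23)
  for (rep in 1:15) {
    g <- make_test_genome(scaffold_sizes = c(a = 50, b = 35))
    targets <- sample(g$genes$gene_id, 6)
    gns1 <- extract_neighbourhoods(g, targets)
    gns2 <- extract_neighbourhoods(g, rev(targets))
    expect_equal(vapply(gns1, `[[`, "", "gn_id"),
                 vapply(gns2, `[[`, "", "gn_id"))
    members <- unlist(lapply(gns1, `[[`, "member_gene_ids"))
    expect_false(anyDuplicated(members) > 0)
    for (gn in gns1) {
      expect_true(all(gn$center_gene_ids %in% gn$member_gene_ids))
    }
  }
})

test_that("interior non-adjacent targets always give 2*flank+1 members", {
  set.seed(31)
  for (rep in 1:15) {
    flank <- sample(2:6, 1)
    n <- 80
    g <- make_test_genome(scaffold_sizes = c(s1 = n))
    ranks <- integer(0)
    for (i in 1:4) {
      cand <- setdiff(seq(flank, n - 1 - flank), unlist(lapply(ranks, function(r)
        (r - 2 * flank - 1):(r + 2 * flank + 1))))
      if (length(cand) == 0) break
      ranks <- c(ranks, sample(cand, 1))
    }
    targets <- g$genes$gene_id[g$genes$rank %in% ranks]
    gns <- extract_neighbourhoods(g, targets, flank = flank)
    expect_equal(vapply(gns, function(x) length(x$member_gene_ids), 0L),
                 rep(2L * flank + 1L, length(ranks)))
  }
})

test_that("size filter keeps qualifying neighbourhoods in order", {
  g <- make_test_genome(scaffold_sizes = c(s1 = 30, s2 = 9, s3 = 40))
  targets <- c(g$genes$gene_id[g$genes$scaffold_id == "s1"][16],
               g$genes$gene_id[g$genes$scaffold_id == "s2"][5],
               g$genes$gene_id[g$genes$scaffold_id == "s3"][8],
               g$genes$gene_id[g$genes$scaffold_id == "s3"][12])
  gns <- extract_neighbourhoods(g, targets)
  sizes <- vapply(gns, function(x) length(x$member_gene_ids), 0L)
  expect_equal(sort(sizes), c(9L, 11L, 15L))
  kept <- filter_by_size(gns)
  expect_equal(vapply(kept, function(x) length(x$member_gene_ids), 0L)
               >= 11L, rep(TRUE, 2L))
  expect_length(filter_by_size(gns, min_genes = 1L), length(gns))
  expect_warning(out <- filter_by_size(gns, min_genes = 100L), "no neighbourhoods")
  expect_length(out, 0L)
})

test_that("BGC classification needs three distinct enzyme classes", {
  g <- make_test_genome(scaffold_sizes = c(s1 = 30))
  target <- g$genes$gene_id[g$genes$rank == 15]
  gn <- extract_neighbourhoods(g, target)[[1]]
  members <- gn$member_gene_ids
  class_map <- c(SQHop_cyclase = "scaffold_generating", p450 = "oxidising",
                 Transferase = "acylating")
  mk <- function(genes, fams, subs) {
    data.frame(gene_id = genes, family = fams, subfamily = subs,
               score = 100, stringsAsFactors = FALSE)
  }
  # thalianol-like content: cyclase + two CYP subfamilies + one acyltransferase
  full <- mk(members[1:4], c("SQHop_cyclase", "p450", "p450", "Transferase"),
             c("", "CYP708A", "CYP705A", "ACT_IIIa"))
  expect_true(classify_bgc(gn, full, class_map))
  only_osc <- mk(members[1], "SQHop_cyclase", "")
  expect_false(classify_bgc(gn, only_osc, class_map))
  two_cyps <- mk(members[1:3], c("SQHop_cyclase", "p450", "p450"),
                 c("", "CYP708A", "CYP705A"))
  expect_false(classify_bgc(gn, two_cyps, class_map))
  # monotone: adding hits never flips TRUE -> FALSE
  expect_true(classify_bgc(gn, rbind(full, only_osc, two_cyps), class_map))
  # hits outside the window do not count
  outside <- mk(rep("TG1_s1_g01", 3), c("SQHop_cyclase", "p450", "Transferase"),
                c("", "", ""))
  expect_false(classify_bgc(gn, rbind(only_osc, outside), class_map))
})

test_that("clade labels propagate from the smallest homogeneous enclosing clade", {
  ref2 <- data.frame(leaf_name = c("R1", "R2"), label = c("I", "II"),
                     stringsAsFactors = FALSE)
  tr <- ape::read.tree(text = "((R1,X),(R2,Y));")
  out <- propagate_clade_labels(tr, ref2)
  expect_equal(out$label[match(c("X", "Y"), out$leaf_name)], c("I", "II"))
  expect_equal(out$source[match(c("X", "Y"), out$leaf_name)],
               rep("propagated", 2))
  expect_equal(out$source[match(c("R1", "R2"), out$leaf_name)],
               rep("reference", 2))

  # mixed cherry of references leaves the outsider ambiguous
  tr2 <- ape::read.tree(text = "((R1,R2),X);")
  out2 <- propagate_clade_labels(tr2, ref2)
  expect_true(is.na(out2$label[out2$leaf_name == "X"]))
  expect_equal(out2$source[out2$leaf_name == "X"], "ambiguous")

  # homogeneous references label everything
  tr3 <- ape::read.tree(text = "((R1,A),(B,(C,D)));")
  out3 <- propagate_clade_labels(
    tr3, data.frame(leaf_name = "R1", label = "II", stringsAsFactors = FALSE))
  expect_equal(out3$label, rep("II", 5))

  expect_error(propagate_clade_labels(
    tr3, data.frame(leaf_name = "ZZZ", label = "I")), "ZZZ")
})

test_that("label propagation matches exhaustive clade enumeration on random trees", {
  set.seed(47)
  for (rep in 1:20) {
    tr <- random_tree(sample(5:10, 1))
    refs <- sample(tr$tip.label, sample(2:3, 1))
    ref <- data.frame(leaf_name = refs,
                      label = sample(c("I", "II"), length(refs), replace = TRUE),
                      stringsAsFactors = FALSE)
    out <- propagate_clade_labels(tr, ref)
    groups <- monophyletic_groups(tr)
    for (leaf in setdiff(tr$tip.label, refs)) {
      enclosing <- Filter(function(g) leaf %in% g && any(refs %in% g), groups)
      smallest <- enclosing[[which.min(vapply(enclosing, length, 0L))]]
      labs <- unique(ref$label[ref$leaf_name %in% smallest])
      got <- out[out$leaf_name == leaf, ]
      if (length(labs) == 1L) {
        expect_identical(got$label, labs)
      } else {
        expect_true(is.na(got$label))
      }
    }
  }
})
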