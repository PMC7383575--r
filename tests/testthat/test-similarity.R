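test_that("pairwise identity behaves on degenerate and known pairs", {
  expect_equal(pairwise_identity("MKLVAH", "MKLVAH"), 100)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0)
  expect_equal(pairwise_identity("AAAA", "AATA"), 75)
  expect_error(pairwise_identity("", "MKL"), "non-empty")
  expect_error(pairwise_identity(NA_character_, "MKL"), "non-empty")
  # symmetric
  a <- "MKWVTFISLLFLFSSAYS"
  b <- "MKWVSFISLLLLFSSATS"
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
})

test_that("alignment scores match an independent affine-gap DP oracle", {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  submat <- e$BLOSUM62
  set.seed(8)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (rep in 1:12) {
    a <- paste(sample(aa, sample(6:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(6:12, 1), replace = TRUE), collapse = "")
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = submat, gapOpening = 10, gapExtension = 0.5,
      type = "global")
    expect_equal(Biostrings::score(aln), gotoh_score(a, b, submat),
                 tolerance = 1e-9)
  }
})

test_that("Hungarian assignment equals brute force on random matrices", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(1:5, 1)
    m <- sample(n:6, 1)
    M <- matrix(runif(n * m), n, m)
    a <- hungarian_assignment(M)
    expect_false(anyDuplicated(a) > 0)
    expect_equal(sum(M[cbind(seq_len(n), a)]), brute_force_assignment(M)$score,
                 tolerance = 1e-9)
  }
  # more rows than columns: transpose path
  M <- matrix(c(0.9, 0.2, 0.3, 0.8, 0.1, 0.4), 3, 2)
  a <- hungarian_assignment(M)
  expect_equal(sum(is.na(a)), 1L)
  got <- sum(M[cbind(which(!is.na(a)), a[!is.na(a)])])
  expect_equal(got, brute_force_assignment(t(M))$score, tolerance = 1e-9)
})

test_that("copy matching trims the surplus side before the assignment", {
  # 2 vs 2: optimal pairing follows the matrix, not row order
  m22 <- matrix(c(0.9, 0.3, 0.2, 0.8), 2, 2) * 100
  got <- gnevol:::match_copies_matrix(m22, c("a1", "a2"), c("b1", "b2"))
  expect_equal(got$gene_b[got$gene_a == "a1"], "b1")
  expect_equal(got$gene_b[got$gene_a == "a2"], "b2")
  expect_equal(mean(got$identity), 85)
  # 3 vs 2: drop the copy with the lowest best match, then brute force agrees
  set.seed(19)
  for (rep in 1:50) {
    m <- matrix(runif(6), 3, 2) * 100
    got <- gnevol:::match_copies_matrix(m, c("a1", "a2", "a3"), c("b1", "b2"))
    expect_equal(nrow(got), 2L)
    drop_expected <- c("a1", "a2", "a3")[which.min(apply(m, 1, max))]
    expect_false(drop_expected %in% got$gene_a)
    keep <- setdiff(1:3, which.min(apply(m, 1, max)))
    expect_equal(sum(got$identity),
                 brute_force_assignment(m[keep, , drop = FALSE])$score,
                 tolerance = 1e-9)
  }
  # ties in best-match identity break by gene id
  tie <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2) * 100
  got <- gnevol:::match_copies_matrix(tie[, 1, drop = FALSE], c("a2", "a1"), "b1")
  expect_equal(got$gene_a, "a1")
})

test_that("matching from sequences returns the single pair for 1 vs 1", {
  ca <- data.frame(gene_id = "x1", protein = "MKLVAHGG")
  cb <- data.frame(gene_id = "y1", protein = "MKLVAHGG")
  got <- match_domain_copies(ca, cb)
  expect_equal(got$identity, 100)
  expect_equal(got$gene_b, "y1")
})

test_that("Jaccard index is plain set arithmetic on domain families", {
  pa <- make_profile("a", list(SQHop_cyclase = c(g1 = "MK"),
                               CYP705A = c(g2 = "MK"),
                               CYP708A = c(g3 = "MK"),
                               ACT_IIIa = c(g4 = "MK")))
  pb <- make_profile("b", list(SQHop_cyclase = c(h1 = "MK"),
                               CYP705A = c(h2 = "MK"),
                               ACT_IIIa = c(h3 = "MK")))
  expect_equal(jaccard_index(pa, pb), 0.75)
  expect_equal(jaccard_index(pa, pa), 1)
  pc <- make_profile("c", list(UDPGT = c(u1 = "MK")))
  expect_equal(jaccard_index(pa, pc), 0)
  empty <- make_profile("e", list())
  expect_equal(jaccard_index(empty, empty), 0)
})

test_that("DSS follows the copy-penalised formula", {
  # family f: 2 vs 1 copies (identical seq, best identity 1),
  # family g: 1 vs 1 with known identity
  s <- "MKWVTFISLLFLFSSAYS"
  g_a <- "MKLHAVCDEF"
  g_b <- "MKLHAVCDEF"
  pa <- make_profile("a", list(f = c(f1 = s, f2 = s), g = c(ga = g_a)))
  pb <- make_profile("b", list(f = c(f3 = s), g = c(gb = g_b)))
  # identities are 1.0 and 1.0; denominator max(2,1)+max(1,1) = 3
  expect_equal(dss_index(pa, pb), (1 + 1) / 3)
  expect_equal(dss_index(pa, pa), 1)
  pd <- make_profile("d", list(h = c(h1 = s)))
  expect_equal(dss_index(pa, pd), 0)
  # symmetry
  expect_equal(dss_index(pa, pb), dss_index(pb, pa))
})

test_that("pair comparison is symmetric, bounded, exact on self", {
  set.seed(29)
  tr <- random_tree(4)
  fam_seqs <- simulate_protein_family(tr, 50, 0.4)
  pa <- make_profile("a", list(f = c(x1 = fam_seqs[[1]], x2 = fam_seqs[[2]]),
                               g = c(x3 = fam_seqs[[3]])))
  pb <- make_profile("b", list(f = c(y1 = fam_seqs[[4]]),
                               h = c(y2 = fam_seqs[[2]])))
  ab <- compare_profiles(pa, pb)
  ba <- compare_profiles(pb, pa)
  expect_equal(ab$jaccard, ba$jaccard)
  expect_equal(ab$dss, ba$dss)
  expect_equal(ab$avg_identity, ba$avg_identity)
  expect_true(ab$jaccard >= 0 && ab$jaccard <= 1)
  expect_true(ab$dss >= 0 && ab$dss <= 1)
  expect_true(ab$avg_identity >= 0 && ab$avg_identity <= 100)
  self <- compare_profiles(pa, pa)
  expect_equal(self$jaccard, 1)
  expect_equal(self$dss, 1)
  expect_equal(self$avg_identity, 100)
  # removing a family private to one profile raises or preserves both indices
  pa2 <- make_profile("a2", list(f = c(x1 = fam_seqs[[1]], x2 = fam_seqs[[2]])))
  ab2 <- compare_profiles(pa2, pb)
  expect_gte(ab2$jaccard, ab$jaccard)
  expect_gte(ab2$dss, ab$dss)
})

test_that("all-vs-all reports every pair and self-consistent bin counts", {
  set.seed(33)
  g <- make_test_genome(scaffold_sizes = c(s1 = 40, s2 = 40),
                        protein = function(i) random_protein(40))
  targets <- g$genes$gene_id[g$genes$rank == 15]
  hits <- simulate_domain_hits(g$genes$gene_id, p_background = 0.08)
  g <- set_domain_hits(g, hits)
  gns <- extract_neighbourhoods(g, targets)
  expect_error(all_vs_all(gns[1], list(g)), "at least 2")
  res <- all_vs_all(gns, list(g))
  expect_equal(nrow(res$pairs), choose(length(gns), 2))
  s <- res$summary
  expect_equal(unname(s["no_shared"] + s["shared"]), unname(s["total_pairs"]))
  shared <- res$pairs[res$pairs$n_shared_families > 0, ]
  expect_equal(unname(s["jaccard_ge_0.5"]), sum(shared$jaccard >= 0.5))
  expect_equal(unname(s["dss_le_0.3"]), sum(shared$dss <= 0.3))
  expect_true(all(is.na(res$pairs$avg_identity) ==
                    (res$pairs$n_shared_families == 0)))
})

test_that("two identical neighbourhoods compare at exactly 1", {
  g1 <- make_test_genome("GA", scaffold_sizes = c(s1 = 20),
                         protein = function(i) strrep("MKLV", 8))
  g2 <- make_test_genome("GB", scaffold_sizes = c(s1 = 20),
                         protein = function(i) strrep("MKLV", 8))
  mk_hits <- function(g) {
    members <- extract_neighbourhoods(
      g, g$genes$gene_id[g$genes$rank == 10])[[1]]$member_gene_ids
    data.frame(gene_id = members[1:3],
               family = c("SQHop_cyclase", "p450", "Transferase"),
               subfamily = c("", "CYP705A", "ACT_IIIa"), score = 100,
               stringsAsFactors = FALSE)
  }
  g1 <- set_domain_hits(g1, mk_hits(g1))
  g2 <- set_domain_hits(g2, mk_hits(g2))
  gns <- c(extract_neighbourhoods(g1, g1$genes$gene_id[g1$genes$rank == 10]),
           extract_neighbourhoods(g2, g2$genes$gene_id[g2$genes$rank == 10]))
  res <- all_vs_all(gns, list(g1, g2))
  expect_equal(res$pairs$jaccard, 1)
  expect_equal(res$pairs$dss, 1)
  expect_equal(res$pairs$avg_identity, 100)
})

test_that("whitelisting restricts profiles to specialized-metabolism domains", {
  g <- make_test_genome(scaffold_sizes = c(s1 = 20))
  target <- g$genes$gene_id[g$genes$rank == 10]
  gn <- extract_neighbourhoods(g, target)[[1]]
  hits <- data.frame(gene_id = gn$member_gene_ids[1:4],
                     family = c("SQHop_cyclase", "p450", "PPR", "WD40"),
                     subfamily = c("", "CYP705A", "", ""), score = 100,
                     stringsAsFactors = FALSE)
  g <- set_domain_hits(g, hits)
  prof <- domain_copy_profile(gn, g, whitelist = c("SQHop_cyclase", "CYP705A"))
  expect_setequal(prof$families, c("SQHop_cyclase", "CYP705A"))
})

test_that("pair bookkeeping reproduces the published clade II arithmetic", {
  bk <- pair_bookkeeping(n_gns = 50, n_small = 11, n_no_shared = 439,
                         n_bgc = 36, n_jaccard_high = 73)
  expect_equal(unname(bk["n_retained"]), 39)
  expect_equal(unname(bk["total_pairs"]), 741)
  expect_equal(unname(bk["shared_pairs"]), 302)
  expect_equal(unname(bk["pct_bgc"]), 72)
  expect_equal(round(unname(bk["pct_jaccard_high"])), 24)
})
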