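#' Global pairwise amino-acid identity
#'
#' Percent identity of two protein sequences under a global (Needleman-
#' Wunsch) alignment with BLOSUM62 scoring and affine gaps (open 10,
#' extend 0.5 by default). Identity is the number of identical aligned
#' residue pairs over the total number of alignment columns, gaps included.
#'
#' @param seq_a,seq_b non-empty amino-acid strings (20 standard residues
#'   plus X; other residues score as mismatches).
#' @param substitution_matrix name of the substitution matrix (default
#'   `"BLOSUM62"`).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                              gap_opening = 10, gap_extension = 0.5) {
  if (is.na(seq_a) || is.na(seq_b) || nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    stop("pairwise_identity requires two non-empty sequences")
  }
  # identity is symmetric, but alignment tie-breaking is not: canonicalise
  # the argument order so that pid(a, b) == pid(b, a) exactly
  if (seq_b < seq_a) {
    tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp
  }
  mat <- get_substitution_matrix(substitution_matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = mat, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  as.numeric(Biostrings::pid(aln, type = "PID1"))
}

get_substitution_matrix <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!exists(name, envir = cache)) {
      e <- new.env()
      utils::data(list = name, package = "Biostrings", envir = e)
      assign(name, get(name, envir = e), envir = cache)
    }
    get(name, envir = cache)
  }
})

#' Domain-copy profile of a neighbourhood
#'
#' Collects, for each domain label present in a neighbourhood, the member
#' genes carrying it (the "copies") together with their protein sequences.
#' An optional whitelist restricts the profile to domain families of interest
#' (for example families known from specialized metabolic pathways).
#'
#' @param gn a `genome_neighbourhood`.
#' @param genome the `annotated_genome` it belongs to.
#' @param whitelist optional character vector of admissible domain labels.
#' @param level domain labelling level, see [domain_label()].
#' @return object of class `domain_copy_profile`: list with `gn_id`,
#'   `families` (character) and `copies` (named list: label -> data.frame
#'   `gene_id`, `protein`).
#' @export
domain_copy_profile <- function(gn, genome, whitelist = NULL,
                                level = c("subfamily", "family")) {
  level <- match.arg(level)
  hits <- genome$hits[genome$hits$gene_id %in% gn$member_gene_ids, , drop = FALSE]
  if (nrow(hits) > 0L) hits$label <- domain_label(hits, level) else hits$label <- character()
  if (!is.null(whitelist)) hits <- hits[hits$label %in% whitelist, , drop = FALSE]
  gene_dom <- unique(hits[, c("gene_id", "label")])
  prot <- genome$genes$protein[match(gene_dom$gene_id, genome$genes$gene_id)]
  fams <- sort(unique(gene_dom$label))
  copies <- lapply(fams, function(f) {
    sel <- gene_dom$label == f
    df <- data.frame(gene_id = gene_dom$gene_id[sel], protein = prot[sel],
                     stringsAsFactors = FALSE)
    df[order(df$gene_id), , drop = FALSE]
  })
  names(copies) <- fams
  structure(list(gn_id = gn$gn_id, families = fams, copies = copies),
            class = "domain_copy_profile")
}

#' Jaccard index of two domain profiles
#'
#' Set similarity of the domain-family content of two neighbourhoods:
#' intersection over union of their domain labels. 0 when both profiles are
#' empty.
#'
#' @param profile_a,profile_b `domain_copy_profile` objects.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_index <- function(profile_a, profile_b) {
  a <- profile_a$families; b <- profile_b$families
  u <- union(a, b)
  if (length(u) == 0L) return(0)
  length(intersect(a, b)) / length(u)
}

#' Match the copies of one domain family across two neighbourhoods
#'
#' When both neighbourhoods carry a shared family, the all-vs-all identities
#' of their copies are computed and the Hungarian algorithm selects the
#' one-to-one pairing with the highest total (hence average) identity. If one
#' side has extra copies, the surplus copies with the lowest best-match
#' identity are removed first, with ties broken by gene id, so both sides
#' have the same number of copies before the assignment is solved.
#'
#' @param copies_a,copies_b data.frames with columns `gene_id`, `protein`
#'   (non-empty).
#' @param ... alignment parameters passed to [pairwise_identity()].
#' @return data.frame with columns `gene_a`, `gene_b`, `identity` (percent),
#'   one row per matched pair; `min(nrow(copies_a), nrow(copies_b))` rows.
#' @export
match_domain_copies <- function(copies_a, copies_b, ...) {
  stopifnot(nrow(copies_a) > 0L, nrow(copies_b) > 0L)
  a_ok <- !is.na(copies_a$protein)
  b_ok <- !is.na(copies_b$protein)
  copies_a <- copies_a[a_ok, , drop = FALSE]
  copies_b <- copies_b[b_ok, , drop = FALSE]
  if (nrow(copies_a) == 0L || nrow(copies_b) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  idm <- matrix(0, nrow(copies_a), nrow(copies_b))
  for (i in seq_len(nrow(copies_a))) {
    for (j in seq_len(nrow(copies_b))) {
      idm[i, j] <- pairwise_identity(copies_a$protein[i], copies_b$protein[j], ...)
    }
  }
  match_copies_matrix(idm, copies_a$gene_id, copies_b$gene_id)
}

# Trim-then-assign on a precomputed identity matrix (rows = side a).
match_copies_matrix <- function(idm, ids_a, ids_b) {
  if (nrow(idm) != ncol(idm)) {
    if (nrow(idm) > ncol(idm)) {
      keep <- trim_surplus(idm, ids_a, ncol(idm))
      ids_a <- ids_a[keep]
      idm <- idm[keep, , drop = FALSE]
    } else {
      keep <- trim_surplus(t(idm), ids_b, nrow(idm))
      ids_b <- ids_b[keep]
      idm <- idm[, keep, drop = FALSE]
    }
  }
  assign <- hungarian_assignment(idm)
  data.frame(gene_a = ids_a,
             gene_b = ids_b[assign],
             identity = idm[cbind(seq_along(assign), assign)],
             stringsAsFactors = FALSE)
}

# rows of idm are the surplus side; keep the n_keep rows with the highest
# best-match identity, ties broken by gene id (lexicographic)
trim_surplus <- function(idm, gene_ids, n_keep) {
  best <- apply(idm, 1L, max)
  ord <- order(-best, gene_ids)
  sort(ord[seq_len(n_keep)])
}

#' Domain sequence similarity (DSS) index
#'
#' Average sequence identity of optimally matched shared domain copies,
#' penalised for copy-number and content differences: the numerator is the
#' summed matched-pair identity (as fractions) over all shared families; the
#' denominator is the summed `max(copies_a, copies_b)` over every family in
#' the union, so unmatched surplus copies and families private to one
#' neighbourhood contribute nothing to the numerator but enlarge the
#' denominator. Self-comparison gives exactly 1.
#'
#' @param profile_a,profile_b `domain_copy_profile` objects.
#' @param matches optional pre-computed list: shared family -> data.frame from
#'   [match_domain_copies()]; computed on the fly when `NULL`.
#' @param ... alignment parameters passed to [pairwise_identity()].
#' @return DSS in `[0, 1]`; 0 when no families are shared.
#' @export
dss_index <- function(profile_a, profile_b, matches = NULL, ...) {
  union_fams <- union(profile_a$families, profile_b$families)
  if (length(union_fams) == 0L) return(0)
  shared <- intersect(profile_a$families, profile_b$families)
  denom <- sum(vapply(union_fams, function(f) {
    max(n_copies(profile_a, f), n_copies(profile_b, f))
  }, 0))
  if (denom == 0) return(0)
  num <- 0
  for (f in shared) {
    mt <- if (!is.null(matches)) matches[[f]] else {
      match_domain_copies(profile_a$copies[[f]], profile_b$copies[[f]], ...)
    }
    num <- num + sum(mt$identity) / 100
  }
  num / denom
}

n_copies <- function(profile, fam) {
  cp <- profile$copies[[fam]]
  if (is.null(cp)) 0L else nrow(cp)
}

#' Compare one pair of neighbourhood profiles
#'
#' @param profile_a,profile_b `domain_copy_profile` objects.
#' @param ... alignment parameters passed to [pairwise_identity()].
#' @return one-row data.frame: `gn_a`, `gn_b`, `jaccard`, `avg_identity`
#'   (percent; `NA` when no family is shared), `dss`, `n_shared_families`.
#' @export
compare_profiles <- function(profile_a, profile_b, ...) {
  shared <- intersect(profile_a$families, profile_b$families)
  matches <- lapply(stats::setNames(shared, shared), function(f) {
    match_domain_copies(profile_a$copies[[f]], profile_b$copies[[f]], ...)
  })
  ids <- unlist(lapply(matches, `[[`, "identity"))
  data.frame(
    gn_a = profile_a$gn_id, gn_b = profile_b$gn_id,
    jaccard = jaccard_index(profile_a, profile_b),
    avg_identity = if (length(ids) > 0L) mean(ids) else NA_real_,
    dss = dss_index(profile_a, profile_b, matches = matches),
    n_shared_families = length(shared),
    stringsAsFactors = FALSE)
}

#' All-vs-all neighbourhood comparison
#'
#' Computes Jaccard, average shared-domain identity and DSS for every
#' unordered pair of neighbourhoods (after the minimum-size filter), plus the
#' summary bin counts used to describe neighbourhood dynamics: pairs sharing
#' no domain, pairs with Jaccard >= 0.5, pairs with average identity < 50%
#' and pairs with DSS <= 0.3 (the latter three among domain-sharing pairs).
#'
#' @param gns list of `genome_neighbourhood` objects.
#' @param genomes list of `annotated_genome` objects covering them.
#' @param whitelist optional vector of admissible domain labels.
#' @param min_genes minimum neighbourhood size (default 11).
#' @param level domain labelling level.
#' @param ... alignment parameters passed to [pairwise_identity()].
#' @return list with `pairs` (data.frame, one row per pair), `profiles`
#'   (named list of `domain_copy_profile`) and `summary` (named numeric of
#'   bin counts).
#' @export
all_vs_all <- function(gns, genomes, whitelist = NULL, min_genes = 11L,
                       level = c("subfamily", "family"), ...) {
  level <- match.arg(level)
  gns <- filter_by_size(gns, min_genes)
  if (length(gns) < 2L) stop("need at least 2 neighbourhoods of >= ",
                             min_genes, " genes")
  genome_ids <- vapply(genomes, `[[`, "", "genome_id")
  profiles <- lapply(gns, function(gn) {
    g <- genomes[[match(gn$genome_id, genome_ids)]]
    domain_copy_profile(gn, g, whitelist = whitelist, level = level)
  })
  names(profiles) <- vapply(gns, `[[`, "", "gn_id")
  n <- length(profiles)
  rows <- vector("list", n * (n - 1L) %/% 2L)
  idx <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      idx <- idx + 1L
      rows[[idx]] <- compare_profiles(profiles[[i]], profiles[[j]], ...)
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  list(pairs = pairs, profiles = profiles,
       summary = summarise_pairs(pairs))
}

#' Summary bin counts for a pairwise comparison table
#'
#' @param pairs data.frame as returned in `all_vs_all()$pairs`.
#' @return named numeric vector: `total_pairs`, `no_shared`, `shared`,
#'   `jaccard_ge_0.5`, `identity_lt_50`, `dss_le_0.3`.
#' @export
summarise_pairs <- function(pairs) {
  shared <- pairs[pairs$n_shared_families > 0L, , drop = FALSE]
  c(total_pairs = nrow(pairs),
    no_shared = nrow(pairs) - nrow(shared),
    shared = nrow(shared),
    jaccard_ge_0.5 = sum(shared$jaccard >= 0.5),
    identity_lt_50 = sum(shared$avg_identity < 50),
    dss_le_0.3 = sum(shared$dss <= 0.3))
}

#' Pair bookkeeping identities
#'
#' The combinatorial bookkeeping used when reporting an all-vs-all
#' neighbourhood comparison: starting from the number of neighbourhoods, the
#' number excluded as undersized, the number of pairs with no shared domain,
#' the number qualifying as BGCs and the number of high-Jaccard pairs, it
#' derives the retained-set size, the total and domain-sharing pair counts
#' and the derived percentages. With the clade II counts (50 neighbourhoods,
#' 11 undersized, 439 pairs with no shared domain, 36 BGCs, 73 pairs at
#' Jaccard >= 0.5) it yields 39 retained, 741 total pairs, 302 shared pairs,
#' 72% BGC and ~24% high-Jaccard.
#'
#' @param n_gns total neighbourhoods considered.
#' @param n_small neighbourhoods excluded for having fewer genes than the
#'   size threshold.
#' @param n_no_shared pairs sharing no domain family.
#' @param n_bgc neighbourhoods meeting the BGC definition (out of `n_gns`).
#' @param n_jaccard_high domain-sharing pairs with Jaccard >= 0.5.
#' @return named numeric vector: `n_retained`, `total_pairs`, `shared_pairs`,
#'   `pct_bgc`, `pct_jaccard_high`.
#' @export
pair_bookkeeping <- function(n_gns, n_small, n_no_shared, n_bgc,
                             n_jaccard_high) {
  n_retained <- n_gns - n_small
  total_pairs <- choose(n_retained, 2)
  shared_pairs <- total_pairs - n_no_shared
  c(n_retained = n_retained,
    total_pairs = total_pairs,
    shared_pairs = shared_pairs,
    pct_bgc = 100 * n_bgc / n_gns,
    pct_jaccard_high = 100 * n_jaccard_high / shared_pairs)
}
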