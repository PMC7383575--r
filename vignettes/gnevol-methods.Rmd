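---
title: "Methods: genome-neighbourhood evolution around biosynthetic target genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-neighbourhood evolution around biosynthetic target genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnevol)
```

# The problem

Plant specialized metabolites are often produced by biosynthetic gene
clusters (BGCs): a scaffold-generating enzyme gene — here the oxidosqualene
cyclases (OSCs) that initiate triterpene biosynthesis — physically flanked by
genes for tailoring enzymes such as cytochrome P450 monooxygenases (CYPs) and
acyltransferases (ACTs). Whether such clusters in related genomes descend
from one ancestral cluster or assembled repeatedly in parallel is an
evolutionary question that can be asked with three ingredients: (i) a
statistical test that tailoring-domain families co-occur with the target gene
more often than the genome background predicts, corrected for phylogenetic
non-independence of the genomes; (ii) a similarity index over neighbourhood
pairs separating shared architecture from shared sequence; and (iii) an
ancestral reconstruction of domain presence on the target-gene tree that
counts gains and losses. `gnevol` implements all three over a common
gene-order representation, together with a simulator that generates genomes
with planted ground truth so every stage can be validated end to end.

# Genome neighbourhoods

A genome neighbourhood (GN) is the window extending `flank` genes either side
of a target gene along its scaffold (default `flank = 5`, hence 11-gene
windows). All window arithmetic happens in *rank* space — the 0-based
position of each gene on its scaffold ordered by start coordinate — so
nucleotide distances, strand and overlapping genes never affect membership,
and genes on either strand count equally. Windows clipped at a scaffold edge
are flagged `truncated`; windows on one scaffold whose rank intervals overlap
*or touch* are merged transitively into a single GN holding all their target
genes. The merge-on-touch default is a deliberate choice: two windows sharing
a boundary describe one contiguous run of genes, and merging avoids counting
the boundary genes twice (a `merge_adjacent = FALSE` switch restores strict
overlap-only merging). Downstream sequence analyses restrict to full-size
neighbourhoods (`min_genes = 11`) so that truncated windows cannot deflate
similarity scores.

A neighbourhood qualifies as a BGC when its genes collectively carry
enzymatic domains from at least three distinct enzyme classes
(scaffold-generating, oxidising, acylating, ...), with the class of each
domain family supplied by the user; two subfamilies of one class (say two CYP
subfamilies) do not qualify on their own.

# Enrichment with a phylogeny-conservative success count

For each target-gene clade and each domain observed in that clade's GNs, the
test asks whether GN genes carry the domain more often than expected from the
pooled universe of all annotated genes: with `N` genes in the universe, `K`
carrying the domain, `n` genes in the clade's GNs and `k` of them carrying
the domain, the p-value is the hypergeometric upper tail `P(X >= k)` (the
one-tailed exact Fisher test), Bonferroni-corrected over the `m` domains
tested within the clade. Counting is at the gene level — a gene with several
copies of a domain counts once — which keeps `k <= n` well defined.

Because related genomes inherit neighbourhood content vertically, treating
every leaf as independent inflates `k`. The conservative mode therefore
collapses, on the tree induced by the clade's leaves, every maximal
monophyletic group of leaves *all* of which carry the domain, and replaces
the group's contribution by its single best leaf (the maximum per-leaf count).
Only `k` is reduced; the draw size `n` is left at its naive value, which
makes the correction strictly conservative. Sharing is interpreted as binary
presence (a group collapses when every leaf has count > 0), with the
max-count leaf retained — an interpretation choice documented here because
equal-count sharing would be a stricter alternative. Two further
conventions: the Bonferroni family is the set of domains observed in the
clade's GNs at the tested level (the natural family for the question "which
of the domains seen here are enriched"), and target genes themselves stay in
the universe and the GN gene sets (an `include_targets = FALSE` switch
removes them; with targets included the target family itself appears as a
sanity-check positive).

Domain labels are taken at family level or subfamily level; at subfamily
level a hit without subfamily annotation keeps its family name, so labelling
is total and the two levels differ only where subfamilies exist
(CYP705A vs p450, ACT_IIIa vs Transferase).

The cost of the conservative collapse is power: when a domain is present in
*every* leaf of a clade, the whole clade is one monophyletic group and `k`
drops to the best single leaf's count. This is the correct behaviour — a
trait fixed in a clade is, under the vertical-inheritance assumption, one
observation, and its clade-wide presence is evidence about the clade's
ancestor, not `n` independent draws. The simulation experiments below
quantify the trade-off.

# Neighbourhood similarity

Three indices are computed per unordered GN pair, on the domain-copy profiles
of the two neighbourhoods (optionally restricted to a whitelist of
specialized-metabolism families):

* **Jaccard index** of the domain-label sets: architectural similarity,
  blind to sequence.
* **Average identity**: for each shared family, all copy-vs-copy global
  alignments are computed, surplus copies on the larger side are discarded
  (lowest best-match identity first, ties by gene id), and the Hungarian
  algorithm selects the one-to-one pairing maximising total identity; the
  index is the mean matched-pair identity across all shared families.
* **DSS (domain sequence similarity)**: the matched-pair identities summed
  over shared families, divided by the summed `max(copies_a, copies_b)` over
  *all* families in the union. Families private to one GN and surplus copies
  contribute denominator but no numerator, so the index penalises both
  content and copy-number differences; self-comparison gives exactly 1. The
  precise normalisation is this package's documented choice — the index
  family it belongs to is usually described verbally — and it is the reason
  DSS <= Jaccard-style content agreement in practice.

Alignments are global (Needleman–Wunsch) under BLOSUM62 with affine gaps
(open 10, extend 0.5), identity = identical aligned pairs / alignment
columns, computed on the full protein sequences of the domain-carrying genes
(domain-envelope sub-sequences could be substituted where envelope
coordinates are available). Because optimal alignments can tie, and tie
resolution depends on argument order, the implementation canonicalises the
sequence order before aligning so every identity — and hence every index —
is exactly symmetric. Genes without translations count for window membership
and Jaccard content but are excluded from the sequence-based indices.

The Hungarian solver is the O(n^3) potentials / shortest-augmenting-path
form of Kuhn–Munkres; the test suite proves it against brute-force
enumeration over all assignments on matrices up to 6x6.

# Ancestral reconstruction

Binary presence/absence of each chosen tailoring domain in each leaf's GN is
reconstructed on the target-gene tree by maximum parsimony. Leaves whose GN
is undersized are pruned first (suppressed unary nodes keep summed branch
lengths), and where a merged multi-target GN appears as several leaves, one
representative leaf is kept — the one maximising the mean DSS between its GN
and the other retained GNs ("surrounding leaves" is read as *all* other
retained leaves by default; a k-nearest-by-patristic-distance alternative is
provided, under which co-resident leaves can genuinely differ; ties break by
leaf name). Unrooted input trees are rooted at a user-named outgroup, else by
midpoint; the parsimony score is rooting-invariant, but gain/loss polarity is
reported only for the chosen rooting.

The implementation runs the classic Fitch bottom-up pass (score = number of
union events) and then a unit-cost dynamic program up and down the tree to
obtain full MPR sets — the states each node can take in *some*
minimum-change reconstruction. A branch is reported as a gain or loss only
when both endpoint MPR sets are resolved singletons that differ; if either
endpoint is ambiguous the branch is flagged `ambiguous` rather than resolved
by an acceleration/delay heuristic, so reported event counts never overstate
certainty (unambiguous gains + losses <= parsimony score, with equality
exactly when the reconstruction is unique). Multifurcations are resolved
arbitrarily to binary with zero-length branches (with a message), since the
two-set Fitch recurrence assumes binary nodes.

# The simulator

`generate_dataset()` produces a fully synthetic study from one seed:

* **Genomes**: `n_genomes` (default 13, one target gene each) with
  `scaffolds_per_genome` scaffolds of `genes_per_scaffold` evenly spaced
  genes; targets are placed at interior ranks with pairwise rank separation
  > 2*flank+1 so default windows are complete and unmerged.
* **Tree**: one Yule (pure-birth, rate 1) subtree per named clade, joined
  under a common root by unit stems, so clades are monophyletic by
  construction (default 7 + 6). Yule trees are a neutral scaffold — nothing
  downstream uses tree shape beyond topology and lengths.
* **Domain hits**: every gene draws each palette domain independently
  (Bernoulli `p_background`, default 0.02); genes inside the windows of a
  planted clade additionally draw the planted labels at `p_foreground`
  (default 0.9, the planted-signal strength used throughout the validation
  experiments). Scores are uniform bit-score-like numbers carrying no signal.
* **Target proteins** evolve along the tree under an equal-rates 20-state
  model: per branch of length t each site substitutes with probability
  1 - exp(-r t) to a uniform different residue. Site-level identity between
  two leaves follows the closed form q + (1-q)/20 with
  q = prod (20 exp(-r t_i) - 1)/19 over the connecting path, which the tests
  verify by simulation. Richer substitution structure (BLOSUM-biased
  exchanges, rate heterogeneity) is deliberately absent: the similarity
  stage only needs controlled divergence.
* **Binary traits** evolve as a two-state Markov chain (gain rate 0.05, loss
  rate 0.05 per unit length by default, root absent) simulated with
  exponential waiting times so every realised event is recorded in the
  ground truth; trait domains are excluded from the background palette so
  leaf states are exactly the planted history.

What the simulator does *not* emulate — tandem duplication, rearrangement,
whole-genome duplication, linkage between domain occurrences, annotation
error — bounds what passing tests show: they validate the statistics and
algorithms under the independence assumptions the tests themselves make, not
robustness of the pipeline to realistic genome evolution.

# Validation experiments and problem sizes

The packaged experiments (also re-run by `scripts/acceptance.R`) use these
sizes, chosen to give stable rates at interactive runtimes:

* *Exactness*: Hungarian vs brute force on random matrices up to 6x6;
  Fitch vs exhaustive internal labelings on trees up to 8 leaves;
  hypergeometric tail vs direct combinatorial summation on a grid up to
  N = 200 (relative error < 1e-10).
* *Type-I error*: 500 null datasets (5000 genes, 20 single-clade
  neighbourhoods, all domains at p = 0.02); the fraction of Bonferroni-
  significant tests at 0.01 stays below 0.01, conservative at most naive.
* *Power*: 100 datasets with one domain planted at p_foreground = 0.9; the
  planted domain is detected (and top-ranked) by the naive test in >= 90%
  of replicates. The conservative test's detection rate under the same
  planting is near zero by design (the domain is fixed in the clade, so it
  collapses to one observation) — reported alongside, not hidden.
* *Event recovery*: 200 replicates of a 39-leaf Yule tree with symmetric
  rates 0.05 (expected ~2 events, <= 3); the parsimony score equals the
  realised event count in >= 80% of replicates. Parsimony is a lower bound,
  so misses are overlapping or reversing event pairs, not algorithm error.
* *Determinism*: the full synthetic pipeline (6 genomes) run twice from one
  seed produces byte-identical outputs; no timestamps enter any output file.

# Known limitations

* The conservative collapse assumes clade-wide presence means orthology;
  horizontally re-assembled clusters inside one clade would be
  over-collapsed.
* DSS values depend on the alignment parameters and on whether whole
  proteins or domain envelopes are aligned; comparisons are meaningful only
  within one parameter set, which is why the parameters are recorded in the
  run manifest.
* Phylogenetic regression cross-checks (logistic regression / mixed models
  on the tree) are out of scope; the enrichment output schema keeps the
  columns needed to join such results.
* Likelihood-based ancestral reconstruction is not provided; with the gene
  gain/loss process for plant BGC assembly poorly characterised, parsimony's
  assumption-light count is used and its ambiguity is surfaced explicitly.
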