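---
title: "Decisive genes, congruence frequencies, and supermatrix bookkeeping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decisive genes, congruence frequencies, and supermatrix bookkeeping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concord)
```

## The problem

A phylogenomic matrix assembled from transcriptomes is ragged: each
ortholog group carries a different subset of the species, so the
single-gene trees inferred from it are incomplete and unrooted. Asking
"how many genes support this clade?" without accounting for that
raggedness conflates absence of signal with conflict. The remedy
implemented here is to count, per clade of a rooted reference topology,
only the *decisive* genes — those whose taxon sampling could in principle
test the clade — and report what fraction of them actually contain it.

## Model and procedure

Let the reference be rooted and strictly binary over a taxon universe
$S$. Each internal non-root node defines a clade: descendant clusters
$D_1$ and $D_2$ (the node's two child leafsets) and basal set
$O = S \setminus (D_1 \cup D_2)$. For a gene tree with leafset $L$:

* **Decisiveness**: $|L \cap D_1| \ge 1$, $|L \cap D_2| \ge 1$ and
  $|L \cap O| \ge 2$. One basal taxon is not enough — the unrooted quartet
  is the smallest configuration distinguishing a split, so two outsiders
  are required. The predicate is monotone: enlarging $L$ never destroys
  decisiveness.
* **Congruence**: among decisive genes only, the unrooted gene tree must
  contain an edge separating exactly $L \cap (D_1 \cup D_2)$ from
  $L \cap O$. This is equivalent to the sampled clade members being
  monophyletic with respect to the sampled outsiders after rooting the
  gene tree at any sampled basal leaf — an equivalence the test suite
  verifies exhaustively on all 15 unrooted binary five-leaf topologies
  and by property checks on simulated sets.

Two consequences worth noting. First, a clade whose basal set has a
single member (possible when a root child is a leaf) is never decisive
for any gene, including a complete one; its congruence frequency is
undefined (NA) by construction. Second, if every gene tree is a
leaf-subsampled copy of the reference with no topological error, every
testable clade scores exactly 100% — pruning preserves induced splits —
which is the sharpest available end-to-end check of the whole chain and
is asserted exactly, not statistically, in the tests.

Both children of the root are kept as distinct clades even though they
induce the same unrooted split: each carries its own outgroup-facing
counts, matching how internodes of a rooted reference are annotated in
practice.

## Choices in the congruence definition

* Gene trees may contain polytomies. A polytomy *compatible* with a clade
  but not resolving it contributes no edge, hence counts as not
  congruent: the statistic demands positive evidence. ML gene trees are
  binary in practice, so this matters only for manually edited input.
* Congruence on the minimal quartet (one taxon per cluster, two basal) is
  well defined — a four-leaf tree has exactly one internal edge — and is
  evaluated, not special-cased.
* Gene-tree taxa absent from the reference universe indicate an upstream
  labeling problem; the default policy is an error, with an explicit
  `unknown_taxon_policy = "ignore"` switch that drops such leaves and
  reports how many were dropped. Silent dropping is never the default.
* Congruence percentages are stored at full precision and formatted to
  one decimal place only in display tables and node labels
  (`"95.7|70"`; untested clades render `"NA|0"`).

Bootstrap summarization (`clade_support`) uses the same split machinery:
the support of a clade is the percentage of complete replicate trees
containing its unrooted split. A clade with a singleton basal set induces
a trivial split present in every tree and is reported as 100.

## Supermatrix bookkeeping

The matrix-construction operations reproduce a standard transcriptomic
pipeline downstream of orthology inference and alignment:

* `select_longest_per_locus` keeps one ORF per assembly subcomponent —
  the longest, ties to the first seen.
* `mask_columns` removes alignment columns whose confidence score falls
  *strictly below* the threshold (default 0.5); a column scoring exactly
  the threshold is retained. This literal boundary matters: the filters
  downstream are exclusive too.
* `filter_orthogroups` retains groups with **more than** 4 taxa and a
  masked length **greater than** 50 amino acids; a 4-taxon or 50-column
  group is excluded. Masking runs first, so the length filter sees the
  masked length.
* `concatenate` fills absent taxa with `'-'` and records partitions as
  1-based inclusive spans (0-based half-open arithmetic is internal
  only). Taxon names match exactly; no whitespace munging.
* `occupancy` counts a cell as occupied iff its character is outside
  `{'-', '?', 'X'}`. Within-sequence alignment gaps therefore count as
  unoccupied, the same as absent-taxon fill — a deliberate single
  unambiguous definition, configurable via `unoccupied_chars` because
  published completeness figures do not always state which convention
  they used.
* `delete_taxa_matrix` and `prune_gene_trees` implement taxon-deletion
  experiments: rows are removed, columns are never re-trimmed, and
  gene trees falling below four leaves are discarded with a reported
  count.

## The simulator and what it does (not) emulate

`simulate_gene_tree_set` models exactly the statistical structure the
concordance machinery assumes, and nothing more:

* **Species tree**: Yule (pure birth, rate 1, no extinction), rooted,
  binary, ultrametric. Branch lengths are recorded but never consumed by
  any statistic here.
* **Gene-tree error**: each gene applies $k \sim \mathrm{Poisson}(\lambda)$
  nearest-neighbor interchanges to a copy of the species tree, each move
  picking an internal edge uniformly and one of its two swaps with
  probability 1/2. One NNI replaces exactly one split, so $\lambda$
  controls topological distance directly. This deliberately models
  *estimation* error; incomplete lineage sorting and other genuine
  biological discordance processes are not simulated, so passing tests
  say nothing about coalescent behavior on real data.
* **Missingness**: each taxon is dropped from each gene independently
  with probability $m$; genes left with fewer than four leaves are
  discarded and reported, not regenerated, so the realized gene count can
  fall below the requested one.
* **Orthogroups**: uniform random lengths, residues drawn uniformly from
  the 20 amino-acid letters, uniform [0,1] column scores. No substitution
  model — these fixtures exercise concatenation arithmetic, not
  inference.

Defaults (`n_taxa = 40`, `n_genes = 516`, `missingness = 0.5`,
`length_range = c(51, 462)`) mirror the shape of a 40-taxon, 516-locus
transcriptomic supermatrix with roughly half its cells occupied: 0.5
missingness targets ~50% occupancy, the length floor of 51 is the
smallest value passing the >50-column filter, and the ceiling of 462
puts the mean group length near 256 columns so the concatenated width
lands near the 130-thousand-column scale such matrices reach. `nni_rate`
has no single natural default; 1.0 produces visible but not overwhelming
conflict and is what the CLI example uses.

Determinism is strict: the same `simulation_config` yields byte-identical
output. Per-gene seeds are drawn up front from the master seed, so gene
$i$'s tree does not depend on how many earlier genes were discarded.

## Numerical and interface choices

* Splits are compared as canonical label sets (the block containing the
  lexicographically first leaf), never as hashes, so equality is exact
  and order-free.
* A bifurcating outermost newick node is read as a root, a trifurcating
  one as unrooted, matching common ML tool output; internal node labels
  are support strings, never taxa.
* All CLI outputs are written atomically (temp file + rename); exit
  status 1 flags validation errors, 2 usage errors. Machine output goes
  only to declared files; logs, including echoed thresholds, package
  version and a config hash, go to stderr.

## Problem sizes used in the tests

The default suite simulates at most 16 taxa × 500 genes for the
statistical laws (monotone degradation of congruence under increasing
NNI rate, shrinking decisive counts under growing missingness) and
40 taxa × 516 genes for the supermatrix arithmetic, with exhaustive
enumeration only on the five-leaf space (15 topologies × all 2- and
3-blocks). These sizes give the concentration the assertions need — e.g.
occupancy within three standard errors of its Bernoulli presence
probability — while keeping the full suite under a minute.

## Known limitations

* No tree inference, no branch-length use, no drawing; the package
  consumes trees others infer.
* The congruence count is agnostic to resolution inside a clade, by
  design; it cannot distinguish two conflicting resolutions *within* a
  supported clade.
* Confidence scores are consumed, never computed; score files must align
  column-for-column with their FASTA.
* The simulator's NNI error model has no notion of branch-length-
  dependent reconstruction difficulty: every internal edge is equally
  likely to be perturbed, whereas real estimation error concentrates on
  short internodes.
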