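# concord

Phylogenomic studies routinely confront disagreement between a concatenated
species tree and the individual gene trees it was built from. When gene
trees are *incomplete* — each locus sampled for a different subset of the
taxa — naive conflict counts are misleading: a gene that never sampled both
sides of a clade, or fewer than two taxa outside it, simply cannot speak to
that clade. `concord` implements the bookkeeping that makes such per-clade
summaries honest, for systematists working with transcriptome- or
genome-scale matrices of partially overlapping loci (the package grew out
of flatworm interordinal phylogenomics, but nothing in it is
taxon-specific).

## The statistic

Fix a rooted, binary reference topology over a taxon set *S*. Every
internal non-root node defines a clade with descendant clusters *D1*, *D2*
and basal set *O* = *S* \ (*D1* ∪ *D2*). For a gene tree *g* with leafset
*L(g)* ⊆ *S*:

- *g* is **decisive** for the clade iff |*L* ∩ *D1*| ≥ 1, |*L* ∩ *D2*| ≥ 1
  and |*L* ∩ *O*| ≥ 2 — minimally a quartet, the smallest configuration
  that can test an unrooted split;
- a decisive *g* is **congruent** with the clade iff the unrooted gene
  tree contains an edge separating exactly *L* ∩ (*D1* ∪ *D2*) from
  *L* ∩ *O* — i.e. the sampled clade members are monophyletic with respect
  to the sampled outsiders. Resolution *within* the clade or the outgroup
  is deliberately ignored; a polytomy that is merely compatible does not
  count as congruent.

The **congruence frequency** of a clade is 100 × (congruent / decisive).
Alongside this core statistic the package provides the supermatrix
pipeline around it: longest-ORF-per-locus selection, confidence-score
column masking (columns scoring below a threshold are removed; a score
equal to the threshold is kept), orthogroup filtering (> 4 taxa and > 50
masked columns), concatenation with partition and occupancy accounting,
taxon-deletion pruning of matrices and gene-tree sets, bootstrap
clade-frequency summarization, and a fully deterministic simulator
(Yule species trees, Poisson-distributed NNI gene-tree error, binomial
taxon subsampling) so each stage is testable without any sequence data.

## Worked example

```r
library(concord)

species <- simulate_yule_tree(10, 42)
genes <- simulate_gene_tree_set(species, simulation_config(
  n_taxa = 10, n_genes = 200, missingness = 0.4, nni_rate = 0.8, seed = 42))
#> simulate_gene_tree_set: discarded 10 gene(s) with < 4 leaves
concordance_table(species, genes)
#>   clade_id      clade_taxa n_genes n_decisive n_congruent congruence_pct
#> 1  c001_t3           t3,t8     190         76          70       92.10526
#> 2  c002_t1          t1,t10     190         70          67       95.71429
#> 3  c003_t1    t1,t10,t3,t8     190        137         126       91.97080
#> 4  c004_t2           t2,t6     190         83          78       93.97590
#> 5  c005_t4           t4,t9     190         68          61       89.70588
#> 6  c006_t2        t2,t5,t6     190        101          91       90.09901
#> 7  c007_t2  t2,t4,t5,t6,t9     190        140         128       91.42857
#> 8  c008_t1 t1,t10,t3,t7,t8     190        109          97       88.99083
```

Of the 200 requested genes, 190 survived the 40% per-taxon subsampling
with at least four leaves. The clade `{t1,t10}` could be tested by 70 of
them (both members plus two outsiders sampled), and 67 of those 70 gene
trees (95.7%) contain an edge keeping its sampled members together; the
shortfall from 100% is exactly the injected NNI estimation error.
`annotate_reference(species, tab)` writes these values onto the reference
as `congruence|decisive` node labels — e.g. `95.7|70` — the conventional
display beneath internodes, and survives a newick round-trip.

The same operations are scriptable from a shell via the thin wrapper in
`inst/cli/`:

```sh
concord simulate --taxa 40 --genes 516 --missingness 0.5 --nni-rate 1 --seed 7 --out-prefix sim/
concord concord  --ref sim/species.nwk --genes sim/genes.nwk --out table.tsv --annotated ann.nwk
concord concat   --groups sim/groups --universe taxa.txt --out matrix.phy \
                 --partitions parts.txt --report occ.tsv
```

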