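# Deterministic simulator: Yule species trees, incomplete error-laden gene
# trees (NNI perturbation + leaf subsampling), and orthogroup alignments.
# Gene-tree error is modeled as topological (NNI) noise rather than
# coalescent incongruence: at deep interordinal divergences, apparent
# conflict among single-gene trees is dominated by estimation error, and
# NNI count gives direct control of topological distance.

# Evaluate code under a temporary RNG state so that every simulator call is
# a pure function of its seed and callers' RNG streams are untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Simulation configuration
#'
#' Bundles the study-shaped simulation conditions: taxon and gene counts,
#' the per-taxon per-gene drop probability (missingness), the expected
#' number of NNI perturbations per gene, the orthogroup length range, and
#' the master seed. Identical configurations yield identical outputs.
#'
#' Defaults mirror the scale of a 40-taxon, 516-gene transcriptomic matrix
#' with roughly half of all taxon-gene cells sampled.
#'
#' @param n_taxa number of species (>= 4 for any clade to be testable).
#' @param n_genes number of gene trees / orthogroups to draw.
#' @param missingness per-taxon per-gene drop probability in [0, 1).
#' @param nni_rate expected NNI perturbations per gene (Poisson mean).
#' @param length_range integer (min, max) orthogroup column counts.
#' @param seed master integer seed.
#' @return a list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_taxa = 40L, n_genes = 516L, missingness = 0.5,
                              nni_rate = 1, length_range = c(51L, 462L),
                              seed = 1L) {
  if (n_taxa < 4L) stop_validation("n_taxa must be >= 4")
  if (n_genes < 1L) stop_validation("n_genes must be positive")
  if (missingness < 0 || missingness >= 1) {
    stop_validation("missingness must be in [0, 1)")
  }
  if (nni_rate < 0) stop_validation("nni_rate must be non-negative")
  if (length(length_range) != 2L || any(length_range < 1L) ||
      length_range[1L] > length_range[2L]) {
    stop_validation("length_range must be positive (min, max)")
  }
  structure(list(n_taxa = as.integer(n_taxa), n_genes = as.integer(n_genes),
                 missingness = missingness, nni_rate = nni_rate,
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Rooted, binary, ultrametric tree with exponential waiting times between
#' speciation events (birth rate 1, no extinction); leaves are labeled
#' \code{t1 ... tn}.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer seed.
#' @return a rooted ultrametric \code{"phylo"}.
#' @export
simulate_yule_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2L) stop_validation("n_taxa must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  tree$tip.label <- sprintf("t%d", seq_len(n_taxa))
  tree
}

#' Randomly subsample the leaves of a tree
#'
#' Each leaf is dropped independently with probability \code{missingness};
#' degree-2 nodes are suppressed. Models the partial taxon sampling of
#' single-gene trees. Pruning preserves all induced splits.
#'
#' @param tree a \code{"phylo"}.
#' @param missingness drop probability in [0, 1).
#' @param seed integer seed.
#' @return the pruned \code{"phylo"}, or \code{NULL} (discard marker) when
#'   fewer than four leaves survive.
#' @export
subsample_leaves <- function(tree, missingness, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (missingness < 0 || missingness >= 1) {
    stop_validation("missingness must be in [0, 1)")
  }
  n <- length(tree$tip.label)
  dropped <- with_seed(seed, stats::runif(n) < missingness)
  if (n - sum(dropped) < 4L) return(NULL)
  if (!any(dropped)) return(tree)
  ape::drop.tip(tree, tree$tip.label[dropped])
}

#' Perturb a tree by random NNI moves
#'
#' Applies \code{k} nearest-neighbor interchanges, each picking an internal
#' edge uniformly at random and one of its two possible subtree swaps with
#' probability 1/2. The leafset is unchanged; each move replaces exactly one
#' split. Rooted input is unrooted first (statistics here never use the
#' root or branch lengths).
#'
#' @param tree a \code{"phylo"} with at least one internal edge when read
#'   as unrooted (i.e. >= 4 leaves, not a star).
#' @param k number of moves (>= 0).
#' @param seed integer seed.
#' @return the perturbed unrooted \code{"phylo"}.
#' @export
perturb_nni <- function(tree, k, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (k < 0) stop_validation("k must be >= 0")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  if (k == 0L) return(tree)
  n <- length(tree$tip.label)
  e <- tree$edge
  # internal edges: child end is an internal node (the stored root has no
  # parent edge, so these rows enumerate each internal edge exactly once)
  candidates <- which(e[, 2L] > n)
  if (length(candidates) == 0L) {
    stop_validation("tree has no internal edges to perturb")
  }
  with_seed(seed, {
    for (move in seq_len(k)) {
      j <- candidates[sample.int(length(candidates), 1L)]
      p <- e[j, 1L]
      v <- e[j, 2L]
      kid_rows <- which(e[, 1L] == v)
      gc_row <- kid_rows[sample.int(length(kid_rows), 1L)]  # which swap: 1/2
      sib_rows <- which(e[, 1L] == p & e[, 2L] != v)
      s_row <- sib_rows[1L]
      e[gc_row, 1L] <- p
      e[s_row, 1L] <- v
    }
  })
  tree$edge <- e
  attr(tree, "order") <- NULL
  stats::reorder(tree, "cladewise")
}

#' Simulate a set of incomplete, error-laden gene trees
#'
#' For each gene: draw an NNI count from Poisson(\code{nni_rate}), perturb a
#' copy of the species tree by that many moves, then subsample its leaves at
#' the configured missingness. Genes left with fewer than four leaves are
#' discarded (reported, not regenerated, so the realized gene count can be
#' smaller than requested). Per-gene seeds are derived deterministically
#' from the master seed, independent of iteration order.
#'
#' @param species_tree a rooted \code{"phylo"} whose leaf count equals
#'   \code{config$n_taxa}.
#' @param config a \code{\link{simulation_config}}.
#' @return a list of class \code{"gene_tree_set"}: \code{trees} (named list
#'   of unrooted \code{"phylo"}), \code{names}, \code{discarded} (count) and
#'   \code{requested}.
#' @export
simulate_gene_tree_set <- function(species_tree, config) {
  stopifnot(inherits(species_tree, "phylo"),
            inherits(config, "simulation_config"))
  if (length(species_tree$tip.label) != config$n_taxa) {
    stop_validation("species tree has ", length(species_tree$tip.label),
                    " leaves but config$n_taxa = ", config$n_taxa)
  }
  seeds <- with_seed(config$seed,
                     matrix(sample.int(2147483646L, 3L * config$n_genes,
                                       replace = TRUE),
                            ncol = 3L))
  base <- ape::unroot(species_tree)
  trees <- list()
  discarded <- 0L
  for (i in seq_len(config$n_genes)) {
    k <- with_seed(seeds[i, 1L], stats::rpois(1L, config$nni_rate))
    gt <- if (k > 0L) perturb_nni(base, k, seeds[i, 2L]) else base
    gt <- subsample_leaves(gt, config$missingness, seeds[i, 3L])
    if (is.null(gt)) {
      discarded <- discarded + 1L
      next
    }
    trees[[sprintf("g%04d", i)]] <- gt
  }
  if (discarded > 0L) {
    message(sprintf("simulate_gene_tree_set: discarded %d gene(s) with < 4 leaves",
                    discarded))
  }
  structure(list(trees = trees, names = names(trees), discarded = discarded,
                 requested = config$n_genes),
            class = "gene_tree_set")
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat(sprintf("gene tree set: %d tree(s) (%d requested, %d discarded)\n",
              length(x$trees), x$requested, x$discarded))
  invisible(x)
}

#' Simulate orthogroup alignments
#'
#' One gapless alignment per gene: uniform random length within the range,
#' residues drawn uniformly from the 20 amino-acid letters, uniform [0, 1]
#' column scores, taxa as given by the per-gene presence sets. No
#' substitution model is involved; these fixtures exercise the supermatrix
#' bookkeeping, not sequence evolution.
#'
#' @param species taxon universe.
#' @param presence list of character vectors: the taxa present in each gene.
#' @param length_range integer (min, max) column counts.
#' @param seed integer seed.
#' @return list of \code{"orthogroup"} objects named \code{g0001 ...}.
#' @export
simulate_orthogroups <- function(species, presence,
                                 length_range = c(51L, 462L), seed = 1L) {
  species <- taxon_universe(species)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (i in seq_along(presence)) {
    if (!all(presence[[i]] %in% species)) {
      stop_validation("presence set ", i, " contains taxa outside the universe")
    }
  }
  with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], length(presence),
                   replace = TRUE)
    lapply(seq_along(presence), function(i) {
      taxa <- presence[[i]]
      seqs <- vapply(taxa, function(t) {
        paste(sample(aa, lens[i], replace = TRUE), collapse = "")
      }, character(1L))
      orthogroup(sprintf("g%04d", i), seqs, stats::runif(lens[i]))
    })
  })
}
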