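# Shared fixtures built in code.

quartet <- function() read_newick("((A,B),(C,D));")

# Independent split enumerator used as an oracle against tree_splits():
# phangorn's bipartition machinery, reduced to canonical key strings.
phangorn_split_keys <- function(tree) {
  sp <- phangorn::as.splits(tree)
  labs <- attr(sp, "labels")
  n <- length(labs)
  keys <- vapply(sp, function(idx) {
    if (length(idx) < 2L || n - length(idx) < 2L) return(NA_character_)
    split_key(labs[idx], labs)
  }, character(1L))
  sort(unique(keys[!is.na(keys)]))
}

# All 15 unrooted binary topologies on 5 labelled leaves, via phangorn's
# exhaustive enumerator (independent of this package's tree code).
all_five_leaf_trees <- function(labels = c("A", "B", "C", "D", "E")) {
  trees <- phangorn::allTrees(5, rooted = FALSE, tip.label = labels)
  lapply(seq_along(trees), function(i) trees[[i]])  # decompress tip labels
}

# Random universe + random clade partition of it, for property tests.
random_clade <- function(universe) {
  n <- length(universe)
  sizes <- c(d1 = sample(1:(n - 3L), 1L))
  rest <- n - sizes[["d1"]]
  sizes[["d2"]] <- sample(1:(rest - 2L), 1L)
  shuffled <- sample(universe)
  d1 <- shuffled[seq_len(sizes[["d1"]])]
  d2 <- shuffled[sizes[["d1"]] + seq_len(sizes[["d2"]])]
  clade_definition(d1, d2, setdiff(shuffled, c(d1, d2)))
}

expect_same_splits <- function(a, b) {
  expect_setequal(names(tree_splits(a)), names(tree_splits(b)))
}
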