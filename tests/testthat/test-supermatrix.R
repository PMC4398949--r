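test_that("longest-ORF selection keeps one maximum per locus, first on ties", {
  recs <- data.frame(locus_id = c("L1", "L1", "L2"),
                     orf_id = c("a", "b", "c"),
                     length = c(300L, 450L, 120L))
  expect_setequal(select_longest_per_locus(recs), c("b", "c"))

  tie <- data.frame(locus_id = c("L1", "L1"), orf_id = c("a", "b"),
                    length = c(300L, 300L))
  expect_identical(select_longest_per_locus(tie), "a")

  expect_identical(select_longest_per_locus(recs[0, ]), character(0L))
  expect_error(select_longest_per_locus(
    data.frame(locus_id = "L1", orf_id = "a", length = 0L)), ">= 1")

  # 1000 random records vs an independent group-by-max scan
  set.seed(99)
  big <- data.frame(locus_id = sample(sprintf("L%03d", 1:120), 1000L,
                                      replace = TRUE),
                    orf_id = sprintf("orf%04d", 1:1000),
                    length = sample.int(2000L, 1000L, replace = TRUE))
  got <- select_longest_per_locus(big)
  brute <- vapply(split(big, big$locus_id), function(d) {
    d$orf_id[which.max(d$length)]  # which.max: first maximum = smallest rank
  }, character(1L))
  expect_setequal(got, unname(brute))
})

test_that("column masking removes scores strictly below the threshold", {
  g <- orthogroup("g1", c(X = "MKLV", Y = "M-LV"),
                  scores = c(0.9, 0.4, 0.5, 0.2))
  m <- mask_columns(g, 0.5)
  expect_identical(unname(m$seqs), c("ML", "ML"))  # boundary 0.5 retained
  expect_identical(m$scores, c(0.9, 0.5))

  all_good <- orthogroup("g2", c(X = "AAA"), scores = c(0.9, 0.8, 0.7))
  expect_identical(mask_columns(all_good, 0.5), all_good)

  wiped <- mask_columns(orthogroup("g3", c(X = "AAA"),
                                   scores = c(0.1, 0.2, 0.3)), 0.5)
  expect_equal(aln_length(wiped), 0L)

  expect_error(mask_columns(orthogroup("g4", c(X = "AA")), 0.5), "no column scores")
  expect_error(orthogroup("g5", c(X = "AA"), scores = 0.5), "2 columns")
})

test_that("orthogroup filters use strict inequalities on taxa and length", {
  mk <- function(n_taxa, len) {
    orthogroup(paste0("n", n_taxa, "l", len),
               stats::setNames(rep(strrep("A", len), n_taxa),
                               sprintf("t%d", seq_len(n_taxa))))
  }
  groups <- list(mk(4, 200), mk(5, 200), mk(10, 50), mk(10, 51))
  kept <- vapply(filter_orthogroups(groups), `[[`, character(1L), "group_id")
  expect_identical(kept, c("n5l200", "n10l51"))
  expect_identical(filter_orthogroups(list()), list())
})

test_that("concatenation fills absent taxa and records partitions", {
  g1 <- orthogroup("g1", c(X = "AAAA", Y = "CCCC"))
  g2 <- orthogroup("g2", c(Y = "DDDDDD", Z = "EEEEEE"))
  sm <- concatenate(list(g1, g2), c("X", "Y", "Z"))
  expect_equal(sm$n_col, 10L)
  expect_identical(unname(sm$rows["X"]), "AAAA------")
  expect_identical(unname(sm$rows["Y"]), "CCCCDDDDDD")
  expect_identical(unname(sm$rows["Z"]), "----EEEEEE")
  expect_identical(sm$partitions$start, c(1L, 5L))
  expect_identical(sm$partitions$end, c(4L, 10L))
  expect_equal(occupancy(sm), 20 / 30)

  single <- concatenate(list(g1), c("X", "Y"))
  expect_identical(unname(single$rows), unname(g1$seqs))

  expect_error(concatenate(list(g1), c("X")), "outside the universe")
})

test_that("occupancy equals a brute-force per-cell count", {
  set.seed(7)
  universe <- sprintf("t%02d", 1:12)
  presence <- lapply(1:30, function(i) {
    universe[stats::runif(12) < 0.6]
  })
  presence <- Filter(length, presence)
  groups <- simulate_orthogroups(universe, presence, c(5L, 40L), seed = 8)
  # inject within-sequence gaps so the two unoccupied sources mix
  groups[[1]]$seqs[1] <- paste0("--", substring(groups[[1]]$seqs[1], 3))
  sm <- concatenate(groups, universe)

  brute <- 0L
  for (tx in universe) {
    cells <- strsplit(sm$rows[[tx]], "", fixed = TRUE)[[1L]]
    for (ch in cells) if (!ch %in% c("-", "?", "X")) brute <- brute + 1L
  }
  expect_equal(occupancy(sm), brute / (12 * sm$n_col))

  # column conservation and per-taxon / per-group decomposition
  expect_equal(sum(sm$partitions$end - sm$partitions$start + 1L), sm$n_col)
  rep <- occupancy_report(sm)
  expect_equal(rep$occupied_cells[rep$scope == "overall"],
               sum(rep$occupied_cells[rep$scope == "taxon"]))
  expect_equal(rep$occupied_cells[rep$scope == "overall"],
               sum(rep$occupied_cells[rep$scope == "group"]))

  # all-fill and gapless extremes
  empty <- concatenate(list(orthogroup("e", c(t01 = "----"))), universe)
  expect_equal(occupancy(empty), 0)
  full <- concatenate(list(orthogroup("f",
    stats::setNames(rep("KKKK", 12), universe))), universe)
  expect_equal(occupancy(full), 1)
})

test_that("taxon deletion drops rows only and decomposes occupancy", {
  set.seed(31)
  universe <- sprintf("t%02d", 1:40)
  presence <- lapply(1:25, function(i) universe[stats::runif(40) < 0.5])
  presence <- Filter(length, presence)
  groups <- simulate_orthogroups(universe, presence, c(10L, 50L), seed = 32)
  sm <- concatenate(groups, universe)

  drop <- universe[1:8]
  pruned <- delete_taxa_matrix(sm, drop)
  expect_length(pruned$taxa, 32L)
  expect_equal(pruned$n_col, sm$n_col)
  expect_identical(pruned$partitions, sm$partitions)

  # occupancy after deletion = occupancy recomputed on surviving rows
  rep <- occupancy_report(sm)
  surviving <- rep$occupied_cells[rep$scope == "taxon" &
                                    !rep$name %in% drop]
  expect_equal(occupancy(pruned), sum(surviving) / (32 * sm$n_col))

  expect_identical(delete_taxa_matrix(sm, character(0L))$rows, sm$rows)
  expect_error(delete_taxa_matrix(sm, "nope"), "not in matrix")
})

test_that("gene-tree pruning restricts splits and discards tiny trees", {
  expect_message(
    out <- prune_gene_trees(list(quartet()), "A"),
    "discarded 1")
  expect_length(out, 0L)

  genes <- lapply(1:5, function(s) ape::unroot(ape::rtree(10)))
  same <- prune_gene_trees(genes, character(0L))
  for (i in 1:5) expect_same_splits(same[[i]], genes[[i]])

  drop <- c("t1", "t2", "t3")
  pruned <- prune_gene_trees(genes, drop)
  for (i in seq_along(pruned)) {
    got <- names(tree_splits(pruned[[i]]))
    # induced restriction of the original splits to the surviving leafset
    orig <- tree_splits(genes[[i]])
    kept_leaves <- pruned[[i]]$tip.label
    restricted <- unique(unlist(lapply(orig, function(block) {
      b <- intersect(block, kept_leaves)
      if (length(b) < 2L || length(kept_leaves) - length(b) < 2L) return(NULL)
      split_key(b, kept_leaves)
    })))
    expect_setequal(got, restricted)
  }
})

test_that("matrix, partition and orthogroup files round-trip", {
  dir <- withr::local_tempdir()
  g1 <- orthogroup("g1", c(X = "MKLV", Y = "M-LV"), scores = c(1, 1, 0.5, 0))
  g2 <- orthogroup("g2", c(Y = "DDDDDD", Z = "EEEEEE"))
  write_orthogroups(list(g1, g2), file.path(dir, "groups"))
  back <- read_orthogroups(file.path(dir, "groups"))
  expect_identical(back$g1$seqs, g1$seqs)
  expect_equal(back$g1$scores, g1$scores)
  expect_null(back$g2$scores)

  sm <- concatenate(list(g1, g2), c("X", "Y", "Z"))
  phy <- file.path(dir, "m.phy")
  parts <- file.path(dir, "parts.txt")
  write_supermatrix_phylip(sm, phy)
  write_partitions(sm, parts)
  rt <- read_supermatrix_phylip(phy, parts)
  expect_identical(rt$rows, sm$rows)
  expect_identical(rt$partitions, sm$partitions)
  expect_equal(occupancy(rt), occupancy(sm))

  fa <- file.path(dir, "m.fa")
  write_supermatrix_fasta(sm, fa)
  aa <- Biostrings::readAAStringSet(fa)
  expect_identical(stats::setNames(as.character(aa), names(aa)), sm$rows)
})
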