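# -- validation helpers -------------------------------------------------------

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("concord_validation_error", "error")))
}

#' Validate a taxon universe
#'
#' A taxon universe is an ordered character vector of unique, non-empty taxon
#' labels. Its order is stable within a run and defines the index space for
#' all split operations.
#'
#' @param labels character vector of taxon labels.
#' @return the validated character vector, invisibly usable as a universe.
#' @export
taxon_universe <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop_validation("taxon universe is empty")
  if (anyDuplicated(labels)) {
    stop_validation("duplicate taxon labels in universe: ",
                    paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (any(!nzchar(labels))) stop_validation("empty taxon label in universe")
  labels
}

# -- newick I/O ---------------------------------------------------------------

# Balanced-parenthesis scan that honours single-quoted labels; returns the
# 1-based offset of the first offending character, or 0L if balanced.
.paren_offence <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  if (depth != 0L) return(nchar(text))
  0L
}

#' Parse a newick string into a tree
#'
#' Wraps the \pkg{ape} newick reader with stricter validation: the statement
#' must end in \code{';'}, parentheses must balance (the error names the
#' character offset of the first offence), and duplicate leaf labels are
#' rejected. Leaf labels, branch lengths, internal-node labels (support
#' values) and polytomies are preserved. Internal-node labels are always
#' treated as support strings, never as taxon names.
#'
#' @param text a single newick statement ending in \code{';'}.
#' @return an object of class \code{"phylo"}.
#' @export
read_newick <- function(text) {
  text <- trimws(text)
  if (length(text) != 1L || !nzchar(text)) {
    stop_validation("expected a single newick statement")
  }
  if (!endsWith(text, ";")) {
    stop_validation("newick statement must end in ';' (offset ", nchar(text), ")")
  }
  off <- .paren_offence(text)
  if (off > 0L) {
    stop_validation("unbalanced parentheses in newick at offset ", off)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop_validation("malformed newick statement")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop_validation("duplicate leaf label: ",
                    paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                          collapse = ", "))
  }
  tree
}

#' Serialize a tree to newick
#'
#' Inverse of \code{\link{read_newick}} up to printed precision: the
#' round-trip preserves the leafset, the split set, branch lengths and
#' internal node labels.
#'
#' @param tree a \code{"phylo"} object.
#' @return a single newick string ending in \code{';'}.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Read a multi-tree newick file (one tree per line)
#'
#' @param path file with one newick statement per line.
#' @return a named list of \code{"phylo"} objects; names are taken from the
#'   file if present, else \code{gene1 ... geneN}.
#' @export
read_gene_trees <- function(path) {
  if (!file.exists(path)) stop_validation("tree file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  trees <- lapply(lines, read_newick)
  names(trees) <- sprintf("gene%d", seq_along(trees))
  trees
}

#' Write a list of trees as newick, one per line
#'
#' @param trees list of \code{"phylo"} objects (or a \code{gene_tree_set}).
#' @param path output file.
#' @export
write_gene_trees <- function(trees, path) {
  trees <- as_tree_list(trees)
  writeLines(vapply(trees, write_newick, character(1L)), path)
  invisible(path)
}

# Accepts phylo, multiPhylo, plain list of phylo, or gene_tree_set.
as_tree_list <- function(trees) {
  if (inherits(trees, "gene_tree_set")) return(trees$trees)
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) return(unclass(trees))
  if (is.list(trees) && all(vapply(trees, inherits, logical(1L), "phylo"))) {
    return(trees)
  }
  stop_validation("expected a tree, a list of trees, or a gene_tree_set")
}

# -- split engine -------------------------------------------------------------

# Tip-index sets descending from every node, by postorder accumulation.
.node_tipsets <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  e <- tree$edge
  for (j in seq_len(nrow(e))) {
    desc[[e[j, 1L]]] <- c(desc[[e[j, 1L]]], desc[[e[j, 2L]]])
  }
  desc
}

#' Canonical key of a bipartition
#'
#' A split is represented by the block containing the first taxon of the
#' (sorted) leafset it is defined over, so that a split and its complement
#' map to the same key.
#'
#' @param block character vector, one block of the split.
#' @param leafset character vector, the full leafset the split lives on.
#' @return a single string identifying the unordered bipartition.
#' @export
split_key <- function(block, leafset) {
  if (!all(block %in% leafset)) {
    stop_validation("block contains taxa outside the leafset: ",
                    paste(setdiff(block, leafset), collapse = ", "))
  }
  anchor <- sort(leafset)[1L]
  side <- if (anchor %in% block) block else setdiff(leafset, block)
  paste(sort(side), collapse = "\t")
}

#' Non-trivial splits of a tree
#'
#' Enumerates the bipartitions induced by the internal edges of the tree,
#' read as unrooted: a rooted tree's two root edges define the same split,
#' which is counted once. Trivial splits (a block of fewer than two leaves)
#' are excluded; trees with fewer than four leaves therefore return an empty
#' set. Polytomies are allowed and simply induce fewer splits.
#'
#' @param tree a \code{"phylo"} object.
#' @return a named list of class \code{"split_set"}: each element is the
#'   canonical block (character vector of taxon labels), named by its
#'   \code{\link{split_key}}.
#' @export
tree_splits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  n <- length(labs)
  out <- list()
  if (n >= 4L) {
    desc <- .node_tipsets(tree)
    e <- tree$edge
    internal_children <- unique(e[e[, 2L] > n, 2L])
    anchor <- sort(labs)[1L]
    for (node in internal_children) {
      tips <- desc[[node]]
      if (length(tips) < 2L || n - length(tips) < 2L) next
      block <- labs[tips]
      side <- if (anchor %in% block) block else setdiff(labs, block)
      key <- paste(sort(side), collapse = "\t")
      if (is.null(out[[key]])) out[[key]] <- sort(side)
    }
  }
  structure(out, class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat(length(x), "non-trivial split(s)\n")
  for (b in x) cat(" ", paste(b, collapse = ","), "\n")
  invisible(x)
}

#' Does a tree contain a given split?
#'
#' TRUE iff some edge of the unrooted tree separates exactly \code{block}
#' from its complement in the tree's leafset. This is the congruence
#' primitive: internal resolution on either side of the edge is irrelevant.
#'
#' @param tree a \code{"phylo"} object with at least four leaves.
#' @param block character vector of taxon labels; must be a subset of the
#'   leafset with \code{2 <= |block| <= n - 2}.
#' @return logical scalar.
#' @export
has_split <- function(tree, block) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (!all(block %in% labs)) {
    stop_validation("block contains taxa absent from the tree: ",
                    paste(setdiff(block, labs), collapse = ", "))
  }
  k <- length(unique(block))
  if (k < 2L || k > length(labs) - 2L) {
    stop_validation("block size ", k, " is trivial for a tree on ",
                    length(labs), " leaves")
  }
  split_key(block, labs) %in% names(tree_splits(tree))
}

#' Reroot a tree on the edge subtending a leaf
#'
#' The unrooted split set is unchanged by rerooting.
#'
#' @param tree a \code{"phylo"} object.
#' @param leaf a taxon label present in the tree.
#' @return a rooted \code{"phylo"} object.
#' @export
reroot_at_leaf <- function(tree, leaf) {
  stopifnot(inherits(tree, "phylo"))
  if (!leaf %in% tree$tip.label) {
    stop_validation("leaf not in tree: ", leaf)
  }
  ape::root(tree, outgroup = leaf, resolve.root = TRUE)
}

#' Is a set of leaves monophyletic in a rooted tree?
#'
#' TRUE iff some node's descendant leafset equals \code{block}. Singletons
#' are monophyletic by definition. Implemented via the most recent common
#' ancestor, independently of the split enumeration in
#' \code{\link{has_split}}, so the two can cross-check each other.
#'
#' @param rooted a rooted \code{"phylo"} object.
#' @param block non-empty character vector of taxon labels in the tree.
#' @return logical scalar.
#' @export
is_monophyletic <- function(rooted, block) {
  stopifnot(inherits(rooted, "phylo"))
  block <- unique(block)
  if (length(block) == 0L) stop_validation("empty block")
  labs <- rooted$tip.label
  if (!all(block %in% labs)) {
    stop_validation("block contains taxa absent from the tree: ",
                    paste(setdiff(block, labs), collapse = ", "))
  }
  if (length(block) == 1L) return(TRUE)
  if (length(block) == length(labs)) return(TRUE)
  mrca <- ape::getMRCA(rooted, block)
  tips <- .node_tipsets(rooted)[[mrca]]
  setequal(labs[tips], block)
}

# -- clade definitions --------------------------------------------------------

#' Construct a clade definition directly
#'
#' A focal rooted clade: its two descendant clusters and the basal
#' (outgroup) set. The three sets must be pairwise disjoint and the
#' descendant clusters non-empty; together they form the taxon universe the
#' clade is tested against. Usually produced in bulk by
#' \code{\link{extract_clade_definitions}}; this constructor serves ad-hoc
#' tests of a single clade.
#'
#' @param d1,d2 character vectors, the two descendant clusters.
#' @param outgroup character vector, all universe taxa outside the clade.
#' @param clade_id identifier string.
#' @return an object of class \code{"clade_def"}.
#' @export
clade_definition <- function(d1, d2, outgroup, clade_id = "clade") {
  if (length(d1) == 0L || length(d2) == 0L) {
    stop_validation("descendant clusters must be non-empty")
  }
  all_taxa <- c(d1, d2, outgroup)
  if (anyDuplicated(all_taxa)) {
    stop_validation("d1, d2 and outgroup must be pairwise disjoint")
  }
  structure(list(clade_id = clade_id, d1 = d1, d2 = d2, outgroup = outgroup,
                 node = NA_integer_),
            class = "clade_def")
}

#' Extract the focal clades of a rooted reference tree
#'
#' One definition per internal non-root node of a rooted binary reference:
#' the node's two child clusters (\code{d1}, \code{d2}, in parse order) and
#' the basal set \code{outgroup} (all universe taxa outside the clade). A
#' rooted binary tree on n leaves yields exactly n - 2 definitions; the two
#' children of the root induce the same unrooted split but are kept as
#' distinct clades, each with its own outgroup-facing statistics.
#'
#' @param ref rooted, strictly binary \code{"phylo"} whose leafset equals
#'   \code{universe}.
#' @param universe taxon universe (defaults to the reference's leafset).
#' @return a list of class \code{"clade_defs"}; each element has fields
#'   \code{clade_id}, \code{d1}, \code{d2}, \code{outgroup} and \code{node}
#'   (the internal \pkg{ape} node number, used for annotation).
#' @export
extract_clade_definitions <- function(ref, universe = NULL) {
  stopifnot(inherits(ref, "phylo"))
  if (!ape::is.rooted(ref)) {
    stop_validation("reference tree is unrooted; root it first")
  }
  if (!ape::is.binary(ref)) {
    stop_validation("reference tree has polytomies; resolve it first")
  }
  if (is.null(universe)) universe <- taxon_universe(ref$tip.label)
  universe <- taxon_universe(universe)
  if (!setequal(ref$tip.label, universe)) {
    stop_validation("reference leafset does not equal the taxon universe")
  }
  labs <- ref$tip.label
  n <- length(labs)
  desc <- .node_tipsets(ref)
  root <- n + 1L
  po <- stats::reorder(ref, "postorder")$edge
  internal_postorder <- unique(po[po[, 2L] > n, 2L])
  e <- ref$edge
  defs <- list()
  idx <- 0L
  for (node in internal_postorder) {
    if (node == root) next
    idx <- idx + 1L
    kids <- e[e[, 1L] == node, 2L]
    d1 <- labs[desc[[kids[1L]]]]
    d2 <- labs[desc[[kids[2L]]]]
    clade <- c(d1, d2)
    def <- list(
      clade_id = sprintf("c%03d_%s", idx, sort(clade)[1L]),
      d1 = d1, d2 = d2,
      outgroup = setdiff(universe, clade),
      node = node
    )
    class(def) <- "clade_def"
    defs[[def$clade_id]] <- def
  }
  structure(defs, class = "clade_defs", universe = universe)
}

#' @export
print.clade_defs <- function(x, ...) {
  cat(length(x), "clade definition(s)\n")
  for (d in x) {
    cat(sprintf(" %s: {%s} + {%s} | basal {%s}\n", d$clade_id,
                paste(d$d1, collapse = ","), paste(d$d2, collapse = ","),
                paste(d$outgroup, collapse = ",")))
  }
  invisible(x)
}

#' @export
as.data.frame.clade_defs <- function(x, ...) {
  data.frame(
    clade_id = vapply(x, `[[`, character(1L), "clade_id"),
    clade_taxa = vapply(x, function(d) paste(sort(c(d$d1, d$d2)), collapse = ","),
                        character(1L)),
    n_clade = vapply(x, function(d) length(d$d1) + length(d$d2), integer(1L)),
    n_outgroup = vapply(x, function(d) length(d$outgroup), integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
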