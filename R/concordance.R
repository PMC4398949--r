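# Per-clade decisive gene counts and congruence frequencies over incomplete
# unrooted gene trees, bootstrap clade-frequency summarization, and
# reference-tree annotation.

#' Is a gene's taxon sampling decisive for a clade?
#'
#' A gene (tree) is potentially decisive for a clade when its taxon sampling
#' permits testing the clade at all: it must sample at least one species in
#' each of the clade's two descendant clusters and at least two distinct
#' species basal to the node — minimally a quartet. Genes with fewer than
#' four sampled taxa are therefore never decisive for any clade.
#'
#' @param gene_leafset character vector of taxa sampled by the gene.
#' @param clade a \code{"clade_def"} from
#'   \code{\link{extract_clade_definitions}}.
#' @return logical scalar.
#' @export
is_decisive <- function(gene_leafset, clade) {
  stopifnot(inherits(clade, "clade_def"))
  sum(gene_leafset %in% clade$d1) >= 1L &&
    sum(gene_leafset %in% clade$d2) >= 1L &&
    sum(gene_leafset %in% clade$outgroup) >= 2L
}

#' Is a decisive gene tree congruent with a clade?
#'
#' Among decisive genes, a gene tree is congruent with a clade when its
#' sampled clade members are monophyletic with respect to the sampled
#' outsiders — i.e. the unrooted gene tree contains an edge separating
#' exactly the sampled members of \code{d1 + d2} from everything else. The
#' count is agnostic to the topology within the clade and within the
#' outgroup. A polytomy that is merely compatible with the clade, without an
#' actual resolving edge, is not congruent.
#'
#' @param gene_tree a \code{"phylo"} object; must be decisive for the clade
#'   (checked; non-decisive input is an error, gate on
#'   \code{\link{is_decisive}}).
#' @param clade a \code{"clade_def"}.
#' @return logical scalar.
#' @export
is_congruent <- function(gene_tree, clade) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(clade, "clade_def"))
  leafset <- gene_tree$tip.label
  if (!is_decisive(leafset, clade)) {
    stop_validation("gene tree is not decisive for clade ", clade$clade_id,
                    "; gate calls on is_decisive()")
  }
  block <- leafset[leafset %in% c(clade$d1, clade$d2)]
  has_split(gene_tree, block)
}

# Congruence check against a precomputed split-key set (fast path used by
# concordance_table; identical semantics to is_congruent).
.congruent_keys <- function(keys, leafset, clade) {
  block <- leafset[leafset %in% c(clade$d1, clade$d2)]
  split_key(block, leafset) %in% keys
}

#' Per-clade decisive counts and congruence frequencies
#'
#' For every clade of the rooted reference tree, counts the gene trees that
#' are decisive for it and, among those, the ones congruent with it. The
#' congruence frequency is the percentage of decisive genes that are
#' congruent (NA when no gene is decisive).
#'
#' @param ref rooted binary reference \code{"phylo"} over \code{universe}.
#' @param genes gene trees: a list of \code{"phylo"}, a \code{multiPhylo},
#'   or a \code{\link{simulate_gene_tree_set}} result. Each tree's leafset
#'   must lie within the universe.
#' @param universe taxon universe; defaults to the reference's leafset.
#' @param unknown_taxon_policy what to do with gene-tree leaves absent from
#'   the universe: \code{"error"} (default) aborts; \code{"ignore"} drops
#'   the offending leaves with a warning reporting how many were dropped.
#' @return a \code{data.frame} with one row per clade and columns
#'   \code{clade_id}, \code{clade_taxa} (comma-joined, sorted),
#'   \code{n_genes}, \code{n_decisive}, \code{n_congruent},
#'   \code{congruence_pct}.
#' @export
concordance_table <- function(ref, genes, universe = NULL,
                              unknown_taxon_policy = c("error", "ignore")) {
  unknown_taxon_policy <- match.arg(unknown_taxon_policy)
  defs <- extract_clade_definitions(ref, universe)
  universe <- attr(defs, "universe")
  trees <- as_tree_list(genes)
  n_genes <- length(trees)

  dropped <- 0L
  leafsets <- vector("list", n_genes)
  keysets <- vector("list", n_genes)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (anyDuplicated(tr$tip.label)) {
      stop_validation("gene tree ", i, " has duplicate leaf labels")
    }
    extra <- setdiff(tr$tip.label, universe)
    if (length(extra) > 0L) {
      if (unknown_taxon_policy == "error") {
        stop_validation("gene tree ", i, " has leaves outside the universe: ",
                        paste(extra, collapse = ", "))
      }
      dropped <- dropped + length(extra)
      if (length(tr$tip.label) - length(extra) >= 2L) {
        tr <- ape::drop.tip(tr, extra)
      } else {
        tr <- NULL
      }
    }
    if (!is.null(tr)) {
      leafsets[[i]] <- tr$tip.label
      keysets[[i]] <- names(tree_splits(tr))
    } else {
      leafsets[[i]] <- character(0L)
      keysets[[i]] <- character(0L)
    }
  }
  if (dropped > 0L) {
    warning(sprintf("dropped %d gene-tree leaf/leaves absent from the universe",
                    dropped))
  }

  n_dec <- integer(length(defs))
  n_con <- integer(length(defs))
  for (k in seq_along(defs)) {
    def <- defs[[k]]
    for (i in seq_len(n_genes)) {
      ls <- leafsets[[i]]
      if (!is_decisive(ls, def)) next
      n_dec[k] <- n_dec[k] + 1L
      if (.congruent_keys(keysets[[i]], ls, def)) n_con[k] <- n_con[k] + 1L
    }
  }

  data.frame(
    clade_id = vapply(defs, `[[`, character(1L), "clade_id"),
    clade_taxa = vapply(defs, function(d) paste(sort(c(d$d1, d$d2)),
                                                collapse = ","), character(1L)),
    n_genes = n_genes,
    n_decisive = n_dec,
    n_congruent = n_con,
    congruence_pct = ifelse(n_dec > 0L, 100 * n_con / n_dec, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Bootstrap clade-frequency summarization
#'
#' For every clade of the reference, the percentage of replicate trees whose
#' split set contains the clade's unrooted split. Replicates must be
#' complete (same leafset as the reference), as bootstrap replicates are by
#' construction. Clades whose unrooted split is trivial (a single-taxon
#' basal set) are present in every tree and reported as 100.
#'
#' @param ref rooted binary reference \code{"phylo"}.
#' @param replicates list of replicate trees (e.g. bootstrap trees), each on
#'   the same leafset as \code{ref}.
#' @return named numeric vector: support percentage per \code{clade_id}.
#' @export
clade_support <- function(ref, replicates) {
  defs <- extract_clade_definitions(ref)
  universe <- attr(defs, "universe")
  reps <- as_tree_list(replicates)
  if (length(reps) == 0L) stop_validation("no replicate trees supplied")
  for (i in seq_along(reps)) {
    if (!setequal(reps[[i]]$tip.label, universe)) {
      stop_validation("replicate ", i, " leafset differs from the reference ",
                      "(bootstrap replicates must be complete)")
    }
  }
  keysets <- lapply(reps, function(tr) names(tree_splits(tr)))
  out <- vapply(defs, function(def) {
    clade <- c(def$d1, def$d2)
    if (length(def$outgroup) < 2L || length(clade) < 2L) return(100)
    key <- split_key(clade, universe)
    100 * mean(vapply(keysets, function(k) key %in% k, logical(1L)))
  }, numeric(1L))
  names(out) <- vapply(defs, `[[`, character(1L), "clade_id")
  out
}

.fmt_pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))

#' Annotate a reference tree with concordance statistics
#'
#' Labels each internal non-root node of the reference with
#' \code{"congruence_pct|n_decisive"} (and, when bootstrap supports are
#' supplied, \code{"congruence_pct|n_decisive|support"}); NA congruence is
#' rendered \code{"NA"}. The labels survive a \code{\link{write_newick}}
#' round-trip.
#'
#' @param ref rooted binary reference \code{"phylo"}.
#' @param rows a \code{\link{concordance_table}} result keyed to this
#'   reference's clade ids.
#' @param supports optional named vector from \code{\link{clade_support}}.
#' @return a list with elements \code{tree} (the labeled \code{"phylo"}) and
#'   \code{table} (the display table, congruence to one decimal place).
#' @export
annotate_reference <- function(ref, rows, supports = NULL) {
  defs <- extract_clade_definitions(ref)
  unknown <- setdiff(rows$clade_id, names(defs))
  if (length(unknown) > 0L) {
    stop_validation("unknown clade_id(s): ", paste(unknown, collapse = ", "))
  }
  labels <- rep("", ref$Nnode)
  n <- length(ref$tip.label)
  for (i in seq_len(nrow(rows))) {
    def <- defs[[rows$clade_id[i]]]
    lab <- paste0(.fmt_pct(rows$congruence_pct[i]), "|", rows$n_decisive[i])
    if (!is.null(supports)) {
      lab <- paste0(lab, "|", .fmt_pct(unname(supports[rows$clade_id[i]])))
    }
    labels[def$node - n] <- lab
  }
  ref$node.label <- labels
  table <- rows
  table$congruence_pct <- .fmt_pct(rows$congruence_pct)
  if (!is.null(supports)) {
    table$support_pct <- .fmt_pct(unname(supports[rows$clade_id]))
  }
  list(tree = ref, table = table)
}
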