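# Supermatrix construction bookkeeping: longest-ORF selection, column
# masking, orthogroup filtering, concatenation with occupancy accounting,
# and taxon-deletion pruning.

#' Keep the longest ORF per locus
#'
#' Transcriptome assemblers emit multiple putative open reading frames per
#' assembly subcomponent (locus); downstream orthology assignment wants one
#' representative each. Keeps, for every distinct \code{locus_id}, the
#' \code{orf_id} with maximum amino-acid length; ties go to the record seen
#' first in input order.
#'
#' @param records a \code{data.frame} with columns \code{locus_id},
#'   \code{orf_id} and \code{length} (positive integers, amino acids).
#'   Input row order defines the tie-break rank.
#' @return character vector of selected \code{orf_id}s, one per locus, in
#'   order of each locus's first appearance.
#' @export
select_longest_per_locus <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(character(0L))
  need <- c("locus_id", "orf_id", "length")
  if (!all(need %in% names(records))) {
    stop_validation("records must have columns: ", paste(need, collapse = ", "))
  }
  if (any(records$length < 1L)) stop_validation("ORF lengths must be >= 1")
  if (anyDuplicated(records[c("locus_id", "orf_id")])) {
    stop_validation("duplicate (locus_id, orf_id) pair")
  }
  rank <- seq_len(nrow(records))
  locus <- factor(records$locus_id, levels = unique(records$locus_id))
  o <- order(locus, -records$length, rank)
  keep <- o[!duplicated(locus[o])]
  records$orf_id[sort(keep)]
}

# -- orthogroup alignments ----------------------------------------------------

#' Construct an orthogroup alignment
#'
#' A container for one aligned orthologous group: at most one amino-acid
#' sequence per taxon, all of the same length, with optional per-column
#' alignment-confidence scores in [0, 1] (ZORRO-style).
#'
#' @param group_id orthogroup identifier.
#' @param seqs named character vector, taxon label -> aligned sequence
#'   (gap \code{'-'}); all of equal length.
#' @param scores optional numeric vector, one score per column.
#' @return an object of class \code{"orthogroup"}.
#' @export
orthogroup <- function(group_id, seqs, scores = NULL) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop_validation("sequences must be named by taxon")
  }
  if (anyDuplicated(names(seqs))) {
    stop_validation("more than one sequence per taxon in group ", group_id)
  }
  lens <- unique(nchar(seqs))
  if (length(lens) > 1L) {
    stop_validation("unequal sequence lengths in group ", group_id, ": ",
                    paste(lens, collapse = ", "))
  }
  width <- if (length(seqs) == 0L) 0L else lens
  if (!is.null(scores)) {
    if (length(scores) != width) {
      stop_validation("group ", group_id, ": ", length(scores),
                      " scores for ", width, " columns")
    }
    if (any(scores < 0 | scores > 1)) {
      stop_validation("group ", group_id, ": scores outside [0, 1]")
    }
  }
  structure(list(group_id = group_id, seqs = seqs, scores = scores),
            class = "orthogroup")
}

#' @export
print.orthogroup <- function(x, ...) {
  cat(sprintf("orthogroup %s: %d taxa x %d columns%s\n", x$group_id,
              length(x$seqs), aln_length(x),
              if (is.null(x$scores)) "" else " (scored)"))
  invisible(x)
}

#' Alignment length (columns) of an orthogroup
#' @param group an \code{"orthogroup"}.
#' @return integer column count.
#' @export
aln_length <- function(group) {
  if (length(group$seqs) == 0L) return(0L)
  nchar(group$seqs[[1L]])
}

#' Mask low-confidence alignment columns
#'
#' Retains exactly the columns whose confidence score is at or above the
#' threshold; columns scoring strictly below are removed. Column order and
#' the score vector are subset accordingly. A boundary score equal to the
#' threshold is retained.
#'
#' @param aln an \code{"orthogroup"} with scores present.
#' @param threshold numeric masking threshold; default 0.5.
#' @return the masked \code{"orthogroup"}.
#' @export
mask_columns <- function(aln, threshold = 0.5) {
  stopifnot(inherits(aln, "orthogroup"))
  if (is.null(aln$scores)) {
    stop_validation("group ", aln$group_id, " has no column scores")
  }
  keep <- aln$scores >= threshold
  if (all(keep)) return(aln)
  seqs <- vapply(strsplit(aln$seqs, "", fixed = TRUE),
                 function(ch) paste(ch[keep], collapse = ""), character(1L))
  names(seqs) <- names(aln$seqs)
  orthogroup(aln$group_id, seqs, aln$scores[keep])
}

#' Filter orthogroups on taxon count and masked length
#'
#' Keeps the groups worth carrying into phylogenetic analysis: strictly more
#' than \code{min_taxa_exclusive} taxa and a (post-masking) alignment length
#' strictly greater than \code{min_length_exclusive} amino acids. A group
#' with exactly 4 taxa, or exactly 50 columns, is excluded under the
#' defaults. Order is preserved.
#'
#' @param groups list of \code{"orthogroup"} objects (post-masking).
#' @param min_taxa_exclusive exclusive lower bound on taxon count; default 4.
#' @param min_length_exclusive exclusive lower bound on columns; default 50.
#' @return the retained sublist.
#' @export
filter_orthogroups <- function(groups, min_taxa_exclusive = 4L,
                               min_length_exclusive = 50L) {
  Filter(function(g) {
    length(g$seqs) > min_taxa_exclusive && aln_length(g) > min_length_exclusive
  }, groups)
}

# -- supermatrix --------------------------------------------------------------

#' Concatenate orthogroup alignments into a supermatrix
#'
#' Column-wise concatenation over a common taxon universe: taxa absent from
#' a group are filled with the gap character for that group's block. The
#' partition map records each group's 1-based inclusive column span, in
#' concatenation order.
#'
#' @param groups list of \code{"orthogroup"} objects.
#' @param universe taxon universe; every group taxon must belong to it.
#' @param fill_char fill character for missing taxa; default \code{'-'}.
#' @return an object of class \code{"supermatrix"}: fields \code{taxa},
#'   \code{n_col}, \code{rows} (named character vector of row strings),
#'   \code{partitions} (data.frame \code{group_id}, \code{start},
#'   \code{end}) and \code{fill_char}.
#' @export
concatenate <- function(groups, universe, fill_char = "-") {
  universe <- taxon_universe(universe)
  lens <- vapply(groups, aln_length, integer(1L))
  ids <- vapply(groups, `[[`, character(1L), "group_id")
  for (g in groups) {
    extra <- setdiff(names(g$seqs), universe)
    if (length(extra) > 0L) {
      stop_validation("group ", g$group_id, " has taxa outside the universe: ",
                      paste(extra, collapse = ", "))
    }
  }
  pieces <- matrix("", nrow = length(universe), ncol = length(groups),
                   dimnames = list(universe, NULL))
  for (j in seq_along(groups)) {
    pieces[, j] <- strrep(fill_char, lens[j])
    pieces[names(groups[[j]]$seqs), j] <- unname(groups[[j]]$seqs)
  }
  rows <- apply(pieces, 1L, paste, collapse = "")
  if (length(groups) == 0L) rows <- stats::setNames(rep("", length(universe)),
                                                    universe)
  ends <- cumsum(lens)
  structure(list(
    taxa = universe,
    n_col = if (length(lens)) sum(lens) else 0L,
    rows = rows,
    partitions = data.frame(group_id = ids,
                            start = if (length(lens)) ends - lens + 1L else integer(0L),
                            end = ends,
                            stringsAsFactors = FALSE),
    fill_char = fill_char
  ), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d columns, %d partitions\n",
              length(x$taxa), x$n_col, nrow(x$partitions)))
  invisible(x)
}

# Occupied-cell count of a character row (ASCII alignment strings).
.count_occupied <- function(row, unoccupied) {
  if (!nzchar(row)) return(0L)
  raw <- charToRaw(row)
  sum(!(raw %in% charToRaw(paste(unoccupied, collapse = ""))))
}

#' Matrix occupancy
#'
#' Fraction of supermatrix cells holding an actual residue rather than a
#' gap or missing-data symbol, over all taxa x columns cells. By default
#' within-sequence alignment gaps count as unoccupied, the same as
#' absent-taxon fill; the symbol set is configurable.
#'
#' @param matrix a \code{"supermatrix"}.
#' @param unoccupied_chars characters counted as unoccupied;
#'   default \code{c("-", "?", "X")}.
#' @return numeric in [0, 1] (NA for a zero-cell matrix).
#' @export
occupancy <- function(matrix, unoccupied_chars = c("-", "?", "X")) {
  stopifnot(inherits(matrix, "supermatrix"))
  cells <- length(matrix$taxa) * matrix$n_col
  if (cells == 0L) return(NA_real_)
  occupied <- sum(vapply(matrix$rows, .count_occupied, integer(1L),
                         unoccupied = unoccupied_chars))
  occupied / cells
}

#' Occupancy report: overall, per taxon, per partition
#'
#' @param matrix a \code{"supermatrix"}.
#' @param unoccupied_chars as in \code{\link{occupancy}}.
#' @return a \code{data.frame} with columns \code{scope} (\code{"overall"},
#'   \code{"taxon"} or \code{"group"}), \code{name}, \code{occupied_cells},
#'   \code{total_cells}, \code{occupancy}.
#' @export
occupancy_report <- function(matrix, unoccupied_chars = c("-", "?", "X")) {
  stopifnot(inherits(matrix, "supermatrix"))
  per_taxon <- vapply(matrix$rows, .count_occupied, integer(1L),
                      unoccupied = unoccupied_chars)
  rows <- data.frame(
    scope = "taxon", name = matrix$taxa,
    occupied_cells = unname(per_taxon[matrix$taxa]),
    total_cells = matrix$n_col, stringsAsFactors = FALSE
  )
  parts <- matrix$partitions
  if (nrow(parts) > 0L) {
    per_group <- vapply(seq_len(nrow(parts)), function(j) {
      sum(vapply(substr(matrix$rows, parts$start[j], parts$end[j]),
                 .count_occupied, integer(1L), unoccupied = unoccupied_chars))
    }, integer(1L))
    rows <- rbind(rows, data.frame(
      scope = "group", name = parts$group_id,
      occupied_cells = per_group,
      total_cells = (parts$end - parts$start + 1L) * length(matrix$taxa),
      stringsAsFactors = FALSE
    ))
  }
  rows <- rbind(data.frame(
    scope = "overall", name = "matrix",
    occupied_cells = sum(per_taxon),
    total_cells = length(matrix$taxa) * matrix$n_col,
    stringsAsFactors = FALSE
  ), rows)
  rows$occupancy <- ifelse(rows$total_cells > 0L,
                           rows$occupied_cells / rows$total_cells, NA_real_)
  rows
}

#' Delete taxa from a supermatrix
#'
#' Removes rows only; columns and partitions are left untouched (no column
#' re-trimming), matching how taxon-deletion experiments re-analyse an
#' otherwise identical matrix.
#'
#' @param matrix a \code{"supermatrix"}.
#' @param drop character vector of taxa to remove (must all be present).
#' @return the pruned \code{"supermatrix"}.
#' @export
delete_taxa_matrix <- function(matrix, drop) {
  stopifnot(inherits(matrix, "supermatrix"))
  unknown <- setdiff(drop, matrix$taxa)
  if (length(unknown) > 0L) {
    stop_validation("taxa not in matrix: ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(matrix$taxa, drop)
  if (length(keep) == 0L) stop_validation("cannot delete every taxon")
  matrix$taxa <- keep
  matrix$rows <- matrix$rows[keep]
  matrix
}

#' Drop taxa from every gene tree
#'
#' Gene-tree counterpart of the taxon-deletion experiments: the listed taxa
#' are removed from each tree (degree-2 nodes suppressed), and trees left
#' with fewer than \code{min_leaves} leaves are discarded with a message
#' reporting the count. Surviving trees' split sets equal the induced
#' restriction of the originals.
#'
#' @param genes gene trees (list, \code{multiPhylo} or gene_tree_set).
#' @param drop taxa to remove; taxa absent from a given tree are ignored.
#' @param min_leaves minimum surviving leaves to keep a tree; default 4.
#' @return a named list of pruned \code{"phylo"} objects.
#' @export
prune_gene_trees <- function(genes, drop, min_leaves = 4L) {
  trees <- as_tree_list(genes)
  nm <- names(trees)
  if (is.null(nm)) nm <- sprintf("gene%d", seq_along(trees))
  out <- list()
  discarded <- 0L
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    gone <- intersect(tr$tip.label, drop)
    survivors <- length(tr$tip.label) - length(gone)
    if (survivors < min_leaves) {
      discarded <- discarded + 1L
      next
    }
    if (length(gone) > 0L) tr <- ape::drop.tip(tr, gone)
    out[[nm[i]]] <- tr
  }
  if (discarded > 0L) {
    message(sprintf("prune_gene_trees: discarded %d tree(s) with < %d leaves",
                    discarded, min_leaves))
  }
  out
}
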