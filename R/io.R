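# File formats: orthogroup FASTA + score files, relaxed PHYLIP, partition
# files, TSV reports. All writers go through an atomic temp-file + rename.

.write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = ".tmp_", tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop_validation("could not write ", path)
  invisible(path)
}

#' Write a TSV table
#' @param x a data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  .write_atomic(path, function(p) {
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  })
}

#' Read a directory of orthogroup FASTA files (with optional score files)
#'
#' Each \code{<group_id>.fa[sta]} file holds one aligned amino-acid
#' orthogroup (sequence names = taxon labels); a sibling
#' \code{<group_id>.scores} file, when present, holds one numeric
#' alignment-confidence score per column, whitespace/newline separated.
#'
#' @param dir directory path.
#' @return named list of \code{"orthogroup"} objects, sorted by group id.
#' @export
read_orthogroups <- function(dir) {
  if (!dir.exists(dir)) stop_validation("orthogroup directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta|faa)$",
                           full.names = TRUE))
  if (length(files) == 0L) stop_validation("no FASTA files in ", dir)
  groups <- lapply(files, function(f) {
    id <- sub("\\.(fa|fasta|faa)$", "", basename(f))
    aa <- Biostrings::readAAStringSet(f)
    seqs <- stats::setNames(as.character(aa), names(aa))
    score_file <- file.path(dir, paste0(id, ".scores"))
    scores <- if (file.exists(score_file)) scan(score_file, quiet = TRUE)
    orthogroup(id, seqs, scores)
  })
  stats::setNames(groups, vapply(groups, `[[`, character(1L), "group_id"))
}

#' Write orthogroups as FASTA (+ score files) into a directory
#' @param groups list of \code{"orthogroup"} objects.
#' @param dir output directory (created if needed).
#' @export
write_orthogroups <- function(groups, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in groups) {
    aa <- Biostrings::AAStringSet(g$seqs)
    .write_atomic(file.path(dir, paste0(g$group_id, ".fa")), function(p) {
      Biostrings::writeXStringSet(aa, p)
    })
    if (!is.null(g$scores)) {
      .write_atomic(file.path(dir, paste0(g$group_id, ".scores")), function(p) {
        writeLines(format(g$scores, trim = TRUE), p)
      })
    }
  }
  invisible(dir)
}

#' Read a taxon-universe file (one label per line)
#' @param path file path.
#' @return character vector of taxon labels.
#' @export
read_taxa <- function(path) {
  if (!file.exists(path)) stop_validation("taxon file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  taxon_universe(lines[nzchar(lines)])
}

#' Write a supermatrix as relaxed PHYLIP
#'
#' Relaxed format: header \code{"<ntaxa> <ncols>"}, then one
#' \code{"<name>  <row>"} line per taxon (names of any length, no
#' truncation).
#'
#' @param matrix a \code{"supermatrix"}.
#' @param path output path.
#' @export
write_supermatrix_phylip <- function(matrix, path) {
  stopifnot(inherits(matrix, "supermatrix"))
  .write_atomic(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", length(matrix$taxa), matrix$n_col), con)
    writeLines(sprintf("%s  %s", matrix$taxa, matrix$rows[matrix$taxa]), con)
  })
}

#' Write a supermatrix as FASTA
#' @param matrix a \code{"supermatrix"}.
#' @param path output path.
#' @export
write_supermatrix_fasta <- function(matrix, path) {
  stopifnot(inherits(matrix, "supermatrix"))
  aa <- Biostrings::AAStringSet(matrix$rows[matrix$taxa])
  .write_atomic(path, function(p) Biostrings::writeXStringSet(aa, p))
}

#' Read a relaxed PHYLIP supermatrix
#'
#' Inverse of \code{\link{write_supermatrix_phylip}}; the partition map is
#' not stored in PHYLIP, so the result carries a single partition spanning
#' the whole matrix unless a partition file is supplied.
#'
#' @param path PHYLIP file.
#' @param partitions optional partition file as written by
#'   \code{\link{write_partitions}}.
#' @return a \code{"supermatrix"}.
#' @export
read_supermatrix_phylip <- function(path, partitions = NULL) {
  if (!file.exists(path)) stop_validation("matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  body <- lines[-1L][nzchar(trimws(lines[-1L]))]
  fields <- strsplit(trimws(body), "\\s+")
  taxa <- vapply(fields, `[[`, character(1L), 1L)
  rows <- stats::setNames(vapply(fields, `[[`, character(1L), 2L), taxa)
  if (length(taxa) != hdr[1L] || any(nchar(rows) != hdr[2L])) {
    stop_validation("PHYLIP header disagrees with body in ", path)
  }
  parts <- if (is.null(partitions)) {
    data.frame(group_id = "all", start = 1L, end = hdr[2L],
               stringsAsFactors = FALSE)
  } else {
    read_partitions(partitions)
  }
  structure(list(taxa = taxon_universe(taxa), n_col = hdr[2L], rows = rows,
                 partitions = parts, fill_char = "-"),
            class = "supermatrix")
}

#' Write a partition file (\code{"<group_id> = <start>-<end>"} per line)
#' @param matrix a \code{"supermatrix"}.
#' @param path output path.
#' @export
write_partitions <- function(matrix, path) {
  stopifnot(inherits(matrix, "supermatrix"))
  p <- matrix$partitions
  .write_atomic(path, function(f) {
    writeLines(sprintf("%s = %d-%d", p$group_id, p$start, p$end), f)
  })
}

#' Read a partition file
#' @param path partition file as written by \code{\link{write_partitions}}.
#' @return data.frame with columns \code{group_id}, \code{start}, \code{end}.
#' @export
read_partitions <- function(path) {
  if (!file.exists(path)) stop_validation("partition file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^(\\S+)\\s*=\\s*(\\d+)-(\\d+)$", lines))
  bad <- vapply(m, length, integer(1L)) != 4L
  if (any(bad)) stop_validation("malformed partition line: ", lines[bad][1L])
  data.frame(group_id = vapply(m, `[[`, character(1L), 2L),
             start = as.integer(vapply(m, `[[`, character(1L), 3L)),
             end = as.integer(vapply(m, `[[`, character(1L), 4L)),
             stringsAsFactors = FALSE)
}
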