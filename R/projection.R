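# Projection of intron sites into protein-alignment column coordinates.
#
# Columns and residue indices are 1-based (R convention).  The gap character
# is '-'; '.' is normalized to '-' on read.

#' Read or construct a protein multiple sequence alignment
#'
#' `read_msa` reads an aligned FASTA file; `as_msa` validates a named
#' character vector of aligned rows.  All rows must have equal length.
#'
#' @param path Path to an aligned FASTA file.
#' @param rows Named character vector of aligned sequences.
#' @return A named character vector of class `"intron_msa"` with attribute
#'   `n_columns`.
#' @export
read_msa <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  as_msa(stats::setNames(as.character(ss), names(ss)))
}

#' @rdname read_msa
#' @export
as_msa <- function(rows) {
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("alignment rows must have unique names")
  rows <- gsub(".", "-", rows, fixed = TRUE)
  w <- nchar(rows)
  if (length(unique(w)) != 1L)
    stop("alignment rows differ in length")
  structure(rows, n_columns = unname(w[1L]), class = "intron_msa")
}

#' @export
print.intron_msa <- function(x, ...) {
  cat(sprintf("protein alignment: %d sequence(s) x %d column(s)\n",
              length(x), attr(x, "n_columns")))
  invisible(x)
}

msa_row_chars <- function(msa, seq_id) {
  if (!seq_id %in% names(msa))
    stop(sprintf("sequence '%s' not in alignment", seq_id))
  strsplit(unname(msa[[seq_id]]), "", fixed = TRUE)[[1L]]
}

#' Alignment column of a residue
#'
#' Returns the column holding the `residue_index`-th non-gap character of a
#' row (both 1-based).
#'
#' @param msa An alignment from [read_msa()] or [as_msa()].
#' @param seq_id Row name.
#' @param residue_index 1-based ungapped residue index (vectorized).
#' @return Integer column index (1-based).
#' @examples
#' m <- as_msa(c(a = "M-KT"))
#' column_of_residue(m, "a", 2)  # column 3
#' @export
column_of_residue <- function(msa, seq_id, residue_index) {
  ch <- msa_row_chars(msa, seq_id)
  nong <- which(ch != "-")
  residue_index <- as.integer(residue_index)
  if (any(residue_index < 1L) || any(residue_index > length(nong)))
    stop(sprintf("residue index out of range for sequence '%s' (%d residues)",
                 seq_id, length(nong)))
  nong[residue_index]
}

#' Project intron sites onto alignment columns
#'
#' Each intron site is mapped to the alignment column of its anchor residue
#' (anchor codon + 1 in 1-based residue numbering); the phase is carried
#' through unchanged.  An intron whose anchor codon falls at or beyond the
#' encoded protein length (i.e. within or after the stop codon) is a
#' projection error.
#'
#' @param msa An alignment whose row names include every `gene_id` in
#'   `sites`.
#' @param sites Data frame of intron sites from [derive_intron_sites()]
#'   (possibly row-bound across genes).
#' @param info Optional data frame with columns `gene_id`, `taxon`,
#'   `family` used to label projections; defaults to `taxon = gene_id` and
#'   `family = NA`.
#' @return Data frame of projected introns: `gene_id`, `ordinal`, `column`,
#'   `phase`, `taxon`, `family`.
#' @export
project_introns <- function(msa, sites, info = NULL) {
  stopifnot(inherits(msa, "intron_msa"))
  if (nrow(sites) == 0L)
    return(data.frame(gene_id = character(), ordinal = integer(),
                      column = integer(), phase = integer(),
                      taxon = character(), family = character()))
  taxon <- stats::setNames(sites$gene_id, sites$gene_id)
  family <- stats::setNames(rep(NA_character_, nrow(sites)), sites$gene_id)
  if (!is.null(info)) {
    taxon[info$gene_id] <- info$taxon
    if (!is.null(info$family)) family[info$gene_id] <- info$family
  }
  cols <- integer(nrow(sites))
  for (gid in unique(sites$gene_id)) {
    idx <- which(sites$gene_id == gid)
    plen <- length(which(msa_row_chars(msa, gid) != "-"))
    anchors <- sites$anchor_codon[idx]
    if (any(anchors >= plen))
      stop(sprintf("gene '%s': intron anchor codon beyond protein length %d",
                   gid, plen))
    cols[idx] <- column_of_residue(msa, gid, anchors + 1L)
  }
  data.frame(gene_id = sites$gene_id, ordinal = sites$ordinal,
             column = cols, phase = sites$phase,
             taxon = unname(taxon[sites$gene_id]),
             family = unname(family[sites$gene_id]),
             stringsAsFactors = FALSE)
}

#' Nucleotide position of a projected intron on a reference gene
#'
#' Expresses an intron position in coding nucleotides of one declared
#' reference sequence: `3 * r + phase`, where `r` is the number of non-gap
#' reference residues in columns strictly before the projection's column.
#' The measure is deterministic even when the column is a gap in the
#' reference (the position collapses to the count of preceding residues).
#'
#' @param msa Alignment.
#' @param ref_id Reference row name.
#' @param column 1-based alignment column (vectorized).
#' @param phase Intron phase, 0..2 (vectorized).
#' @return Integer nucleotide coordinate(s) on the reference coding axis.
#' @export
ref_nt_position <- function(msa, ref_id, column, phase) {
  ch <- msa_row_chars(msa, ref_id)
  nong <- cumsum(ch != "-")
  column <- as.integer(column)
  if (any(column < 1L) || any(column > length(ch)))
    stop("column out of range")
  r <- ifelse(column == 1L, 0L, nong[column - 1L])
  as.integer(3L * r + as.integer(phase))
}

#' Nucleotide offset between two projected introns
#'
#' Absolute difference of [ref_nt_position()] for two projections on the
#' same reference.  `a` and `b` are one-row data frames or lists with
#' `column` and `phase` elements.
#'
#' @inheritParams ref_nt_position
#' @param a,b Projections (one-row data frames or lists with `column`,
#'   `phase`).
#' @return Non-negative integer offset in nucleotides.
#' @export
offset_between <- function(msa, ref_id, a, b) {
  abs(ref_nt_position(msa, ref_id, a$column, a$phase) -
      ref_nt_position(msa, ref_id, b$column, b$phase))
}

#' Write a projection report
#'
#' @param projections Data frame from [project_introns()].
#' @param path Output TSV path.
#' @export
write_projection_tsv <- function(projections, path) {
  utils::write.table(projections, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
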