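# Gene structures: ordered coding-exon spans, intron positions and phases.
#
# All coordinates are 0-based half-open internally; GFF3's 1-based inclusive
# convention is converted at the boundary.  The CDS is taken to include the
# stop codon, so the encoded protein length is CDS/3 - 1.

#' Construct a gene structure
#'
#' A gene structure is the ordered list of coding-exon spans of one gene in
#' one species, in transcript 5'->3' order.  It is the raw material from
#' which intron positions and phases are derived.
#'
#' @param gene_id Gene or transcript identifier.
#' @param exons Two-column matrix or data frame of exon spans
#'   (`start`, `end`), 0-based half-open, in transcript orientation.  For a
#'   minus-strand gene in genomic coordinates this means descending genomic
#'   position.
#' @param species,family Optional species and gene-family labels
#'   (e.g. `"slc26a1"`).
#' @param strand `"+"` or `"-"`.
#' @param contig_id Optional contig/chromosome identifier for
#'   genome-coordinate structures.
#' @return An object of class `"gene_structure"`.
#' @examples
#' g <- gene_structure("geneX", cbind(c(0, 800), c(300, 1202)))
#' cds_length(g)  # 702
#' @export
gene_structure <- function(gene_id, exons, species = NA_character_,
                           family = NA_character_, strand = "+",
                           contig_id = NA_character_) {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L)
    stop("exons must have two columns (start, end)")
  storage.mode(exons) <- "double"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1L)
    stop(sprintf("gene '%s': at least one exon required", gene_id))
  if (any(exons[, "start"] >= exons[, "end"]))
    stop(sprintf("gene '%s': exon with start >= end", gene_id))
  if (!strand %in% c("+", "-"))
    stop(sprintf("gene '%s': unknown strand '%s'", gene_id, strand))
  ## overlap check in genomic order
  o <- order(exons[, "start"])
  so <- exons[o, , drop = FALSE]
  if (nrow(so) > 1L && any(so[-nrow(so), "end"] > so[-1L, "start"]))
    stop(sprintf("gene '%s': overlapping exons", gene_id))
  len <- sum(exons[, "end"] - exons[, "start"])
  if (len < 3 || len %% 3 != 0)
    stop(sprintf("gene '%s': CDS length %d not a positive multiple of 3",
                 gene_id, as.integer(len)))
  ## transcript orientation: ascending for +, descending for -
  st <- exons[, "start"]
  if (strand == "+" && is.unsorted(st, strictly = TRUE))
    stop(sprintf("gene '%s': plus-strand exons not in ascending order", gene_id))
  if (strand == "-" && is.unsorted(rev(st), strictly = TRUE))
    stop(sprintf("gene '%s': minus-strand exons not in descending genomic order",
                 gene_id))
  structure(list(gene_id = as.character(gene_id),
                 species = as.character(species),
                 family = as.character(family),
                 strand = strand,
                 contig_id = as.character(contig_id),
                 exons = exons),
            class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  cat(sprintf("gene structure '%s' (%s%s): %d exon(s), CDS %d nt\n",
              x$gene_id,
              if (is.na(x$family)) "" else paste0(x$family, ", "),
              x$strand, nrow(x$exons), cds_length(x)))
  invisible(x)
}

#' Total coding length of a gene structure
#'
#' @param g A [gene_structure()].
#' @return Integer CDS length in nucleotides (stop codon included).
#' @export
cds_length <- function(g) {
  as.integer(sum(g$exons[, "end"] - g$exons[, "start"]))
}

#' Read gene structures from a file
#'
#' Reads coding-exon structures either from a tab-separated exon table or
#' from GFF3 CDS features.  The exon table dialect has a header row and the
#' columns `gene_id`, `species`, `family`, `strand`, `contig_id`,
#' `exon_index`, `start`, `end`, with 0-based half-open coordinates in
#' transcript order.  GFF3 CDS features are grouped by their `Parent` (or,
#' failing that, `ID`) attribute; 1-based inclusive coordinates are converted
#' and minus-strand features are re-ordered into transcript orientation.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"gff3"`.
#' @param species,family Optional labels applied to GFF3 records (the format
#'   carries neither).
#' @return A list of [gene_structure()] objects, named by gene id.
#' @export
read_gene_structures <- function(path, format = c("tsv", "gff3"),
                                 species = NA_character_,
                                 family = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "tsv") read_structures_tsv(path) else
    read_structures_gff3(path, species = species, family = family)
}

read_structures_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "species", "family", "strand", "contig_id",
            "exon_index", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("exon table '%s' missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  out <- lapply(split(tab, tab$gene_id), function(d) {
    d <- d[order(d$exon_index), , drop = FALSE]
    gene_structure(d$gene_id[1L], cbind(d$start, d$end),
                   species = d$species[1L], family = d$family[1L],
                   strand = d$strand[1L], contig_id = d$contig_id[1L])
  })
  out[unique(tab$gene_id)]
}

read_structures_gff3 <- function(path, species = NA_character_,
                                 family = NA_character_) {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(gr) == 0L) stop(sprintf("no CDS features in '%s'", path))
  parent <- if (!is.null(gr$Parent)) {
    vapply(as.list(gr$Parent), function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, "")
  } else rep(NA_character_, length(gr))
  ids <- ifelse(is.na(parent) | parent == "",
                if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
                parent)
  if (anyNA(ids)) stop(sprintf("CDS feature without Parent/ID in '%s'", path))
  out <- lapply(split(seq_along(gr), ids), function(i) {
    sub <- gr[i]
    strand <- unique(as.character(BiocGenerics::strand(sub)))
    if (length(strand) != 1L || !strand %in% c("+", "-"))
      stop(sprintf("gene '%s': unknown or mixed strand", ids[i[1L]]))
    start0 <- BiocGenerics::start(sub) - 1L   # GFF3 1-based inclusive -> 0-based half-open
    end0 <- BiocGenerics::end(sub)
    o <- order(start0)
    if (strand == "-") o <- rev(o)
    gene_structure(ids[i[1L]], cbind(start0[o], end0[o]),
                   species = species, family = family, strand = strand,
                   contig_id = as.character(GenomicRanges::seqnames(sub))[1L])
  })
  out[unique(ids)]
}

#' Intron phase of a coding-nucleotide offset
#'
#' An intron inserted after `p` coding nucleotides has phase `p mod 3`:
#' phase 0 introns lie between codons, phase 1 after the first base of a
#' codon, phase 2 after the second.
#'
#' @param p Positive integer offset(s): the number of coding nucleotides
#'   strictly 5' of the intron.
#' @return Integer vector of phases in `{0, 1, 2}`.
#' @examples
#' classify_phase(c(3, 4, 1000))  # 0 1 1
#' @export
classify_phase <- function(p) {
  p <- as.integer(p)
  if (any(is.na(p)) || any(p < 1L))
    stop("invalid intron position: p must be >= 1")
  p %% 3L
}

#' Derive intron sites from a gene structure
#'
#' The k-th intron of a gene lies after the cumulative coding length of
#' exons 1..k.  Each site records that offset `p`, its phase `p mod 3`, and
#' its anchor codon `floor(p / 3)` (0-based; for phase-0 introns this is the
#' codon immediately following the intron).
#'
#' @param g A [gene_structure()].
#' @return A data frame with one row per intron (`gene_id`, `ordinal`,
#'   `cds_offset`, `phase`, `anchor_codon`); zero rows for a single-exon CDS.
#' @examples
#' g <- gene_structure("g", cbind(c(0, 300), c(300, 702)))
#' derive_intron_sites(g)  # p = 300, phase 0, anchor codon 100
#' @export
derive_intron_sites <- function(g) {
  stopifnot(inherits(g, "gene_structure"))
  widths <- g$exons[, "end"] - g$exons[, "start"]
  n <- length(widths)
  if (n == 1L)
    return(data.frame(gene_id = character(), ordinal = integer(),
                      cds_offset = integer(), phase = integer(),
                      anchor_codon = integer()))
  p <- as.integer(cumsum(widths)[-n])
  data.frame(gene_id = g$gene_id,
             ordinal = seq_len(n - 1L),
             cds_offset = p,
             phase = classify_phase(p),
             anchor_codon = p %/% 3L,
             stringsAsFactors = FALSE)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Check splice-site dinucleotides against the gt-ag rule
#'
#' Canonical spliceosomal introns begin with `gt` and end with `ag`.  Given a
#' genome-coordinate structure and its contig sequence, this extracts every
#' intron and checks its first and last two nucleotides, case-insensitively
#' and strand-aware (minus-strand introns are checked on the reverse
#' complement).
#'
#' @param g A [gene_structure()] with genomic coordinates.
#' @param contig Nucleotide sequence of the contig as a single string (or
#'   anything coercible by `as.character`).
#' @return Data frame with one row per intron: `ordinal`, genomic `start`
#'   and `end` (0-based half-open), `starts_gt`, `ends_ag`, `too_short`.
#' @export
validate_splice_sites <- function(g, contig) {
  stopifnot(inherits(g, "gene_structure"))
  contig <- as.character(contig)
  ex <- g$exons
  n <- nrow(ex)
  if (n == 1L)
    return(data.frame(ordinal = integer(), start = integer(), end = integer(),
                      starts_gt = logical(), ends_ag = logical(),
                      too_short = logical()))
  out <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    if (g$strand == "+") {
      s <- ex[k, "end"]; e <- ex[k + 1L, "start"]
    } else {
      s <- ex[k + 1L, "end"]; e <- ex[k, "start"]
    }
    if (e < s || e > nchar(contig))
      stop(sprintf("gene '%s': intron %d outside contig", g$gene_id, k))
    too_short <- (e - s) < 4
    if (too_short) {
      out[[k]] <- data.frame(ordinal = k, start = s, end = e,
                             starts_gt = FALSE, ends_ag = FALSE,
                             too_short = TRUE)
      next
    }
    iseq <- substr(contig, s + 1L, e)           # 0-based half-open -> R substr
    if (g$strand == "-") iseq <- reverse_complement(iseq)
    iseq <- tolower(iseq)
    out[[k]] <- data.frame(
      ordinal = k, start = s, end = e,
      starts_gt = substr(iseq, 1L, 2L) == "gt",
      ends_ag = substr(iseq, nchar(iseq) - 1L, nchar(iseq)) == "ag",
      too_short = FALSE)
  }
  do.call(rbind, out)
}
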