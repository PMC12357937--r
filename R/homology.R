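# Intron-position homology: exact (column, phase) clustering, near-miss
# reporting, cross-family convergence, and the presence/absence matrix.
#
# Homology requires exact column-and-phase identity.  Nearby positions
# (e.g. 7 or 23 nt apart) remain distinct characters and are only *reported*
# as near matches; clusters are never merged.

#' Cluster projected introns into homologous position characters
#'
#' Partitions projections by exact `(column, phase)` identity.  Character
#' ids are deterministic, ordered by column then phase.
#'
#' @param projections Data frame from [project_introns()].
#' @return An object of class `"position_clusters"`: a list with
#'   `$clusters` (data frame `character_id`, `column`, `phase`,
#'   `n_members`) and `$members` (the input projections plus a
#'   `character_id` column).
#' @export
cluster_introns <- function(projections) {
  if (nrow(projections) == 0L) {
    clusters <- data.frame(character_id = character(), column = integer(),
                           phase = integer(), n_members = integer())
    members <- cbind(projections, character_id = character(0))
    return(structure(list(clusters = clusters, members = members),
                     class = "position_clusters"))
  }
  key <- paste(projections$column, projections$phase, sep = "/")
  uk <- unique(key[order(projections$column, projections$phase)])
  id <- stats::setNames(sprintf("pos%04d_p%d",
                                as.integer(sub("/.*", "", uk)),
                                as.integer(sub(".*/", "", uk))), uk)
  members <- projections
  members$character_id <- unname(id[key])
  clusters <- data.frame(
    character_id = unname(id),
    column = as.integer(sub("/.*", "", uk)),
    phase = as.integer(sub(".*/", "", uk)),
    n_members = as.integer(table(members$character_id)[id]),
    stringsAsFactors = FALSE)
  structure(list(clusters = clusters, members = members),
            class = "position_clusters")
}

#' @export
print.position_clusters <- function(x, ...) {
  cat(sprintf("%d intron position character(s) from %d projection(s)\n",
              nrow(x$clusters), nrow(x$members)))
  invisible(x)
}

cluster_nt_positions <- function(clusters, msa = NULL, ref_id = NULL) {
  cl <- clusters$clusters
  if (is.null(msa) || is.null(ref_id)) {
    ## schematic gapless axis: column c holds reference residue c
    3L * (cl$column - 1L) + cl$phase
  } else {
    ref_nt_position(msa, ref_id, cl$column, cl$phase)
  }
}

#' Report near-miss pairs of intron position characters
#'
#' All unordered pairs of distinct characters whose positions, measured in
#' coding nucleotides of a reference sequence, differ by at most
#' `max_offset_nt` (and more than 0).  Clusters are never merged: a near
#' match is a report, not a homology statement.
#'
#' @param clusters A [cluster_introns()] result.
#' @param max_offset_nt Reporting ceiling in nucleotides (default 30, which
#'   covers the 7 and 23 bp near-insertions seen in slc26 genes with
#'   margin).
#' @param msa,ref_id Optional alignment and reference row used to measure
#'   offsets on a real coding axis; when omitted, offsets are measured on a
#'   gapless schematic axis (`3 * (column - 1) + phase`).
#' @return Data frame `cluster_a`, `cluster_b`, `offset_nt`,
#'   `reference_id`, sorted by offset.
#' @export
near_matches <- function(clusters, max_offset_nt = 30, msa = NULL,
                         ref_id = NULL) {
  stopifnot(inherits(clusters, "position_clusters"))
  cl <- clusters$clusters
  empty <- data.frame(cluster_a = character(), cluster_b = character(),
                      offset_nt = integer(), reference_id = character())
  if (nrow(cl) < 2L) return(empty)
  pos <- cluster_nt_positions(clusters, msa, ref_id)
  pairs <- utils::combn(nrow(cl), 2L)
  off <- abs(pos[pairs[1L, ]] - pos[pairs[2L, ]])
  keep <- off > 0 & off <= max_offset_nt
  if (!any(keep)) return(empty)
  out <- data.frame(cluster_a = cl$character_id[pairs[1L, keep]],
                    cluster_b = cl$character_id[pairs[2L, keep]],
                    offset_nt = as.integer(off[keep]),
                    reference_id = if (is.null(ref_id)) NA_character_ else ref_id,
                    stringsAsFactors = FALSE)
  out[order(out$offset_nt, out$cluster_a), , drop = FALSE]
}

#' Detect convergent intron insertion between gene families
#'
#' Clusters projections within each family separately, then reports
#' cross-family character pairs at identical positions (offset 0, flag
#' `"identical"`) or within `max_offset_nt` (flag `"near"`).  Identical or
#' near positions in *different* families are the signature of convergent
#' intron gain.
#'
#' @param projections Data frame from [project_introns()] with a non-NA
#'   `family` column, all on one joint alignment.
#' @inheritParams near_matches
#' @return Data frame `family_a`, `family_b`, `character_a`, `character_b`,
#'   `column_a`, `column_b`, `offset_nt`, `flag`; empty when fewer than two
#'   families are present.
#' @export
detect_convergence <- function(projections, max_offset_nt = 30, msa = NULL,
                               ref_id = NULL) {
  empty <- data.frame(family_a = character(), family_b = character(),
                      character_a = character(), character_b = character(),
                      column_a = integer(), column_b = integer(),
                      offset_nt = integer(), flag = character())
  fams <- unique(projections$family)
  fams <- fams[!is.na(fams)]
  if (length(fams) < 2L) return(empty)
  percl <- lapply(fams, function(f)
    cluster_introns(projections[projections$family == f, , drop = FALSE]))
  names(percl) <- fams
  rows <- list()
  for (i in seq_len(length(fams) - 1L)) for (j in seq(i + 1L, length(fams))) {
    a <- percl[[i]]$clusters; b <- percl[[j]]$clusters
    pa <- cluster_nt_positions(percl[[i]], msa, ref_id)
    pb <- cluster_nt_positions(percl[[j]], msa, ref_id)
    for (x in seq_len(nrow(a))) for (y in seq_len(nrow(b))) {
      off <- abs(pa[x] - pb[y])
      if (off > max_offset_nt) next
      rows[[length(rows) + 1L]] <- data.frame(
        family_a = fams[i], family_b = fams[j],
        character_a = a$character_id[x], character_b = b$character_id[y],
        column_a = a$column[x], column_b = b$column[y],
        offset_nt = as.integer(off),
        flag = if (off == 0) "identical" else "near",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$offset_nt, out$character_a), , drop = FALSE]
}

#' Build the taxa-by-characters presence/absence matrix
#'
#' Cell `(t, c)` is 1 iff taxon `t` possesses a member of character `c`.
#' Taxa that contributed a gene but possess no introns appear as all-zero
#' rows.  A taxon contributing two distinct genes of the same family is
#' rejected: the matrix is defined for one gene per taxon per family, and
#' the caller must deduplicate paralogs first.
#'
#' @param clusters A [cluster_introns()] result.
#' @param taxon_of_gene Optional named character vector mapping gene ids to
#'   taxa; defaults to the `taxon` column carried by the projections.  Taxa
#'   present in the mapping but possessing no introns still get (all-zero)
#'   rows.
#' @return Binary integer matrix, rows = taxa, columns = character ids.
#' @export
build_presence_matrix <- function(clusters, taxon_of_gene = NULL) {
  stopifnot(inherits(clusters, "position_clusters"))
  mem <- clusters$members
  if (is.null(taxon_of_gene)) {
    taxon_of_gene <- stats::setNames(mem$taxon, mem$gene_id)
    taxon_of_gene <- taxon_of_gene[!duplicated(names(taxon_of_gene))]
  }
  if (nrow(mem) && any(!mem$gene_id %in% names(taxon_of_gene)))
    stop(sprintf("no taxon mapping for gene(s): %s",
                 paste(unique(mem$gene_id[!mem$gene_id %in%
                                          names(taxon_of_gene)]),
                       collapse = ", ")))
  ## one gene per taxon per family
  if (nrow(mem)) {
    gf <- unique(mem[, c("gene_id", "family")])
    gf$taxon <- unname(taxon_of_gene[gf$gene_id])
    dup <- duplicated(gf[, c("taxon", "family")]) |
      duplicated(gf[, c("taxon", "family")], fromLast = TRUE)
    if (any(dup))
      stop(sprintf(paste("taxon with multiple genes in one family: %s;",
                         "deduplicate paralogs before building the matrix"),
                   paste(unique(gf$taxon[dup]), collapse = ", ")))
  }
  taxa <- unique(unname(taxon_of_gene))
  chars <- clusters$clusters$character_id
  m <- matrix(0L, nrow = length(taxa), ncol = length(chars),
              dimnames = list(taxa, chars))
  if (nrow(mem)) {
    tx <- unname(taxon_of_gene[mem$gene_id])
    m[cbind(match(tx, taxa), match(mem$character_id, chars))] <- 1L
  }
  m
}

#' Read and write presence/absence matrices
#'
#' The TSV layout has taxa as rows (first column `taxon`) and character ids
#' as the remaining column names.  The phylip-like relaxed layout has a
#' `"<ntaxa> <ncharacters>"` header line followed by `name<space>binarystring`
#' rows, for interop with parsimony programs.
#'
#' @param m Binary matrix (taxa x characters).
#' @param path File path.
#' @param format `"tsv"` or `"phylip"`.
#' @return `read_presence_matrix` returns the binary integer matrix.
#' @export
write_presence_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- data.frame(taxon = rownames(m), m, check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c(sprintf("%d %d", nrow(m), ncol(m)),
               sprintf("%s %s", rownames(m),
                       apply(m, 1L, paste, collapse = "")))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d[[1L]]
  if (length(m) && !all(m %in% c(0L, 1L)))
    stop(sprintf("matrix '%s' has non-binary cells", path))
  m
}
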