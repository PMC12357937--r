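# Exon-intron diagram rendering: one row per gene, numbered exon boxes
# separated by thin intron bars, written as standalone SVG (text-only, no
# raster dependencies).

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render gene structures as an SVG diagram
#'
#' Draws one row per gene: coding exons as filled numbered boxes and
#' introns as white vertical bars between them, with exon widths scaled to
#' coding length.  When a tree is supplied, rows follow its tip order.
#'
#' @param structures List of [gene_structure()] objects.
#' @param file Optional output path; when `NULL` the SVG text is returned.
#' @param tree Optional tree accepted by [read_species_tree()] whose tip
#'   labels (matched against gene ids, then species) order the rows.
#' @param width Drawing width in pixels.
#' @return The SVG document as a character scalar (invisibly when written
#'   to `file`).
#' @export
render_structures <- function(structures, file = NULL, tree = NULL,
                              width = 800) {
  if (!length(structures)) stop("need at least one structure")
  if (inherits(structures, "gene_structure")) structures <- list(structures)
  if (!is.null(tree)) {
    tr <- read_species_tree(tree)
    ids <- vapply(structures, function(g) g$gene_id, "")
    sp <- vapply(structures, function(g) g$species, "")
    o <- match(tr$tip.label, ids)
    if (all(is.na(o))) o <- match(tr$tip.label, sp)
    o <- o[!is.na(o)]
    if (length(o) == length(structures)) structures <- structures[o]
  }
  row_h <- 34; box_h <- 16; label_w <- 170; bar_w <- 3
  n <- length(structures)
  max_cds <- max(vapply(structures, cds_length, 0L))
  scale <- (width - label_w - 20) / max_cds
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%d" height="%d">'),
                   width, n * row_h + 10),
           '<style>text{font-family:sans-serif;font-size:11px}</style>')
  for (i in seq_len(n)) {
    g <- structures[[i]]
    y <- (i - 1) * row_h + 8
    lab <- if (!is.na(g$species) && nzchar(g$species) &&
               g$species != g$gene_id)
      paste0(g$gene_id, " (", g$species, ")") else g$gene_id
    out <- c(out, sprintf('<text x="4" y="%d">%s</text>',
                          y + box_h - 3, svg_escape(lab)))
    widths <- g$exons[, "end"] - g$exons[, "start"]
    x <- label_w
    for (k in seq_along(widths)) {
      w <- max(widths[k] * scale, 6)
      out <- c(out,
               sprintf(paste0('<rect x="%.1f" y="%d" width="%.1f" ',
                              'height="%d" fill="#4477aa" stroke="black"/>'),
                       x, y, w, box_h),
               sprintf(paste0('<text x="%.1f" y="%d" fill="white" ',
                              'text-anchor="middle">%d</text>'),
                       x + w / 2, y + box_h - 4, k))
      x <- x + w
      if (k < length(widths)) {   # intron bar
        out <- c(out,
                 sprintf(paste0('<rect x="%.1f" y="%d" width="%d" ',
                                'height="%d" fill="white" stroke="black"/>'),
                         x, y, bar_w, box_h))
        x <- x + bar_w
      }
    }
  }
  out <- c(out, "</svg>")
  doc <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}
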