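# Synthetic data with planted truth: coding genes evolving on a rooted tree
# with Dollo-style intron gain/loss (single origin per position, optional
# losses), point substitutions and optional codon-aligned indels on the
# encoded protein, and transposon-style introns carrying a target-site
# duplication, terminal inverted repeats and a central tandem array.
#
# The generator is first-class, tested code: every planted event is logged
# so the whole pipeline (structure parsing -> projection -> clustering ->
# Dollo reconstruction) can be validated against exact truth.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y")
DNA_ALPHABET <- c("a", "c", "g", "t")

## one deterministic codon per amino acid (alphabetically first), stop = taa
codon_for_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  tab <- vapply(AA_ALPHABET, function(a) sort(names(gc)[gc == a])[1L], "")
  tolower(tab)
})

random_dna <- function(n) paste(sample(DNA_ALPHABET, n, replace = TRUE),
                                collapse = "")

#' Configuration for the gene-evolution simulator
#'
#' Rates are events per unit branch length (per site for substitutions and
#' indels).  Defaults describe a gene the size of an slc26 anion transporter
#' (~700 codons) evolving with rare intron turnover — gains rarer than one
#' per branch and losses rarer still — matching the regime in which intron
#' presence/absence characters are informative.
#'
#' @param tree Newick string/path or `phylo`: the species tree to simulate
#'   along (branch lengths default to 1 when absent).
#' @param root_codons CDS length of the root gene in codons, stop codon
#'   included (minimum 50).
#' @param root_introns Data frame `codon` (1-based anchor residue index),
#'   `phase` of introns already present at the root; default one ancient
#'   phase-0 intron at the middle codon.
#' @param gain_rate,loss_rate Intron gains/losses per unit branch length.
#' @param subst_rate Amino-acid substitutions per site per unit branch
#'   length.
#' @param indels Enable codon-aligned insertions/deletions.
#' @param indel_rate Indel events per site per unit branch length (split
#'   evenly between insertion and deletion).
#' @param minus_strand_prob Probability that a leaf gene is written on the
#'   minus strand of its contig.
#' @param intron_length_range Genomic intron lengths drawn uniformly from
#'   this range (nt).
#' @param family Family label stamped on the simulated genes.
#' @param seed Integer seed; all randomness in [simulate_genes()] flows
#'   from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(tree, root_codons = 700, root_introns = NULL,
                       gain_rate = 0.5, loss_rate = 0.1, subst_rate = 0.05,
                       indels = FALSE, indel_rate = 0.005,
                       minus_strand_prob = 0.5,
                       intron_length_range = c(60, 150),
                       family = "simgene", seed = 1) {
  if (root_codons < 50) stop("root CDS must be at least 50 codons")
  if (any(c(gain_rate, loss_rate, subst_rate, indel_rate) < 0))
    stop("rates must be non-negative")
  plen <- root_codons - 1L
  if (is.null(root_introns))
    root_introns <- data.frame(codon = as.integer(round(plen / 2)), phase = 0L)
  if (nrow(root_introns) &&
      (any(root_introns$codon < 1L) || any(root_introns$codon > plen) ||
       any(root_introns$codon == 1L & root_introns$phase == 0L)))
    stop("root introns must lie strictly inside the CDS")
  structure(list(tree = tree, root_codons = as.integer(root_codons),
                 root_introns = root_introns, gain_rate = gain_rate,
                 loss_rate = loss_rate, subst_rate = subst_rate,
                 indels = indels, indel_rate = indel_rate,
                 minus_strand_prob = minus_strand_prob,
                 intron_length_range = as.integer(intron_length_range),
                 family = family, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate coding genes with planted intron gain and loss
#'
#' Evolves a root gene down the tree.  On each branch, amino-acid sites
#' substitute independently, optional codon-aligned indels rearrange the
#' true alignment, intron gains arrive as a Poisson process at uniformly
#' drawn (codon, phase) positions never reused anywhere on the tree (so
#' single origin holds by construction), and losses remove currently
#' present introns.  Leaf genes are written onto synthetic contigs with
#' gt..ag introns so the full structure-parsing path can run on the output.
#'
#' @param config A [sim_config()].
#' @return A list of class `"intron_sim"`: `tree` (labelled species tree),
#'   `structures` (list of [gene_structure()], one per leaf, genomic
#'   coordinates), `contigs`, `cds`, `proteins` (named character vectors),
#'   `alignment` (the true protein alignment as an `intron_msa`), and
#'   `truth` (`characters`: planted characters with true alignment
#'   `column` and `phase`; `gains`/`losses`: per-branch event log keyed by
#'   child node label; `seed`).
#' @export
simulate_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tr <- read_species_tree(config$tree)
  ntip <- ape::Ntip(tr)
  bl <- tr$edge.length
  if (is.null(bl)) bl <- rep(1, nrow(tr$edge))
  plen <- config$root_codons - 1L

  ## mutable simulation state
  registry <- seq_len(plen)                 # global column order of site ids
  next_id <- plen + 1L
  used_keys <- character(0)                 # "site/phase" ever used by a gain
  gains <- list(); losses <- list()
  gain_n <- 0L

  root_state <- list(
    sites = seq_len(plen),
    residues = sample(AA_ALPHABET, plen, replace = TRUE),
    introns = data.frame(character = sprintf("anc%02d",
                                             seq_len(nrow(config$root_introns))),
                         site = as.integer(config$root_introns$codon),
                         phase = as.integer(config$root_introns$phase),
                         stringsAsFactors = FALSE))
  used_keys <- paste(root_state$introns$site, root_state$introns$phase,
                     sep = "/")
  root_chars <- root_state$introns

  states <- vector("list", ntip + tr$Nnode)
  root_node <- ntip + 1L
  states[[root_node]] <- root_state
  edges <- ape::reorder.phylo(tr, "cladewise")$edge  # parent before child
  edge_len <- if (is.null(tr$edge.length)) rep(1, nrow(edges)) else {
    key <- paste(edges[, 1L], edges[, 2L])
    tr$edge.length[match(key, paste(tr$edge[, 1L], tr$edge[, 2L]))]
  }

  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]; child <- edges[e, 2L]; b <- edge_len[e]
    st <- states[[parent]]
    child_label <- node_label(tr, child)

    ## substitutions
    p <- length(st$sites)
    hit <- which(stats::runif(p) < config$subst_rate * b)
    for (i in hit)
      st$residues[i] <- sample(setdiff(AA_ALPHABET, st$residues[i]), 1L)

    ## codon-aligned indels
    if (config$indels && config$indel_rate > 0) {
      n_ind <- stats::rpois(1L, config$indel_rate * b * length(st$sites))
      for (dummy in seq_len(n_ind)) {
        if (stats::runif(1L) < 0.5) {         # insertion after position j
          j <- sample(0:length(st$sites), 1L)
          id <- next_id; next_id <- next_id + 1L
          at <- if (j == 0L) 0L else match(st$sites[j], registry)
          registry <- append(registry, id, after = at)
          st$sites <- append(st$sites, id, after = j)
          st$residues <- append(st$residues, sample(AA_ALPHABET, 1L),
                                after = j)
        } else {                              # deletion, sparing intron anchors
          del_ok <- setdiff(seq_along(st$sites),
                            match(st$introns$site, st$sites))
          del_ok <- del_ok[del_ok > 1L]       # keep first codon
          if (!length(del_ok)) next
          j <- if (length(del_ok) == 1L) del_ok else sample(del_ok, 1L)
          st$sites <- st$sites[-j]
          st$residues <- st$residues[-j]
        }
      }
    }

    ## intron gains: Poisson, distinct (site, phase) tree-wide
    n_gain <- stats::rpois(1L, config$gain_rate * b)
    for (dummy in seq_len(n_gain)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        idx <- sample(length(st$sites), 1L)
        ph <- sample(0:2, 1L)
        if (idx == 1L && ph == 0L) next       # p = 0 is not an intron
        key <- paste(st$sites[idx], ph, sep = "/")
        if (key %in% used_keys) next
        ok <- TRUE; break
      }
      if (!ok)
        stop("position collision exhaustion: CDS too short for requested gains")
      used_keys <- c(used_keys, key)
      gain_n <- gain_n + 1L
      ch <- sprintf("g%03d", gain_n)
      st$introns <- rbind(st$introns,
                          data.frame(character = ch, site = st$sites[idx],
                                     phase = ph, stringsAsFactors = FALSE))
      gains[[length(gains) + 1L]] <-
        data.frame(character = ch, child = child_label,
                   site = st$sites[idx], phase = ph, stringsAsFactors = FALSE)
    }

    ## intron losses
    n_loss <- min(stats::rpois(1L, config$loss_rate * b), nrow(st$introns))
    if (n_loss > 0L) {
      drop <- sample(nrow(st$introns), n_loss)
      losses[[length(losses) + 1L]] <-
        data.frame(character = st$introns$character[drop],
                   child = child_label, stringsAsFactors = FALSE)
      st$introns <- st$introns[-drop, , drop = FALSE]
    }

    states[[child]] <- st
  }

  ## assemble leaf outputs
  leaves <- tr$tip.label
  structures <- vector("list", ntip); names(structures) <- leaves
  contigs <- cds <- proteins <- character(ntip)
  names(contigs) <- names(cds) <- names(proteins) <- leaves
  aln_rows <- character(ntip); names(aln_rows) <- leaves
  for (t in seq_len(ntip)) {
    st <- states[[t]]
    leaf <- leaves[t]
    proteins[leaf] <- paste(st$residues, collapse = "")
    cds_codons <- c(codon_for_aa[st$residues], "taa")
    cds[leaf] <- paste(cds_codons, collapse = "")
    cds_len <- nchar(cds[leaf])
    ## intron offsets p in CDS coordinates, in gene order
    p <- integer(0)
    if (nrow(st$introns)) {
      anchor_idx <- match(st$introns$site, st$sites)
      p <- sort(3L * (anchor_idx - 1L) + st$introns$phase)
    }
    ## genomic layout: pad + exons interleaved with gt..ag introns + pad
    bounds <- c(0L, p, cds_len)
    exon_seqs <- substring(cds[leaf], utils::head(bounds, -1L) + 1L,
                           bounds[-1L])
    ilen <- sample(seq(config$intron_length_range[1L],
                       config$intron_length_range[2L]),
                   length(p), replace = TRUE)
    intron_seqs <- vapply(ilen, function(l)
      paste0("gt", random_dna(l - 4L), "ag"), "")
    pad5 <- random_dna(30L); pad3 <- random_dna(30L)
    pieces <- character(0)
    for (k in seq_along(exon_seqs)) {
      pieces <- c(pieces, exon_seqs[k])
      if (k <= length(intron_seqs)) pieces <- c(pieces, intron_seqs[k])
    }
    gene_seq <- paste(pieces, collapse = "")
    contig_plus <- paste0(pad5, gene_seq, pad3)
    ## exon spans on the plus-oriented contig
    widths <- nchar(exon_seqs)
    starts <- integer(length(widths)); pos <- 30L
    for (k in seq_along(widths)) {
      starts[k] <- pos
      pos <- pos + widths[k] + if (k <= length(ilen)) ilen[k] else 0L
    }
    ends <- starts + widths
    strand <- if (stats::runif(1L) < config$minus_strand_prob) "-" else "+"
    if (strand == "-") {
      lc <- nchar(contig_plus)
      contig <- reverse_complement(contig_plus)
      new_starts <- lc - ends; new_ends <- lc - starts
      o <- order(new_starts, decreasing = TRUE)  # transcript orientation
      starts <- new_starts[o]; ends <- new_ends[o]
    } else {
      contig <- contig_plus
    }
    contigs[leaf] <- contig
    structures[[leaf]] <- gene_structure(
      leaf, cbind(starts, ends), species = leaf, family = config$family,
      strand = strand, contig_id = paste0(leaf, "_contig"))
    res <- st$residues[match(registry, st$sites)]
    res[is.na(res)] <- "-"
    aln_rows[leaf] <- paste(res, collapse = "")
  }

  gains <- if (length(gains)) do.call(rbind, gains) else
    data.frame(character = character(), child = character(),
               site = integer(), phase = integer())
  losses <- if (length(losses)) do.call(rbind, losses) else
    data.frame(character = character(), child = character())
  root_chars$child <- node_label(tr, root_node)
  characters <- rbind(
    data.frame(character = root_chars$character, child = root_chars$child,
               site = root_chars$site, phase = root_chars$phase,
               stringsAsFactors = FALSE),
    gains)
  characters$column <- match(characters$site, registry)

  structure(list(tree = tr, structures = structures, contigs = contigs,
                 cds = cds, proteins = proteins,
                 alignment = as_msa(aln_rows),
                 truth = list(characters = characters, gains = gains,
                              losses = losses, seed = config$seed),
                 config = config),
            class = "intron_sim")
}

#' @export
print.intron_sim <- function(x, ...) {
  cat(sprintf("simulated dataset: %d leaves, %d planted character(s), %d loss(es), seed %d\n",
              ape::Ntip(x$tree), nrow(x$truth$characters),
              nrow(x$truth$losses), x$truth$seed))
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Emits the exon-table TSV, CDS/protein/contig FASTA files, the true
#' alignment as aligned FASTA, the tree as Newick, and the truth log as
#' JSON (schema version 1).
#'
#' @param sim An [simulate_genes()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "intron_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(sim$structures, function(g)
    data.frame(gene_id = g$gene_id, species = g$species, family = g$family,
               strand = g$strand, contig_id = g$contig_id,
               exon_index = seq_len(nrow(g$exons)),
               start = g$exons[, "start"], end = g$exons[, "end"])))
  utils::write.table(rows, file.path(dir, "structures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(toupper(sim$contigs)),
                              file.path(dir, "contigs.fasta"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(toupper(sim$cds)),
                              file.path(dir, "cds.fasta"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$proteins),
                              file.path(dir, "proteins.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(as.character(sim$alignment),
                                            names(sim$alignment))),
    file.path(dir, "alignment.fasta"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(c(list(schema_version = 1L), sim$truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Generate a transposon-style intron with planted signatures
#'
#' Builds an intron flanked by exonic sequence, carrying (i) a target-site
#' duplication whose copies sit at the two intron ends — the repeat is
#' `gt...ag`, so the splice dinucleotides lie inside the direct repeats,
#' as observed for transposon-derived introns; (ii) a terminal inverted
#' repeat element between the copies whose arms begin `tgt` and end `aca`;
#' and (iii) a central tandem array (default a 37-nt unit repeated 4 times
#' with 2 point mutations).  A deterministic redraw guard ensures no chance
#' flank base extends the planted duplication, so detectors recover the
#' planted lengths exactly under any seed.
#'
#' @param tsd_len Target-site duplication length (0 disables; lengths >= 4
#'   straddle the splice sites, shorter ones are placed in the exonic
#'   flanks).
#' @param tir_arm Terminal-inverted-repeat arm length (>= 3).
#' @param unit_len,copies,n_mutations Tandem array parameters: unit length,
#'   copy number, and number of point mutations scattered over the array.
#' @param flank_len Length of each exonic flank.
#' @param seed Integer seed.
#' @return List (`flank5`, `intron`, `flank3`, `truth`); `truth` records
#'   every planted coordinate and sequence.
#' @export
make_te_intron <- function(tsd_len = 4, tir_arm = 12, unit_len = 37,
                           copies = 4, n_mutations = 2, flank_len = 60,
                           seed = 1) {
  if (tir_arm < 3) stop("TIR arm must be at least 3 nt")
  set.seed(seed)
  unit <- random_dna(unit_len)
  array <- strrep(unit, copies)
  if (n_mutations > 0 && copies >= 2) {
    at <- sample(nchar(array), min(n_mutations, nchar(array)))
    arr <- seq_chars(array)
    for (i in at) arr[i] <- sample(setdiff(DNA_ALPHABET, arr[i]), 1L)
    array <- paste(arr, collapse = "")
  }
  for (attempt in seq_len(200L)) {
    tir_left <- paste0("tgt", random_dna(tir_arm - 3L))
    tir_right <- reverse_complement(tir_left)   # ends "aca"
    spacer1 <- random_dna(15L); spacer2 <- random_dna(15L)
    core <- paste0(tir_left, spacer1, array, spacer2, tir_right)
    if (tsd_len >= 4) {
      tsd <- paste0("gt", random_dna(tsd_len - 4L), "ag")
      intron <- paste0(tsd, core, tsd)
      flank5 <- random_dna(flank_len); flank3 <- random_dna(flank_len)
    } else if (tsd_len > 0) {
      tsd <- random_dna(tsd_len)
      intron <- paste0("gt", core, "ag")
      flank5 <- paste0(random_dna(flank_len - tsd_len), tsd)
      flank3 <- paste0(tsd, random_dna(flank_len - tsd_len))
    } else {
      tsd <- ""
      intron <- paste0("gt", core, "ag")
      flank5 <- random_dna(flank_len); flank3 <- random_dna(flank_len)
    }
    ## redraw guard: the top detected duplication must be the planted one
    if (tsd_len > 0) {
      cand <- detect_tsd(flank5, intron, flank3)
      if (!nrow(cand) || cand$length[1L] != tsd_len ||
          cand$seq[1L] != tsd) next
    }
    return(list(flank5 = flank5, intron = intron, flank3 = flank3,
                truth = list(tsd = tsd, tsd_len = tsd_len,
                             tir_left = tir_left, tir_right = tir_right,
                             tir_arm = tir_arm, unit = unit,
                             unit_len = unit_len, copies = copies,
                             n_mutations = n_mutations, seed = seed)))
  }
  stop("could not assemble a clean construct; widen the parameters")
}

#' Plant a query in decoy contigs
#'
#' Builds a small synthetic genome: `n_copies` contigs carry a (possibly
#' mutated) copy of `query` embedded in random sequence, plus `n_empty`
#' contigs of pure random sequence.
#'
#' @param query Nucleotide string to plant.
#' @param n_copies Number of contigs carrying a copy.
#' @param n_empty Number of decoy contigs without a copy.
#' @param contig_len Length of each contig (>= query length + 20).
#' @param mutation_rate Per-base substitution probability applied to each
#'   planted copy.
#' @param seed Integer seed.
#' @return Named character vector of contigs.
#' @export
make_decoy_contigs <- function(query, n_copies = 3, n_empty = 2,
                               contig_len = 1000, mutation_rate = 0,
                               seed = 1) {
  set.seed(seed)
  nq <- nchar(query)
  if (contig_len < nq + 20L) stop("contigs too short for the query")
  out <- character(n_copies + n_empty)
  names(out) <- sprintf("contig%02d", seq_along(out))
  for (i in seq_len(n_copies)) {
    q <- seq_chars(query)
    if (mutation_rate > 0) {
      hit <- which(stats::runif(nq) < mutation_rate)
      for (j in hit) q[j] <- sample(setdiff(DNA_ALPHABET, q[j]), 1L)
    }
    at <- sample(contig_len - nq - 10L, 1L) + 5L
    out[i] <- paste0(random_dna(at), paste(q, collapse = ""),
                     random_dna(contig_len - at - nq))
  }
  for (i in seq_len(n_empty)) out[n_copies + i] <- random_dna(contig_len)
  out
}
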