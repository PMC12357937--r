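# Packaged lineage-level fixture for slc26a1/slc26a2 intron turnover in
# ray-finned fishes.
#
# The fixture transcribes the published lineage-level exon-intron structure
# statements into presence/absence matrices over 11 lineage taxa, plus the
# two competing Euteleostei topologies (Galaxiiformes sister to
# Neoteleostei, after Lavoue et al./Near et al., versus Galaxiiformes with
# Esociformes/Salmoniformes/Argentiniformes, after Betancur-R et al.).
# Event counts are invariant to expanding a lineage row into its member
# species, so lineage-level taxa suffice for all matrix and event
# computations.  The per-character alignment columns shipped alongside are
# SYNTHETIC schematic placeholders: distinct and order-preserving, chosen
# so that the two published near-insertion offsets (7 nt and 23 nt) are
# reproduced on the schematic axis, but they are not real coordinates.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "intronevo")
  if (p == "") stop(sprintf("fixture file '%s' not found", file))
  p
}

#' The slc26a1/slc26a2 lineage fixture
#'
#' Loads the packaged presence/absence matrices (11 lineage taxa by 7
#' slc26a1 characters and 6 slc26a2 characters), the schematic character
#' coordinates, and the two candidate Euteleostei species trees.
#'
#' Characters: `A1`/`A1p` are the ancient jawed-vertebrate introns of
#' slc26a1/slc26a2; `R1` the ray-finned slc26a2 intron; `E1`-`E5` the
#' Eurypterygii slc26a1 gains; `Q1` the Eurypterygii slc26a2 gain;
#' `O1`/`O2` the Osmeriformes/Stomiiformes gains near (but not at) `E2`
#' and `Q1`; `N1`/`N2` the two notothenioid slc26a2 gains.
#'
#' @return List with `matrices` (`$slc26a1`, `$slc26a2`), `combined`
#'   (both matrices column-bound over the same taxa), `characters`
#'   (data frame `family`, `character`, `column`, `phase`, `note`), and
#'   `trees` (`$lavoue_near`, `$betancur`).
#' @examples
#' fx <- slc26_fixture()
#' fit <- dollo_reconstruct(fx$trees$lavoue_near, fx$matrices$slc26a1)
#' exon_count_at(fit, "Eurypterygii")  # 7
#' @export
slc26_fixture <- function() {
  m1 <- read_presence_matrix(fixture_path("slc26a1_matrix.tsv"))
  m2 <- read_presence_matrix(fixture_path("slc26a2_matrix.tsv"))
  stopifnot(identical(rownames(m1), rownames(m2)))
  chars <- utils::read.delim(fixture_path("slc26_characters.tsv"),
                             stringsAsFactors = FALSE)
  trees <- list(
    lavoue_near = read_species_tree(fixture_path("euteleostei_lavoue_near.nwk")),
    betancur = read_species_tree(fixture_path("euteleostei_betancur.nwk")))
  list(matrices = list(slc26a1 = m1, slc26a2 = m2),
       combined = cbind(m1, m2),
       characters = chars,
       trees = trees)
}

#' Schematic projections for the fixture characters
#'
#' Expands a fixture family's presence matrix and schematic character
#' coordinates into a projected-intron data frame (one pseudo-gene per
#' possessor taxon), suitable for [cluster_introns()], [near_matches()]
#' and [detect_convergence()] demonstrations and tests.
#'
#' @param fixture A [slc26_fixture()] result.
#' @param family `"slc26a1"`, `"slc26a2"`, or `"both"`.
#' @return Data frame with the [project_introns()] columns.
#' @export
fixture_projections <- function(fixture, family = c("both", "slc26a1",
                                                    "slc26a2")) {
  family <- match.arg(family)
  fams <- if (family == "both") c("slc26a1", "slc26a2") else family
  rows <- list()
  for (f in fams) {
    m <- fixture$matrices[[f]]
    ch <- fixture$characters[fixture$characters$family == f, , drop = FALSE]
    ch <- ch[order(ch$column, ch$phase), , drop = FALSE]
    for (tx in rownames(m)) {
      has <- ch[m[tx, ch$character] == 1L, , drop = FALSE]
      if (!nrow(has)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = paste(tx, f, sep = "_"),
        ordinal = seq_len(nrow(has)),
        column = has$column, phase = has$phase,
        taxon = tx, family = f, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
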