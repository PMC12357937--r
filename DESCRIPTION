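Package: intronevo
Title: Intron Gain and Loss Reconstruction in Coding Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying intron turnover in protein-coding genes across
    species: derivation of intron positions and phases from exon structures,
    projection of splice sites onto protein multiple sequence alignments,
    clustering of intron positions into homologous characters, detection of
    convergent intron insertion between gene families, Dollo parsimony
    reconstruction of intron gain and loss events on a rooted species tree,
    and detection of transposable-element signatures (target-site
    duplications, terminal inverted repeats, tandem repeats, interspersed
    genomic copies) in newly gained introns. Includes a synthetic-data
    generator that plants intron gains and losses on a tree for end-to-end
    validation, and a packaged lineage-level presence/absence fixture for the
    slc26a1/slc26a2 anion-transporter genes of ray-finned fishes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    Biostrings,
    rtracklayer,
    BiocGenerics,
    GenomicRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
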