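---
title: "Reconstructing intron turnover with intronevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing intron turnover with intronevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronevo)
```

## The model

An intron in a protein-coding gene is fully located by the number `p` of
coding nucleotides 5' of it. Its *phase* is `p mod 3` — 0 between codons,
1 or 2 inside a codon — and its *anchor residue* is codon `floor(p/3)`
(for phase 0 this is the residue immediately following the intron; one
uniform rule for all phases keeps the bookkeeping simple). Two introns in
different genes are *positionally homologous* when their anchor residues
occupy the same column of a protein multiple sequence alignment **and**
their phases agree. This package treats that joint identity as the
character definition and never merges nearby-but-distinct positions:
empirically, independent insertions can land within a handful of
nucleotides of each other (7 nt and 23 nt offsets occur between the
Osmeriformes/Stomiiformes introns and their Eurypterygii neighbours in
the slc26 fixture), and conflating them would fabricate homology. Near
positions are *reported* (`near_matches()`, default ceiling 30 nt, which
covers the observed 7 and 23 nt cases with margin; the ceiling is a free
reporting parameter, not a homology threshold) and cross-family identical
or near positions are flagged as candidate convergent insertions
(`detect_convergence()`).

Gain/loss history is inferred under **Dollo parsimony**: each character
arises exactly once, losses are unlimited. This matches the usual
reasoning about intron positions — the chance of two independent
insertions at the same nucleotide and phase is treated as negligible, and
the package's own convergence detector exists precisely to surface the
exceptions. For a character with possessor set *S*, the minimal
reconstruction is closed-form: the gain sits on the branch above
MRCA(*S*); a node below the MRCA has state 1 iff its subtree contains a
member of *S*; every state-1 node's state-0 child contributes one loss.
The test suite proves minimality by exhaustive enumeration of all
single-origin state assignments on random trees of up to 8 leaves.
Singleton characters are reconstructed as terminal-branch gains and
flagged as weak evidence (a one-species character cannot be distinguished
from annotation error by parsimony alone). Multifurcations are allowed; a
possessor-free polytomy child counts as one loss.

`compare_topologies()` refits the same matrix on competing species trees
and reports total events. For the packaged slc26 fixture this contrasts
the two published Euteleostei hypotheses: with Galaxiiformes sister to
Neoteleostei the combined matrix needs 14 events; with Galaxiiformes
beside Esociformes/Salmoniformes/Argentiniformes it needs 20. The package
reports both Dollo optima rather than asserting an event list for the
disfavoured topology.

## Coordinate conventions

Internally all sequence coordinates are 0-based half-open; GFF3's 1-based
inclusive convention is converted at the parser boundary, and minus-strand
CDS features are re-ordered into transcript orientation. Alignment columns
and residue indices in the R API are **1-based**, the R convention.
The CDS is taken to include the stop codon (the GFF3 CDS convention), so
the encoded protein has `CDS/3 - 1` residues, and an intron whose anchor
falls in or after the stop codon is rejected at projection. Offsets
between intron positions are measured on one declared reference gene's
coding axis (`3*r + phase`, `r` = reference residues left of the column);
when the column is a gap in the reference the position collapses to the
count of preceding reference residues, keeping the measure deterministic.
Genes with species-specific amino-terminal extensions must be trimmed by
the caller before input — mirroring standard practice of excluding exons
that encode non-conserved N-terminal sequence — since the tool cannot
decide which extension is non-homologous.

## TE signature detectors

Transposon insertion through a staggered cut duplicates the target site,
leaving a short direct repeat flanking the element, and DNA transposons
typically carry terminal inverted repeats. In known transposon-derived
introns the splice dinucleotides can lie *inside* these repeats, so
`detect_tsd()` allows candidate repeats to straddle the exon/intron
junction (a strict exon-only mode is available); candidates are exact
L-mer pairs (default 3–10 nt) with one occurrence within 10 nt of each
junction, ranked by length then 5' proximity. `detect_tir()` scores
prefix/suffix arm pairs by identity against the reverse complement and
reports the arm maximizing `matches - (1 - max_mismatch)*arm`, so an
exact-armed element is reported at its true arm length rather than padded
out to the identity floor.

`tandem_period()` had a genuinely open design point: "the fraction of
matching positions over the best window" is degenerate if taken literally
(a tiny perfect window always wins). The implementation scores, for each
unit length `k`, the segment of the lag-`k` match indicator maximizing
`matches - threshold*length` with at least two copies spanned (exactly,
via prefix sums), and reports the `k` with the highest score, ties to the
smallest `k`. This keeps the intended behaviour: a 37-nt array is
reported as 37, not 74 (the doubled period spans half as many positions);
a homopolymer collapses to the smallest admissible unit and is flagged
low-complexity; and the suite checks agreement with a quadratic
brute-force oracle.

`scan_interspersed()` is a deliberately small seed-and-extend homology
search (exact 13-mers chained by diagonal, ungapped identity over the
chained span), sufficient for deciding "does this intron look like it
occurs at multiple loci" on desk-scale contig sets — it is not a BLAST
replacement. Overlapping chains on one contig are merged so a tandem
array inside the query cannot inflate the locus count. `classify_te()`
calls an intron a putative TE at ≥ 3 distinct loci by default;
"multiple loci" is not defined more precisely in the source literature,
so the threshold is exposed.

## The synthetic world

`simulate_genes()` generates the conditions the inference assumes: a
single gene evolving down a rooted tree, intron gains as a Poisson
process per branch at uniformly drawn (codon, phase) positions that are
never reused anywhere on the tree (zero homoplasy by construction),
losses as a Poisson process over currently present introns, uniform
random amino-acid substitutions, and optional codon-aligned indels with
the true alignment tracked through site identities. Defaults state a
realistic regime: a ~700-codon gene (the size of an slc26 anion
transporter), gains at 0.5 and losses at 0.1 per unit branch length —
turnover rare enough that characters stay informative, as observed in
fish genes where a handful of events span hundreds of millions of years.
Substitutions default to 0.05 per site per unit length; protein evolution
uses no rate matrix because only alignment-coordinate bookkeeping, not
phylogenetic signal, is exercised — the true alignment is emitted so MSA
construction stays out of scope. Leaf genes are written onto synthetic
contigs (random strand) with `gt..ag` introns so the parser, splice
validator and projection run end-to-end; tests verify exact recovery of
the planted character inventory and event map over 20 seeded replicates
at loss rate 0, and against planted totals on a loss-bearing draw whose
cleanness is certified by the exhaustive oracle first.

What a green simulation test does **not** establish: robustness to
alignment error (the true alignment is given), to paralog confusion, to
annotation error in exon boundaries, or to genuinely convergent
insertion — the generator excludes homoplasy by construction.

`make_te_intron()` builds the transposon-style construct: direct repeat
`gt…ag` (default 4 nt, hence exactly `gtag`) at both intron ends — so the
splice dinucleotides sit inside the repeats, as in the published
schematics — a TIR element between them whose arms begin `tgt` and end
`aca` (default 12 nt), and a central tandem array (default 37-nt unit ×
4 copies with 2 point mutations). A deterministic redraw guard
regenerates the random parts if a chance flank base would extend the
planted repeat, so the detectors recover the planted lengths under any
seed; this is part of the stated construct, not a tuned quantity.

## The slc26 fixture

`slc26_fixture()` packages the lineage-level presence/absence matrices
for slc26a1 (7 characters × 11 lineage taxa) and slc26a2 (6 × 11)
transcribed from published structure statements, plus both candidate
Euteleostei topologies. Lineage-level taxa suffice because Dollo event
counts are invariant to expanding a lineage into member species with
identical rows. The per-character alignment columns shipped with the
fixture are **synthetic placeholders** — distinct and order-preserving,
chosen so the two published near-insertion offsets (7 nt, 23 nt) are
reproduced on the schematic axis — because the real per-species
coordinates exist only graphically in the source material. Every numeric
claim in the README is computed by the test suite from this fixture and
the reconstruction code, not stored.

## Limitations

* Dollo parsimony, not likelihood: no gain/loss rate estimation, no
  divergence times, no uncertainty on event placement.
* Homology is exact column-and-phase identity on a *given* alignment;
  alignment errors propagate directly into characters.
* One gene per taxon per family is required for matrix building; paralogs
  (e.g. unreduced ohnolog pairs) must be resolved upstream.
* The interspersed scan is ungapped and exact-seeded; diverged or
  heavily indel-ridden TE copies will be under-detected relative to a
  full local aligner.
* Frameshifted pseudogenes and codon-aware alignment are out of scope.
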