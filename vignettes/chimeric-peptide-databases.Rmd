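---
title: "Chimeric peptide databases from regular and expanded codons"
author: "chimeraPep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chimeric peptide databases from regular and expanded codons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraPep)
```

## The model

Ribosomes occasionally decode codons expanded by one or two extra
nucleotides — tetracodons and pentacodons — with the expanded positions
silent: only the first three nucleotides of each group determine the amino
acid. A peptide translated partly under regular tricodons and partly under
expanded codons from contiguous genomic sequence is *chimeric*. Detecting
such peptides in mass-spectrometry data requires a theoretical database of
every chimeric peptide a genome could encode.

`chimeraPep` builds that database for a circular genome (the reference use
case is the 16,569 bp human mitogenome, translated under the vertebrate
mitochondrial genetic code). Each database entry comes from a sliding window
holding three segments: $n_1$ regular tricodons, $n_2$ codons expanded by
$k \in \{1,2\}$ silent nucleotides, and $n_3$ regular tricodons. With the
default $n_1 = n_2 = n_3 = 30$ the window spans

$$3 n_1 + (3+k)\,n_2 + 3 n_3 \;=\; \begin{cases} 300\ \text{nt} & k = 1\\
330\ \text{nt} & k = 2 \end{cases}$$

Windows advance by single nucleotides along the complete circular genome on
both strands, so a genome of $L$ bp yields $2L$ windows per expansion type.
Every translated stop codon (AGA, AGG, TAA, TAG under the mitochondrial
code; TGA is tryptophan) is substituted by one amino acid, the *same* letter
at every stop of a peptide, once for each of the 19 mass-distinguishable
amino acids (leucine and isoleucine are isobaric and merged). The nominal
database size per expansion type is therefore $2 L \times 19$; for
$L = 16{,}569$ that is $629{,}622$. Stop-free windows are emitted once —
duplicating them 19 times would add no information — while the nominal
$\times 19$ count is kept as the normalization for expectation values
(`nominalDbSize()`), which is why the written FASTA is slightly smaller
than the nominal count.

```{r constants}
windowSpan(1); windowSpan(2)
nominalDbSize(16569)
```

## Translation and its oracle

Expanded-codon translation is defined by its first-three-nucleotides rule,
equivalently by the *del-transform*: deleting every 4th (or 4th and 5th)
nucleotide after each nucleotide triplet and translating regular tricodons.
The two routes are implemented independently (`translateExpanded()` vs
`deleteSilent()` + `translateTricodons()`) and their equality over seeded
random sequences is a standing property test — the strongest check the
package has that the expansion bookkeeping is right.

```{r oracle}
s <- "ATGGTGAC"
translateExpanded(s, k = 1)$aa
translateTricodons(deleteSilent(s, k = 1))$aa
```

## Detection-side utilities

In-silico digestion (`digestPeptide()`) cuts at the carboxyl or amino
extremity of one residue species (L/I merged) with a missed-cleavage budget
(default at most one, the trypsin setting of the original searches);
the per-sample search enumeration is the $2 \times 19 = 38$ (residue,
extremity) grid. Monoisotopic masses use the standard residue masses plus
water (18.010565 Da), with carbamidomethyl-C (+57.02146 Da) fixed and
oxidation-M (+15.99491 Da) and Lys→PyrLys (+109.05276 Da) variable by
default — Unimod values, since the search protocol names the modifications
without printing masses. False-discovery rates over scored hits use a plain
target–decoy estimator against per-record reversed decoys
(`makeDecoyDb()`, `targetDecoyQvalues()`); vendor scores are pass-through
inputs, never recomputed.

## Annotation: junction parsimony

A detected peptide is matched to templates as a contiguous substring under
I/L collapse; lowercase letters (claimed stop-translated residues) align
only with template stop positions carrying that substitution letter. The
matched residues inherit segment labels, and the boundary between tricoded
and expanded parts is then refined by parsimony: residues of the expanded
segment that the continued tricodon reading frame would translate
identically are *ambiguous* and assigned to the tricoded side.

One subtlety deserves a paragraph, because it decides what "ambiguous"
means operationally. Under the trailing-silent convention the first
expanded codon's informative trinucleotide coincides with the tricodon
continuation at the same position, so a comparison made exactly at the
boundary is vacuous — it can never fail, and taking it literally would make
every 5′ junction ambiguous by at least one residue. The package therefore
lets the comparisons that involve the silent nucleotides decide: the
ambiguous run at the tricoded→expanded boundary extends while continuation
tricodon $j{+}1$ reproduces expanded residue $j{+}1$ ($j = 0, 1, \dots$),
and a junction whose first such comparison fails is clean (span 0). When
every comparison holds — a homopolymer stretch is the extreme case — the
whole expanded segment collapses onto the tricoded side and the match is no
longer chimeric. The mirrored rule applies at the expanded→tricoded
boundary, where no comparison is vacuous; the 5′ extension takes precedence
if the two runs would meet.

Annotations pass the chimera filter when at least `minLen` (default 8)
consecutive tricoded and `minLen` consecutive expanded residues remain,
adjacent across the junction. The associated expectation value is
implemented exactly as the defining expression $N \cdot 19^{-\text{minLen}}$
with $N$ the nominal database size; note that for $N = 629{,}622$ and
`minLen = 8` this evaluates to $3.7\times10^{-5}$, not to the 0.0014
sometimes quoted alongside the same expression — the package reports what
the formula yields.

```{r evalue}
chimeraEvalue(nominalDbSize(16569), 8)
```

Tricoded runs that fall inside a canonical CDS on the same strand *and* in
its reading frame are reported as protein hits with 1-based residue ranges
(`mapToGene()`); near-frame placements are rejected, and when the genome
sequence is available the hit must also be sequence-concordant (L/I
collapsed, stop-substituted positions exempt). The bundled
`inst/extdata/human_mito_cds.tsv` carries the coordinates of the 13
mitochondrial protein-coding genes for the reference use case.

## The synthetic experiment

`randomGenome()` draws i.i.d. nucleotides at GC 0.44 (the human mitogenome
composition, cosmetically); `plantDetections()` emulates a detected-peptide
list by sampling windows, rendering a stop variant, digesting it with the
configured cleavage rule and keeping a fragment that straddles a junction
with at least `minLen` residues on each side *after* the parsimony
reassignment (windows are resampled when digestion yields none), plus
uniform-random noise peptides. A single integer seed drives everything and
the global RNG state is left untouched.

What this emulates is the combinatorial layer: window enumeration,
translation, substitution, digestion and matching. What it does not emulate
is everything spectral — noise peptides are uniform strings, not
near-isobaric false matches; there are no intensities, retention times or
fragmentation spectra, and vendor scores are placeholders. Passing the
planted-recovery tests therefore certifies the bookkeeping from genome to
annotated junction, not the behaviour of any search engine on real spectra.

```{r plant, message = FALSE}
g <- randomGenome(2000, seed = 11)
dbs <- lapply(1:2, function(k) buildChimeraDb(g, k))
sim <- plantDetections(g, dbs, nPlants = 5, noisePeptides = 2, seed = 5)
anno <- annotateAll(sim$detected, dbs, g)
anno[anno$sample == "plant", c("rendered", "triLen", "expLen",
  "ambiguousSpan", "junctionSide", "frame", "posStart")]
```

## Numerical and design choices

* **Coordinates** are 0-based half-open internally; all reported positions
  are 1-based inclusive, matching the convention of printed annotation
  tables. Frames are numbered 1–6 (1–3 the + strand at offsets 0–2, 4–6 the
  reverse complement likewise); the offset-within-strand pairing
  `offset = (frame − 1) mod 3` is a documented convention since only the
  strand split of frame numbers is standard.
* **Circularity** is on by default — the $2L$ window count requires windows
  near the 3′ end to wrap — and can be disabled, in which case only fitting
  windows are enumerated.
* **Genetic code**: NCBI table 2 by default, selectable by identifier; the
  code table itself comes from `Biostrings`.
* **Silent positions trail** their codon, consistent with the del-transform
  ("deleting after each triplet") definition.
* **Tie-breaks** are fixed for determinism: windows enumerate + strand
  first then −, ascending start; among multiple matching templates the best
  has fewest stop substitutions in the matched span, then + strand, lowest
  start, lowest $k$; stop variants are emitted alphabetically.
* **Degenerate inputs**: peptides with mixed lowercase substitution letters
  match nothing (no single variant can produce them); matches confined to
  one segment annotate with a zero-length partner and simply fail the
  filter; empty databases write valid empty FASTA.
* **Test scales**: property tests run at a few hundred seeded cases;
  the database-construction check runs at the full 2 × 16,569-window scale
  per expansion type, and planted recovery at a 5,000 bp genome with 200
  plants — sizes at which every code path, including wraparound and both
  strands, is exercised.

## Limitations

Only single-genome, single-chromosome inputs are supported; ambiguity codes
are rejected rather than resolved. Codons expanded by more than two
nucleotides are out of scope, as are spectral matching and semi-supervised
FDR re-scoring — the annotation layer starts from peptide sequences that a
search engine already accepted. The e-value is a database-scale expectation,
not a per-spectrum significance.
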