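# chimeraPep

Theoretical chimeric-peptide databases from regular and expanded codons,
with the companion utilities needed to annotate detections against them.

## The problem

Ribosomes occasionally read codons expanded by one or two silent
nucleotides (tetracodons and pentacodons: only the first three nucleotides
of each group code). A *chimeric* peptide is translated from contiguous
genomic sequence partly under regular tricodons and partly under expanded
codons. Finding such peptides in mass-spectrometry data needs a custom
search database enumerating every chimeric peptide a genome could encode —
the reference use case is the 16,569 bp human mitogenome under the
vertebrate mitochondrial genetic code (NCBI table 2).

`chimeraPep` is for proteogenomics users who want to build that database,
and to take the peptide lists a search engine returns and annotate them:
infer the tricodon/expanded-codon junction, apply the chimera filter, and
map the regular-coded part onto canonical mitochondrial proteins.

## The method

Each database entry comes from a sliding window of
*n₁* = 30 tricodons + *n₂* = 30 codons expanded by *k* ∈ {1,2} nucleotides
+ *n₃* = 30 tricodons, i.e.

    3·30 + (3+k)·30 + 3·30 = 300 nt (k = 1) or 330 nt (k = 2),

advancing one nucleotide at a time along both strands of the circular
genome: 2·L windows per expansion type. Windows containing stop codons
(AGA/AGG/TAA/TAG; TGA is Trp) are included once per mass-distinguishable
amino acid substituted at *all* stops (19 variants; L/I merged, rendered
lowercase), so the nominal database size per expansion type is
2·L·19 = **629,622** for the mitogenome. Supporting operations: in-silico
digestion with carboxyl/amino cleavage sides and a missed-cleavage budget,
the 2 × 19 = 38 per-sample search-configuration grid, monoisotopic masses
with the standard fixed/variable modifications, reverse-decoy databases
with target–decoy q-values, and junction parsimony (ambiguous residues —
identical under both readings — count as tricoded). The chimera filter
keeps annotations with ≥ 8 consecutive residues on each side of the
junction; its expectation value is N·19⁻⁸ ≈ 3.7e−5 at N = 629,622.

## Worked example

```r
library(chimeraPep)

g   <- randomGenome(5000, seed = 42)                 # synthetic circular genome
dbs <- lapply(1:2, function(k) buildChimeraDb(g, k)) # tetra- and pentacodon DBs
dbs[[1]]
#> ChimericPeptideDB: 10000 templates (k=1, 30/30/30 codons) over 'synthetic' (5000 bp)
#>   9987 templates contain translated stops

writeChimeraDb(dbs[[1]], "db_k1.fa")                 # FASTA with provenance headers
#> >synthetic|s=+|p=1|k=1|stop=A|seg=30,30,30|sp=19,27,54,71,89
#> PREVHPCTILADNVTPRFaNAATKMDaMGNERGIGALAGPRRGWTVGSDLVYRaPTNGLL...

sim  <- plantDetections(g, dbs, nPlants = 3, noisePeptides = 1, seed = 7)
anno <- annotateAll(sim$detected, dbs, g)
anno[, c("sequence", "matched", "triLen", "expLen", "junctionSide", "frame",
         "posStart", "passesFilter")]
#>                                        sequence matched triLen expLen        junctionSide frame posStart passesFilter
#> 1 SSGVDPMYhINSKWYIhDEDHhhPFVGhRhTNSLPTVHPRRGPAK    TRUE     16     29 3prime_noncanonical     6     1575         TRUE
#> 2               STVNWQFRTEMNQLDHkSEAPYFGSAMHNHK    TRUE     13     18 5prime_noncanonical     2      569         TRUE
#> 3         ILRGILkLSLANLETENNVEQLRSFNISQIGQNQTNK    TRUE     19     18 5prime_noncanonical     5     1450         TRUE
#> 4         GTENGCEGNKVREDQLKQSLCPKMRKTWFGDLTKTWW   FALSE     NA     NA                <NA>    NA       NA        FALSE
```

Row by row: the three planted fragments are matched back to their source
windows; `triLen`/`expLen` are the residue counts on the tricoded and
expanded sides of the inferred junction (lowercase letters are
stop-substituted residues), `junctionSide` says which extremity is
noncanonical, and `frame`/`posStart` give the tricoded part's position in
the 1–6 frame-translation coordinate system used for gene mapping. The
random noise peptide matches nothing. At mitogenome scale the filter's
expectation value is `chimeraEvalue(nominalDbSize(16569), 8)` = 3.707e−5.

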