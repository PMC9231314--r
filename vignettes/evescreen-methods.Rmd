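---
title: "Methods: EVE screening and virome characterization with evescreen"
author: "evescreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EVE screening and virome characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evescreen)
```

## The problem

Insect genomes carry endogenous viral elements (EVEs): fragments of viral
genomes that integrated into the germline during past infections and were
inherited vertically. Detecting them in a host assembly, deciding which
apparent hits are genuine integrations rather than co-sequenced
contamination, and establishing which insertions are orthologous across
independently assembled genomes together form a small, well-defined
paleovirological workflow. A complementary workflow characterizes
*exogenous* viruses from transcriptome assemblies — annotating ORFs,
triaging contig completeness, preparing concatenated trimmed alignments
for phylogenetics, and quantifying viral RNA abundance relative to a
housekeeping gene. `evescreen` implements both workflows for the black
soldier fly (*Hermetia illucens*) use case, together with a synthetic
data generator that makes every screening step testable against known
ground truth.

## Translated homology search

The screening engine is a BLASTx-style translated search: each genome
contig is translated in six frames (standard code; ambiguity codons
become `X`, stops `*`), and each frame is scanned against the viral
protein set with exact amino-acid k-mer seeds followed by ungapped
X-drop extension under BLOSUM62. Per (region, subject) only the
best-scoring segment is kept, with ties broken by percent identity and
then subject id. Coordinates are reported 0-based half-open on the
forward strand, with the frame recorded.

Tunable parameters, defaults, and why:

* `kmer_k = 3` (amino acids). Seed length trades specificity for
  sensitivity. At the decay levels the screen must handle (planted
  copies at 60% nucleotide identity are only ~30% amino-acid identity),
  a 200–400 residue fragment fails to contain any exact 4-mer with a
  probability of a few percent, while exact 3-mers are essentially
  always present. Since the extension step and the score floor carry
  the specificity, the shorter seed is the right default here.
* `min_score = 80` (raw BLOSUM62 sum). Chosen from an ungapped
  Karlin–Altschul estimate (lambda ~0.318, K ~0.13): for the
  database sizes this package targets (hundreds of kilobases of genome
  against a few thousand residues of protein), the expected count of
  random segments scoring 80 or more is ~1e-3, while genuine decayed
  EVEs score in the hundreds. Both the false-positive and the recall
  acceptance suites run at this default.
* `min_aln_len_aa = 15`, `x_drop = 20`. Minimum reported segment length
  and the extension termination threshold; the X-drop value is the
  conventional ungapped setting and is exposed for tuning.

No E-values are computed: the stand-in search ranks by raw score, and
externally produced tabular hits (the 12-column `outfmt 6` dialect) can
be ingested with their own E-values via `read_tabular_hits()` /
`tabular_to_hits()`, making an external DIAMOND/BLASTx run a drop-in
replacement for the built-in engine.

A note on reported identity: an X-drop extender returns the
*maximal-scoring* segment. When the random flank continues net-positive
for a few residues, the segment legitimately overhangs a planted
fragment, which dilutes percent identity slightly below 100 even though
every planted residue is matched. The test suite therefore asserts full
coverage and matched-residue counts rather than a literal 100.

## From hits to EVE calls

1. **Merging** (`merge_hits`): within each (contig, family) group, hits
   separated by a gap strictly less than 50 bp are unioned transitively
   into one candidate; overlapping hits always merge; families never
   merge with each other. Merging is strand-agnostic because EVE decay
   scrambles reading frames. The implementation rides on
   `IRanges::reduce(min.gapwidth = 50)`, and the suite checks it against
   an independent brute-force transitive clustering oracle.
2. **Host-protein screen** (`host_protein_screen`): a candidate is
   discarded iff its nucleotide sequence receives any translated-search
   hit against the host proteome at the same thresholds — the guard
   against host genes that merely resemble viral proteins.
3. **Contamination filter** (`contamination_filter`): a candidate is
   discarded iff it has less than 50 bp of host sequence on *both*
   sides, i.e. the "EVE" is essentially the whole contig. That is the
   signature of co-sequenced free virus or reagent contamination rather
   than an integration.
4. **Naming**: calls are named by family short code (`TotiEVE`,
   `ParvoEVE`, ...), with locus labels filled in later.

## Orthology across assemblies

`assign_loci` anchors loci on a reference assembly (the chromosome-level
one, by convention) and places every other EVE by two independent
conditions: (a) global nucleotide identity of the two EVE sequences at
or above 98% (match +1, mismatch −1, gap −2 per position; identity =
matches / alignment columns), and (b) both flanks of the query EVE must
align to the reference EVE's 20 kb window with at least 50 matched
nucleotides. The 98% bar is applied to the EVE sequence only, with flank
placement as a separate condition — the two-condition reading keeps
"same virus" and "same insertion site" logically distinct. Loci are
labeled per family in reference coordinate order (`T1`, `T2`, ...,
`PR1`, ..., `PT1`, `Rh1`, `Xi1`); failures keep `np`. Windows clipped at
contig edges are allowed down to the minimum usable flank.

The pairwise aligner behind both conditions is
`Biostrings::pairwiseAlignment` (global for EVE identity, local for
flank placement), a deterministic substitute for interactive mapping
tools.

## Exogenous virus annotation

`find_orfs` enumerates all ATG-to-stop ORFs of at least `min_len_aa`
codons on six frames and labels the two longest mutually non-overlapping
ORFs following the canonical totivirus layout: the longer (RdRP-bearing)
ORF is `POL` and is expected 3' of the capsid `GAG`; when the layout is
inverted the contig's implied orientation is reported as `-` rather than
rewriting the sequence. Equal lengths fall back to coordinate order with
a warning. `triage_viral_contigs` classes a contig `near_complete` iff
it is strictly longer than 5 kb *and* carries both labels; everything
else is `partial`.

Alignment preparation follows the preprocessing contract used before
tree inference: ends are trimmed until a column with at least 50%
occupancy is met (the end-trim rule is this package's own definition,
config-exposed, since "trimmed at both ends" admits several readings and
end-trim is applied before the occupancy filter), then a column is
retained iff at least 10% of rows have a residue — a column at exactly
10% occupancy is kept. `concat_alignments` joins parts keyed by taxon
and records per-part column ranges for partition files. Alignment
*inference* and tree inference are deliberately out of scope; the
package consumes aligned FASTA and emits aligned FASTA / relaxed PHYLIP
/ NEXUS charsets.

## Quantification

TPM over a supplied CDS feature set: `rate_i = count_i / length_i`,
`TPM_i = 1e6 * rate_i / sum(rate)`. The denominator uses only the
supplied features, so each sample's TPM column sums to one million by
construction — matching the convention of the packaged abundance table.
Multi-placed reads count once toward their best placement; ties are
dropped. Ratios against the housekeeping gene are rounded half-even to
3 decimals, which reproduces every printed ratio cell of the packaged
table. The bundled mapper (`map_reads`) is an exact-substring matcher
for error-free synthetic reads; real data should arrive as counts or
minimal SAM text.

## The synthetic data generator

`simulate_eve_dataset` fixes the study conditions: three assemblies of
nine 24 kb contigs; nine planted loci from five families mirroring the
orthology pattern of the motivating study (five loci shared by all three
assemblies with conserved flanks, two shared by two, two private to the
reference); planted nucleotide identities spanning 0.60–1.00 with longer
fragments (up to ~380 aa) at lower identity, the way older insertions
present as longer but more decayed fossils; one flankless all-viral
contig to exercise the contamination filter; and one insert copied into
the host proteome as a decoy to exercise the false-positive screen.
Degradation is substitution-only so realized identity is exactly
controllable; reverse translation chooses codons uniformly; host
background is i.i.d. uniform nucleotides (GC configurable).

What the generator does *not* emulate — repeat landscapes, indels,
sequencing error, paired-end structure, real codon usage — bounds what
green tests mean: they demonstrate the screening logic and its
thresholds, not performance on real assemblies. The orthology
acceptance suite reuses the generator at 8 kb contigs (20 seeded
scenarios) to keep the default test run fast; the vignette-level claims
are unchanged by that scaling.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; the printed
  `SEQID:START-END` report dialect is mapped so span = END − START,
  the only reading consistent with the table's own span range
  (148–3750 nt).
* Candidate best hits break ties by score, then percent identity, then
  lexicographic subject id; locus placement takes the highest-identity
  passing anchor.
* Empty inputs degrade gracefully: empty FASTA → zero records; empty
  protein set → zero hits; empty locus set → empty matrices; all-gap
  alignments trim to zero width (valid); all-zero counts are an error
  ("no expressed features"), as TPM is undefined there.
* All generators take explicit integer seeds and restore the caller's
  RNG state; identical seeds reproduce files byte-identically.

## Known limitations

Ungapped extension cannot recover homology interrupted by indels or
frameshifts (frame-scrambled decay is still found when any single frame
retains seedable stretches); the search has no composition-based score
adjustment and no E-value calibration; orthology placement assumes the
reference assembly actually contains each shared locus; and the triage
rule is purely structural (length + two-ORF layout), not a sequence
classifier.
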