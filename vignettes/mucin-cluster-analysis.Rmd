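---
title: "Detecting and characterizing membrane-mucin gene clusters"
author: "MucinCluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing membrane-mucin gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MucinCluster)
```

## The problem

Membrane mucins such as MUC3A/MUC3B at human 7q22 carry a single enormous
exon encoding a PTS domain: a proline/threonine/serine-rich protein region
built from tandemly repeated DNA (a VNTR). Clusters of such genes are
doubly hard to analyze: the repeat arrays defeat short-read assembly, so
cluster members go missing from reference genomes, and surviving paralogs
are so similar (around 90% identity) that standard RNA-seq quantification
cannot tell their transcripts apart. This package implements the
computational workflow for that situation end to end, together with a
synthetic-data generator that plants a fully known truth, so that every
stage can be validated without touching external data.

## Gene detection in a marker-anchored interval

`callMucinGenes()` works on the forward strand of the interval between two
flanking marker genes located by `locateMarker()` (15-mer seeding, modal
diagonal, bounded Smith-Waterman refinement, ties to the lower
coordinate). A candidate gene must satisfy four criteria:

1. an in-frame **ATG** upstream of the PTS segment;
2. a **PTS-encoding segment** of at least `minPtsNt` (default 1,000 nt);
3. a **SEA-domain hit** downstream of the PTS segment;
4. **unique flanking sequence**: adjacent candidates whose non-PTS
   portions align at or above 95% global identity are treated as one locus
   and merged. The threshold sits above the 87-93% region identity
   observed between genuine mucin paralogs and below what assembly
   duplicates exhibit.

PTS segments are found per reading frame by a 100-residue sliding window
at P/T/S fraction at least 0.4, then sharpened in two steps: the
maximum-sum subinterval of (indicator - 0.7) pins the boundary where local
density crosses 70%, and a period-aware polish moves each boundary (at
most one repeat period) to where the periodic self-agreement
`x[i] == x[i + p]` breaks. On noise-free planted arrays this recovers the
exon boundaries exactly; under substitution noise the drift is bounded by
one period.

The start codon is chosen among upstream in-frame ATGs by an "openness"
score, codons spanned minus 150 per in-frame stop spanned. The penalty is
far above the reciprocal of the stop density expected from rare
substitution noise inside a real ORF (so a noise-created stop does not
disqualify the true start) and far below the reciprocal of the roughly
3/64 per-codon stop density of intergenic sequence (so spacer ATGs lose).
The SEA scan translates through premature stops for the same reason;
TM/PDZ annotation uses the stop-free protein. TM is the best 19-residue
window with mean Kyte-Doolittle hydropathy at least 1.6 (leftmost on
ties); the Class I PDZ motif is the C-terminal `[S/T]-X-{L,I,V,F,M}`.

Alignment identity is always matches divided by all alignment columns,
terminal gap columns included, under match +1, mismatch -1, gap open -2,
extend -1 (a gap run of length L costs 2 + L); `detectSea()` uses BLOSUM62
with gap open 10, extend 1, the conventional protein-local regime.

## Tandem-repeat decomposition

`detectPeriod()` scores each lag p by the self-agreement fraction A(p) and
returns the smallest lag within 95% of the maximum, which suppresses the
harmonics at 2p, 3p, ...; below A = 0.5 no period is called.
`decomposeArray()` cuts the array into consecutive period-length windows
at the phase that maximizes the number of units matching a provisional
consensus (majority over the phase-0 cut) at the perfect threshold.
A unit is *perfect* iff it has exact unit length and at least 70%
positional identity to the consensus — strict 100% identity would
contradict the within-unit variation that real consensus logos show —
and *imperfect* otherwise. The final consensus is the column-wise
majority over perfect units with ties broken toward the lexicographically
smallest residue, and the position-frequency matrix is computed over the
same units (columns sum to 1). Flanking residues outside complete units
are kept verbatim, so flanks plus units always reconstruct the input.
The perfect/imperfect rule is a declared operationalization; published
perfect-repeat counts for real loci depend on the (unstated) rule used
there, so matching them exactly is not promised.

## Paralog-aware quantification

`uniqueKmerMask()` marks a transcript position as discriminating iff some
k-mer covering it (default k = 31) occurs exactly once in the whole
transcript set. `placeReads()` is a seed-and-verify matcher: each read is
split into `maxMm + 1` disjoint segments (pigeonhole: one segment of a
read with at most `maxMm` mismatches is error-free), segments are looked
up in a k-mer index, and candidates are verified by full-read Hamming
comparison. Reads are *unique* when one transcript attains the minimum
mismatch count, *shared* when several tie, *unassigned* otherwise; the
three classes always partition the input. A minimal SAM importer can
replace the built-in matcher with any external aligner's placements.

`quantifyParalogs()` reports unique counts, RPK over the discriminating
(unique-maskable) length — the full-length denominator is available as an
option — and TPM computed from effective counts,
`tpm_i = 1e6 (c_i / L_i) / sum_j (c_j / L_j)`. Shared reads are
apportioned among their tied transcripts proportionally to unique-read
rates (equal split when all tied genes lack unique reads); the estimator
is deliberately isolated in one function so a different allocation can be
substituted. Multi-sample aggregation reports group means and SDs only;
inferential statistics are out of scope.

## In-silico PCR and restriction discrimination

`findPrimerSites()` scans every offset on both strands, with IUPAC classes
in the primer matching their base sets while template `N`s never match
(assembly gaps must not look like binding sites). By default the primer's
3'-terminal base must match exactly, reflecting polymerase extension
chemistry. `predictAmplicon()` pairs the leftmost forward site with the
nearest downstream minus-strand site within `maxLen`;
`digestSequence()` cuts leftmost-first at non-overlapping IUPAC site
occurrences, and `discriminateFragments()` compares the fragment multiset
against labelled signatures within a 5 bp per-fragment tolerance,
returning "inconclusive" unless exactly one signature matches. The
reverse primer is interpreted as the 5'-to-3' minus-strand sequence
(bench convention), so its reverse complement is searched on the
template.

## Promoter conservation

`extractUpstream()` takes the 1 kb (configurable) upstream of the
transcription start on the gene strand. Cross-species comparison uses
reference-anchored pairwise global alignments rather than a full multiple
alignment: the conclusions only require projecting each species' motif
hits onto reference coordinates, which the per-species column maps
provide, and externally computed alignments can be supplied instead.
`pwmScan()` scores windows with log-odds weights
`log2((f + 0.5 bg) / ((N + 0.5) bg))` (pseudocount 0.5, uniform
background by default) on both strands and reports hits by relative score
(default threshold 0.8 of the achievable range). A reference hit is
*conserved* iff every other species has a same-motif hit whose projected
footprint overlaps at least 50% of the reference footprint — published
phrasing like "completely conserved" defines no coordinate tolerance, so
the 50% rule is this package's declared operationalization. Candidate
cis-regulatory element boundaries derived from accessibility data are
accepted as configuration (`readSignalTrack()` averages a BED-like track
over a region) rather than recomputed.

## The synthetic generator: what it emulates

`buildClusterGenome()` plants, between two random marker genes, a row of
mucin-like genes separated by realistic spacers. Its defaults are the
study conditions of the MUC3 cluster: three genes; the 17-residue unit
`ITTTETTSHSTPSFTSS`; perfect-repeat counts 166 and 549 for the paralog
pair (plus 120 for the third gene, a round mid-scale value); intergenic
gaps of 10,939 bp and 2,469 bp; non-PTS paralog identity 93%; N-terminal
and C-terminal blocks of 728 and 2,020 residues, echoing the roughly
2.2 kb and 6.3 kb coding blocks reported for MUC3-type genes. Each gene
is one open reading frame whose N-term, PTS and C-term blocks are
recorded as role-tagged exons: the generator plants no introns, matching
the scanner's granularity, which calls (start, PTS segment, C-terminal
feature block) rather than modelling 12-exon splice structure. An
in-frame TAA is planted immediately 5' of each ATG, a realistic feature
(an ORF boundary) that also makes the planted start recoverable exactly.
Back-translation uses one fixed codon per amino acid so planted repeats
are nucleotide-perfect; divergence is introduced afterwards by
`mutateSequence()` (per-position substitutions, uniform over the three
alternatives; optional 1 bp indels; stop-creating substitutions in
paralog derivation are reverted to keep frames open). Reads are drawn
with probability proportional to abundance times transcript length,
uniform starts, independent per-base substitution errors, constant
qualities.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: splice sites and introns, VNTR length
polymorphism between individuals, sequencing indels and quality-dependent
errors, paired-end structure, GC or positional coverage bias, and
biological codon usage variation. Results on real loci additionally
depend on assembly correctness of the repeat arrays, which is exactly
what short-read references get wrong.

## Numerical conventions and degenerate inputs

Coordinates are 1-based closed intervals (the Bioconductor convention)
throughout, converted only at external boundaries; GFF3 maps directly.
All "best hit" selections break ties toward the lower start coordinate;
consensus ties go to the lexicographically smallest residue; PFM columns
are validated to sum to 1 within 1e-9; TPM sums to 1e6 within 1e-6
relative, with an all-zero count vector returning all-zero TPM and a
warning rather than dividing by zero. Proteins shorter than the PTS
window give an empty scan (not an error); transcripts shorter than k get
all-FALSE masks with a warning; degenerate arrays with fewer than two
complete units refuse decomposition. Reads must be long enough to hold
`maxMm + 1` disjoint seed segments of at least 8 nt.

Deliberate deviations from the neighbouring conventions: the k-mer mask
accepts any k >= 3 (tiny k values are useful for exhaustively checkable
examples even though production masks use k = 31), and `findOrfs()`
enforces a 30 nt minimum ORF, so toy inputs must embed their ORFs in
longer context.

## Problem sizes

The shipped tests exercise clusters at full study scale (repeat counts
166/549/120, roughly 86 kb of contig), repeat arrays from 2 to 600 units,
and quantification at 50,000 simulated 100 nt reads per abundance ratio;
oracle-equivalence checks run on small randomized instances where
exhaustive enumeration is feasible (5-mer alignments, 120-150 nt
templates, 200-300 reads). These sizes keep the whole suite in the
low minutes on one core while still covering the regimes the methods are
meant for.

## Known limitations

The scanner assumes the provided interval's forward strand carries the
genes (pass the reverse complement otherwise) and does not infer splice
graphs. The period detector reports the smallest strong lag, so a unit
that is itself internally periodic is reported at its fundamental period.
Shared-read apportionment is a simple rate-proportional estimator, not an
EM fit; at paralog identities above roughly 98% with short reads the
unique-read signal vanishes and ratio estimates degrade. Restriction
digestion models complete digestion of a linear template only.
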