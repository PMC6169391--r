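---
title: "Promoter-trap screen analysis with traptag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-trap screen analysis with traptag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traptag)
```

## The screen and its two read-outs

A piggyBac promoter-trap element carries a promoterless fluorescent
reporter ORF behind a 3' splice acceptor (SA). piggyBac integrates at TTAA
tetranucleotides and duplicates the TTAA on both flanks. When the element
lands in an intron of a transcribed gene, on the same strand as the
transcript, the spliceosome can join the host exon's donor to the
element's acceptor and the reporter is expressed as a fusion message. Two
constructs are modelled: a *non-IRES* element whose engineered acceptor AG
abuts the reporter +1 directly, and an *IRES* element in which an
additional, unplanned acceptor sits 15 nt upstream of the reporter +1, so
fusion transcripts retain a 15-nt element tag between the host sequence
and the reporter. That retained tag is what discriminates the constructs
in junction reads.

`traptag` implements the computational side of such a screen:

1. **Synthetic data** (`synthetic_config`, `generate_genome`,
   `plant_insertions`, `simulate_splinkerette`, `simulate_reads`) — a
   generator for genomes, annotation, insertions, splinkerette fragments
   and paired-end reads with a machine-readable truth set.
2. **Junction finding** (`verify_marker_uniqueness`, `scan_read_pairs`,
   `classify_construct`, `locate_junction`, `aggregate_junctions`) — the
   exact-match classification of read pairs into reporter-fusion events.
3. **Insertion annotation** (`map_flank`, `call_feature`,
   `distance_to_orf_start`, `tabulate_insertions`) — DNA-level mapping of
   splinkerette flanks and feature classification.
4. **Acceptor scoring** (`extract_acceptor_windows`,
   `build_acceptor_matrix`, `score_acceptor`) — a position conservation
   matrix over intron-terminal windows.
5. **Screen statistics** (`remobilization_frequency`, `chisq_gof`,
   `intron_position_test`, `distance_summary`).
6. **Orchestration** (`run_config`, `run_pipeline`, `write_report`) — a
   file-based, restartable, seed-reproducible pipeline.

## The exact-match fusion classifier

The classifier assumes the reporter's first 14 nt occur nowhere in the
genome on either strand (`verify_marker_uniqueness` asserts this; the
generator scrubs the genome to guarantee it). Under that assumption and a
zero sequencing-error rate, any read carrying the marker derives from a
fusion transcript, which gives the classifier a provable zero
false-positive guarantee — the test suite confirms sensitivity 1.0 and 0
false positives on synthetic screens.

A pair is accepted iff

* one mate contains an exact match to the reporter anchored at the
  reporter +1 (internal reporter matches are not junction evidence),
  occupying the 3' end of the read once oriented to the reporter strand,
  of at least `min_reporter_match` = 14 nt;
* that reporter segment runs toward the other mate. The published rule is
  stated without an operational definition; we encode it as standard
  forward–reverse fragment geometry: a junction mate matching the fusion
  transcript's sense strand requires the mate's reverse complement to
  match the reporter, and vice versa (`require_orientation`, on by
  default);
* the other mate is an exact reporter substring of at least
  `min_mate_match` = 47 nt;
* the junction mate's non-reporter 5' segment — after excision of a
  *full* 15-nt retained tag, which classifies the pair as IRES — is at
  least `min_genomic_tag` = 15 nt. Reads whose 5' end falls inside the
  retained tag (1–14 tag nt visible) are `unresolved`: the visible suffix
  is consistent with both constructs.

Raising any threshold can only shrink the hit set (a tested invariant),
and the hit set is invariant under reverse-complementing both files and
swapping mates.

Localisation exact-matches the genomic tag against both strands; only a
unique hit is mapped (multi-mapping tags keep their multiplicity and are
excluded from the occurrence table, mirroring the screen's
"unique occurrences" rule). The reported position is the fusion-proximal
end of the tag — the last host-exon base joined to the element acceptor.
When that base is an annotated splice donor, the junction is labelled by
the intron the element inserted into: `5'-UTR` for 5'-UTR introns,
otherwise `Intron i of n`. The acceptor dinucleotide of the element SA
that formed the junction is reported and flagged when non-AG; canonical
acceptors end in AG, and both element acceptor contexts modelled here do
(the published description of a "canonical NGA site" is most plausibly a
transposition of NAG, but the code records the observed dinucleotide
rather than enforcing either reading).

## DNA-level mapping conventions

Splinkerette fragments read element → genome: 30 nt of element terminus,
the TTAA junction, then flanking DNA to the first recognition site of the
digestion enzyme (BstYI RGATCY or BglII AGATCT, matched IUPAC-aware; both
motifs are palindromic). `map_flank` strips the terminal tag (≥ 20 nt
exact), requires a unique genomic match for the remainder, verifies TTAA
at the junction (a non-TTAA junction is flagged, not dropped), and infers
element orientation from which terminus was read and the matched strand.

Feature calls use the second TTAA base as the reference point, 1-based
fully-closed coordinates throughout (BED output converts to 0-based
half-open at the boundary). Intron ordinals count 5'-UTR and coding
introns in a single 5'→3' series per transcript — an `Intron 1 of 4`
label cannot distinguish the two, and one series keeps calls comparable.
Overlapping genes are resolved by reporting orientation first, then
nearer transcription start; the synthetic generator never places
overlapping genes, so this tie-break matters only for real annotation.

Distance to the ORF +1 is the genomic-coordinate distance from the TTAA
start to the first base of the start codon, positive upstream (the
published 183–44882 bp range reads as genomic span). Because intronic
sequence is excised from the message, a spliced (exonic-bases-only)
distance is emitted as a secondary column; genes without an annotated CDS
retain their call with an undefined distance.

## The acceptor conservation matrix

Acceptor windows are the terminal `width` = 21 nt of each annotated
intron in transcript sense (shorter introns are skipped and counted).
Frequencies use a Laplace pseudocount of 1 by default — matrices here are
often trained on dozens, not tens of thousands, of windows; pseudocount 0
is permitted and used by the exactness tests. Information content is
`IC_i = 2 + Σ_b p_i(b) log2 p_i(b)` bits, 0 for uniform usage and 2 for an
invariant position, with `0·log 0 = 0`.

Two scoring modes are supported because "base conservation by position"
does not pin down the arithmetic: the default frequency-weighted mode
`score = Σ_i IC_i · p_i(b_i)` (bounded by
`max_score = Σ_i IC_i · max_b p_i(b)`, attained by the consensus), and a
consensus-indicator mode `Σ_i IC_i · [b_i = consensus_i]` behind a flag.
Sequences shorter than the window (e.g. the 17-nt planned acceptor) are
right-aligned to the acceptor end; uncovered positions contribute 0 — the
padding convention is ours, chosen to anchor the acceptor-proximal
signal. `read_acceptor_matrix` loads an externally supplied per-position
table so a published matrix can be scored under either mode when one is
available; no such table ships with the package, so the package reports
scores only for matrices it builds itself.

## Screen statistics

Remobilization frequency is `100 × events / screened`, rounded half-up to
two decimals (the presentation convention of screen summary tables;
unrounded values are carried alongside), with an exact binomial 95% CI.
The bundled `screen_counts.tsv` reproduces a five-line screen summary —
620 events in 124,378 screened — exactly.

`chisq_gof` wraps Pearson's chi-square (via `stats::chisq.test`) with
df = k − 1 and a low-expected-count warning; the tests verify it against
the closed form `Σ(O−E)²/E` on an exhaustive grid and calibrate its
type-I error at 5% ± 2% over 2000 simulated uniform-reinsertion screens.
The expected proportions for the chromosomal-distribution ("local
hopping") test default to uniform across locations with an
arm-length-proportional option — the null behind a published test of this
kind is rarely stated, so both are exposed as configuration.

`intron_position_test` uses the null that each intron of each hit gene is
equally likely (expected count for ordinal j is `Σ_e [j ≤ n_e]/n_e`). The
category layout is configurable — per-ordinal with a pooled tail
(`pool_beyond = 25` reproduces a df = 24 convention) or first-vs-rest —
because published groupings vary. Median convention: mean of the central
pair for even n (`stats::median`); quartiles are `stats::quantile`
defaults.

## What the generator emulates, and what it does not

Defaults are the study conditions: 4 scaffolds × 200 kb, 24 genes (half
with a 5'-UTR intron), transcription-start-to-ATG distances drawn
uniformly from 183–44882 bp and absorbed almost entirely by the 5'-UTR
intron, coding introns of 80–3000 bp, 20 planted insertions per construct
allocated across feature classes (45% 5'-UTR intron, 30% coding intron,
10% exon, 5% 3'-UTR, 10% intergenic) in both orientations, 4000 50-nt
read pairs with a 5% chimera fraction, and BstYI digestion. Every intron
starts GT, ends AG behind a pyrimidine-rich tract (so the acceptor matrix
is learnable), and contains at least one TTAA. Identical configuration
and seed give byte-identical outputs (the GFF3 carries one run-date
comment line; all content lines are reproducible).

Deliberate simplifications:

* background reads are drawn uniformly from spliced transcripts (polyA
  selection approximated as transcript-only reads); no expression-level
  model, no coverage bias;
* no sequencing-error, indel, PCR-duplicate or polymorphism model by
  default (`error_rate` is configurable but 0, because the classifier is
  exact-match — with errors, sensitivity necessarily degrades and the
  zero-false-positive argument weakens);
* splinkerette adapters are not modelled as sequence; a fragment is
  defined terminus → first recognition site, which is what mapping
  consumes, and each insertion is treated as its own mosquito line so its
  flanking DNA is the unmodified genome (in a real screen each line
  carries a single new insertion);
* opposite-strand and non-intronic insertions never produce chimeric
  reads, encoding the strandedness requirement of the reporter;
* uniform base composition; real genomes' repeat structure and GC skew
  are absent, so multi-mapping flanks are rarer here than in practice.

Passing tests on this generator therefore demonstrate the correctness of
the algorithms under the stated assumptions, not robustness to
sequencing error, repeats or incomplete annotation.

## Numerical and degenerate-input choices

* Coordinates 1-based fully closed everywhere; conversions only at format
  boundaries (BED).
* Exact matching only, no mismatches, in both the junction finder and
  flank mapper — string equality, so no tolerance parameters exist.
* A flank whose genomic portion is shorter than 14 nt is refused
  (unmappable); a flank with no recognition site before the scaffold
  boundary is truncated and flagged, not dropped.
* `chisq_gof` rejects proportion vectors off unit sum by more than 1e-9.
* Matrix scores compare against `max_score` with 1e-12 slack in tests
  (floating-point only; the inequality is exact mathematics).
* Ties in the consensus (equal base frequencies) resolve to the first
  base in A, C, G, T order.

## Problem sizes used by the tests and acceptance script

Module tests run on a 2 × 80 kb genome with 8 genes, 10 insertions and
400 read pairs; the deeper acceptance checks and `scripts/acceptance.R`
use the full default configuration (40 insertions, 4000 pairs, ~800 kb).
The chi-square calibration uses 2000 replicates; power and null
calibration of the intron-position test use 200 replicates of 65 events —
the scale of a real screen's mapped set. These sizes were chosen so the
whole suite exercises every path at screen-realistic scale while staying
comfortably interactive.

## Reproducing a full-data run

On real data the same junction finder applies unchanged: trim reads,
verify the reporter marker's uniqueness against the assembly
(`verify_marker_uniqueness`), then run `scan_read_pairs` on the trimmed
FASTQ pair with the element's reporter ORF and `locate_junction` against
the assembly and its annotation. For the screen this package models, that
means the deposited read set (SRA SRR3195175) against the AsteS1
assembly, expecting the published count of 145 fusion pairs; the download
is several gigabytes and the run is therefore not part of the test suite.
Real-data alignment and splice-junction prediction (Trimmomatic, Tophat2,
Cufflinks) are out of scope — the classifier consumes reads and an
annotation, not alignments.

## Limitations

* One transcript per gene: multi-isoform annotation is reduced to the
  longest transcript by the caller before `call_feature`.
* The published per-position acceptor matrix and per-insertion
  supplementary tables are not redistributed here; the package verifies
  its statistics against a bundled *synthetic* stand-in table whose
  aggregates match the published summaries
  (`inst/extdata/synthetic_insertion_table.tsv`).
* The intron-position null ignores intron length; a length-weighted null
  (longer introns offer more TTAA sites) would be a natural extension.
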