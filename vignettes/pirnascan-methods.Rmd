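---
title: "Methods: from multi-copy lncRNA loci to candidate piRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multi-copy lncRNA loci to candidate piRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnascan)
```

## The analysis problem

Mouse Y-chromosome long arms carry multi-copy repeat loci that transcribe
spliced, polyadenylated noncoding RNAs in testis. Short (10--30 nt)
stretches of these transcripts reappear in the untranslated regions of
autosomal genes whose proteins are deregulated when part of the Y long arm
is deleted, and the same stretches behave like PIWI-interacting RNAs
(piRNAs): ~22--35 nt, derived from the transcripts, often mapping
exclusively to the Y. `pirnascan` implements the computational chain that
connects these observations:

1. **Spliced alignment** of near-identical transcript clones onto a genome,
   reporting every locus copy above an identity threshold (default 97%).
2. **Splice annotation**: canonical GT..AG junction validation and
   classification of isoform differences into the six event classes
   (exon skipping, alternative 5'/3' splice sites, mutually exclusive
   exons, intron retention, complex).
3. **Homology scanning** of UTR sets for short stretches with 0--2
   mismatches, in both orientations, split into exonic versus
   exon-junction-spanning matches.
4. **Exact small-RNA mapping** with per-chromosome copy counts and
   chromosome-exclusivity flags.
5. **Livak 2^--ddCt quantification** of qPCR copy-number assays with an
   unpaired t-test.

A ground-truthed synthetic-data generator emulates every input, so the
entire pipeline is exercised end-to-end without any external downloads.

## The scanner and its definition of a hit

BLAST-style heuristics cannot express a 10-nt match budgeted at one
mismatch, so the scanner defines hits from first principles. A hit is a
pair of equal-length substrings (query versus target, or
reverse-complemented query versus target for the `+/-` orientation) whose
Hamming distance is at most `max_mismatch`, whose length lies within
`[min_len, max_len]`, and which is *maximal*: any 1-nt extension on either
side would break the mismatch budget or the length cap. Two presets
mirror the two search regimes: `deregulated` (10--16 nt, 0--1 mismatch)
and `utrdb` (16--30 nt, 1--2 mismatches).

The implementation seeds on exact `floor(min_len / (max_mismatch + 1))`-mers
-- by the pigeonhole principle every reportable hit contains such an exact
word -- and extends along diagonals with a two-pointer sweep. A brute-force
enumerator of the same definition, `scan_homology_naive()`, is kept
in-tree as the permanent correctness reference; the test suite and the
acceptance script compare the two hit-for-hit on hundreds of random pairs.

A match is *junction-spanning* when its transcript-coordinate interval
covers an exon-exon boundary with at least `junction_min_overhang` nt
(default 1) on each side; such a stretch exists only in the spliced RNA.
Counting "unique homologous stretches" collapses hits in two steps:
overlapping maximal hits of one query/target/orientation sharing at least
half of the shorter query interval are merged (longer, then
fewer-mismatch, then leftmost wins), and survivors are deduplicated by
their query-strand substring. A unique stretch inherits `junction` if any
member hit spans a junction. The dedup key is a genuine choice -- by
sequence, by locus, or by query/target pair would all be defensible; the
by-sequence default reads "unique stretch" most literally.

## The spliced aligner

The transcripts this pipeline targets are >97% identical clones of their
loci, so the aligner deliberately models substitutions only (no exonic
indels). It finds all maximal exact matches of at least `anchor_k` nt
(default 18) between transcript and genome on both strands, chains them
colinearly by dynamic programming (score: summed anchor length minus 2
per intron; ties break towards the smallest genomic span, which prevents
chimeric chains stitched across tandem locus copies), and closes each
inter-anchor gap either within an exon (equal-length gap) or as an intron
of 30--50,000 nt. Each intron boundary may slide up to `boundary_window`
nt (default 10) to reach a canonical GT..AG placement -- canonical first,
then maximal exon identity, then leftmost, making output deterministic.
Chains are extracted iteratively, best first, removing anchors on used
genome intervals, so every locus copy above the identity threshold is
reported; transcripts with no surviving placement are reported as
unplaced rather than dropped.

Identity is defined as matching bases divided by transcript length,
computed against the spliced genome sequence the chain implies.

## Event classification

Isoform differences are decomposed greedily over genomic order:
intron retention first (one chain's exon spans the other's
exon-intron-exon), then boundary shifts on overlapping exon pairs
(donor-side shift = alternative 5' site on `+`, acceptor-side =
alternative 3', both sides = complex), then mutually exclusive exons
(adjacent catalog exons, one per chain, identical flanks), then exon
skipping (internal exon absent with flanks intact). Whatever remains is
reported as one `complex` event -- "complex" is defined here as
*not decomposable into the five elementary classes*, a choice the source
material leaves open. Differences at the outermost transcript ends that do
not move an intron boundary are reported separately as `end_variation`
and excluded from the six classes, because fixed amplification primers pin
the ends of RT-PCR-derived clones; such variation is an artefact of the
assay, not splicing.

## Exact small-RNA mapping

Candidate piRNAs are defined operationally: sequences of 22--35 nt that
place at 100% identity and full coverage. Every occurrence on either
strand counts towards the copy number (overlapping occurrences included,
as placement counts in multi-copy repeats conventionally are); a
palindromic read matching both strands of one site counts that physical
copy once, with the both-strand count reported alongside, since it is
unstated which convention published copy ranges used. Exclusivity to a
named chromosome generalizes "maps only to the Y". Matching uses
`Biostrings::matchPattern()`; the test suite cross-checks placements by
re-extracting and comparing the strand-resolved genomic substrings.

## Livak quantification

Relative copy number / expression is computed exactly as the Livak method
prescribes: per-replicate dCt = Ct(target) - Ct(reference), ddCt =
mean dCt(test) - mean dCt(control), fold change 2^--ddCt, assuming perfect
per-cycle doubling (no efficiency correction -- Pfaffl-style calibration
is out of scope). The companion test is an unpaired t-test on the
replicate dCt values, Welch by default because equal variances between a
wild-type and a deletion strain should not be assumed; Student's pooled
variant is available by flag. When replicate identifiers do not pair
target and reference wells (pooled-cDNA layouts), dCt falls back to group
means with a warning and the test is suppressed. Degenerate inputs follow
explicit conventions: zero variance in both groups with equal means gives
t = 0, p = 1.

## What the synthetic generator emulates -- and what it does not

`synth_config()` describes a complete toy study. Its defaults are the
study conditions the pipeline targets: a main chromosome with 3 locus
copies (substitution rate 0.01 between copies, consistent with >97%
within-family identity) plus a decoy chromosome; six-exon loci with
canonical GT..AG introns and one engineered site per event class;
isoform sets drawn uniformly over the six classes; 4 UTRs of 120 nt with
8 exonic and 2 junction plants spanning both orientations and 0--1
mismatches; 30 transcript-derived reads of 22--35 nt (the published match
range; the generator exposes the range rather than fixing a distribution,
since only ranges are reported for real piRNA sets) plus 5
rejection-sampled decoys verified absent from genome and transcripts; and
two-group Ct tables with a true 3-fold copy-number reduction, noise 0.2
cycles, 4 replicates -- the configuration of a 4-animal-per-group
copy-number assay.

Background composition is uniform over A/C/G/T, which keeps chance-hit
probabilities computable and lets the brute-force oracle arbitrate. The
generator does **not** emulate real repeat structure (LINE/SINE/LTR
content), sequencing error, or expression levels; passing recovery tests
therefore demonstrates algorithmic correctness on clean multi-copy loci,
not robustness to genomic repeat noise.

### Ground-truth identifiability devices

Three deliberate generator constraints make *exact* recovery a
well-defined target; all three are properties of the synthetic truth, not
of the algorithms under test:

* **Plant admissibility.** A planted stretch with fewer mismatches than
  the budget *and* shorter than the length cap is strictly contained in a
  longer maximal hit, so its exact coordinates are unrecoverable by any
  maximal-hit scanner. `plant_spec()` therefore requires
  `length == max_len` or `mismatches == max_mismatch`, and the 1-nt
  flanks of every plant are set to mismatch the corresponding query
  extension.
* **Background sanitation.** Uniform random backgrounds of realistic size
  carry several chance 10-mer hits per dataset. The generator iteratively
  destroys off-truth maximal hits by point mutations outside all planted
  regions, and re-draws a plant whose own content chance-matches other
  transcript positions, until the scanner's unique-stretch table equals
  the planted truth exactly.
* **Anchor-sharp exon termini.** Every exon starts and ends with a
  non-G base, so maximal exact anchors terminate precisely at the GT..AG
  boundaries and recovered chains can be compared to truth
  coordinate-for-coordinate.

## Numerical and interface conventions

Coordinates are 0-based half-open everywhere internally; GFF3 output is
1-based inclusive (via `rtracklayer`), BED6 half-open. All comparisons run
in the DNA alphabet after U -> T normalization; the input alphabet is
remembered and restored on output. `N` never matches anything, including
another `N` -- the conservative choice, which cannot fabricate homology.
Full IUPAC ambiguity codes are intentionally not supported. Sort orders
use byte (radix) collation so outputs are locale-independent; reruns of
the pipeline with one configuration are byte-identical.

## Problem sizes used by the tests and acceptance script

The suite exercises: scanner/oracle equivalence on 200 random pairs of up
to 300 nt in both parameter modes; planted-hit recovery over 100 generator
seeds (3 isoforms, 4 UTRs, 10 plants each); splice recovery over 100 seeds
(7 isoforms); copy-number recovery for 1--10 locus copies; and 500
Monte-Carlo Ct tables at fold 1/3, noise 0.2, n = 4 for the Livak
mean-recovery and Welch-power checks. These sizes give stable,
reproducible statistics while the whole suite stays desk-scale.

## Known limitations

* The aligner assumes substitution-only divergence; indel-bearing or
  trans-spliced transcripts are out of scope.
* Mutually-exclusive-exon detection relies on catalog adjacency of the
  two partners; interleaved alternative variants between the partners
  could mask it.
* Real-data headline counts (single-locus/multi-locus transcript splits,
  SRA piRNA tallies) depend on genome and database versions and on
  unpublished BLAST parameterizations; this package defines its own
  deterministic procedures and makes no concordance guarantee on
  accession data.
* The homology scanner scales as (query x target) diagonals and is meant
  for transcript-versus-UTR-set scans, not genome-scale search.

## A worked example

```{r example, eval = FALSE}
dir <- tempfile("pirnascan")
simulate_dataset(synth_config(seed = 5, n_isoforms = 4), dir)
cfg <- pipeline_config(
  genome = file.path(dir, "genome.fa"),
  transcripts = file.path(dir, "transcripts.fa"),
  utrs = file.path(dir, "utrs.fa"),
  reads = file.path(dir, "reads.fa"),
  ct_table = file.path(dir, "ct_table.tsv"),
  output_dir = file.path(dir, "out"), seed = 5)
summary <- run_pipeline(cfg)
str(summary)
```

The run writes a locus report, a GFF3 of exon chains, junction and event
tables, per-mode hit/unique-stretch/summary tables, read placements with
copy numbers, the Livak result, and `summary.json` collecting the
headline numbers.
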