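---
title: "Discovering bona fide miRNAs from sponge small-RNA libraries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering bona fide miRNAs from sponge small-RNA libraries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongemir)
```

## The problem

MicroRNAs are ~22-nt regulatory RNAs excised by Drosha and Dicer from
stem-loop precursors. In deeply sequenced small-RNA libraries, genuine
miRNAs are recognisable by a conjunction of signals that degradation
products lack: reads pile up at a precise 5' position (Dicer cuts are
exact at the 5' end), the locus folds into a single-stemmed hairpin, the
dominant read block pairs with a partner region on the opposite arm, and
the mature/star duplex carries the hallmark 2-nt 3' overhang on each
strand. `spongemir` implements this reasoning as a tested pipeline for
demosponge small-RNA data — read cleaning, mapping, hairpin discovery with
processing-signature metrics, and cross-species conservation analysis —
together with a first-class simulator that generates genomes with planted
precursors and read libraries with known ground truth.

All user-facing functions take a data frame and return a tibble, so a run
composes with the pipe; fitted runs support `tidy()`, `glance()` and
`autoplot()`.

## Read cleaning

The cascade mirrors standard small-RNA practice: terminal bases with
Phred < 20 are trimmed (end-trimming, not a sliding window — only the read
ends are described as low quality in this protocol), the 3' adapter is
removed at its leftmost exact prefix match with a minimum overlap of 6 nt,
and reads shorter than 16 nt are dropped. Reads are then collapsed to
unique sequences with counts; sequences seen fewer than 5 times per
library are removed as likely sequencing errors. The choice of exact-match
adapter trimming and end-trimming is ours; the thresholds (20, 16 nt, 5
copies) are the conventional ones for this kind of library.

Known non-coding RNA fragments (tRNA, rRNA and similar) are removed with a
self-contained decoy filter: each read is locally aligned (Smith-Waterman;
match +1, mismatch −2, gap open −5, gap extend −2, via
`Biostrings::pairwiseAlignment`) against both strands of a decoy FASTA,
and reads scoring ≥ 18 are excluded and labelled with their best hit. The
default threshold is calibrated so that exact ~20-nt ncRNA fragments are
always removed (an exact 21-mer scores 21) while unrelated random
sequences essentially never reach 18. This emulates the usual
BLASTN-vs-Rfam step (nominal e-value ~1e-5) without requiring a database
download; candidate sets can still be exported as FASTA for an external
BLASTN. The bundled `synthetic_decoys.fa` is a synthetic stand-in decoy
set generated by `synthetic_decoys()`, not real Rfam sequence.

## Mapping

`build_index()` hashes every 12-mer of the genome; `map_read()` seeds on
the read's first and last 12-mers and verifies end-to-end alignments with
at most `max_mm` substitutions (no indels — small-RNA reads are short and
the reference mappers for this task are substitution-only). For reads
shorter than 24 nt the two seeds overlap, and a substitution inside the
overlap breaks both; completeness for one mismatch is restored by also
looking up every single-substitution variant of the first seed. The mapper
is tested for exact agreement with a brute-force scan over all positions
and strands.

Two policy choices follow the field's conventions rather than any stated
parameter: only best-stratum alignments (minimum mismatch count per read)
are reported, and reads hitting more than 5 loci are discarded as
multi-mappers. Best-stratum reporting matters more than it may appear:
when the star arm carries a mutation relative to the reverse complement of
the mature, mature-arm reads would otherwise also map antisense onto the
star locus with one mismatch, creating a mirror read stack on the wrong
strand at every hairpin.

## Hairpin discovery

Aligned reads are grouped by scaffold and strand, and 5' positions at most
3 nt apart are single-linked into stacks; stacks with a summed count ≥ 10
seed candidates. Per stack, two precursor windows are excised — one
assuming the stack is the 5p arm (15 nt upstream, 70 nt downstream of the
read) and one assuming 3p (mirrored). Windows containing a run of ≥ 5 `N`s
are flagged gap-interrupted, excluded from folding, and reported
separately: an assembly gap between the two arms makes a real miRNA
undiscoverable by mapping patterns, and the pipeline surfaces these loci
rather than silently dropping them.

### Folding and validation

`fold_nussinov()` performs base-pair maximisation over nested structures
(Watson-Crick plus GU wobble; `N` never pairs; hairpin loops ≥ 3 nt) with
a deterministic traceback, implemented in C++ and tested for exact
agreement with exhaustive enumeration on short sequences. It stands in for
free-energy folding: for genuine precursors, the long duplex helix
dominates either objective. The difference matters in the flanks — pure
pair counting happily builds junk helices out of random flank sequence
where an energy model would not — and the candidate evaluation is designed
around that:

* **Subwindow retries.** If the full window does not validate, the
  loop-distal flank is tightened stepwise (70 → 55 → 45 → 35 → 28 nt) and
  the first validating subwindow is kept. A real ~60-nt precursor survives
  tightening; junk structures do not reproduce across subwindows.
* **Register repair.** Along a duplex helix the sum `i + partner(i)` is
  constant. When pair maximisation reroutes bases beyond an internal star
  mismatch into nearby loop helices, unpaired duplex ends are re-closed in
  the fold-implied register (Watson-Crick/GU only) — the analogue of an
  energy model absorbing a terminal mismatch as a small internal loop.
* **Restriction and pruning.** The pair set is restricted to the inferred
  precursor extent, and micro-helices internal to one arm or nested inside
  the duplex loop are dropped before the structural checks; they carry no
  information about duplex geometry but would read as extra hairpin loops.

`validate_hairpin()` then accepts a candidate iff the structure has at
most one hairpin loop (no multiloop), the mature lies entirely on one arm
protruding at most 2 nt into the loop, and ≥ 60% of mature bases are
paired into the duplex. The star interval is the register image of the
mature shifted 2 nt toward its own 3' end — the canonical Dicer duplex
geometry.

### Processing signature and score

Per candidate the pipeline computes the 5'-end consistency (fraction of
stack reads at the modal 5' position), the mature/star read partition, and
the 3' overhang of each duplex strand. Overhangs are measured by register
projection — the offset between a strand's 3' end and the register image
of the partner strand's 5' end — using the read-defined star 5' cut when
star reads exist (the Dicer cut leaves a precise stack) and the
fold-implied boundary otherwise. Projection makes the measurement immune
to frayed terminal pairs and to chance stem extension into the loop.

Candidates are scored with a transparent additive surrogate for the usual
probabilistic miRNA scores:

score = 2·pairing_fraction + g(overhang) + 2·consistency + log10(mature_count + 1),

with `g(2) = 1`, `g(1) = g(3) = 0.5`, else 0. Selection keeps candidates
with score ≥ 5, consistency ≥ 0.90 and overhang in [0, 4]; overlapping
candidates at a locus (either strand — an antisense mirror is the same
physical locus) reduce to the highest-scoring one, while identical mature
sequences at distinct loci are all kept, as separate paralogous records.
The original study treats its score threshold as an opaque cut-off at 5;
our formula is auditable, monotone in each component, and configurable,
but it is a surrogate, not a reimplementation. The consistency and
overhang thresholds stand in for selection criteria published only in
supplementary material; they are defaults, not the original authors'
exact values.

## Conservation analysis

`match_known()` compares a mature against a reference set ungapped at
every offset within ±2 nt and reports the best reference at ≤ 2
mismatches — a testable stand-in for BLASTN against a miRNA registry.
`cluster_cross_species()` single-links equal-length matures at Hamming
distance ≤ 1 across two species' sets; conserved sponge miRNA homologs
are length-matched with at most one mismatch between species, so this
parameter-free rule recovers the published cross-species families.
`arm_dominance()` reports which arm carried more reads (ties are reported,
not resolved). `conservation_profile()` computes per-column modal-base
fractions over aligned matures with display bins at >80%, >60% and >40%,
and `tally_exact_matches()` counts reads identical to reference matures,
rendered with a dash for zero in reports.

The package bundles, as a checksummed fixture, the 30 printed bona fide
mature miRNAs of the two Red Sea demosponges (11 from *Stylissa carteri*,
19 from *Xestospongia testudinaria*) with their known-family annotations;
`load_table2_fixture()` returns it as a tibble. On this fixture the
clustering yields exactly 5 families shared between the two species with a
maximum cross-species distance of one base.

## The simulator: what it emulates, and what it does not

`simulate_study()` generates the conditions the discovery stage assumes:

* a multi-scaffold genome (default 5 × 20 kb, GC 0.40 — AT-rich, as
  invertebrate genomes tend to be);
* planted precursors: mature (21–23 nt) + loop (8–15 nt) + star, the star
  being the reverse complement of the paired mature region with 1
  substitution and a 2-nt 3' overhang on each strand, planted on a random
  strand ≥ 150 bp apart; optionally, hairpins whose loop is replaced by a
  ≥ 10-nt `N` run, emulating the assembly-gap artifact that hides a real
  miRNA from mapping-based discovery;
* reads: per-hairpin mature depth ~ lognormal(log 200, 0.5); star and loop
  reads at 10% and 2% of mature; 95% of arm reads start at the true 5' end
  (the rest shifted 1–2 nt, ±1 twice as likely as ±2); 3' ends jitter with
  geometrically decaying weights (a dominant canonical isoform with
  off-by-n minorities, as real mature miRNA stacks show); qualities start
  at Phred 38 and decay toward the 3' end, with a 10% chance of a
  low-quality tail; reads run into the 3' adapter with probability 0.3;
* background: 10,000 reads drawn evenly from decoy ncRNAs, random genome
  slices and random sequence, as degradation products with a dominant
  cleavage point, ragged minority ends and skewed per-product abundances.

Ground truth records every planted interval; the planted read counts are
defined as the number of arm reads that clean back to the exact arm
sequence under the default trimming, which makes them directly comparable
to an exact-match tally of the collapsed library.

The simulator does not model sequencer substitution errors, platform
quality profiles, paired ends, or the two library size ranges of the
original protocol beyond a read-length knob; 5' homogeneity is a single
Bernoulli parameter rather than a learned positional profile. Passing
recovery tests therefore demonstrates that the pipeline's logic is correct
under its stated assumptions — not that it is robust to every artifact of
real sequencing data.

## Reference analyses and problem sizes

The test suite validates the folder against exhaustive enumeration
(200 random sequences ≤ 12 nt), the mapper against a brute-force scan
(100 reads, two 2.5-kb scaffolds, 0–1 mismatches), the decoy filter
against an independently coded Smith-Waterman, and the pipeline against
ground truth on the standard simulated study: 21 planted hairpins (one
N-gap-interrupted) and 10,000 background reads, ~14,000 raw reads in all —
sizes chosen so the full suite runs in about a minute and a half while
still exercising every stage at realistic per-locus depths. On that study
the pipeline recovers ≥ 18 of the 20 recoverable planted matures at their
exact 5' positions, reports a modal 3' overhang of 2 nt, excludes the
gap-split hairpin from calls while listing its locus in the gap report,
and makes zero bona fide calls on a decoy-only genome of the same size.
`scripts/acceptance.R` recomputes all of these from scratch for any seed.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally; GFF3 output converts to
1-based inclusive. Collapsed reads sort by (count desc, sequence asc) and
traceback/tie-breaks are deterministic, so identical configurations
reproduce byte-identical artifacts. Empty inputs (no reads, no hairpins,
no candidates) yield structurally valid empty results — an empty library
warns and still writes a valid empty FASTQ. `sample()`-style size traps
with scalar ranges are avoided throughout the simulator. Stack clustering
breaks modal-start ties leftmost; `arm_dominance()` reports ties; the
fixture loader verifies a checksum and refuses a corrupted bundle.

## Known limitations

Base-pair maximisation plus register repair is a pragmatic substitute for
thermodynamic folding; borderline precursors with long internal loops or
multiple bulges may still be rejected where an energy model would accept
them. There are no shuffling-based significance estimates for hairpin
robustness, no indel-aware alignment, and conservation matching is
ungapped by design. The score is a surrogate: absolute values are not
comparable to probabilistic miRNA-discovery scores, only the ranking and
threshold behaviour within this pipeline.
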