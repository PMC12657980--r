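---
title: "Methods: calling and classifying class-switch-recombination junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and classifying class-switch-recombination junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchjoint)
```

## The analysis problem

Class switch recombination (CSR) joins a DNA double-strand break in the
donor switch region (Sµ) of the immunoglobulin heavy-chain locus to a break
in a downstream acceptor switch region (Sγ1, Sα, ...), deleting the
intervening DNA. Two sequencing assays interrogate the joints:

* **LR-PCR long-read sequencing.** Fixed primers flank the recombining
  interval; every productive deletional joint yields one amplicon whose
  length reports the deletion extent, sequenced as PacBio CCS reads. Joints
  formed after extensive nucleolytic resection fall outside the S regions
  and yield shorter, unproductive amplicons. Inversional joints are not
  amplified at all — the assay, by construction, sees deletional events
  only.
* **HTGTS.** A bait primer 5' of Sµ linearly amplifies junctions between
  the fixed Sµ break and any prey site, capturing both deletional and
  inversional joints genome-wide; the result is a junction table (bait and
  prey coordinate/strand per read), not raw reads.

`switchjoint` implements the junction-level analyses of both assays —
breakpoint calling from split long-read alignments, unique-junction
deduplication with a sequencing-depth floor, S-S versus resected joint
classification, deletional/inversional orientation, repair-signature
calling (microhomology, untemplated insertion, direct joints), V(D)J
Sanger-junction decomposition, and Fisher-exact contrasts of metaphase
aberration counts — together with a seeded simulator that provides ground
truth for validation.

## Coordinate model

All internal coordinates are **0-based half-open on the canonical
(transcriptional) strand** of the locus, with position 0 at the canonical
5' end. Genome-frame coordinates exist only at I/O boundaries
(configuration files, SAM/BAM, TLX tables, BED) and are converted with
`to_canonical()` / `to_genome()`. For a minus-strand locus such as Igh the
conversion is order-reversing, which keeps "downstream in transcription"
monotone increasing everywhere in the package and eliminates strand sign
errors. Configuration files must declare their convention explicitly
(`0-based-half-open` or `1-based-inclusive`); nothing is guessed.

A junction is a coordinate pair: the **donor break** `d` is the half-open
end of the retained donor segment (the last donor base is `d - 1`), and
the **acceptor break** `a` is the first retained acceptor coordinate for
deletional joints, or the half-open end of the inverted acceptor segment
for inversional joints. Consequently the donor break is *inside* its S
region `[s1, s2)` iff `s1 < d <= s2`, while the acceptor break is inside
iff `s1 <= a < s2`. A joint is **resected** when either break is outside
its S region; it is **productive-length** when the coordinate-derived
amplicon length `(d - primer5.start) + insertion + (primer3.end - a)`
exceeds the isotype's productive minimum.

## Microhomology: definition and placement convention

When the two sides of a junction share flanking sequence, the physical
break placement is ambiguous: for a deletional junction `(d, a)` every
`(d + i, a + i)` with `ref[d..d+i) == ref[a..a+i)` (and symmetrically to
the left) produces the same joined molecule. We define the
**microhomology (MH) length as the number of alternative junction
placements**, i.e. the shared flank on either side of the stated break,
capped at `mh_max` (default 20). For inversional junctions the acceptor
template is the reverse complement, and the alternative placements are
`(d + i, a - i)`.

Every junction the package reports is placed **donor-maximal** (ambiguous
bases assigned to the donor side), which makes the placement unique and
makes the reported MH equal the classical "bases immediately 5' of the
junction shared by both templates" definition. The simulator's truth
tables use the same placement, so exact coordinate comparisons between
truth and calls are meaningful. The V(D)J decomposition
(`analyze_vdj_junction()`) breaks placement ties V-maximal — the same
convention seen from the V side.

MH and untemplated insertion are mutually exclusive per junction: any
untemplated base sets MH to 0. This matches the three-way partition used
for repair-signature summaries (direct / MH-bearing / insertion-bearing),
where a **direct joint** has neither MH nor insertion. The package calls
exact-match MH only; whether mismatch-tolerant ("imperfect") MH should
count is left out deliberately, except in the V(D)J decomposition where a
`max_mismatch` knob exists for Sanger data.

## The built-in chained aligner

Synthetic validation must not depend on an external mapper, so
`chain_align_read()` implements a deliberately narrow split-read aligner
for CCS-quality amplicon reads with at most a few segments:

1. **Unique k-mer anchors** (k = 21, both strands). K-mers occurring more
   than once across the two strands of the reference are discarded —
   switch-region repeats make non-unique anchors uninformative. Read
   k-mers are sampled every 13 bp and looked up by exact numeric value.
2. **Diagonal grouping.** Anchors are grouped by strand and (anti)diagonal
   within a 32-bp band, which absorbs small-indel drift. Two guards remove
   *chimeric anchors* — read k-mers spanning the junction that happen to
   match a unique reference k-mer on a nearby diagonal: anchors deviating
   more than 16 bp from the group's median diagonal are dropped, and edge
   anchors whose diagonal jumps more than 5 bp from their neighbor are
   peeled off (true indel drift between adjacent anchors is ±1).
3. **Exact-match end extension.** Block ends are extended while read and
   reference match exactly, stopping at the first mismatch. This is the
   load-bearing numerical choice: switch repeats make donor and acceptor
   context locally similar, so *any* mismatch-tolerant extension
   (score-based or mismatch-fraction-based) can walk across an error-free
   junction by chance matches — and because the overrun is determined by
   the sequence, every read of the event misses identically, defeating
   consensus. Exact extension lands precisely on the donor-maximal
   junction boundary of an error-free read; an isolated CCS error near a
   junction perturbs only that read.
4. **Divergence cap.** Interior block divergence is estimated frame-true
   (mismatches within constant-diagonal anchor runs) and blocks above
   `max_diverg` (default 2%) plus a small cushion are dropped.

Real data enter through `read_alignment_chains()` (SAM/BAM from any
long-read mapper; primary + supplementary records per read, soft/hard
clips consumed to recover read coordinates). Junction coordinates can
shift within MH tracts between mappers; the donor-maximal convention is
applied downstream regardless.

## Breakpoint calling, error handling and the depth floor

`extract_breakpoint()` takes the chain of a read passing the both-ends
region-of-interest filter (`roi_filter()`: at least one block overlapping
the donor-side window and one overlapping the acceptor-side window, each S
region ± `roi_pad`). The donor block is the roi5-overlapping block holding
the read's 5' end (reverse-sequenced chains are flipped first); the
acceptor block is the roi3-overlapping block holding the 3' end. Read
overlap between the blocks is MH ambiguity and is resolved donor-maximal;
a positive read gap is the untemplated-insertion candidate; intermediate
blocks (e.g. intra-Sµ deletions) become secondary junctions; chains with
more than 4 blocks are excluded as complex.

Two mechanisms make per-junction consensus robust at CCS-like error rates
without ever touching error-free calls:

* **Placement re-scoring (gap-free junctions only).** With read and
  reference available, every junction placement `j` in a window around the
  block boundaries is scored by prefix-sum mismatch counts along the donor
  and acceptor diagonals; the donor-maximal minimizer is taken. An
  isolated sequencing error adds a constant to all placements, so the
  minimizer is unchanged; inside an MH tract the cost is flat and the
  maximal placement is canonical. Junctions with a positive gap are
  *never* re-scored: a chance diagonal match could silently convert a real
  untemplated insertion into a junction, deterministically across all
  reads of the event.
* **Jitter rescue at deduplication.** `dedup_and_filter()` groups calls by
  the exact junction key (donor break, acceptor break, orientation) and
  counts supporting reads. Before applying the depth floor, keys with at
  most 2 supporting reads lying within 100 bp (both coordinates, same
  orientation) of a key with at least 5 reads are folded into that key.
  Errors near a junction scatter single reads onto nearby spurious keys;
  this reassigns them to the junction they came from. Genuine junctions
  carry at least the depth floor of reads and are never folded. The
  rescue is off (`rescue_tol = 0`) when `dedup_and_filter()` is called
  directly, preserving plain by-key semantics.

The depth floor itself (default `min_depth = 10` supporting reads per
unique breakpoint pair) counteracts PCR amplification bias: an
over-amplified molecule contributes one junction, not many. Depth counts
pass-ROI reads only, with no base-quality weighting. Junction keys exactly
matching a configured blocklist entry — such as the pre-rearranged
non-productive allele of the CH12F3 cell line — are removed (a coordinate
tolerance exists for mapper jitter on real data, default exact).

Consensus insertion length and sequence are majority votes over the
supporting reads; MH is computed from the reference at the consensus
coordinates. Junctions whose signature rests on a single read are flagged.

## HTGTS classification

`classify_record()` assigns each TLX prey to a region: intra-donor (donor
S ± `roi_pad`), acceptor (acceptor S ± `junction_pad`, default 10 kb — the
"acceptor ± 10 kb" assignment window), a named extra S region, `outside`
(on the locus but unassigned), or `translocation_other` (off the locus).
Orientation is deletional iff the prey strand equals the configured
`del_strand` — a locus property determined by genome strand and bait
design, never inferred. Acceptor joins with prey outside the *unpadded*
acceptor S region are flagged resected, mirroring the within/outside split
of the zoom window. `summarize_htgts()` reports region percentages, the
INV/DEL ratio and resected fraction among acceptor joins, a 1-kb-binned
genome-wide junction histogram, a 250-bp-binned zoom over the acceptor
window, and (when junction context or a reference is available) a repair
signature summary. Whether the INV/DEL ratio should be computed over the
padded or unpadded acceptor window is not settled; the padded window is
the default with `acceptor_window = "proper"` as the alternative.

## Repair-signature summaries

`signature_summary()` reports the percentage of direct joints, of joints
with MH at least `mh_class_min` (default 4 bp — short-MH usage is the
hallmark of Pol θ-mediated end joining), of joints with insertions longer
than 1 bp, and the MH-usage landscape: the fraction of joints at each MH
length 0..`mh_max`. Insertion joints are tallied separately, so the
landscape sums to the direct-plus-MH fraction and the three classes
partition to 100%.

## Fisher's exact contrasts

`fisher_exact_two_sided()` implements the probability-mass two-sided rule:
with both margins fixed, the p-value sums hypergeometric probabilities of
all tables at most as probable as the observed one, with a relative tie
tolerance of 1e-12. `aberration_report()` applies it three ways per
genotype against the reference group — normal vs aberrant (aberrant =
breaks + translocations, disjoint by input schema), break vs others,
translocation vs others. Raw p-values are reported without
multiple-testing correction, matching how such cytogenetic contrasts are
conventionally presented. The test suite checks the implementation against
an exact-rational enumeration oracle for every table with total ≤ 40 and
against `stats::fisher.test()` on spot tables.

## The synthetic-data generator

`make_synthetic_locus()` builds a 60-kb (configurable, ≥ 20 kb) canonical
reference: 5' primer site, donor S region, spacer, acceptor S region,
spacer, 3' primer site. S regions are tandem G-rich pentamer repeats
(units such as GAGCT/GGGGT) with 5% per-base variation — repeat-rich
enough to produce realistic MH tracts and to stress the unique-anchor
aligner, varied enough that junctions remain identifiable. Productive
thresholds are scaled so that every strictly S-S joint is
productive-length and the germline primer-to-primer span exceeds the
productive maximum (the locus cannot amplify unrecombined).

`sample_events()` draws events at the break-coordinate level (no AID
chemistry, transcription or base-excision intermediates are modeled):

* orientation: inversional with probability `p_inversion` (default 0.12);
* resection: with probability `p_resected` (default 0.13) at least one
  break is displaced beyond its S border by a geometric tract of mean
  `resection_mean` (default 500 bp; the tract is capped at `roi_pad` − 100
  so every event stays amplifiable and ROI-detectable). The resected side
  is donor/acceptor/both with weights 0.4/0.4/0.2. Resection *enlarges*
  the deletion — the donor break moves 5' of Sµ, the acceptor break 3' of
  the acceptor region — shortening the amplicon, which is what makes
  resected joints visible as sub-threshold fragments. The geometric shape
  is a modeling choice, not an inference; no empirical resection-length
  distribution is asserted. The default class fractions emulate an
  NHEJ-deficient (Xrcc4-null-like) junction library; a wild-type-like
  setting would use roughly 0.04/0.01.
* insertions: with probability `p_insertion` (default 0.15), 1 to
  `insertion_len_max` (default 10) random bases whose boundary bases are
  constrained not to extend flanking homology — otherwise the insertion
  would be partially templated and the truth coordinates unidentifiable
  from the molecule;
* depth: uniform 10–20 reads per event; CCS errors: independent per-base
  substitutions (default 0.2%) and 1-bp indels (default 0.05%).

Truth coordinates are canonicalized to the donor-maximal placement and
`region_class` is recomputed from the canonical coordinates (the drawn
Bernoulli flags are kept in `*_drawn` columns, which is what the
binomial-fraction property tests check — near an S border the placement
canonicalization can legitimately move a break across the boundary).

`render_lrpcr_reads()` emits amplicons for deletional events only and
returns inversional events as an unamplified list. `render_htgts_table()`
emits one TLX row per event with a junction-context window (default 40 bp
per side). `render_vdj_junctions()` generates germline V/J segments and
junctions with geometric resections (mean 4 bp per side, Sanger-scale),
insertions, and truth recorded at the V-maximal placement. All renderers
are pure functions of (events, reference, parameters): byte-identical
outputs for identical seeds.

**What passing the synthetic validation does and does not show.** The
simulator emulates junction structure, repeat context, class fractions,
depth and CCS-like noise. It does not emulate mapper-specific alignment
artifacts, chimeric library molecules, AID hotspot sequence bias,
non-uniform break position distributions within S regions, PCR length
bias across amplicon sizes, or quality-score structure. Exact recovery on
synthetic data therefore validates the calling, classification and
summary logic — not the upstream mapping choices a real dataset requires.

## Problem sizes and runtime envelope

The validation suite runs entirely on one CPU: the MH-oracle comparison
uses 10,000 random junctions on the 60-kb locus; the Fisher sweep covers
all 135,750 2×2 tables with total ≤ 40; end-to-end deletional recovery
simulates 2,000 events at depth 10–20 (error-free); noise robustness uses
400 events at the default CCS error rates; V(D)J recovery uses 500
junctions. These sizes were chosen so the full suite and the acceptance
script each complete within a few minutes while keeping every fraction
estimate's sampling error well below the tolerances being checked.

## Known limitations

* The internal aligner is contract-limited (≤ 4 segments, ≤ 2% divergence,
  unique anchors); it is not a general mapper and real data should come
  through SAM/BAM.
* Per-key deduplication treats the ≥ 10× rule as per junction key; whether
  the rule should instead apply per coordinate independently is not
  determinable and the per-key reading is implemented.
* 1-bp untemplated insertions at a junction are formally indistinguishable
  (on a single read) from a substitution error adjacent to the junction;
  the package preserves the insertion call and relies on read consensus.
* No liftover between genome builds: configurations must match the build
  of the alignments/tables they describe.
* Means ± SEM across biological replicates are reported only when
  per-experiment rows are provided; pooled-count statistics otherwise.
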