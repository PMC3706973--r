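---
title: "Methods: complementary long padlock probe capture in silico"
author: "clppkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complementary long padlock probe capture in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clppkit)
```

## The method in brief

Long padlock probes (LPPs) are single-stranded DNA probes of roughly 320
bases whose two terminal *capture arms* hybridize to the reference sequence
flanking a target region. Polymerase gap-filling copies the target between
the annealed arms and ligation closes the circle; exonucleases then remove
everything linear, so only circularized, target-carrying molecules survive.
A *complementary* LPP (cLPP) is the double-stranded form: its two strands
act as two independent padlock probes, one against the sense and one against
the antisense strand of the target, which raises the chance that at least
one stable probe–target hybrid forms (particularly for GC-rich targets where
one strand may fail).

`clppkit` implements the complete computational side of this assay:

1. **Probe design** — precursor PCR primers, restriction trimming, panel
   reference files (`design_panel()`).
2. **Capture simulation** on synthetic diploid genomes with planted SNVs,
   indels, and copy-number changes (`generate_genome()`,
   `simulate_capture()`).
3. **Reciprocal paired-end (rPE) library simulation** and FASTQ generation
   (`amplify_rpe()`, `generate_reads()`).
4. **Read processing** — demultiplexing, insert-reference filtering,
   amplicon assignment with orientation-based PCR-group classification,
   coverage/pileup, and a frequency-threshold genotyper
   (`classify_reads()`, `split_groups()`, `compute_coverage()`,
   `call_variants()`).
5. **Copy-number analysis** — scale normalization against a reference
   sample, median combination, lowess smoothing, binned log-ratio SD QC, and
   threshold calls (`scale_normalize()`, `median_combine()`, `call_cnv()`).

## Probe design

Each functional probe is released from a ~350 bp *precursor*, itself the PCR
product of two ~60-mer primers over a common 280 bp spacer backbone. The
forward primer is `[MlyI site][5-nt spacer][upstream arm][backbone anneal]`;
the reverse primer carries the BsaI site, a 1-nt spacer and the
reverse-complemented downstream arm. Digesting the precursor with both
enzymes (MlyI `GAGTC(5/5)`, blunt; BsaI `GGTCTC(1/5)`, 4-nt 5' overhang —
standard catalogue geometries, overridable via `restriction_enzyme()`)
releases the middle fragment: a duplex whose strand termini are exactly the
capture arms.

The spacer lengths are a design choice of this package: the protocol only
requires that digestion leave *target sequence* at each probe end. A 5-nt
spacer puts the MlyI blunt cut precisely at the upstream arm boundary; a
1-nt spacer drops the BsaI overhang 4 nt *inside* the downstream arm, so the
overhang bases belong to the arm terminus and the only trimming cost is a
4-nt 3' recession on one strand (the extension-primer end, which tolerates
it). `make_functional_probe()` hard-fails any design whose post-digestion
termini do not equal the arms.

Other designer parameters, with defaults:

* `arm_len = 25` (mid-range of the feasible 18–28); a greedy ±3-nt length
  search dodges internal restriction sites. Arms must abut the target, so a
  site within 18 nt of the target boundary is undodgeable and the target is
  reported as failed rather than silently mis-designed.
* `max_gap = 550` bases of gap-fill per probe; larger targets are tiled into
  the minimal number of sub-targets with `overlap = 50`.
* Abundance weights mirror the bench practice of adding more probe for
  GC-rich targets: weight 1 up to GC 0.65, rising linearly to 4 at GC 0.80
  (capped above). GC is computed over arms + insert, the sequence that
  actually hybridizes.
* The packaged backbone is a synthetic 280 bp sequence, free of both
  recognition sites, with the two post-capture amplification-primer landing
  sites embedded at its ends; any site-free backbone FASTA may be
  substituted.

## Capture model

Capture is modelled at the event level: no hybridization kinetics, no
temperatures. For each (probe, genome copy, strand) the number of
circularized molecules is Binomial(`depth * weight`, *p*) with

*p* = `p0` · exp(−*k* · max(0, GC − 0.65)),  *k* = ln 2 / 0.15,

i.e. per-strand base efficiency `p0` (default 0.9) halved at GC 0.80. The
exponential form is this package's choice; the assay literature constrains
only the direction (GC-rich targets escape more often). In ssLPP mode a
single strand is active, which is exactly how the duplex advantage is
expressed: the duplex succeeds when either strand does,
`1 − (1 − p₁)(1 − p₂) ≥ max(p₁, p₂)` (`duplex_success_prob()`). Deleted
copies contribute no molecules; failed (linear) species are never emitted,
because the exonuclease cleanup makes them invisible to everything
downstream.

The synthetic genome carries uniform random base composition, planted
non-overlapping SNVs and small indels (het on one random haplotype), an
optional per-contig ploidy (a male X is ploidy 1), and copy-number segments
(a trisomy is one extra copy of a contig on one haplotype; a focal deletion
is copy 0 over listed exons). Truth tables are exact and exactly
reproducible under a fixed seed.

## Reciprocal paired-end libraries

Standard paired-end sequencing of an amplicon always reads the same end
with the same mate, so read-quality asymmetry (mate 2 decays faster)
systematically hits the same target bases. The rPE trick is two separate
post-capture PCRs whose amplification primers swap the adaptor ends of the
template; pooling both PCRs yields **four** distinct (mate × strand) read
species per captured molecule instead of two, and the longest insert fully
covered by at least one read becomes `r1_len + max(r1_len, r2_len)` instead
of `r1_len + r2_len`.

One geometry convention matters. The assay's own coverage arithmetic counts
insert coverage as read length per side (151-base PE reads → 300 bp maximum
insert; 175/150 rPE → 350 bp). That arithmetic holds only if a read's first
base is the first captured base, so the simulator starts mate 1 at the first
template base past the amplification-site primer and mate 2 symmetrically
from the far junction, with reads running into the opposite adaptor when
they are longer than the interior. `max_covered_insert()` measures the
quantity directly: it generates the pooled reads from swept insert lengths,
maps each read back by exact matching, and reports the largest fully covered
length — 350 for 175/150 rPE, 325 for the same lengths in standard PE mode.

Base qualities start at Q38 and decay linearly, mate 2 falling 1.5× faster
than mate 1 — a deliberately simple stand-in for the observed PE imbalance;
the quality *model* is not an accuracy surface, only the filter semantics
are. PCR substitution errors are applied independently per PCR (default 0;
tests exercise 2 × 10⁻³ as a stress case). Read names carry the sample
index (`idx=`) and, unless `blind = TRUE`, a parseable ground-truth suffix
(capture id, PCR label) that the test suite uses as an oracle.

## Read processing

The processing pipeline mirrors an alignment-based triage:

1. **Demultiplexing** by 6-base sample index, unique within `max_mismatch`
   (default 0); ambiguous or non-matching pairs go to `undetermined`.
2. **Stage 1 filter** against the *insert-only* reference (amplicons minus
   probe landing sites): a k-mer–seeded candidate search (k = 15, every 10
   bases) followed by banded local alignment (match +1, mismatch −2) scored
   with a Karlin–Altschul-style E-value, E = K·m·n·e^(−λS) with λ = 1.28,
   K = 0.46. Reads whose best E-value exceeds 10⁻⁶ — including reads made
   only of linkers/adaptors, which never seed a candidate — are discarded.
3. **Stage 2 assignment** against the full amplicon reference: best-scoring
   matched segment kept (adaptor bases trimmed away by the local
   alignment); equal-score ties between amplicons broken by a seeded
   uniform draw and demoted to mapping score 0; a second compatible segment
   on the same amplicon extends the kept interval to the spanning region.
   Unique best hits get mapping score 60.
4. **PCR-group classification** purely from (mate, match strand): mate 1
   sense and mate 2 antisense are PCR-A; the reverse pair is PCR-B. Group
   splitting writes the four FASTQ streams; a read whose mate was discarded
   is kept as a singleton with the first three nucleotides of the original
   mate as a placeholder, so pairing structure survives downstream tools.
5. **Coverage and pileup** re-anchor each assigned read on its amplicon.
   Two filters are deliberately separated: bases below quality 20 are
   masked from depth and allele counts but do *not* remove the read from
   the per-amplicon count *A*; reads below mapping score 30 are removed
   entirely. *A* counts reads whose matched-interval midpoint lies in the
   amplicon insert — "aligned within" needs a tie-break rule for partial
   overlap, and the midpoint rule is deterministic and unambiguous. For
   tiled amplicons the tiling overlap columns are excluded from both depth
   and counting, so no genomic base is double-counted.
6. **Genotyping** is a frequency-threshold caller: depth ≥ 20, alternate
   fraction ≥ 0.85 → hom; within [0.25, 0.75] → het; otherwise no call.
   Indels are called from alignment gap tallies, limited to simple events
   fully contained in single reads. This replaces a full realigner/
   genotyper stack by design: on amplicon panels every read is anchored to
   a short known reference, so global realignment adds nothing at this
   scale.

## Copy-number analysis

The raw statistic is the per-amplicon, per-PCR read count *A*. For a test
sample against a reference sample within the same PCR:

ratio_i = (A_test,i / T_test) / (A_ref,i / T_ref),

with *T* the total filtered count for that sample × PCR — "scale
normalization" is read here as library-size scaling, the simplest
interpretation consistent with dividing by a reference sample. Amplicons
with zero reference count are flagged `NA` and excluded downstream. Ratios
are median-combined across PCRs and repeats, then thresholded: loss ≤ 0.7,
gain ≥ 1.35 — midway between integer copy states at diploid baseline — with
runs of ≥ 2 amplicons merged into focal calls and a per-contig summary for
whole-chromosome events. An optional per-contig ploidy table divides out
expected baselines (male X vs female reference = 0.5) before thresholding.
Lowess smoothing (span 0.3, `stats::lowess`) is generated for plots only;
calls always use unsmoothed combined ratios, matching the stated use of
smoothing for visualization. Log ratios are base 2 throughout, and the
binned SD diagnostic sorts amplicons by reference coverage into bins of 200
before taking the SD of log₂ ratios per bin.

A composition caveat that the test suite makes explicit: library-size
scaling is only unbiased when aberrant regions are a small fraction of the
panel. A trisomic chromosome measured against a panel where half the
amplicons are deleted drags *T* and inflates ratios to ~2.0; with a
genome-wide panel (aberrant fraction ≲ 15%) the trisomy lands at the
expected ~3/2 within ±0.1. The recovery tests therefore use panels
dominated by neutral autosomal amplicons and evaluate the aneuploidy sample
and the hemizygous-deletion male as separate subjects against the same
diploid reference — which is also how the real samples were analysed.

## What the simulator does and does not emulate

It emulates: diploid (and aneuploid/hemizygous) copy structure with exact
truth tables; strand-resolved capture with GC-dependent efficiency and
probe-abundance weighting; adaptor-swap template structure, read-length and
quality asymmetry, PCR duplicates and substitution errors; index-based
sample pooling.

It does not emulate: off-target capture (so in-model specificity is 100%
and the metric only validates bookkeeping), chimeric circles, sequencing
indel errors, base-composition bias of real genomes, or flow-cell
artifacts. Passing tests therefore demonstrate the correctness of the
pipeline's logic and the recoverability of planted signal under the stated
noise model — not field performance on real libraries, whose headline
percentages depend on wet-lab factors outside this model.

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open internally; BED output is 0-based,
  VCF 1-based.
* `N` never matches a restriction recognition site (conservative
  digestion); digestion cuts that would fall outside the duplex are skipped
  with a warning record rather than clipped.
* Tie-breaks (equal alignment scores) use the caller-supplied seed; across
  seeds a two-way tie splits 50/50.
* `lowess_smooth()` passes through inputs with fewer than 3 points, with a
  warning; `scale_normalize()` errors on disjoint amplicon sets and flags
  zero-reference amplicons instead of dividing by zero.
* Problem sizes in the shipped tests — panels of 2–100 targets on contigs
  of 6–130 kb, read depths giving ~100–500× per insert, five simulation
  seeds for the copy-number recovery properties — were chosen as the
  smallest sizes at which the binomial/Poisson tolerances in the
  assertions are comfortably non-flaky.

## Known limitations

Arm selection cannot shift arms away from the target boundary, so a
recognition site within 18 nt of the boundary fails the target (reported in
the design report). The E-value calibration uses fixed ungapped constants
rather than fitted gapped parameters — adequate for a pass/fail filter at
10⁻⁶, not for fine E-value comparisons. The genotyper has no base-quality
recalibration and no multi-allelic model. Copy-number segmentation is
run-merging only; no HMM or circular binary segmentation.
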