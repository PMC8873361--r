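---
title: "Detecting miRNA mutation and editing sites: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting miRNA mutation and editing sites: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editome)
```

## The problem

Mature miRNAs frequently deviate from their genomic template: adenosines
are deaminated to inosine (read as G by sequencers; A-to-I editing by
ADAR enzymes), cytidines to uridine (C-to-U, APOBEC family), untemplated
adenosines or uridines are appended to the 3' end, and occasionally a
base appears upstream of the annotated 5' end, which shifts the seed
register and can rewire the miRNA's entire target repertoire.  Calling
such mutation/editing (M/E) sites from small RNA-seq data is delicate
because the signal — a systematic per-position deviation from the
hairpin template — must be separated from sequencing error, from SNPs,
and from reads that in truth originate at a different genomic locus.

`editome` implements this analysis as a tested pipeline: per-sample site
calling, cohort aggregation and annotation, differential editing between
groups, and target-set comparison for edited mature forms, together with
a synthetic-data generator that produces every input with known ground
truth.

## Per-sample model

**Read filtering.**  A read is kept when its first 25 bases (all bases
for shorter reads) each have Phred quality ≥ 30 and its length strictly
exceeds 18 nt.  The leading-span reading of the quality rule is a design
choice: small-RNA 3' ends carry adapter remnants and untemplated tails,
so a per-base rule over the read head is both stricter where it matters
and robust where it does not.  Identical surviving sequences are
collapsed with summed counts.

**Alignment.**  Collapsed reads are placed on the hairpins by a
seed-and-extend matcher specialised for ≤ 200-nt templates.  A placement
may contain at most one internal substitution, one single-base indel, an
untemplated 3' tail of up to 3 nt and up to 2 extra 5' bases; the best
placements (fewest internal edits, then most templated bases) are kept,
with deterministic tie-breaking (lowest precursor id, then offset, then
leftmost gap).  The caps bound ambiguity: observed tails are
overwhelmingly single-base, and a longer allowance would let alignment
ambiguity masquerade as editing.  External aligner binaries are
deliberately not invoked — the equivalent contract (report-all genomic
hits at ≤ 1 mismatch; best hairpin placements) is implemented natively
so that results do not depend on tools outside the package.

**Cross-mapping correction.**  Reads mapping to several genomic loci are
not discarded; their weight is divided among loci proportionally to each
locus's *perfect-match expression* (the weighted count of zero-mismatch
reads there).  Because expression depends on the weights, the allocation
is iterated to a fixed point (tolerance 1e-6, at most 50 sweeps, both
fixed for determinism).  Weights of one read always sum to 1; loci whose
perfect expression is all zero fall back to uniform weights.

**Site calling.**  For every covered position the pipeline tallies
templated coverage plus *adjacency* mass — reads whose templated end is
immediately before (or start immediately after) the position.  Adjacency
is what gives untemplated 3'-tail and 5'-addition sites a meaningful
denominator: the editing level of a 3'-A site is the tailed fraction of
reads that *could* have carried the tail, i.e. reads ending at the arm
end.  Editing level = deviant weighted mass / coverage weight.

**Significance.**  Deviant support is tested against a one-sided
binomial sequencing-error model: `P[X ≥ k | n, p_err]` with
`p_err = 1e-3`, the error rate implied by the Q30 quality floor — the
error model and the filtering threshold are deliberately one number.
p-values are Benjamini–Hochberg adjusted per sample over all candidate
sites.  A site is *significant* when its level is ≥ 5%, at least 10
reads support it, and the adjusted p-value is < 0.05.  Support counts
use raw reads while levels use weights: weights handle multi-mapping,
integer counts guard against phantom fractional support.

**Classification.**  Decision order: positions past a mature arm's 3'
end (or tail operations) are 3'-A / 3'-U / 3'-Other by the added base;
5'-additions and substitutions within 2 nt upstream of an arm start are
5'-editing; central substitutions are A-to-I (A→g), C-to-U (C→u) or
Other; central indels are indel.  Sites outside any arm neighbourhood
are excluded from reports.

## Cohort stage

Sites significant in at least one sample form the cohort matrix; every
cell keeps that sample's level (0 when covered but undetected) because
the differential tests need dense group vectors.  Sites must be
significant in at least `ceiling(0.07 × n_samples)` samples to survive
the prevalence filter (8 of 111 in the emulated study design), which
suppresses scattered error artefacts.

**SNPs.**  A site is relabelled SNP when its genomic position and both
alleles match a SNP record (alleles reverse-complemented for minus-
strand precursors, since SNP tables are plus-strand) and its level
reaches 100% in at least one sample.  "100%" is implemented as
≥ 99.5%: with per-base error at 1e-3 and coverage ~1000, a truly
homozygous variant's measured level is ~0.999, and an exact test would
reject most genuine SNPs, while genuine editing at levels ≤ 0.5 cannot
reach 99.5% at such coverage.

**Pseudo sites.**  An apparent site whose deviant reads are, more likely
than not, templated products of another locus: flagged when > 50% of the
deviant read mass has a perfect (zero-mismatch) genomic hit outside the
precursor's own span.  This operationalisation is this package's own;
the threshold is strict (exactly 50% does not flag).

**Conservation.**  An editing site is conserved when another species'
table lists a site of the same type at the same mature-miRNA position
(offset from the arm's 5' start).

## Differential editing

Editing levels between two groups are compared per site with a
two-sided Mann–Whitney U test.  For combined sample sizes ≤ 12 the
p-value is computed by complete enumeration of group assignments using
midranks — exact with or without ties; for larger samples the normal
approximation with tie-corrected variance and continuity correction is
used.  (The enumeration path covers tied data too, rather than falling
back to the approximation, because small cohort-level vectors are
heavily tied at 0 and the exact conditional test is both available and
cheap; the continuity-corrected approximation deviates from the exact
distribution by up to ~0.011 at n = 8 + 8.)  Cells where a site was
callable (coverage ≥ 10 reads) but undetected enter as level 0;
uncallable cells are excluded — this keeps prevalence-passing sites at
full group size without inventing observations.  BH correction is
applied across tested sites, and both tiers (raw p < 0.05 and
FDR < 0.05) are reported with direction by median difference (rank-sum
side on ties).

## Retargeting (MiCPAR-lite)

Edited mature variants are constructed from their sites (a 5'-editing
site prepends its base and shifts the seed; central substitutions
replace — A-to-I renders as G; 3' tails append).  Target evidence
follows PAR-CLIP logic: reads are aligned to transcripts with at most
one non-T-to-C mismatch (T-to-C conversions, the crosslink signature,
are free), overlapping reads merge into clusters, and only clusters
with at least one converted read are searched.  Within a cluster ± 10 nt
(crosslinks sit near, not on, seed matches) the reverse complement of
the seed is sought as 8mer (mature positions 1–8), 7mer (2–8) or 6mer
(2–7).  Each site gets a transparent score `p_s`: the probability of a
match at least that long arising in the window under an i.i.d.
background with the window's own base frequencies — anti-monotone in
match length by construction.  The full scoring of the original
PAR-CLIP target algorithm is richer; this package implements the
documented evidence rules plus this transparent score, and reports call
it MiCPAR-lite.  Gene sets are compared after collapsing to gene level;
newly gained targets are prioritised by removing duplicates and
non-coding genes and requiring ≥ 10 PAR-CLIP reads in the best cluster.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not the full complexity of real libraries:

* hairpins of 80 nt with two 22-nt arms, embedded in a synthetic genome
  with random spacers;
* per-arm depth 1000 (a typical well-expressed arm) with 0–1 nt
  templated trimming jitter at each end, so end-variation detection is
  tested against realistic end noise;
* planted events of every category at per-group true levels; 3' tails
  attach to reads ending exactly at the arm end and 5' additions to
  reads starting exactly at the arm start, matching how the caller
  measures their levels;
* i.i.d. per-base errors at 1e-3 with a constant Q30 quality string, so
  the caller's error model matches the generator by construction;
* decoy loci: exact arm copies (multi-mapping/cross-mapping test beds)
  and edited-arm copies (pseudo-site test beds);
* homozygous SNPs at level 1.0 with matching SNP-table rows;
* PAR-CLIP transcripts with planted reverse-complement seed sites,
  scrubbed of accidental seed matches outside planted windows, and reads
  converting each covered template T to C at a configurable rate.

The default two-group design mirrors a 28 vs 38 prefrontal-cortex
cohort.  What passing tests show is that the pipeline recovers what it
models — planted levels, categories, group differences — under its own
error model; they do not certify behaviour under adapter contamination,
position-dependent error profiles, expression-dependent biases or
incomplete annotations, none of which the generator emulates.

## Numerical choices and degenerate inputs

* Percentages are rounded half away from zero (1 decimal in category
  summaries, 2 in differential summaries).
* Binomial tests run on rounded integer masses; `k > n` is a contract
  violation, not silently clamped.
* `ceiling(fraction × n)` for prevalence uses a 1e-9 slack so exact
  products are not pushed up by floating-point representation.
* Empty inputs (no reads, no sites, empty species tables) yield empty
  outputs, not errors; genuinely contradictory inputs (annotation
  mismatches, invalid intervals, k > n) are hard errors naming the
  offender.
* Positions reached only by multi-base tails have no adjacency mass;
  the deviant mass itself then floors the denominator, and the 10-read
  support rule keeps such sites from surfacing spuriously.

## Problem sizes used in validation

The shipped checks simulate single-hairpin samples at coverage 1000 for
level recovery (100 seeds per level), 200 null samples for type-I
control, twenty 20 vs 20 cohorts for differential power, a ten-hairpin
fixture for classification, and 100 transcripts for the seed-shift
property — sizes chosen so the whole suite validates every module's
statistical behaviour in a few minutes on one core.

## Known limitations

* The 1-substitution alignment cap drops reads that carry both an edit
  and a sequencing error, which biases estimated levels slightly
  downward (about −0.005 at level 0.5 with coverage 1000 and error rate
  1e-3).  At high editing levels the estimator's coverage of the exact
  binomial 99% interval is therefore ~97–99% rather than ≥ 99%.
* Insertions are aligned and classified but never planted by the
  generator (real data shows deletions almost exclusively).
* The aligner is not splice-aware and assumes adapter-free reads.
* Cross-species conservation requires pre-matched miRNA names; no
  ortholog mapping is attempted.
* `p_s` is a background-probability score, not a thermodynamic or
  conservation-aware target score.
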