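---
title: "Pseudogene-masked variant calling with long-read rescue: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudogene-masked variant calling with long-read rescue: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paramask)
```

## The problem

Some disease genes are shadowed by a pseudogene so similar that short reads
cannot be placed uniquely. The motivating geometry is a gene whose internal
exon block (exons 6–84 of 86 in the motivating case) is duplicated into a
pseudogene at >98% identity, leaving only the first five and last two exons
unique. Reads from the duplicated block map ambiguously; many diagnostic
panels simply exclude such genes.

One practical strategy is to **hard-mask the pseudogene** in the reference
(replace it with `N`), so that reads from *all four* homologous copies — two
gene haplotypes and two pseudogene haplotypes — align onto the gene. Nothing
is lost to mismapping, but every downstream quantity is reshaped:

* a heterozygous gene variant appears in **1/4** of reads instead of 1/2;
* a homozygous gene variant appears in **2/4** instead of all;
* a heterozygous exon deletion removes **1/4** of the depth (ratio 0.75),
  far from the 0.5 a diploid CNV caller is built to see — which is exactly
  why such deletions are missed by standard pipelines;
* short reads cannot say *which* locus carries a variant, except through
  paralogous sequence variants (PSVs), the fixed positions where gene and
  pseudogene differ.

Long reads resolve the ambiguity: each read spans many PSVs, so it can be
binned to its locus of origin, after which diploid genotyping, phasing and
structural-variant detection work per locus. This package re-enacts the
whole strategy at desk scale: a synthetic gene/pseudogene pair, a read
simulator, a small seed-and-extend mapper, the four-copy genotyper and CNV
caller, the PSV-binning long-read stage, consequence annotation and cohort
accounting.

## The four-copy allele-balance model

At a homology position, reads carrying the alternate allele arise from `a`
of the four collapsed copies, so the expected alt fraction is `a/4`,
attenuated by sequencing error `eps`:

```
p_h = theta_h (1 - eps) + (1 - theta_h) eps / 3,
theta in {0, 1/4, 1/2, 3/4, 1}.
```

`genotype_site()` evaluates a binomial likelihood over this grid (the
ordinary `{0, 1/2, 1}` grid in unique regions) with a configurable prior:
flat over the three common hypotheses, 0.01 for the rare `3/4` and `1`
states (homozygous in one locus *and* carried in the other), which are kept
so the model is complete. A site whose top two log-likelihoods are within
**2 nats** is flagged ambiguous and is exactly the kind of site the
long-read stage is for. The hypothesis `theta = 1/2` is deliberately labelled
`hom_one_locus_or_het_both`: short reads cannot distinguish a homozygous
gene variant from one heterozygous in both loci — the long-read stage can.

Locus assignment from short reads (`assign_locus()`) is attempted only
through PSV co-observation: each alt-carrying read that also overlaps a PSV
votes `+log((1-q)/q)` for the gene base and the negative for the pseudo
base. Sites with fewer than 3 informative reads or |log-odds| < 3 nats stay
ambiguous; in unique regions the gene is the only possible carrier.

Candidate discovery (`scan_candidates()`) takes pileup columns whose
strongest non-reference, non-PSV signal reaches an alt fraction of 0.12 at
depth ≥ 20. The 0.12 operating point catches `theta = 1/4` sites with
analytic sensitivity above 99% at 100× (binomial tail); PSV columns are
expected at pseudo-base fraction ~0.5 under masking and are suppressed
unless they depart from 0.5 by more than 0.2 — such departures are
copy-number signals and are consumed by the CNV caller instead. Deletion
support from CIGAR `D` ops longer than 50 bp is excluded here, so
exon-scale deletion junctions are not mistaken for small indels.

## Read-depth copy number on the four-copy grid

`depth_profile()` computes mean sequenced depth per exon (CIGAR `M` bases
only) and normalises within-sample against the median of unique-region
control exons: with control median `m` (two copies), the per-copy depth is
`m/2` and each exon's ratio is `depth / (baseline_copies * m/2)`, sitting at
1.0 in both region types for an unaffected sample. Within-sample
normalisation avoids needing a reference cohort.

`call_combined_cn()` scores each exon's effective fragment count against
Poisson expectations on the combined-copy grid `cn = 0..6` (expected ratio
`cn/4` in homology, `cn/2` unique). Two calibration choices matter:

* **Fragment units.** The two mates of a read pair cover the locus as one
  sampling event, so effective counts use two read lengths of depth per
  unit. Without this the likelihood is overconfident by about a factor two.
* **Thresholds.** `phi` (default 1.3) divides the log-likelihood to absorb
  mild capture-style overdispersion; adjacent exons with the same
  non-baseline MAP copy number merge when the joint gain exceeds 2 nats;
  an event is reported when its gain over baseline exceeds `min_gain = 3`
  nats (about a one-sided z of 2.4 on calibrated units), which holds the
  per-exon false-positive rate of a null sample below 1% while a true
  `cn = 3` exon at 100× carries a gain far above it.

The same function exposes `mode = "diploid"`: the conventional
`{0, 1/2, 1}` grid, included deliberately. On identical data a 0.75-ratio
exon is nearer 1.0 than 0.5, so the diploid grid rarely reaches the
reporting threshold — the missed-CNV mechanism made reproducible. The
acceptance suite measures both detectors over 200 simulated replicates.

When combined copy number drops to 3, `attribute_deleted_locus()` asks
*which* locus lost its copy: PSV pseudo-base fractions inside the event
shift from 2/4 to **2/3** (gene copy lost) or **1/3** (pseudogene copy
lost); a binomial log-likelihood ratio of 3 nats decides, and events with
no informative PSVs stay ambiguous and are escalated to long reads.

## The long-read rescue stage

`bin_reads()` votes every PSV a read spans. With weight
`w = log((1-q)/q)` per concordant base and an assignment threshold of 3
nats, a read with five informative PSVs is misassigned only if at least
four of them are miscalled (three flips leave |log-odds| = `w` < 3, i.e.
unassigned); at `q = 0.05` that probability is about `3e-5`. PSV votes
accumulate over the whole read and take priority; reads the PSVs leave
ambiguous are assigned directly when they align over ≥ 30 bases of
unique gene sequence (gene) or of pseudogene flanking sequence (pseudo).

`regenotype_per_locus()` undoes the collapse: restricted to gene-binned
reads, a truly homozygous variant shows ~100% alt instead of the ~50% of
the masked pileup, confirming homozygosity without parental samples.
Genotyping is the ordinary diploid binomial over `theta in {0, 1/2, 1}`.

`detect_deletions()` collects `D` ops ≥ 200 bp (and gaps between colinear
split alignments of one read), clusters breakpoints by chain linkage at
±20 bp, and reports median breakpoints, length, read support (≥ 3) and the
majority bin of supporting reads.

`phase_variants()` is a deliberately simple read-backed phaser: sites in
coordinate order, consecutive sites linked when at least 5 shared
informative reads agree on an orientation (alt alleles co-occurring = cis,
alternating = trans) with a vote margin of at least 0.8; the block breaks
otherwise. A margin failure therefore produces an *unphased* pair, never a
wrongly phased one. At 30× with 2–5% read error the margin rule has a
small per-link chance (well under 1%) of a conservative break driven by
irreducible base errors, so occasional single-run breaks are expected
behaviour, not a defect; the tests assert near-complete recovery across
replicates and zero wrong orientations.

### Allele extraction under noisy alignment

A subtlety that dominates long-read accuracy in practice: the variant
itself destroys the seed anchors that overlap it, so every alt-carrying
read has an anchor-free window around the site; a 1-bp indel error falling
in that window shifts the alignment frame locally and the raw pileup base
at the column becomes a neighbouring base. `site_allele_calls()` therefore
re-extracts each read's segment across the site and scores it against two
candidate windows (reference allele vs alternate allele at the centre)
with a small banded semi-global alignment; the better-scoring window wins
and ties are uninformative. Phasing and per-locus re-genotyping use these
realigned calls whenever the reference sequence is supplied.

## The synthetic data generator

`make_paralog_reference()` builds uniform-random DNA with a regular
exon/intron layout, copies the duplicated block (exons plus intervening
introns) into a pseudogene locus and plants PSVs uniformly at density
`1 - identity` (default 0.98, matching the >98% identity of the motivating
duplication), with three deliberate regularities:

* at least one PSV per duplicated exon, so every exon is locus-resolvable
  (mirroring the reliance on known sequence differences for assay design);
* no PSVs within ~12 bp of the block edges, so the duplication boundary is
  anchored by contiguous identical sequence, as real breakpoints are;
* both loci carry `flank_len` (default 800 bp) of unique flanking sequence,
  emulating the surrounding genomic context. Flanks keep fragment sampling
  uniform across the loci — without them, depth ramps at the artificial
  molecule ends distort the depth ratios the CNV caller reads — and, like
  the real flanking chromosome, they are *not* masked.

`simulate_short_reads()` draws fragments uniformly at `coverage/4` fold per
haplotype (so the collapsed homology depth totals `coverage`, and unique
regions sit near `coverage/2` — itself a signature of masking), fragment
lengths uniform on 150–300 bp as in a capture-based paired-end library,
i.i.d. substitution errors, constant Q30. `simulate_long_reads()` draws
log-normal lengths (default mean 3 kb), substitution plus 1-bp indel
errors, constant Q12. Constant qualities are intentional: all callers use
explicit error-rate parameters rather than per-base qualities. Truth origin
is carried in the read tables for scoring only and is never written to
FASTQ nor visible to any caller.

What the generator does **not** emulate: GC and PCR biases, strand effects,
quality-score error profiles, repeat structure beyond the duplication
itself, multi-copy (>2) paralog families, or indel divergence between the
paralogs (supported by the map structure, off by default since the
motivating gene pair is substitution-dominated). Passing tests therefore
demonstrate the *logic* of the combined strategy under clean statistical
conditions, not robustness to every artefact of real capture or nanopore
data.

## The built-in mapper

A dependency-free seed-and-extend mapper keeps the pipeline testable at
desk scale (externally produced SAM is also accepted). Exact k-mer anchors
(default `k = 13`, stride `k`; k-mers containing `N` are never indexed, so
masked territory cannot seed an alignment) are clustered by diagonal with
tolerance `band`, clusters are chained greedily left-to-right, and
diagonal shifts become CIGAR I/D ops. Details that matter:

* **Junction refinement.** Op placement between anchors is only
  anchor-resolution accurate; every I/D junction is rescanned over shifts
  (window 15 bp, 60 bp for deletions ≥ 30 bp) and placed at the
  best-matching split, leftmost on ties. This gives error-free deletion
  breakpoints exact to within junction micro-homology.
* **Masked-gap splitting.** A chain whose deletion would span masked `N`
  sequence joins two placements that cannot belong to one locus (a
  pseudogene read continuing into its flank); the side with more aligned
  bases is kept, the rest soft-clipped.
* **Guarded extension.** Unanchored read ends are extended only while the
  extension stays locally homologous (at most 3 mismatches in any 8-base
  window) and never end on a mismatch — unrelated sequence beyond a
  homology boundary (~75% mismatch) stops within a base or two, while runs
  of nearby PSVs pass, so chance-matching bases cannot inject false
  alleles into pileups and paralog-dense read ends are not over-clipped.
  The ungapped fast path (most short reads) validates its terminal 12
  bases for the same reason.
* Equal-scoring placements resolve to the leftmost position; unmappable
  reads are reported as unaligned, never dropped.

## Problem sizes and numerical choices

The packaged tests and analysis scripts use three geometries, chosen so
each stage is measured where its signal lives: a general 8-exon locus
(200-bp exons) for genotyping and masking work; a long-intron variant of it
(800-bp introns) so a 1678-bp deletion — the size of the motivating
single-exon event — fits inside the homology block for long-read work; and
a 1400-bp-exon geometry for read-depth CNV calling, where per-exon depth at
100× is tight enough (roughly ±5%) to separate the 0.75 heterozygous-
deletion ratio from baseline with high sensitivity while the diploid grid
stays quiet. Coverage defaults are 100× collapsed for short reads and 30×
for long reads. Degenerate inputs fail loudly: zero-PSV references,
mask intervals out of bounds, paralog-pair derivation on unrelated
sequences, copy-number calling without unique control exons, zero-depth
sites (a no-call, never a reference call).

Coordinates are 1-based inclusive internally (VCF convention); BED output
is 0-based half-open (bedtools convention). Because published masked
intervals do not always state their convention, `mask_reference()` takes
`coords = "bed"` or `"one-based"` explicitly.

## Cohort accounting

`load_family_fixture()` ships a transcription of the variant table of a
published 17-family cohort with biallelic variants in a pseudogene-shadowed
PCD gene: per family the one or two causal alleles, zygosity, and the
sequencing stage each allele required. Applying the tiering rules
(`families_to_statuses()`, `cohort_summary()`) reproduces the published
accounting — 15 families solvable by the masked short-read stage, 2 more
by long reads, 6 homozygous and 11 compound-heterozygous families, and
17/242 ≈ 7% of the genetically confirmed cohort. The fixture lists 25
distinct cDNA changes while the source text says 24; the rows are preserved
as printed. Individual-level counts are not modelled.

## Known limitations

* The mapper is a toy: no paired-end rescue, no base-quality use, no
  general repeat handling; its accuracy claims hold for the simulator's
  error profile at desk scale.
* The genotyper is single-sample and site-wise; no local reassembly, no
  joint calling.
* Locus attribution and binning assume exactly one paralog pair in
  collinear orientation.
* cDNA/HGVS handling is limited to the toy transcript and the fixture's
  patterns; there is no clinical classification logic.
* Adaptive-sampling enrichment is represented only as the long-read
  coverage parameter.
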