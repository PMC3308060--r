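---
title: "Methods: capture evaluation, consensus genotyping, and the synthetic truth model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capture evaluation, consensus genotyping, and the synthetic truth model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements: what each stage assumes, which parameters matter, how the
synthetic data generator is constructed, and where we made design choices
that the underlying problem leaves open.

## The pipeline and its assumptions

`excap` evaluates solution hybrid-capture experiments after alignment. It
takes aligned paired-end records (or simulator output with truth
alignments), applies seven lane-level steps, merges lanes per sample, and
calls diploid consensus genotypes over the intended target. The design
premise throughout is that *only independent, uniquely placed, on-probe
observations should reach the genotype model*:

1. **Adapter clipping.** When a library insert is shorter than the read
   length, both reads run into the ligated adapters. We infer the insert
   length by a gapless scan of the two reads against each other (one of
   them complemented): candidate insert length $L$ implies a mutual
   overlap window of $\min(L,\,2R-L,\,R)$ bases for read length $R$; a
   candidate is accepted when the window has at least `clip_min_overlap`
   (default 10) bases and at most a `clip_max_mismatch` (default 0.1)
   fraction of mismatches, with the flanking bases additionally checked
   against the adapter sequences. Among accepted candidates the longest
   window wins, then the shortest insert. Reads are truncated to $L$
   only when $L < R$; "no clip" is a normal outcome. The defaults are
   ours: the mutual-overlap construction fixes the procedure, but no
   canonical mismatch tolerance exists.
2. **Pair mapping quality.** $q_m = -10\log_{10} P$ with $P$ the
   probability the reported locus is wrong; the pair is assigned
   $\min(q_{m,1}, q_{m,2})$ — a pair is only as trustworthy as its worse
   mate.
3. **Proper pairs.** One reference sequence, mates pointing at each
   other with the forward-strand mate leftmost, outer span at most
   `max_span` = 1,000 bp. We read "a maximum of 1,000 bp" as inclusive:
   a span of exactly 1,000 is proper.
4. **PCR duplicate removal.** Two independently captured molecules
   essentially never share both outer coordinates, so pairs with
   identical (reference, outer start, outer end, orientation) are PCR
   copies. Orientation is part of the key because an opposite-orientation
   coincidence is physically a different molecule. The representative is
   the pair with the highest summed base quality (ties: input order) —
   the copy most informative downstream.
5. **Probe/MQ filter.** Pairs are kept only at the aligner's *maximum*
   mapping quality (equality with `required_mq` = 60, not a lower
   bound), and only when *each mate* overlaps the probe set by at least
   `min_probe_overlap` = 20 aligned bases. Reads are kept whole once the
   overlap test passes; we do not trim read bases to probe boundaries.
   The alternative reading — base-level trimming outside probes — would
   shrink off-target noise further but discards real observations
   adjacent to probes; we implement read-level filtering and note the
   alternative here.
6. **Mate-overlap collapsing.** Where the mates overlap on the
   reference, the overlapping segment is removed from the mate with the
   lower summed quality in the overlap (ties trim mate 2; a mate
   contained in the other's span is trimmed entirely so the remainder
   stays contiguous). Retained overlap positions are recalibrated as
   independent evidence on the Phred scale: agreement gives
   $\min(q_1+q_2, \text{quality\_cap}=60)$, disagreement keeps the
   higher-quality base at $|q_1-q_2|$. The additive-Phred treatment is
   the standard combination rule for independent observations; the cap
   guards against overconfidence from model misfit. Reads whose CIGAR
   contains insertions or deletions are dropped (read-level): the
   pipeline's scope is substitutions in coding regions.
7. **On-target accounting.** Bases of surviving reads falling inside the
   intended target are counted; these feed depth, breadth and the
   per-lane report.

## The consensus genotype model

At each target position with at least one collapsed observation, the
caller computes a posterior over the ten unordered diploid genotypes.
Observations are modelled as independent draws from the two alleles: a
base $b$ with Phred quality $q$ (error probability $e = 10^{-q/10}$) has
likelihood $1-e$ under a matching allele and $e/3$ under any other, and a
genotype's per-observation likelihood is the equal mixture of its two
alleles. Priors are positional relative to the reference base:
heterozygous ref/non-ref genotypes share `het` = 1e-3, homozygous
non-reference genotypes share `hom_alt` = 5e-4, the three non-reference
heterozygotes share 1e-6, and the rest of the mass is homozygous
reference. These are conventional orders of magnitude for human-like
polymorphism rates; no authoritative values exist for the workflow we
re-implement, so they are configurable. The reported consensus quality is
$q_c = -10\log_{10}(1 - \text{posterior of the winner})$, capped at 255;
ties break towards homozygous reference, then lexicographically. Calls
are emitted at $q_c \ge$ `min_quality` = 50, i.e. at most a $10^{-5}$
chance of an incorrect genotype; gold standards built from calls use
$q_c \ge 100$.

This is a deliberate simplification of the classical Maq-style consensus
model: we assume base errors are independent (no error-dependency
correction) and model substitutions only (indel evidence was removed in
step 6). The simplification is what makes the caller checkable against an
independent brute-force posterior in the tests. Numerical work is done in
log space with an error-probability floor of $10^{-10}$ per observation;
posterior normalization is exact by construction and asserted in tests.

## The synthetic truth model

The generator exists so that every downstream claim can be tested against
a complete, recorded truth. It emulates:

- **Genome**: i.i.d. bases at a configurable GC fraction (default 0.41).
- **Diploid truth**: per-base variant probability `snv_rate`;
  heterozygous with probability `het_fraction` (default 0.6, the
  proportion seen in human variant panels), phased to a random
  haplotype; transitions with probability 2/3 (expected Ts/Tv of 2).
- **Capture design**: non-overlapping exon-like features (normal lengths,
  mean 150 bp — a typical exon — sd 50, truncated to [75, 500]), probes
  extending `probe_margin` = 100 bp into each flank. The margin is
  chosen once so that a typical 200 bp insert hybridizing at a feature
  edge is still recoverable and feature-edge depth does not collapse.
  A configurable fraction of features carries no probes, emulating genes
  absent from a kit.
- **Library**: insert lengths from a truncated normal (`"gel"`: mean
  200, sd 25, range 150–250 bp, the tight gel-excision profile) or a
  minimum-truncated lognormal (`"bead"`: median ~190 bp, from ~100 bp to
  beyond 300 bp, the broader bead-selection profile). The parametric
  forms are ours; only the ranges and peak are anchored to observed
  distributions.
- **Placement**: with probability `off_probe_fraction` an insert is
  placed uniformly in the non-probe genome (rejected if it touches a
  probe at all); otherwise it is placed so that *both mates* overlap a
  probe by at least 20 bases. This is the capture model: a molecule is
  recovered when it hybridizes substantially to a probe. It also makes
  the probe filter's retention exactly equal to the truth table's
  on-probe flags, which the tests exploit.
- **Mapping quality**: binary — 60 for uniquely placed pairs, 0 for an
  `ambiguous_rate` (default 0.02) fraction standing in for placements in
  repetitive sequence. The pipeline consumes only the maximum-quality
  stratum, so a richer MQ model would be untestable here anyway.
- **Duplicates**: each molecule is re-emitted with probability
  `duplicate_rate`; the copy shares coordinates but has freshly sampled
  errors and qualities (PCR first, sequencing later). Original molecules
  are given pairwise-distinct coordinate keys by rejection sampling, so
  the duplicate structure is exactly identifiable from coordinates and
  dedup can be scored against truth with equality rather than
  approximately. Real libraries can collide; at desk scale the collision
  rate would otherwise contaminate an exact oracle.
- **Base errors**: a two-state quality model (q15/q35) mixed so the mean
  error probability equals `error_rate`, each base's realized error
  probability honouring its assigned quality (below q35 demand the model
  degenerates to a single calibrated quality). Errors substitute a
  uniform other base. Positions of planted errors are recorded per read.

Determinism: every generator function takes a seed and restores the
caller's RNG state; a lane is a pure function of (config, seed).

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: GC-dependent capture efficiency,
quality decay along the read cycle, correlated/systematic error modes,
indels and structural variation, optical duplicates, reference bias and
mismapping (alignments are emitted at the true locus). Results on real
data will be worse than on these clean simulations in ways the package
measures but cannot predict.

## Numerical and interface choices

- Coordinates are 0-based half-open everywhere internally; SAM and VCF
  positions convert at the I/O boundary. Interval sets normalize on
  construction (sorted, overlapping *and abutting* intervals merged):
  the semantics are base sets, not features. Whether vendor interval
  files contain overlapping features is unknowable from their size
  alone; we normalize before any size is reported.
- Chromosome names are exact strings; `read_bed(alias_chr = TRUE)` maps
  bare numerals to `chr`-prefixed names only on explicit request.
- Enrichment is computed on post-dedup proper pairs (duplicates carry no
  independent information about specificity).
- Depth tracks count collapsed bases: a pair contributes at most one
  observation per position, matching what the caller sees.
- Replicate depth correlation is per-base Pearson with zero-depth bases
  included; the choice is configurable (`method = "spearman"`), since
  "correlation of depth" admits both readings.
- Disagreement percentages use called-positions denominators; uncalled
  gold positions appear in "percent genotyped", not in disagreement.
- "Called as variant" means a confident call with ≥ 1 non-reference
  allele; a heterozygote called homozygous-alternate counts as a
  detected variant but as a genotype disagreement.
- Gene-level coverage collapses transcripts of one gene to the union of
  their CDS exons; coding-effect classification evaluates each
  transcript and reports the most severe effect. Stop gains/losses fold
  into "non-synonymous".
- The config layer rejects unknown keys outright: a silently ignored
  typo in a threshold name would corrupt the analysis semantics.

## Problem sizes

The reference experiment used by the test suite and by
`scripts/acceptance.R` is a 2 Mb genome with ~400 targets (~60 kb of
target), `snv_rate` 1e-3, two lanes of 15,000 molecules each (plus
duplicates), giving ~33× mean collapsed target depth — about twice the
20× needed for reliable calling, so that depth troughs at feature edges
stay above threshold. The test suite runs three replicate experiments
under fixed seeds; unit tests use 50–150 kb genomes with a few hundred
to a few thousand pairs. These sizes were chosen as the smallest at
which the binomial tolerances used in the tests (typically ±3 SD) are
meaningfully tight.

## Known limitations

- The caller's independence assumption makes $q_c$ optimistic when
  errors are correlated; on real data the $q_c \ge 50$ stratum will not
  achieve a literal $10^{-5}$ error rate.
- Indels are out of scope by construction (indel-bearing reads are
  dropped), so indel-adjacent substitutions can be under-covered.
- The probe filter's read-level (not base-level) semantics slightly
  inflate near-probe off-target coverage; see step 5 above.
- Gold standards derived from the generator share the generator's
  simplifications; they validate the pipeline's logic, not platform
  chemistry.
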