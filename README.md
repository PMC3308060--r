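# excap

Evaluation of hybrid-capture (exome) sequencing experiments in R.

Solution hybrid capture enriches the protein-coding fraction of a genome
before sequencing. Deciding whether a capture experiment worked — and
whether two capture platforms differ — requires a disciplined chain of
read-level filtering and a small set of well-defined metrics. `excap`
implements that chain end to end:

- **Lane-level processing** of aligned read pairs, in order:
  1. adapter read-through clipping (mutual overlap of the two reads after
     complementing one of them);
  2. pair mapping quality `q_m = -10 log10 P` assigned as the minimum of
     the two mates;
  3. proper-pair classification (one reference, mates oriented towards
     each other, outer span ≤ 1,000 bp);
  4. PCR duplicate removal: pairs sharing both outer coordinates and
     orientation are copies of one molecule, keeping the highest-quality
     representative;
  5. probe filtering: only pairs at the aligner's maximum mapping quality
     (60) with ≥ 20 bases of probe overlap per read;
  6. mate-overlap collapsing, so a pair contributes at most one
     observation per reference base, with base-quality recalibration
     (qualities add when mates agree, capped at 60; the higher-quality
     base wins at the quality difference when they disagree) and removal
     of indel-bearing reads;
  7. counting of bases on the intended target.
- **Consensus genotyping**: lanes are merged and a naive-Bayes diploid
  caller computes, at every covered target position, the posterior over
  all ten diploid genotypes from the collapsed base qualities, reporting
  Phred-scaled consensus qualities `q_c`; calls are kept at `q_c ≥ 50`
  (≤ 1e-5 probability of an incorrect genotype).
- **Capture metrics**: coverage breadth at 1× / 20×, depth uniformity
  histograms, enrichment score (fraction of proper pairs on probe),
  insert-size distributions, replicate depth correlation, and the
  raw-data-for-depth rule (genome size × desired depth).
- **Concordance scoring** against variant-focused or comprehensive gold
  standards: percent genotyped, genotype disagreement, variant and
  heterozygote sensitivity and false discovery rate, Ts/Tv.
- **Gene reports**: refFlat gene models, per-gene percent of coding bases
  targeted and genotyped, synonymous/non-synonymous classification of
  coding substitutions.
- A **synthetic experiment generator** with complete known truth (diploid
  variants, insert-size models for gel- and bead-based size selection,
  PCR duplicates, off-probe pairs, adapter read-through, Phred-calibrated
  base errors), so the whole pipeline is testable without external data.

It is aimed at method developers and bioinformaticians who want a
desk-scale, fully reproducible harness for capture-evaluation logic.

## Worked example

```r
library(excap)

genome <- simulate_genome(c(chr1 = 500000), seed = 1)
truth  <- plant_variants(genome, snv_rate = 1e-3, het_fraction = 0.6, seed = 2)
design <- design_capture(genome, n_targets = 100, seed = 3)
profile <- library_profile(insert = "gel", error_rate = 0.005,
                           duplicate_rate = 0.1, off_probe_fraction = 0.12)
lane   <- simulate_lane(genome, truth, design, profile, n_pairs = 8000, seed = 4)

result <- run_lane(lane, design)
result$stats
#> lane_stats:
#>   input              8800
#>   clipped            0
#>   proper             8800
#>   after_dedup        8000
#>   duplicates_removed 800
#>   on_probe_proper    7046
#>   after_probe_mq     6907
#>   segments           13814
#>   bases_on_target    531492
round(enrichment_score(result$stats), 4)
#> [1] 0.8808
```

The lane entered with 8,800 pairs (8,000 molecules plus 800 PCR
duplicates); dedup removed exactly the 800 duplicates, and the probe/MQ
filter kept 6,907 pairs. The enrichment score 0.881 recovers the
simulated 12% off-probe fraction.

```r
calls <- call_genotypes(result, genome, design$target)
cov   <- coverage_report(depth_track(result, design$target))
cov
#> coverage_report: 15113 target bases, mean depth 35.17
#>   breadth @1: 1.0000
#>   breadth @20: 0.9942

gold <- truth_gold_standard(truth, genome, design$target, "variant_focused")
concordance_report(calls, gold)
#> concordance_report:
#>   percent genotyped      100.0000
#>   percent disagreement   0.0000
#>   variant sensitivity    100.0000
#>   variant FDR            0.0000
#>   het sensitivity        100.0000
#>   het FDR                0.0000
#>   het disagreement       0.0000
#>   Ts/Tv                  2.7500
```

All 15 planted variants inside the target are recovered with correct
genotypes; mean collapsed depth is 35× with 99.4% of target bases at
20× or better.

## Command line

A thin wrapper lives at `inst/cli/excap` (installed under
`system.file("cli", "excap", package = "excap")`):

```sh
excap full --config run.cfg --seed 5 --out-dir report/
```

Subcommands `simulate`, `run-lane`, `call`, `metrics`, `concord`,
`genes`, `full`; the configuration is a flat `key=value` file (unknown
keys are errors). `full` writes the lane-level (per-lane filtered SAM +
statistics TSV) and sample-level (calls VCF, coverage, concordance and
gene-report TSVs) report files.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "excap", load_package = "installed")'
```

The suite checks every operation against independent brute-force oracles
(per-base interval enumeration, linear-space genotype posteriors,
exhaustive concordance counting, a hand-built codon table) and runs the
complete pipeline on replicate synthetic experiments.

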