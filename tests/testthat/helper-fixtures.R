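# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from stored data files.

# A minimal aligned pair in the raw pair-table schema. Defaults give a
# proper FR pair of 10-base reads with all-q30 qualities and MQ 60.
pair_row <- function(qname = "p1", chrom = "chr1", pos1 = 100, strand1 = "+",
                     mq1 = 60, seq1 = "ACGTACGTAC", pos2 = 150,
                     strand2 = "-", mq2 = 60, seq2 = "ACGTACGTAC",
                     cigar1 = paste0(nchar(seq1), "M"),
                     cigar2 = paste0(nchar(seq2), "M"),
                     qual1 = strrep("?", nchar(seq1)),
                     qual2 = strrep("?", nchar(seq2)),
                     chrom2 = chrom) {
  data.frame(qname = qname, chrom1 = chrom, pos1 = pos1, strand1 = strand1,
             mq1 = mq1, cigar1 = cigar1, seq1 = seq1, qual1 = qual1,
             chrom2 = chrom2, pos2 = pos2, strand2 = strand2, mq2 = mq2,
             cigar2 = cigar2, seq2 = seq2, qual2 = qual2,
             stringsAsFactors = FALSE)
}

pair_table <- function(...) do.call(rbind, list(...))

# Phred+33 quality string from integer qualities.
qstr <- function(q) intToUtf8(q + 33)

# A small deterministic experiment for pipeline-level tests.
small_experiment <- function(seed = 11, n_pairs = 2500, n_targets = 30,
                             genome_kb = 150, profile = library_profile(),
                             untargeted_fraction = 0, snv_rate = 1e-3) {
  g <- simulate_genome(c(chrA = genome_kb * 1000), seed = seed)
  tr <- plant_variants(g, snv_rate = snv_rate, seed = seed + 1)
  d <- design_capture(g, n_targets = n_targets,
                      untargeted_fraction = untargeted_fraction,
                      seed = seed + 2)
  lane <- simulate_lane(g, tr, d, profile, n_pairs = n_pairs,
                        seed = seed + 3)
  list(genome = g, truth = tr, design = d, lane = lane,
       profile = profile)
}

# Single-column lane: one synthetic pileup column as a segment table, for
# driving the caller with hand-chosen observations.
column_segments <- function(bases, quals, chrom = "chrA", pos = 10) {
  data.frame(qname = sprintf("r%03d", seq_along(bases)),
             mate = 1L, chrom = chrom, start = pos,
             seq = bases, qual = vapply(quals, qstr, ""),
             strand = "+", mq = 60L, stringsAsFactors = FALSE)
}

# Genome with one chromosome of given sequence string.
literal_genome <- function(seq, chrom = "chrA") {
  structure(list(sequences = stats::setNames(seq, chrom), seed = 0L),
            class = "sim_genome")
}

# Call a single pileup column through the package caller.
call_column <- function(bases, quals, ref, refpos = 10,
                        priors = prior_model(), min_quality = 0) {
  flank <- strrep("A", 40)
  seq <- paste0(flank, ref, flank)  # ref base at 0-based position 40
  g <- literal_genome(seq)
  segs <- column_segments(bases, quals, pos = 40)
  target <- interval_set("chrA", 40, 41)
  call_genotypes(segs, g, target, priors = priors,
                 min_quality = min_quality)
}
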