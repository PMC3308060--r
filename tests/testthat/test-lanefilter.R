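# Lane-level pipeline: adapter clipping, proper-pair classification, pair
# mapping quality, duplicate removal, probe filtering, overlap collapsing,
# and the assembled run_lane().

test_that("adapter clipping recovers simulated short inserts exactly", {
  short <- library_profile(insert = list(type = "gel", mean = 50, sd = 8,
                                         min = 30, max = 70),
                           error_rate = 0, duplicate_rate = 0,
                           off_probe_fraction = 0, ambiguous_rate = 0)
  ex <- small_experiment(seed = 71, n_pairs = 300, profile = short)
  cl <- clip_adapters(ex$lane$pairs$seq1, ex$lane$pairs$qual1,
                      ex$lane$pairs$seq2, ex$lane$pairs$qual2)
  expect_true(all(cl$clipped))
  expect_equal(cl$insert_len, ex$lane$truth$insert_len)
  expect_equal(nchar(cl$seq1), ex$lane$truth$insert_len)
  expect_equal(nchar(cl$qual1), nchar(cl$seq1))
})

test_that("long inserts and unrelated reads are not clipped", {
  # insert >= twice the read length: no mutual overlap at all
  ex <- small_experiment(seed = 72, n_pairs = 150,
                         profile = library_profile(error_rate = 0))
  keep <- ex$lane$truth$insert_len >= 152
  cl <- clip_adapters(ex$lane$pairs$seq1[keep], ex$lane$pairs$qual1[keep],
                      ex$lane$pairs$seq2[keep], ex$lane$pairs$qual2[keep])
  expect_false(any(cl$clipped))
  expect_identical(cl$seq1, ex$lane$pairs$seq1[keep])

  # adapter-free random reads with no mutual overlap: "no clip"
  set.seed(9)
  r1 <- replicate(30, paste(sample(c("A", "C", "G", "T"), 76, TRUE),
                            collapse = ""))
  r2 <- replicate(30, paste(sample(c("A", "C", "G", "T"), 76, TRUE),
                            collapse = ""))
  q <- strrep("I", 76)
  cl2 <- clip_adapters(r1, q, r2, q)
  expect_false(any(cl2$clipped))
})

test_that("proper-pair classification covers every failure mode", {
  # same chrom, FR orientation, span 300
  p <- pair_row(pos1 = 100, strand1 = "+", pos2 = 390, strand2 = "-")
  expect_equal(classify_pair(p), "proper")
  # mates on different chromosomes
  p2 <- pair_row(chrom2 = "chr9")
  expect_equal(classify_pair(p2), "improper:different-chrom")
  # same strand
  p3 <- pair_row(strand2 = "+")
  expect_equal(classify_pair(p3), "improper:wrong-orientation")
  # outward-facing (reverse mate leftmost)
  p4 <- pair_row(pos1 = 200, strand1 = "-", pos2 = 300, strand2 = "+")
  expect_equal(classify_pair(p4), "improper:wrong-orientation")
  # the 1,000 bp boundary is inclusive
  p5 <- pair_row(pos1 = 0, pos2 = 990, seq2 = strrep("A", 10))
  expect_equal(classify_pair(p5), "proper")     # span exactly 1000
  p6 <- pair_row(pos1 = 0, pos2 = 991, seq2 = strrep("A", 10))
  expect_equal(classify_pair(p6), "improper:span")  # span 1001
})

test_that("pair mapping quality is the exhaustive minimum", {
  expect_equal(pair_mapping_quality(60, 60), 60)
  expect_equal(pair_mapping_quality(60, 0), 0)
  grid <- expand.grid(q1 = 0:60, q2 = 0:60)
  expect_equal(pair_mapping_quality(grid$q1, grid$q2),
               mapply(min, grid$q1, grid$q2))
})

test_that("duplicate removal keys on coordinates and keeps best quality", {
  p <- rbind(
    pair_row("a", pos1 = 100, pos2 = 150, qual1 = qstr(rep(20, 10)),
             qual2 = qstr(rep(20, 10))),
    pair_row("b", pos1 = 100, pos2 = 150, qual1 = qstr(rep(30, 10)),
             qual2 = qstr(rep(30, 10))),
    pair_row("c", pos1 = 300, pos2 = 350))
  kept <- remove_duplicates(p)
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "removed"), 1)
  expect_true("b" %in% kept$qname)  # higher summed quality wins
  expect_true("c" %in% kept$qname)

  # ties break by input order
  p_tie <- rbind(pair_row("x", pos1 = 100, pos2 = 150),
                 pair_row("y", pos1 = 100, pos2 = 150))
  expect_equal(remove_duplicates(p_tie)$qname, "x")

  # opposite orientation at the same coordinates is not a duplicate
  p_or <- rbind(pair_row("f", pos1 = 100, strand1 = "+", pos2 = 150,
                         strand2 = "-"),
                pair_row("r", pos1 = 100, strand1 = "-", pos2 = 150,
                         strand2 = "+"))
  expect_equal(nrow(remove_duplicates(p_or)), 2)
})

test_that("dedup on simulated lanes equals the truth exactly", {
  clean <- library_profile(duplicate_rate = 0)
  ex0 <- small_experiment(seed = 81, n_pairs = 800, profile = clean)
  cls <- classify_pair(ex0$lane$pairs)
  kept <- remove_duplicates(ex0$lane$pairs[cls == "proper", ])
  expect_equal(attr(kept, "removed"), 0)

  prof <- library_profile(duplicate_rate = 0.2)
  ex <- small_experiment(seed = 82, n_pairs = 1500, profile = prof)
  cls <- classify_pair(ex$lane$pairs)
  kept <- remove_duplicates(ex$lane$pairs[cls == "proper", ])
  expect_equal(attr(kept, "removed"), sum(!is.na(ex$lane$truth$dup_of)))

  # matches brute-force grouping
  tt <- ex$lane$truth
  expect_equal(nrow(kept),
               oracle_dedup_groups(tt$chrom, tt$insert_start,
                                   tt$insert_start + tt$insert_len,
                                   tt$strand1))
})

test_that("probe filter enforces 20-base overlap per mate and MQ equality", {
  probes <- interval_set("chr1", 1000, 1100)
  mk <- function(pos1, pos2, mq = 60)
    pair_row(pos1 = pos1, pos2 = pos2, mq1 = mq, mq2 = mq,
             seq1 = strrep("A", 50), seq2 = strrep("A", 50),
             qual1 = strrep("?", 50), qual2 = strrep("?", 50))
  # mate1 at 970 covers 970..1019: exactly 20 bases on the probe
  p20 <- mk(970, 1040)   # mate2 covers 1040..1089, fully on probe
  expect_equal(nrow(probe_filter(p20, probes)), 1)
  # one base to the left: 19-base overlap, dropped
  expect_equal(nrow(probe_filter(mk(969, 1040), probes)), 0)
  # MQ 59 is dropped regardless of overlap
  expect_equal(nrow(probe_filter(mk(1020, 1040, mq = 59), probes)), 0)

  # on simulated lanes retention equals the truth on-probe flags
  ex <- small_experiment(seed = 91, n_pairs = 1200,
                         profile = library_profile(off_probe_fraction = 0.25,
                                                   ambiguous_rate = 0,
                                                   duplicate_rate = 0))
  cls <- classify_pair(ex$lane$pairs)
  proper <- ex$lane$pairs[cls == "proper", ]
  flt <- probe_filter(proper, ex$design$probes)
  expect_setequal(flt$qname,
                  ex$lane$truth$qname[ex$lane$truth$on_probe])
})

test_that("mate-overlap collapse trims, recalibrates, and drops indels", {
  # non-overlapping mates come back unchanged
  p <- pair_row(pos1 = 100, pos2 = 200)
  segs <- collapse_pairs(excap:::align_pairs(p))
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start, c(100, 200))
  expect_equal(segs$seq[1], "ACGTACGTAC")

  # 10-base full overlap of agreeing q30 bases -> quality 60 at the cap
  # (mate 2 is minus-strand: its read-orientation sequence is the reverse
  # complement of the reference bases)
  po <- pair_row(pos1 = 100, pos2 = 100,
                 seq2 = excap:::revcomp("ACGTACGTAC"))
  so <- collapse_pairs(excap:::align_pairs(po), quality_cap = 60)
  expect_equal(nrow(so), 1)
  expect_equal(utf8ToInt(so$qual) - 33, rep(60, 10))
  expect_equal(so$seq, "ACGTACGTAC")

  # partial overlap, disagreement: higher-quality base wins at |q1-q2|
  p2 <- pair_row(pos1 = 100, seq1 = "AAAAAAAAAA", qual1 = qstr(rep(30, 10)),
                 pos2 = 105, seq2 = "CCCCCCCCCC", qual2 = qstr(rep(20, 10)))
  s2 <- collapse_pairs(excap:::align_pairs(p2))
  # mate 2 has the lower summed quality in the overlap -> trimmed
  m1 <- s2[s2$mate == 1, ]
  m2 <- s2[s2$mate == 2, ]
  expect_equal(m1$seq, "AAAAAAAAAA")        # disagreements keep the A at q10
  expect_equal(utf8ToInt(m1$qual) - 33, c(rep(30, 5), rep(10, 5)))
  expect_equal(m2$start, 110)               # left part trimmed off
  expect_equal(nchar(m2$seq), 5)

  # indel-bearing reads are dropped read-level, not pair-level
  pi <- pair_row(cigar1 = "4M2D6M", pos2 = 300)
  si <- collapse_pairs(excap:::align_pairs(pi))
  expect_equal(si$mate, 2)
  pi2 <- pair_row(cigar1 = "4M2I4M")
  expect_false(1 %in% collapse_pairs(excap:::align_pairs(pi2))$mate)
})

test_that("collapse never double-covers a position; error-free collapse keeps bases", {
  # property over simulated pairs: after collapse no reference position
  # receives two bases from one pair; with error_rate 0 base identities
  # are untouched
  prof <- library_profile(error_rate = 0, insert = list(
    type = "gel", mean = 120, sd = 20, min = 80, max = 160))
  ex <- small_experiment(seed = 101, n_pairs = 400, profile = prof)
  res <- run_lane(ex$lane, ex$design)
  segs <- res$segments
  by_pair <- split(seq_len(nrow(segs)), segs$qname)
  for (idx in by_pair) {
    pos <- unlist(lapply(idx, function(i)
      seq(segs$start[i], segs$start[i] + nchar(segs$seq[i]) - 1)))
    expect_false(any(duplicated(pos)))
  }
  # error-free collapse only changes qualities, never bases
  g <- ex$genome$sequences[["chrA"]]
  hp <- excap:::haplotype_pair(g, ex$truth)
  tt <- ex$lane$truth
  for (i in sample(nrow(segs), 60)) {
    t <- tt[tt$qname == segs$qname[i], ]
    ref_part <- substring(hp[[t$hap]], segs$start[i] + 1,
                          segs$start[i] + nchar(segs$seq[i]))
    expect_equal(segs$seq[i], ref_part)
  }
})

test_that("run_lane: clean lanes survive fully; stats monotone; deterministic", {
  clean <- library_profile(error_rate = 0, duplicate_rate = 0,
                           off_probe_fraction = 0, ambiguous_rate = 0)
  ex <- small_experiment(seed = 111, n_pairs = 600, profile = clean)
  res <- run_lane(ex$lane, ex$design)
  ct <- res$stats$counts
  expect_equal(unname(ct["proper"]), 600)
  expect_equal(unname(ct["after_dedup"]), 600)
  expect_equal(unname(ct["after_probe_mq"]), 600)
  # monotone non-increasing through the filtering steps
  expect_true(all(diff(ct[c("input", "proper", "after_dedup",
                            "after_probe_mq")]) <= 0))
  expect_lte(res$stats$on_probe_proper, res$stats$proper_total)

  # determinism: identical outputs on re-run
  res2 <- run_lane(ex$lane, ex$design)
  expect_identical(res$segments, res2$segments)
  expect_identical(res$stats$counts, res2$stats$counts)

  # off_probe_fraction 0.3 -> step-5 removal fraction about 0.3
  prof <- library_profile(off_probe_fraction = 0.3, ambiguous_rate = 0,
                          duplicate_rate = 0)
  ex3 <- small_experiment(seed = 112, n_pairs = 2000, profile = prof)
  res3 <- run_lane(ex3$lane, ex3$design)
  removed <- 1 - res3$stats$counts[["after_probe_mq"]] /
    res3$stats$counts[["after_dedup"]]
  expect_lt(abs(removed - 0.3), 3 * sqrt(0.3 * 0.7 / 2000) + 0.01)

  # empty input gives empty output with zeroed statistics
  empty <- list(pairs = excap:::empty_pair_table(),
                seq_lengths = ex$lane$seq_lengths)
  res0 <- run_lane(empty, ex$design)
  expect_equal(nrow(res0$segments), 0)
  expect_equal(unname(res0$stats$counts["input"]), 0)
  expect_equal(res0$stats$bases_on_target, 0)
})

test_that("bases-on-target equals a per-base brute-force recount", {
  ex <- small_experiment(seed = 121, n_pairs = 250)
  res <- run_lane(ex$lane, ex$design)
  target_df <- as.data.frame(ex$design$target)
  brute <- 0
  tkeys <- enumerate_bases(target_df)
  for (i in seq_len(nrow(res$segments))) {
    len <- nchar(res$segments$seq[i])
    keys <- paste0(res$segments$chrom[i], ":",
                   seq(res$segments$start[i],
                       res$segments$start[i] + len - 1))
    brute <- brute + sum(keys %in% tkeys)
  }
  expect_equal(res$stats$bases_on_target, brute)
})

test_that("dedup and probe filtering commute on duplicate-free lanes", {
  prof <- library_profile(duplicate_rate = 0)
  ex <- small_experiment(seed = 131, n_pairs = 900, profile = prof)
  cls <- classify_pair(ex$lane$pairs)
  proper <- ex$lane$pairs[cls == "proper", ]
  a <- probe_filter(remove_duplicates(proper), ex$design$probes)
  b <- remove_duplicates(probe_filter(proper, ex$design$probes))
  expect_equal(a$qname, b$qname)
  sa <- collapse_pairs(excap:::align_pairs(a))
  sb <- collapse_pairs(excap:::align_pairs(b))
  expect_identical(sa$seq, sb$seq)
})

test_that("filtered lanes round-trip through SAM", {
  ex <- small_experiment(seed = 141, n_pairs = 200)
  res <- run_lane(ex$lane, ex$design)
  f <- withr::local_tempfile(fileext = ".sam")
  write_lane_result(res, f)
  back <- read_sam_segments(f)
  ord <- function(d) d[order(d$chrom, d$start, d$qname, d$mate), ]
  expect_equal(ord(back)[c("qname", "chrom", "start", "seq", "qual")],
               ord(res$segments)[c("qname", "chrom", "start", "seq", "qual")],
               ignore_attr = TRUE)
  # provenance comment present
  expect_true(any(grepl("^@CO\t.*min_probe_overlap", readLines(f))))
})
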