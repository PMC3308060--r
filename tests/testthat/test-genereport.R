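# Gene models: refFlat parsing, gene-level coverage accounting, and
# coding-effect classification against an independent translation oracle.

refflat_line <- function(gene = "G1", name = "G1.1", chrom = "chrA",
                         strand = "+", txStart = 0, txEnd = 100,
                         cdsStart = txStart, cdsEnd = txEnd,
                         exonStarts = txStart, exonEnds = txEnd) {
  paste(gene, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
        length(exonStarts), paste0(paste(exonStarts, collapse = ","), ","),
        paste0(paste(exonEnds, collapse = ","), ","), sep = "\t")
}

write_refflat_lines <- function(...) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(c(...), f)
  f
}

test_that("refFlat parsing: CDS clipping, flags, and parse errors", {
  f <- write_refflat_lines(
    refflat_line("G1", txStart = 0, txEnd = 99, cdsStart = 0, cdsEnd = 99),
    # exon partially 5' UTR: CDS clipped at cdsStart
    refflat_line("G2", txStart = 200, txEnd = 300, cdsStart = 250,
                 cdsEnd = 298),
    # non-coding transcript
    refflat_line("G3", txStart = 400, txEnd = 500, cdsStart = 450,
                 cdsEnd = 450),
    # two exons
    refflat_line("G4", txStart = 600, txEnd = 700, cdsStart = 610,
                 cdsEnd = 695, exonStarts = c(600, 660),
                 exonEnds = c(640, 700)))
  models <- read_refflat(f)
  expect_length(models, 4)
  expect_equal(total_bases(models[[1]]$cds), 99)
  expect_true(models[[1]]$coding)
  expect_equal(models[[1]]$frame_ok, TRUE)
  expect_equal(as.data.frame(models[[2]]$cds),
               data.frame(chrom = "chrA", start = 250, end = 298))
  expect_equal(models[[3]]$cds_len, 0)
  expect_false(models[[3]]$coding)
  expect_equal(as.data.frame(models[[4]]$cds),
               data.frame(chrom = "chrA", start = c(610, 660),
                          end = c(640, 695)))
  expect_false(models[[4]]$frame_ok)  # 65 bases, not a codon multiple

  bad <- write_refflat_lines("G1\tonly\tthree")
  expect_error(read_refflat(bad), "11 tab-separated")
})

test_that("random models: CDS base count equals brute-force clip and count", {
  set.seed(53)
  for (rep in 1:15) {
    ex_s <- sort(sample(0:400, 3))
    ex_e <- ex_s + sample(20:60, 3)
    cds_s <- sample(ex_s[1]:ex_e[3], 1)
    cds_e <- sample(cds_s:(ex_e[3]), 1)
    f <- write_refflat_lines(refflat_line(
      "R", txStart = ex_s[1], txEnd = ex_e[3], cdsStart = cds_s,
      cdsEnd = cds_e, exonStarts = ex_s, exonEnds = ex_e))
    m <- read_refflat(f)[[1]]
    # exons may overlap in the random draw; count unique covered bases
    pos <- unlist(lapply(1:3, function(i)
      seq(max(ex_s[i], cds_s), min(ex_e[i], cds_e) - 1)[
        seq_len(max(min(ex_e[i], cds_e) - max(ex_s[i], cds_s), 0))]))
    expect_equal(m$cds_len, length(unique(pos)))
  }
})

test_that("gene coverage report matches hand-computed fixtures", {
  target <- interval_set("chrA", c(0, 500), c(100, 600))
  models <- read_refflat(write_refflat_lines(
    refflat_line("FULL", txStart = 0, txEnd = 60),       # fully targeted
    refflat_line("HALF", txStart = 450, txEnd = 550),    # half targeted
    refflat_line("NONE", txStart = 900, txEnd = 960)))   # untargeted
  calls <- structure(data.frame(
    chrom = "chrA", pos = c(0:29, 500:549, 905:910),
    ref = "A", genotype = "A/A", qc = 100, depth = 30,
    stringsAsFactors = FALSE), class = c("genotype_calls", "data.frame"))
  rep <- gene_coverage_report(models, target, calls)
  rep <- rep[match(c("FULL", "HALF", "NONE"), rep$gene), ]
  expect_equal(rep$coding_bases, c(60, 100, 60))
  expect_equal(rep$pct_targeted, c(100, 50, 0))
  expect_equal(rep$pct_genotyped, c(50, 50, 10))

  # fully covered gene: 100 / 100
  calls_full <- structure(data.frame(
    chrom = "chrA", pos = 0:59, ref = "A", genotype = "A/A", qc = 100,
    depth = 30, stringsAsFactors = FALSE),
    class = c("genotype_calls", "data.frame"))
  r2 <- gene_coverage_report(models[1], target, calls_full)
  expect_equal(r2$pct_targeted, 100)
  expect_equal(r2$pct_genotyped, 100)
})

test_that("untargeted simulator features show up as 0% targeted", {
  ex <- small_experiment(seed = 331, n_pairs = 100,
                         untargeted_fraction = 0.3)
  f <- withr::local_tempfile(fileext = ".txt")
  write_refflat(ex$design$annotation, f)
  models <- read_refflat(f)
  probed_target <- interval_set(
    ex$design$features$chrom[ex$design$features$targeted],
    ex$design$features$start[ex$design$features$targeted],
    ex$design$features$end[ex$design$features$targeted])
  empty_calls <- structure(
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               genotype = character(0), qc = numeric(0), depth = integer(0)),
    class = c("genotype_calls", "data.frame"))
  rep <- gene_coverage_report(models, probed_target, empty_calls)
  free <- ex$design$features$gene[!ex$design$features$targeted]
  expect_true(all(rep$pct_targeted[rep$gene %in% free] == 0))
  expect_true(all(rep$pct_genotyped == 0))
})

test_that("coding effects: canonical codon examples", {
  # GGA->GGG, third codon position: synonymous (both glycine)
  g <- literal_genome(paste0("GGA", "AAA", strrep("A", 54)))
  m <- read_refflat(write_refflat_lines(
    refflat_line("X", txStart = 0, txEnd = 60)))[[1]]
  expect_equal(coding_effect(list(chrom = "chrA", pos = 2, ref = "A",
                                  alt = "G"), m, g), "synonymous")
  # AAA->GAA, first position: Lys->Glu
  expect_equal(coding_effect(list(chrom = "chrA", pos = 3, ref = "A",
                                  alt = "G"), m, g), "non-synonymous")
  # outside the CDS
  g2 <- literal_genome(strrep("A", 200))
  expect_equal(coding_effect(list(chrom = "chrA", pos = 150, ref = "A",
                                  alt = "G"), m, g2), "non-coding")
  # reference mismatch is an error
  expect_error(coding_effect(list(chrom = "chrA", pos = 2, ref = "C",
                                  alt = "G"), m, g), "does not match")
})

test_that("coding effects agree with the translation oracle on both strands", {
  set.seed(61)
  for (rep in 1:12) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    g <- literal_genome(seq)
    strand <- sample(c("+", "-"), 1)
    # two-exon CDS, total length a codon multiple
    s1 <- 20; e1 <- s1 + 30
    s2 <- 100; e2 <- s2 + 30
    m <- read_refflat(write_refflat_lines(refflat_line(
      "O", strand = strand, txStart = s1, txEnd = e2, cdsStart = s1,
      cdsEnd = e2, exonStarts = c(s1, s2), exonEnds = c(e1, e2))))[[1]]
    for (k in 1:6) {
      pos <- sample(c(s1:(e1 - 1), s2:(e2 - 1)), 1)
      ref <- substr(seq, pos + 1, pos + 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      v <- list(chrom = "chrA", pos = pos, ref = ref, alt = alt)
      expect_equal(coding_effect(v, m, g), oracle_coding_effect(v, m, g),
                   info = sprintf("strand %s pos %d %s>%s", strand, pos,
                                  ref, alt))
    }
  }
})

test_that("a variant reads the same on either strand representation", {
  # minus-strand gene: representing the substitution on the reference
  # strand is the only convention; classification must match the oracle,
  # which translates the reverse complement
  seq <- paste0(strrep("C", 10), "TTACGGATCAGG", strrep("C", 10))
  g <- literal_genome(seq)
  m <- read_refflat(write_refflat_lines(refflat_line(
    "M", strand = "-", txStart = 10, txEnd = 22)))[[1]]
  for (pos in 10:21) {
    ref <- substr(seq, pos + 1, pos + 1)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      v <- list(chrom = "chrA", pos = pos, ref = ref, alt = alt)
      expect_equal(coding_effect(v, m, g), oracle_coding_effect(v, m, g))
    }
  }
})

test_that("transcript multiplicity reports the most severe effect", {
  seq <- paste0("ATGGGATAA", strrep("A", 91))
  g <- literal_genome(seq)
  models <- read_refflat(write_refflat_lines(
    refflat_line("S", "S.1", txStart = 0, txEnd = 9),
    refflat_line("S", "S.2", txStart = 0, txEnd = 6)))
  # GGA->GGG: synonymous in both transcripts
  v <- list(chrom = "chrA", pos = 5, ref = "A", alt = "G")
  expect_equal(coding_effect_any(v, models, g), "synonymous")
  # GGA->GAA: non-synonymous wins over any weaker classification
  v2 <- list(chrom = "chrA", pos = 4, ref = "G", alt = "A")
  expect_equal(coding_effect_any(v2, models, g), "non-synonymous")
})
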