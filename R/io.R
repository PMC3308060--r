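# File I/O: FASTA/FASTQ (via Biostrings), SAM pair records, VCF-subset and
# TSV tables. All genomic coordinates are 0-based half-open in memory;
# SAM POS and VCF POS are converted at this boundary.

#' Write and read a simulated genome as FASTA
#'
#' @param genome a `sim_genome` (named list of chromosome strings) or any
#'   named character vector of sequences.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(unlist(as.list(genome$sequences %||% genome)))
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @return `read_genome_fasta()` returns a `sim_genome`-compatible list with
#'   a `sequences` element (named character vector).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  structure(list(sequences = stats::setNames(as.character(ss), names(ss)),
                 seed = NA_integer_),
            class = "sim_genome")
}

#' Write paired reads to a pair of FASTQ files
#'
#' Reads are written in read orientation with Phred+33 qualities.
#'
#' @param pairs pair table with columns `qname`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (read orientation).
#' @param path_r1,path_r2 output FASTQ paths for mate 1 and mate 2.
#' @export
write_pair_fastq <- function(pairs, path_r1, path_r2) {
  for (m in 1:2) {
    ss <- Biostrings::DNAStringSet(pairs[[paste0("seq", m)]])
    names(ss) <- paste0(pairs$qname, "/", m)
    Biostrings::writeXStringSet(
      ss, filepath = if (m == 1) path_r1 else path_r2, format = "fastq",
      qualities = Biostrings::BStringSet(pairs[[paste0("qual", m)]]))
  }
  invisible(c(path_r1, path_r2))
}

#' @rdname write_pair_fastq
#' @return `read_pair_fastq()` returns a data frame with columns `qname`,
#'   `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_pair_fastq <- function(path_r1, path_r2) {
  rd <- function(p) {
    s <- Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
    data.frame(qname = sub("/[12]$", "", sub("\\s.*$", "", names(s))),
               seq = as.character(s),
               qual = as.character(S4Vectors::mcols(s)$qualities),
               stringsAsFactors = FALSE)
  }
  r1 <- rd(path_r1); r2 <- rd(path_r2)
  if (!identical(r1$qname, r2$qname))
    stop("read IDs differ between the two FASTQ files")
  data.frame(qname = r1$qname, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

# ---- CIGAR -----------------------------------------------------------------

# Tokenize a CIGAR string into lengths and ops.
cigar_ops <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1) stop("malformed CIGAR: ", cigar)
  tok <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", tok)),
       op = sub("^[0-9]+", "", tok))
}

# Number of read bases aligned as matches (M/=/X ops).
cigar_aligned_len <- function(cigar) {
  vapply(cigar, function(cg) {
    co <- cigar_ops(cg)
    sum(co$len[co$op %in% c("M", "=", "X")])
  }, 0L, USE.NAMES = FALSE)
}

cigar_has_indel <- function(cigar) {
  grepl("[0-9](I|D)", cigar)
}

# Leading soft clip length (read bases before the first aligned base,
# in SAM record orientation).
cigar_left_clip <- function(cigar) {
  vapply(cigar, function(cg) {
    co <- cigar_ops(cg)
    if (co$op[1] == "S") co$len[1] else 0L
  }, 0L, USE.NAMES = FALSE)
}

# ---- SAM pair records ------------------------------------------------------

# FLAG bits
FLAG_PAIRED <- 0x1; FLAG_PROPER <- 0x2; FLAG_REVERSE <- 0x10
FLAG_MREVERSE <- 0x20; FLAG_FIRST <- 0x40; FLAG_LAST <- 0x80

#' Write aligned read pairs as SAM
#'
#' One record per mate, standard 11 mandatory columns. Sequences of
#' minus-strand mates are stored reverse-complemented with reversed
#' qualities, per the SAM convention. Adapter tails that the aligner would
#' not place are represented as soft clips.
#'
#' @param pairs pair table in read orientation with per-mate columns
#'   `chrom1`/`chrom2`, `pos1`/`pos2` (0-based leftmost aligned),
#'   `strand1`/`strand2`, `cigar1`/`cigar2` (record orientation),
#'   `mq1`/`mq2`, `seq1`/`seq2`, `qual1`/`qual2` (read orientation), plus
#'   `qname`.
#' @param path output SAM path.
#' @param seq_lengths named vector of reference lengths for the `@SQ` header.
#' @param comments character vector written as `@CO` lines (e.g. filtering
#'   provenance).
#' @export
write_sam_pairs <- function(pairs, path, seq_lengths, comments = character(0)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                   as.integer(seq_lengths)),
           if (length(comments)) paste0("@CO\t", comments))
  rec <- function(m, other) {
    strand <- pairs[[paste0("strand", m)]]
    ostrand <- pairs[[paste0("strand", other)]]
    flag <- FLAG_PAIRED + FLAG_PROPER +
      ifelse(strand == "-", FLAG_REVERSE, 0L) +
      ifelse(ostrand == "-", FLAG_MREVERSE, 0L) +
      if (m == 1) FLAG_FIRST else FLAG_LAST
    seq <- pairs[[paste0("seq", m)]]
    qual <- pairs[[paste0("qual", m)]]
    minus <- strand == "-"
    seq[minus] <- revcomp(seq[minus])
    qual[minus] <- str_rev(qual[minus])
    cg <- pairs[[paste0("cigar", m)]]
    pos <- pairs[[paste0("pos", m)]]
    opos <- pairs[[paste0("pos", other)]]
    chrom <- pairs[[paste0("chrom", m)]]
    ochrom <- pairs[[paste0("chrom", other)]]
    rnext <- ifelse(ochrom == chrom, "=", ochrom)
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
            pairs$qname, as.integer(flag), chrom, as.integer(pos) + 1L,
            as.integer(pairs[[paste0("mq", m)]]), cg, rnext,
            as.integer(opos) + 1L, seq, qual)
  }
  body <- character(0)
  if (nrow(pairs) > 0) {
    body <- as.vector(rbind(rec(1, 2), rec(2, 1)))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_sam_pairs
#' @return `read_sam_pairs()` returns the pair table (read orientation) plus
#'   the `@SQ` lengths as attribute `seq_lengths`.
#' @export
read_sam_pairs <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  if (length(body) == 0L) {
    out <- empty_pair_table()
    attr(out, "seq_lengths") <- stats::setNames(ln, sn)
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- vapply(f, length, 0L)
  if (any(nf < 11L))
    stop("SAM parse error: record with fewer than 11 fields at body line ",
         which(nf < 11L)[1])
  g <- function(i) vapply(f, `[[`, "", i)
  d <- data.frame(qname = g(1), flag = as.integer(g(2)), chrom = g(3),
                  pos = as.integer(g(4)) - 1L, mq = as.integer(g(5)),
                  cigar = g(6), seq = g(10), qual = g(11),
                  stringsAsFactors = FALSE)
  minus <- bitwAnd(d$flag, FLAG_REVERSE) > 0L
  d$strand <- ifelse(minus, "-", "+")
  d$seq[minus] <- revcomp(d$seq[minus])
  d$qual[minus] <- str_rev(d$qual[minus])
  first <- bitwAnd(d$flag, FLAG_FIRST) > 0L
  d1 <- d[first, ]; d2 <- d[!first, ]
  d2 <- d2[match(d1$qname, d2$qname), ]
  if (any(is.na(d2$qname))) stop("SAM pairing error: unmatched mate records")
  out <- data.frame(qname = d1$qname,
                    chrom1 = d1$chrom, pos1 = d1$pos, strand1 = d1$strand,
                    mq1 = d1$mq, cigar1 = d1$cigar, seq1 = d1$seq,
                    qual1 = d1$qual,
                    chrom2 = d2$chrom, pos2 = d2$pos, strand2 = d2$strand,
                    mq2 = d2$mq, cigar2 = d2$cigar, seq2 = d2$seq,
                    qual2 = d2$qual,
                    stringsAsFactors = FALSE)
  attr(out, "seq_lengths") <- stats::setNames(ln, sn)
  out
}

empty_pair_table <- function() {
  data.frame(qname = character(0),
             chrom1 = character(0), pos1 = integer(0),
             strand1 = character(0), mq1 = integer(0), cigar1 = character(0),
             seq1 = character(0), qual1 = character(0),
             chrom2 = character(0), pos2 = integer(0),
             strand2 = character(0), mq2 = integer(0), cigar2 = character(0),
             seq2 = character(0), qual2 = character(0),
             stringsAsFactors = FALSE)
}

#' Write collapsed read segments as SAM
#'
#' After mate-overlap collapsing each surviving read is a single
#' fully-aligned segment; records are emitted sorted by coordinate with
#' all-match CIGARs.
#'
#' @param segments data frame with columns `qname`, `mate`, `chrom`, `start`
#'   (0-based), `seq`, `qual` (reference orientation), `strand`, `mq`.
#' @inheritParams write_sam_pairs
#' @export
write_sam_segments <- function(segments, path, seq_lengths,
                               comments = character(0)) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                   as.integer(seq_lengths)),
           if (length(comments)) paste0("@CO\t", comments))
  s <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  body <- character(0)
  if (nrow(s) > 0) {
    flag <- ifelse(s$strand == "-", FLAG_REVERSE, 0L)
    seq <- s$seq; qual <- s$qual
    minus <- s$strand == "-"
    seq[minus] <- revcomp(seq[minus])
    qual[minus] <- str_rev(qual[minus])
    body <- sprintf("%s/%d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                    s$qname, as.integer(s$mate), as.integer(flag), s$chrom,
                    as.integer(s$start) + 1L, as.integer(s$mq),
                    nchar(s$seq), seq, qual)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_sam_segments
#' @return `read_sam_segments()` returns the segment data frame.
#' @export
read_sam_segments <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L)
    return(data.frame(qname = character(0), mate = integer(0),
                      chrom = character(0), start = integer(0),
                      seq = character(0), qual = character(0),
                      strand = character(0), mq = integer(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(body, "\t", fixed = TRUE)
  g <- function(i) vapply(f, `[[`, "", i)
  qn <- g(1)
  flag <- as.integer(g(2))
  minus <- bitwAnd(flag, FLAG_REVERSE) > 0L
  seq <- g(10); qual <- g(11)
  seq[minus] <- revcomp(seq[minus])
  qual[minus] <- str_rev(qual[minus])
  data.frame(qname = sub("/[12]$", "", qn),
             mate = as.integer(sub("^.*/", "", qn)),
             chrom = g(3), start = as.integer(g(4)) - 1L,
             seq = seq, qual = qual,
             strand = ifelse(minus, "-", "+"), mq = as.integer(g(5)),
             stringsAsFactors = FALSE)
}

# ---- VCF subset ------------------------------------------------------------

#' Write genotype calls as a VCF subset
#'
#' Emits the columns CHROM POS ID REF ALT QUAL FILTER INFO FORMAT and one
#' sample column carrying GT. QUAL is the Phred-scaled consensus quality.
#' Homozygous-reference calls are emitted as `ALT = "."` records when
#' `all_sites = TRUE`, otherwise skipped.
#'
#' @param calls a `genotype_calls` data frame (see [call_genotypes()]).
#' @param path output path.
#' @param sample sample name for the genotype column.
#' @param all_sites include confident homozygous-reference calls.
#' @export
write_vcf_calls <- function(calls, path, sample = "SAMPLE", all_sites = TRUE) {
  a1 <- substr(calls$genotype, 1, 1)
  a2 <- substr(calls$genotype, 3, 3)
  is_ref <- a1 == calls$ref & a2 == calls$ref
  x <- calls[all_sites | !is_ref, , drop = FALSE]
  a1 <- substr(x$genotype, 1, 1); a2 <- substr(x$genotype, 3, 3)
  alts <- mapply(function(r, b1, b2) {
    u <- setdiff(unique(c(b1, b2)), r)
    if (length(u) == 0) "." else paste(u, collapse = ",")
  }, x$ref, a1, a2, USE.NAMES = FALSE)
  gt <- mapply(function(r, alt, b1, b2) {
    al <- c(r, strsplit(alt, ",", fixed = TRUE)[[1]])
    paste(match(b1, al) - 1L, match(b2, al) - 1L, sep = "/")
  }, x$ref, alts, a1, a2, USE.NAMES = FALSE)
  if (nrow(x) == 0) gt <- character(0)
  lines <- c("##fileformat=VCFv4.2",
             sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s",
                     sample),
             sprintf("%s\t%d\t.\t%s\t%s\t%.0f\tPASS\tDP=%d\tGT\t%s",
                     x$chrom, as.integer(x$pos) + 1L, x$ref, alts, x$qc,
                     as.integer(x$depth), gt))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vcf_calls
#' @return `read_vcf_calls()` returns a data frame with columns `chrom`,
#'   `pos` (0-based), `ref`, `genotype` ("X/Y", alleles sorted), `qc`,
#'   `depth`.
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), genotype = character(0),
                      qc = numeric(0), depth = integer(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(body, "\t", fixed = TRUE)
  g <- function(i) vapply(f, `[[`, "", i)
  ref <- g(4); alt <- g(5); gtf <- g(10)
  geno <- mapply(function(r, a, gt) {
    al <- c(r, if (a != ".") strsplit(a, ",", fixed = TRUE)[[1]])
    ix <- as.integer(strsplit(sub(":.*$", "", gt), "[/|]")[[1]]) + 1L
    paste(sort(al[ix]), collapse = "/")
  }, ref, alt, gtf, USE.NAMES = FALSE)
  dp <- suppressWarnings(as.integer(sub("^.*DP=([0-9]+).*$", "\\1", g(8))))
  data.frame(chrom = g(1), pos = as.integer(g(2)) - 1L, ref = ref,
             genotype = geno, qc = as.numeric(g(6)), depth = dp,
             stringsAsFactors = FALSE)
}
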