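# Lane-level processing: adapter clipping, proper-pair classification,
# pair mapping quality, PCR-duplicate removal, probe-overlap + mapping
# quality filtering, mate-overlap collapsing, and on-target base counting.

#' Default lane-processing configuration
#'
#' All thresholds of the lane pipeline in one list. The defaults reproduce
#' the reference settings: maximum proper-pair span 1,000 bp (inclusive),
#' at least 20 bases of probe overlap per read, pairs kept only at the
#' aligner's maximum mapping quality of 60, and collapsed base qualities
#' capped at 60.
#'
#' @param max_span maximum outer span of a proper pair (bases, inclusive).
#' @param min_probe_overlap minimum aligned bases of read/probe overlap.
#' @param required_mq the pair mapping quality required at the probe filter
#'   (equality, not a lower bound: only uniquely placed pairs at the
#'   aligner's maximum are used).
#' @param quality_cap cap for recalibrated base qualities after collapsing.
#' @param clip_min_overlap minimum mutual-overlap evidence (bases) for
#'   adapter clipping.
#' @param clip_max_mismatch maximum mismatch fraction tolerated in the
#'   mutual overlap.
#' @return a `lane_config` list.
#' @export
lane_config <- function(max_span = 1000, min_probe_overlap = 20,
                        required_mq = 60, quality_cap = 60,
                        clip_min_overlap = 10, clip_max_mismatch = 0.1) {
  stopifnot(max_span > 0, min_probe_overlap >= 1, required_mq >= 0,
            quality_cap > 0, clip_min_overlap >= 5,
            clip_max_mismatch >= 0, clip_max_mismatch < 1)
  structure(list(max_span = max_span, min_probe_overlap = min_probe_overlap,
                 required_mq = required_mq, quality_cap = quality_cap,
                 clip_min_overlap = clip_min_overlap,
                 clip_max_mismatch = clip_max_mismatch),
            class = "lane_config")
}

#' Clip adapter read-through from short-insert pairs
#'
#' For each pair, the two reads are aligned against each other after
#' complementing one of them (gapless scan over candidate insert lengths).
#' A candidate insert length `L` is accepted when the implied mutual
#' overlap is at least `min_overlap` bases with at most a `max_mismatch_rate`
#' fraction of mismatches; when `L` is shorter than the read length the
#' flanking bases are additionally checked against the adapters. Among
#' accepted candidates the one with the longest overlap (then the shortest
#' insert) wins. If the winning `L` is shorter than the read length, both
#' reads (and their qualities) are truncated to `L` bases; otherwise the
#' pair is returned unchanged ("no clip" is a valid outcome).
#'
#' @param seq1,qual1,seq2,qual2 character vectors (read orientation); all
#'   reads must share one read length.
#' @param adapter1,adapter2 adapter sequences used for the flanking check.
#' @param min_overlap minimum overlap evidence in bases (>= 5).
#' @param max_mismatch_rate maximum tolerated mismatch fraction.
#' @param adapter_check_len flanking bases compared against the adapter
#'   (0 disables the check).
#' @return data frame with clipped `seq1`, `qual1`, `seq2`, `qual2`,
#'   `insert_len` (inferred insert length, NA when no overlap was found)
#'   and `clipped` (logical).
#' @export
clip_adapters <- function(seq1, qual1, seq2, qual2,
                          adapter1 = ADAPTER_R1, adapter2 = ADAPTER_R2,
                          min_overlap = 10, max_mismatch_rate = 0.1,
                          adapter_check_len = 8) {
  stopifnot(min_overlap >= 5)
  n <- length(seq1)
  out <- data.frame(seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
                    insert_len = NA_integer_, clipped = FALSE,
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  R <- unique(c(nchar(seq1), nchar(seq2)))
  if (length(R) != 1)
    stop("clip_adapters() expects a uniform read length")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  M1 <- seq_matrix(seq1)
  M2c <- matrix(comp[seq_matrix(seq2)], nrow = n)
  A1 <- strsplit(paste0(adapter1, strrep("A", R)), "")[[1]]
  A2 <- strsplit(paste0(adapter2, strrep("A", R)), "")[[1]]
  best_w <- integer(n)
  best_L <- rep(NA_integer_, n)
  for (L in seq(min_overlap, 2 * R - min_overlap)) {
    i0 <- max(1L, L - R + 1L); i1 <- min(R, L)
    w <- i1 - i0 + 1L
    if (w < min_overlap) next
    mm <- rowSums(M1[, i0:i1, drop = FALSE] !=
                    M2c[, (L - i0 + 1L):(L - i1 + 1L), drop = FALSE])
    ok <- mm <= floor(max_mismatch_rate * w)
    if (L < R && adapter_check_len > 0 && any(ok)) {
      flen <- min(adapter_check_len, R - L)
      fcols <- (L + 1L):(L + flen)
      mmA <- rowSums(M1[, fcols, drop = FALSE] !=
                       matrix(A1[seq_len(flen)], n, flen, byrow = TRUE)) +
        rowSums(seq_matrix(seq2)[, fcols, drop = FALSE] !=
                  matrix(A2[seq_len(flen)], n, flen, byrow = TRUE))
      ok <- ok & (mmA <= ceiling(max_mismatch_rate * 2 * flen))
    }
    upd <- ok & (w > best_w)
    if (any(upd)) {
      best_w[upd] <- w
      best_L[upd] <- L
    }
  }
  out$insert_len <- best_L
  do_clip <- !is.na(best_L) & best_L < R
  if (any(do_clip)) {
    out$seq1[do_clip] <- substr(seq1[do_clip], 1, best_L[do_clip])
    out$qual1[do_clip] <- substr(qual1[do_clip], 1, best_L[do_clip])
    out$seq2[do_clip] <- substr(seq2[do_clip], 1, best_L[do_clip])
    out$qual2[do_clip] <- substr(qual2[do_clip], 1, best_L[do_clip])
    out$clipped[do_clip] <- TRUE
  }
  out
}

#' Classify read pairs as proper or improper
#'
#' A pair is proper when both mates are mapped to the same reference
#' sequence, the mates are oriented towards each other with the
#' forward-strand mate leftmost, and the outer span is at most `max_span`
#' bases (inclusive: a span of exactly `max_span` is proper).
#'
#' @param pairs pair table (see [read_sam_pairs()]).
#' @param max_span maximum outer span in bases.
#' @return character vector: `"proper"` or `"improper:<reason>"` with
#'   reasons `unmapped`, `different-chrom`, `wrong-orientation`, `span`.
#' @export
classify_pair <- function(pairs, max_span = 1000) {
  n <- nrow(pairs)
  out <- rep("proper", n)
  len1 <- cigar_aligned_len(pairs$cigar1)
  len2 <- cigar_aligned_len(pairs$cigar2)
  e1 <- pairs$pos1 + len1
  e2 <- pairs$pos2 + len2
  span <- pmax(e1, e2) - pmin(pairs$pos1, pairs$pos2)
  unmapped <- is.na(pairs$pos1) | is.na(pairs$pos2) |
    pairs$chrom1 == "*" | pairs$chrom2 == "*"
  diff_chrom <- !unmapped & pairs$chrom1 != pairs$chrom2
  fwd_pos <- ifelse(pairs$strand1 == "+", pairs$pos1, pairs$pos2)
  rev_pos <- ifelse(pairs$strand1 == "+", pairs$pos2, pairs$pos1)
  bad_orient <- !unmapped & !diff_chrom &
    (pairs$strand1 == pairs$strand2 | fwd_pos > rev_pos)
  bad_span <- !unmapped & !diff_chrom & !bad_orient & span > max_span
  out[bad_span] <- "improper:span"
  out[bad_orient] <- "improper:wrong-orientation"
  out[diff_chrom] <- "improper:different-chrom"
  out[unmapped] <- "improper:unmapped"
  out
}

#' Mapping quality of a read pair
#'
#' The pair as a whole is assigned the minimum of its two mate mapping
#' qualities: a pair is only as reliably placed as its worse mate.
#'
#' @param q1,q2 Phred-scaled mate mapping qualities in `[0, 60]`.
#' @return element-wise minimum.
#' @export
pair_mapping_quality <- function(q1, q2) {
  stopifnot(all(q1 >= 0), all(q2 >= 0))
  pmin(q1, q2)
}

# Outer coordinates of each pair (0-based half-open).
pair_outer <- function(pairs) {
  len1 <- cigar_aligned_len(pairs$cigar1)
  len2 <- cigar_aligned_len(pairs$cigar2)
  list(start = pmin(pairs$pos1, pairs$pos2),
       end = pmax(pairs$pos1 + len1, pairs$pos2 + len2))
}

#' Remove PCR duplicate pairs
#'
#' Two independently captured molecules essentially never share both outer
#' alignment coordinates, so pairs mapping to identical coordinates are PCR
#' copies of one original insert. One representative is retained per
#' (reference, outer start, outer end, orientation) key: the pair with the
#' highest summed base quality, ties broken by input order. Orientation is
#' part of the key because an opposite-orientation coincidence is not a PCR
#' copy.
#'
#' @param pairs pair table of proper pairs.
#' @return the retained pairs, with attribute `removed` (count).
#' @export
remove_duplicates <- function(pairs) {
  if (nrow(pairs) == 0) {
    attr(pairs, "removed") <- 0L
    return(pairs)
  }
  outer <- pair_outer(pairs)
  key <- paste(pairs$chrom1, outer$start, outer$end, pairs$strand1)
  sumq <- vapply(seq_len(nrow(pairs)), function(i) {
    sum(utf8ToInt(pairs$qual1[i])) + sum(utf8ToInt(pairs$qual2[i]))
  }, 0) - 33 * (nchar(pairs$qual1) + nchar(pairs$qual2))
  ord <- order(key, -sumq, seq_len(nrow(pairs)))
  keep_ord <- !duplicated(key[ord])
  keep <- sort(ord[keep_ord])
  out <- pairs[keep, , drop = FALSE]
  attr(out, "removed") <- nrow(pairs) - length(keep)
  out
}

# Per-mate probe overlap test (>= min_overlap aligned bases for each mate).
pair_probe_overlap_ok <- function(pairs, probes, min_overlap = 20) {
  len1 <- cigar_aligned_len(pairs$cigar1)
  len2 <- cigar_aligned_len(pairs$cigar2)
  ov1 <- interval_overlap_bases(pairs$chrom1, pairs$pos1, pairs$pos1 + len1,
                                probes)
  ov2 <- interval_overlap_bases(pairs$chrom2, pairs$pos2, pairs$pos2 + len2,
                                probes)
  ov1 >= min_overlap & ov2 >= min_overlap
}

#' Filter pairs on probe overlap and mapping quality
#'
#' Retains a pair only if its pair mapping quality equals `required_mq`
#' (only uniquely placed pairs at the aligner's maximum are used) and each
#' mate overlaps the probe interval set by at least `min_overlap` aligned
#' bases. Reads are kept whole once the overlap criterion is met; bases
#' outside the probes are not trimmed.
#'
#' @param pairs pair table.
#' @param probes probe `interval_set`.
#' @param min_overlap minimum per-mate overlap in bases.
#' @param required_mq required pair mapping quality (equality).
#' @return the retained pairs, with attributes `on_probe` (count of pairs
#'   passing the overlap criterion regardless of mapping quality) and
#'   `removed` (count dropped).
#' @export
probe_filter <- function(pairs, probes, min_overlap = 20, required_mq = 60) {
  ok_ov <- pair_probe_overlap_ok(pairs, probes, min_overlap)
  ok_mq <- pair_mapping_quality(pairs$mq1, pairs$mq2) == required_mq
  out <- pairs[ok_ov & ok_mq, , drop = FALSE]
  attr(out, "on_probe") <- sum(ok_ov)
  attr(out, "removed") <- nrow(pairs) - nrow(out)
  out
}

# Convert a (possibly clipped) pair table to reference-oriented aligned
# mates: sequence/quality strings in reference orientation, restricted to
# the aligned (non-soft-clipped) bases.
align_pairs <- function(pairs) {
  cvt <- function(m) {
    cg <- pairs[[paste0("cigar", m)]]
    alen <- cigar_aligned_len(cg)
    seq <- pairs[[paste0("seq", m)]]
    qual <- pairs[[paste0("qual", m)]]
    keep <- pmin(nchar(seq), alen)
    seq <- substr(seq, 1, keep)
    qual <- substr(qual, 1, keep)
    strand <- pairs[[paste0("strand", m)]]
    minus <- strand == "-"
    seq[minus] <- revcomp(seq[minus])
    qual[minus] <- str_rev(qual[minus])
    # an over-clipped minus-strand read loses its reference-left bases
    start <- pairs[[paste0("pos", m)]] + ifelse(minus, alen - keep, 0L)
    list(start = start, len = keep, seq = seq, qual = qual,
         strand = strand, indel = cigar_has_indel(cg))
  }
  m1 <- cvt(1); m2 <- cvt(2)
  data.frame(qname = pairs$qname, chrom = pairs$chrom1,
             s1 = m1$start, len1 = m1$len, strand1 = m1$strand,
             seq1 = m1$seq, q1 = m1$qual, indel1 = m1$indel, mq1 = pairs$mq1,
             s2 = m2$start, len2 = m2$len, strand2 = m2$strand,
             seq2 = m2$seq, q2 = m2$qual, indel2 = m2$indel, mq2 = pairs$mq2,
             stringsAsFactors = FALSE)
}

#' Collapse overlapping mates of each pair
#'
#' Where the two mates of a pair align over a common reference segment, the
#' overlapping bases of one mate are removed so that no reference base
#' receives more than one observation from the same pair, and the retained
#' bases are recalibrated: where the mates agreed the qualities add (capped
#' at `quality_cap`); where they disagreed the higher-quality base is kept
#' at the quality difference. The mate with the lower summed base quality
#' in the overlap is trimmed (3' side; ties trim mate 2); a mate whose
#' aligned span is contained in the other's is trimmed entirely. Reads
#' whose CIGAR contains insertions or deletions are dropped (read-level,
#' not pair-level).
#'
#' @param aligned reference-oriented pair table from the lane pipeline
#'   (internally produced; see [run_lane()]).
#' @param quality_cap Phred cap for recalibrated qualities.
#' @return a segment table: one row per retained read with columns `qname`,
#'   `mate`, `chrom`, `start`, `seq`, `qual`, `strand`, `mq`.
#' @export
collapse_pairs <- function(aligned, quality_cap = 60) {
  seg <- function(m, rows) {
    a <- aligned[rows, , drop = FALSE]
    data.frame(qname = a$qname, mate = rep.int(m, nrow(a)), chrom = a$chrom,
               start = a[[paste0("s", m)]], seq = a[[paste0("seq", m)]],
               qual = a[[paste0("q", m)]], strand = a[[paste0("strand", m)]],
               mq = a[[paste0("mq", m)]], stringsAsFactors = FALSE)
  }
  n <- nrow(aligned)
  if (n == 0) return(seg(1, integer(0)))
  keep1 <- !aligned$indel1 & aligned$len1 > 0
  keep2 <- !aligned$indel2 & aligned$len2 > 0
  e1 <- aligned$s1 + aligned$len1
  e2 <- aligned$s2 + aligned$len2
  ov_s <- pmax(aligned$s1, aligned$s2)
  ov_e <- pmin(e1, e2)
  has_ov <- keep1 & keep2 & ov_e > ov_s
  out1 <- seg(1, which(keep1 & !has_ov))
  out2 <- seg(2, which(keep2 & !has_ov))
  ov_idx <- which(has_ov)
  extra <- vector("list", length(ov_idx))
  for (k in seq_along(ov_idx)) {
    i <- ov_idx[k]
    os <- ov_s[i]; oe <- ov_e[i]
    q1v <- utf8ToInt(aligned$q1[i]) - 33L
    q2v <- utf8ToInt(aligned$q2[i]) - 33L
    i1 <- (os - aligned$s1[i] + 1L):(oe - aligned$s1[i])
    i2 <- (os - aligned$s2[i] + 1L):(oe - aligned$s2[i])
    contained1 <- aligned$s1[i] >= aligned$s2[i] & e1[i] <= e2[i]
    contained2 <- aligned$s2[i] >= aligned$s1[i] & e2[i] <= e1[i]
    trim2 <- if (contained1 && !contained2) FALSE
      else if (contained2 && !contained1) TRUE
      else sum(q2v[i2]) <= sum(q1v[i1])
    kmate <- if (trim2) 1L else 2L
    tmate <- if (trim2) 2L else 1L
    kq <- if (trim2) q1v else q2v
    tq <- if (trim2) q2v else q1v
    ki <- if (trim2) i1 else i2
    ti <- if (trim2) i2 else i1
    kseq <- strsplit(aligned[[paste0("seq", kmate)]][i], "")[[1]]
    tseq <- strsplit(aligned[[paste0("seq", tmate)]][i], "")[[1]]
    agree <- kseq[ki] == tseq[ti]
    newq <- kq[ki]
    newb <- kseq[ki]
    newq[agree] <- pmin(kq[ki][agree] + tq[ti][agree], quality_cap)
    if (any(!agree)) {
      d <- which(!agree)
      t_wins <- tq[ti][d] > kq[ki][d]
      newb[d][t_wins] <- tseq[ti][d][t_wins]
      newq[d] <- abs(kq[ki][d] - tq[ti][d])
    }
    kseq[ki] <- newb
    kq[ki] <- newq
    # trimmed mate keeps its bases outside the retained mate's span
    ks <- aligned[[paste0("s", kmate)]][i]
    ke <- ks + length(kseq)
    ts_ <- aligned[[paste0("s", tmate)]][i]
    te <- ts_ + length(tseq)
    rows <- list(data.frame(
      qname = aligned$qname[i], mate = kmate, chrom = aligned$chrom[i],
      start = ks, seq = paste(kseq, collapse = ""),
      qual = intToUtf8(kq + 33L),
      strand = aligned[[paste0("strand", kmate)]][i],
      mq = aligned[[paste0("mq", kmate)]][i], stringsAsFactors = FALSE))
    if (ts_ < ks) {  # left remainder of the trimmed mate
      w <- ks - ts_
      rows <- c(rows, list(data.frame(
        qname = aligned$qname[i], mate = tmate, chrom = aligned$chrom[i],
        start = ts_, seq = paste(tseq[1:w], collapse = ""),
        qual = intToUtf8(tq[1:w] + 33L),
        strand = aligned[[paste0("strand", tmate)]][i],
        mq = aligned[[paste0("mq", tmate)]][i], stringsAsFactors = FALSE)))
    }
    if (te > ke) {  # right remainder of the trimmed mate
      w <- te - ke
      idx <- (length(tseq) - w + 1L):length(tseq)
      rows <- c(rows, list(data.frame(
        qname = aligned$qname[i], mate = tmate, chrom = aligned$chrom[i],
        start = ke, seq = paste(tseq[idx], collapse = ""),
        qual = intToUtf8(tq[idx] + 33L),
        strand = aligned[[paste0("strand", tmate)]][i],
        mq = aligned[[paste0("mq", tmate)]][i], stringsAsFactors = FALSE)))
    }
    extra[[k]] <- do.call(rbind, rows)
  }
  out <- rbind(out1, out2, do.call(rbind, extra))
  out[order(out$chrom, out$start, out$qname, out$mate), , drop = FALSE]
}

#' Run the lane-level pipeline
#'
#' Applies, in order: (1) adapter read-through clipping; (2) pair mapping
#' quality assignment (minimum of the mates); (3) proper-pair filtering;
#' (4) PCR duplicate removal; (5) probe-overlap and mapping-quality
#' filtering; (6) mate-overlap collapsing and removal of indel-bearing
#' reads; (7) counting of bases falling within the intended target.
#'
#' @param input a `sim_lane`, a list with a `pairs` table (see
#'   [read_lane()]), or a path to a SAM file of aligned pairs.
#' @param design a `capture_design`, or a list with `probes` and `target`
#'   `interval_set`s.
#' @param config a [lane_config()].
#' @return a `lane_result`: list with `segments` (collapsed read segments),
#'   `stats` (a `lane_stats` object), and `seq_lengths`.
#' @export
run_lane <- function(input, design, config = lane_config()) {
  if (is.character(input)) input <- read_lane(input)
  pairs <- input$pairs
  seq_lens <- input$seq_lengths %||% attr(pairs, "seq_lengths")
  n_input <- nrow(pairs)

  # step 1: adapter clipping
  if (n_input > 0) {
    cl <- clip_adapters(pairs$seq1, pairs$qual1, pairs$seq2, pairs$qual2,
                        min_overlap = config$clip_min_overlap,
                        max_mismatch_rate = config$clip_max_mismatch)
    pairs$seq1 <- cl$seq1; pairs$qual1 <- cl$qual1
    pairs$seq2 <- cl$seq2; pairs$qual2 <- cl$qual2
    n_clipped <- sum(cl$clipped)
  } else n_clipped <- 0L

  # steps 2-3: pair mapping quality; proper pairs
  cls <- classify_pair(pairs, max_span = config$max_span)
  reasons <- table(cls)
  proper <- pairs[cls == "proper", , drop = FALSE]

  # step 4: PCR duplicates
  dedup <- remove_duplicates(proper)
  n_dup <- attr(dedup, "removed")

  # step 5: probe overlap + mapping quality
  flt <- probe_filter(dedup, design$probes,
                      min_overlap = config$min_probe_overlap,
                      required_mq = config$required_mq)
  n_on_probe <- attr(flt, "on_probe")

  # step 6: collapse
  aligned <- align_pairs(flt)
  segments <- collapse_pairs(aligned, quality_cap = config$quality_cap)

  # step 7: bases on target
  bases_on_target <- if (nrow(segments) > 0) {
    sum(interval_overlap_bases(segments$chrom, segments$start,
                               segments$start + nchar(segments$seq),
                               design$target))
  } else 0
  outer <- pair_outer(flt)
  stats <- structure(list(
    counts = c(input = n_input, clipped = n_clipped,
               proper = nrow(proper), after_dedup = nrow(dedup),
               duplicates_removed = n_dup, on_probe_proper = n_on_probe,
               after_probe_mq = nrow(flt), segments = nrow(segments)),
    improper_reasons = reasons[names(reasons) != "proper"],
    proper_total = nrow(dedup),
    on_probe_proper = n_on_probe,
    bases_on_target = bases_on_target,
    insert_lengths = outer$end - outer$start),
    class = "lane_stats")
  structure(list(segments = segments, stats = stats,
                 seq_lengths = seq_lens),
            class = "lane_result")
}

#' @export
print.lane_stats <- function(x, ...) {
  cat("lane_stats:\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  cat(sprintf("  %-18s %.0f\n", "bases_on_target", x$bases_on_target))
  invisible(x)
}

#' Write lane statistics as TSV
#'
#' @param stats a `lane_stats` object.
#' @param path output path.
#' @export
write_lane_stats <- function(stats, path) {
  d <- data.frame(metric = c(names(stats$counts), "bases_on_target",
                             "mean_insert"),
                  value = c(unname(stats$counts), stats$bases_on_target,
                            if (length(stats$insert_lengths))
                              mean(stats$insert_lengths) else NA))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a lane result as a filtered SAM file
#'
#' Unmapped and filtered reads are excluded; filtering provenance is
#' recorded in `@CO` header lines.
#'
#' @param result a `lane_result` from [run_lane()].
#' @param path output SAM path.
#' @param config the `lane_config` used (recorded in the header).
#' @export
write_lane_result <- function(result, path, config = lane_config()) {
  prov <- sprintf(
    "excap lane filter: max_span=%d min_probe_overlap=%d required_mq=%d quality_cap=%d",
    config$max_span, config$min_probe_overlap, config$required_mq,
    config$quality_cap)
  write_sam_segments(result$segments, path, result$seq_lengths,
                     comments = prov)
}
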