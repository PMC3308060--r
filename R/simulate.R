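# Synthetic capture-experiment generator with known truth. Every downstream
# module (lane filtering, calling, metrics, concordance) is validated against
# lanes produced here, where the true genotypes, duplicate structure,
# on/off-probe provenance and planted base errors are all recorded.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Simulate a reference genome
#'
#' Draws i.i.d. bases with a configurable GC content. The realized GC
#' fraction concentrates around the request (binomially) and is within about
#' two percentage points for chromosomes of 10 kb and more.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bases).
#' @param gc_fraction target GC content in (0, 1); default 0.41, a typical
#'   mammalian value.
#' @param seed integer seed; the result is fully determined by
#'   `(chrom_lengths, gc_fraction, seed)`.
#' @return a `sim_genome`: list with `sequences` (named character vector of
#'   chromosome strings) and `seed`.
#' @export
simulate_genome <- function(chrom_lengths, gc_fraction = 0.41, seed = 1L) {
  stopifnot(length(chrom_lengths) >= 1, gc_fraction > 0, gc_fraction < 1)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (any(chrom_lengths < 1))
    stop("chromosome lengths must be at least 1 base")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  seqs <- with_seed(seed, {
    vapply(as.integer(chrom_lengths), function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE, prob = p), collapse = "")
    }, "")
  })
  names(seqs) <- names(chrom_lengths)
  structure(list(sequences = seqs, seed = as.integer(seed)),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d sequence(s), %s bases total\n",
              length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ",")))
  invisible(x)
}

seq_lengths <- function(genome) {
  vapply(genome$sequences, nchar, 0L)
}

#' Plant diploid single-nucleotide variants
#'
#' Each genome base independently becomes a variant site with probability
#' `snv_rate`. A site is heterozygous (ref/alt) with probability
#' `het_fraction`, otherwise homozygous alternate; heterozygous alternate
#' alleles are phased onto one of the two haplotypes at random. The
#' alternate allele is the transition partner of the reference with
#' probability `transition_prob` (default 2/3, i.e. expected Ts/Tv of 2),
#' otherwise one of the two transversions.
#'
#' @param genome a `sim_genome`.
#' @param snv_rate per-base variant probability.
#' @param het_fraction fraction of variant sites that are heterozygous.
#' @param transition_prob probability that the alternate allele is a
#'   transition.
#' @param seed integer seed.
#' @return a `diploid_truth` data frame with columns `chrom`, `pos`
#'   (0-based), `ref`, `alt`, `genotype` ("het" or "hom"), `hap` (1 or 2 for
#'   het sites, NA for hom).
#' @export
plant_variants <- function(genome, snv_rate, het_fraction = 0.6,
                           transition_prob = 2 / 3, seed = 1L) {
  stopifnot(snv_rate >= 0, snv_rate <= 1,
            het_fraction >= 0, het_fraction <= 1,
            transition_prob >= 0, transition_prob <= 1)
  transition_of <- c(A = "G", C = "T", G = "A", T = "C")
  out <- with_seed(seed, {
    rows <- lapply(names(genome$sequences), function(ch) {
      s <- genome$sequences[[ch]]
      L <- nchar(s)
      pos <- which(stats::runif(L) < snv_rate) - 1L
      if (length(pos) == 0L) return(NULL)
      ref <- substring(s, pos + 1, pos + 1)
      is_ts <- stats::runif(length(pos)) < transition_prob
      alt <- character(length(pos))
      alt[is_ts] <- transition_of[ref[is_ts]]
      # transversion: pick one of the two non-transition, non-ref bases
      if (any(!is_ts)) {
        alt[!is_ts] <- vapply(which(!is_ts), function(i) {
          cand <- setdiff(DNA_BASES, c(ref[i], transition_of[ref[i]]))
          cand[sample.int(2L, 1L)]
        }, "")
      }
      het <- stats::runif(length(pos)) < het_fraction
      hap <- ifelse(het, sample(c(1L, 2L), length(pos), replace = TRUE),
                    NA_integer_)
      data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                 genotype = ifelse(het, "het", "hom"), hap = hap,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genotype = character(0), hap = integer(0),
                      stringsAsFactors = FALSE)
  structure(out, seed = as.integer(seed),
            class = c("diploid_truth", "data.frame"))
}

# Truth genotype string ("X/Y", alleles sorted) at a variant row.
truth_genotype_string <- function(truth) {
  ifelse(truth$genotype == "het",
         paste(pmin(truth$ref, truth$alt), pmax(truth$ref, truth$alt),
               sep = "/"),
         paste(truth$alt, truth$alt, sep = "/"))
}

#' Design a capture experiment
#'
#' Places non-overlapping exon-like target features on the genome and tiles
#' probes over them. Probes extend `probe_margin` bases into the flanks of
#' each targeted feature, emulating kits that place probes next to as well
#' as within the target of interest. A configurable fraction of target
#' features carries no probes at all, emulating genes present in the
#' annotation but absent from a kit's design.
#'
#' @param genome a `sim_genome`.
#' @param n_targets number of target features.
#' @param target_length_mean,target_length_sd normal target-length model
#'   (bases), truncated to `[min_target_length, max_target_length]`. The
#'   default mean of 150 bp matches a typical exon length.
#' @param min_target_length,max_target_length truncation bounds.
#' @param probe_margin bases of probe extension into each flank (default
#'   100, so a typical 200 bp insert hybridizing at a feature edge is still
#'   recoverable).
#' @param untargeted_fraction fraction of features (in expectation) left
#'   without probes.
#' @param seed integer seed.
#' @return a `capture_design`: list with `target` and `probes`
#'   (`interval_set`s), `features` (per-feature data frame with `targeted`
#'   flag and gene name), `annotation` (refFlat-style single-exon gene
#'   models whose CDS is the feature trimmed to a codon multiple), and
#'   `probe_margin`.
#' @export
design_capture <- function(genome, n_targets, target_length_mean = 150,
                           target_length_sd = 50, min_target_length = 75,
                           max_target_length = 500, probe_margin = 100,
                           untargeted_fraction = 0, seed = 1L) {
  stopifnot(n_targets >= 1, untargeted_fraction >= 0, untargeted_fraction <= 1)
  lens <- seq_lengths(genome)
  edge <- probe_margin + 200  # keep features clear of chromosome ends
  with_seed(seed, {
    tl <- round(stats::rnorm(n_targets, target_length_mean, target_length_sd))
    tl <- pmin(pmax(tl, min_target_length), max_target_length)
    n_per <- stats::rmultinom(1, n_targets, prob = lens / sum(lens))[, 1]
    min_sep <- max_target_length + 2 * probe_margin + 10
    feats <- NULL
    done <- 0L
    for (ci in seq_along(lens)) {
      n_i <- n_per[ci]
      if (n_i == 0) next
      clen <- lens[ci]
      lo <- edge; hi <- clen - edge - max_target_length
      if (hi - lo < n_i * min_sep)
        stop("genome too small for the requested capture design")
      li <- tl[done + seq_len(n_i)]
      done <- done + n_i
      starts <- numeric(0)
      tries <- 0
      while (length(starts) < n_i) {
        tries <- tries + 1
        if (tries > 500 * n_i)
          stop("genome too small for the requested capture design")
        cand <- lo + floor(stats::runif(1) * (hi - lo))
        if (length(starts) == 0 || all(abs(cand - starts) >= min_sep))
          starts <- c(starts, cand)
      }
      o <- order(starts)
      feats <- rbind(feats, data.frame(
        chrom = names(lens)[ci], start = starts[o], end = starts[o] + li[o],
        stringsAsFactors = FALSE))
    }
    feats <- feats[order(feats$chrom, feats$start), , drop = FALSE]
    feats$targeted <- stats::runif(nrow(feats)) >= untargeted_fraction
    feats$gene <- sprintf("GENE%04d", seq_len(nrow(feats)))
    feats$strand <- sample(c("+", "-"), nrow(feats), replace = TRUE)
    target <- interval_set(feats$chrom, feats$start, feats$end,
                           label = "intended target")
    pf <- feats[feats$targeted, , drop = FALSE]
    probes <- if (nrow(pf) > 0) {
      interval_set(pf$chrom,
                   pmax(pf$start - probe_margin, 0),
                   pmin(pf$end + probe_margin, lens[pf$chrom]),
                   label = "probes")
    } else interval_set(label = "probes")
    cds_len <- 3 * ((feats$end - feats$start) %/% 3)
    annotation <- data.frame(
      geneName = feats$gene, name = paste0(feats$gene, ".1"),
      chrom = feats$chrom, strand = feats$strand,
      txStart = feats$start, txEnd = feats$end,
      cdsStart = feats$start, cdsEnd = feats$start + cds_len,
      exonCount = 1L,
      exonStarts = paste0(feats$start, ","),
      exonEnds = paste0(feats$end, ","),
      stringsAsFactors = FALSE)
    structure(list(target = target, probes = probes, features = feats,
                   annotation = annotation, probe_margin = probe_margin,
                   seed = as.integer(seed)),
              class = "capture_design")
  })
}

#' @export
print.capture_design <- function(x, ...) {
  cat(sprintf(paste0("capture_design: %d features (%d probed), ",
                     "target %s b, probes %s b\n"),
              nrow(x$features), sum(x$features$targeted),
              format(total_bases(x$target), big.mark = ","),
              format(total_bases(x$probes), big.mark = ",")))
  invisible(x)
}

# Standard library adapters (read-through sequence seen at the 3' end of
# short-insert reads).
ADAPTER_R1 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
ADAPTER_R2 <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"

#' Sequencing library profile
#'
#' Bundles the read length, insert-size model, error model and library
#' artifact rates used by [simulate_lane()].
#'
#' Two insert-size models are provided: `"gel"` -- a truncated normal,
#' emulating tight agarose-gel size selection (default mean 200, sd 25,
#' range 150-250 bp); and `"bead"` -- a minimum-truncated lognormal,
#' emulating the broader bead-based selection (default median ~190 bp,
#' extending from about 100 bp to beyond 300 bp).
#'
#' @param read_length read length in bases (default 76, paired-end 76-cycle
#'   chemistry).
#' @param insert one of `"gel"` or `"bead"`, or a list with `type` and the
#'   model parameters (`mean`, `sd`, `min`, `max` for gel; `meanlog`,
#'   `sdlog`, `min` for bead).
#' @param error_rate mean per-base substitution probability. Base qualities
#'   are drawn from a two-state high/low model (q35/q15) mixed so the mean
#'   error probability equals `error_rate`, and each base's realized error
#'   probability honours its assigned quality.
#' @param duplicate_rate probability that a library molecule is re-emitted
#'   as a PCR duplicate (re-sequenced with fresh errors and qualities).
#' @param off_probe_fraction fraction of pairs drawn uniformly from the
#'   non-probe genome instead of from probe-overlapping inserts.
#' @param ambiguous_rate fraction of pairs placed in (notionally) repetitive
#'   sequence and therefore reported with mapping quality 0; all other pairs
#'   are uniquely placed at mapping quality 60.
#' @param adapter1,adapter2 adapter sequences appended on read-through.
#' @return a `library_profile` list.
#' @export
library_profile <- function(read_length = 76, insert = "gel",
                            error_rate = 0.005, duplicate_rate = 0.1,
                            off_probe_fraction = 0.12, ambiguous_rate = 0.02,
                            adapter1 = ADAPTER_R1, adapter2 = ADAPTER_R2) {
  if (is.character(insert)) {
    insert <- switch(match.arg(insert, c("gel", "bead")),
      gel = list(type = "gel", mean = 200, sd = 25, min = 150, max = 250),
      bead = list(type = "bead", meanlog = log(190), sdlog = 0.35, min = 100))
  }
  stopifnot(read_length > 0, insert$min > 0,
            error_rate >= 0, error_rate <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            off_probe_fraction >= 0, off_probe_fraction <= 1,
            ambiguous_rate >= 0, ambiguous_rate <= 1)
  structure(list(read_length = as.integer(read_length), insert = insert,
                 error_rate = error_rate, duplicate_rate = duplicate_rate,
                 off_probe_fraction = off_probe_fraction,
                 ambiguous_rate = ambiguous_rate,
                 adapter1 = adapter1, adapter2 = adapter2),
            class = "library_profile")
}

#' Capture-platform presets
#'
#' Convenience profiles whose off-probe fractions are parameterized from
#' published enrichment ranges for tight gel-selected libraries
#' (87.20-90.27% of proper pairs on probe) and broader bead-selected
#' libraries (69.25-71.50%).
#'
#' @param name `"nimblegen-like"` (gel inserts, off-probe 0.1126) or
#'   `"agilent-like"` (bead inserts, off-probe 0.2963).
#' @param ... overrides passed to [library_profile()].
#' @return a `library_profile`.
#' @export
capture_preset <- function(name = c("nimblegen-like", "agilent-like"), ...) {
  name <- match.arg(name)
  if (name == "nimblegen-like")
    library_profile(insert = "gel", off_probe_fraction = 1 - 0.8874, ...)
  else
    library_profile(insert = "bead", off_probe_fraction = 1 - 0.7037, ...)
}

# Draw insert lengths from the profile model.
sample_insert_lengths <- function(insert, n) {
  if (n == 0) return(integer(0))
  if (insert$type == "gel") {
    out <- round(stats::rnorm(n, insert$mean, insert$sd))
    bad <- which(out < insert$min | out > insert$max)
    while (length(bad) > 0) {
      out[bad] <- round(stats::rnorm(length(bad), insert$mean, insert$sd))
      bad <- bad[out[bad] < insert$min | out[bad] > insert$max]
    }
  } else {
    out <- round(stats::rlnorm(n, insert$meanlog, insert$sdlog))
    bad <- which(out < insert$min)
    while (length(bad) > 0) {
      out[bad] <- round(stats::rlnorm(length(bad), insert$meanlog,
                                      insert$sdlog))
      bad <- bad[out[bad] < insert$min]
    }
  }
  as.integer(out)
}

# Two-state base-quality model: returns list(q = possible qualities,
# p_low = probability of the low state). Mean error equals error_rate.
quality_model <- function(error_rate) {
  q_lo <- 15L; q_hi <- 35L
  e_lo <- unphred(q_lo); e_hi <- unphred(q_hi)
  if (error_rate == 0)
    return(list(q_lo = 40L, q_hi = 40L, p_low = 0, e_lo = 0, e_hi = 0))
  if (error_rate <= e_hi) {
    q <- as.integer(round(phred(error_rate, max_q = 40)))
    return(list(q_lo = q, q_hi = q, p_low = 0,
                e_lo = unphred(q), e_hi = unphred(q)))
  }
  if (error_rate >= e_lo) {
    q <- as.integer(round(phred(error_rate, max_q = 40)))
    return(list(q_lo = q, q_hi = q, p_low = 1,
                e_lo = unphred(q), e_hi = unphred(q)))
  }
  list(q_lo = q_lo, q_hi = q_hi, p_low = (error_rate - e_hi) / (e_lo - e_hi),
       e_lo = e_lo, e_hi = e_hi)
}

# Apply the diploid truth to the reference, returning the two haplotype
# sequences for one chromosome.
haplotype_pair <- function(refseq, truth_chr) {
  subst <- function(seq, pos0, alt) {
    if (length(pos0) == 0) return(seq)
    r <- charToRaw(seq)
    r[pos0 + 1] <- charToRaw(paste(alt, collapse = ""))
    rawToChar(r)
  }
  hom <- truth_chr$genotype == "hom"
  h1 <- subst(refseq, truth_chr$pos[hom | truth_chr$hap == 1L],
              truth_chr$alt[hom | truth_chr$hap == 1L])
  h2 <- subst(refseq, truth_chr$pos[hom | truth_chr$hap == 2L],
              truth_chr$alt[hom | truth_chr$hap == 2L])
  list(h1, h2)
}

#' Simulate one sequencing lane of a capture experiment
#'
#' Draws `n_pairs` original library molecules: with probability
#' `off_probe_fraction` an insert is placed uniformly in the non-probe
#' genome (neither mate touches a probe), otherwise it is placed so that
#' both mates overlap a probe by at least `capture_overlap` bases (the
#' hybrid-capture recovery model; see the package vignette). Each molecule
#' is assigned a haplotype, a strand for read 1, and unique outer
#' coordinates among originals, so PCR duplicates -- re-emissions of a
#' molecule with freshly sampled errors and qualities -- are exactly
#' identifiable by their coordinates. Inserts shorter than the read length
#' read through into the adapters. Mapping quality is 60 for uniquely
#' placed pairs and 0 for the `ambiguous_rate` fraction emulating
#' repetitive placements.
#'
#' @param genome a `sim_genome`.
#' @param truth a `diploid_truth` from [plant_variants()].
#' @param design a `capture_design` from [design_capture()].
#' @param profile a `library_profile`.
#' @param n_pairs number of original molecules (duplicates are emitted on
#'   top of these).
#' @param seed integer seed.
#' @param lane_id identifier used in read names.
#' @param capture_overlap minimum per-mate probe overlap (bases) the
#'   placement model guarantees for on-probe pairs.
#' @return a `sim_lane`: list with `pairs` (read/alignment table: read
#'   sequences and qualities in read orientation plus aligner-style
#'   positions, strands, CIGARs and mapping qualities), `truth` (per-pair
#'   provenance: insert coordinates, haplotype, on-probe flag, duplicate-of,
#'   planted error positions), `seq_lengths`, `profile`, `lane_id`, `seed`.
#' @export
simulate_lane <- function(genome, truth, design, profile, n_pairs,
                          seed = 1L, lane_id = "L1", capture_overlap = 20) {
  stopifnot(n_pairs >= 1)
  lens <- seq_lengths(genome)
  if (profile$insert$min >= min(lens))
    stop("insert model minimum exceeds a chromosome length")
  R <- profile$read_length
  pf <- design$features[design$features$targeted, , drop = FALSE]
  probe_start <- pmax(pf$start - design$probe_margin, 0)
  probe_end <- pmin(pf$end + design$probe_margin, lens[pf$chrom])
  probes <- design$probes

  with_seed(seed, {
    L <- sample_insert_lengths(profile$insert, n_pairs)
    off <- stats::runif(n_pairs) < profile$off_probe_fraction
    chrom <- character(n_pairs)
    s <- integer(n_pairs)

    # on-probe placement: both mates overlap the probe by >= capture_overlap
    on_idx <- which(!off)
    if (length(on_idx) > 0) {
      if (nrow(pf) == 0) stop("design has no probed features")
      k <- capture_overlap
      pi <- sample.int(nrow(pf), length(on_idx), replace = TRUE,
                       prob = probe_end - probe_start)
      Li <- L[on_idx]
      m <- pmin(R, Li)
      plen <- probe_end[pi] - probe_start[pi]
      too_long <- Li > plen - 2 * k + m
      Li[too_long] <- (plen - 2 * k + m)[too_long]
      m <- pmin(R, Li)
      s_lo <- probe_start[pi] + k - m
      s_hi <- probe_end[pi] - k - Li + m
      s_lo <- pmax(s_lo, 0)
      s_hi <- pmin(s_hi, lens[pf$chrom[pi]] - Li)
      si <- s_lo + floor(stats::runif(length(on_idx)) * (s_hi - s_lo + 1))
      chrom[on_idx] <- pf$chrom[pi]
      s[on_idx] <- as.integer(si)
      L[on_idx] <- Li
    }

    # off-probe placement: uniform, rejected if the insert touches a probe
    off_idx <- which(off)
    if (length(off_idx) > 0) {
      draw_off <- function(n, Ls) {
        ci <- sample.int(length(lens), n, replace = TRUE,
                         prob = lens / sum(lens))
        st <- floor(stats::runif(n) * (lens[ci] - Ls))
        list(chrom = names(lens)[ci], s = as.integer(st))
      }
      d <- draw_off(length(off_idx), L[off_idx])
      repeat {
        cand <- interval_overlaps_any(d$chrom, d$s, d$s + L[off_idx], probes)
        if (!any(cand)) break
        redo <- which(cand)
        nd <- draw_off(length(redo), L[off_idx][redo])
        d$chrom[redo] <- nd$chrom
        d$s[redo] <- nd$s
      }
      chrom[off_idx] <- d$chrom
      s[off_idx] <- d$s
    }

    # unique outer coordinates for original molecules
    strand1 <- sample(c("+", "-"), n_pairs, replace = TRUE)
    key <- paste(chrom, s, s + L, strand1)
    dup_key <- duplicated(key)
    while (any(dup_key)) {
      redo <- which(dup_key)
      s[redo] <- pmax(s[redo] + sample(c(-5L, -3L, 3L, 5L),
                                       length(redo), replace = TRUE), 0L)
      s[redo] <- pmin(s[redo], as.integer(lens[chrom[redo]]) - L[redo])
      key <- paste(chrom, s, s + L, strand1)
      dup_key <- duplicated(key)
    }

    hap <- sample(c(1L, 2L), n_pairs, replace = TRUE)
    ambiguous <- stats::runif(n_pairs) < profile$ambiguous_rate
    mq <- ifelse(ambiguous, 0L, 60L)

    # PCR duplicates: re-emissions of original molecules
    is_dup_src <- stats::runif(n_pairs) < profile$duplicate_rate
    dup_src <- which(is_dup_src)
    idx_all <- c(seq_len(n_pairs), dup_src)
    n_all <- length(idx_all)
    qname <- sprintf("%s:%06d", lane_id, seq_len(n_pairs))
    qname_all <- c(qname,
                   if (length(dup_src)) paste0(qname[dup_src], ":d"))
    dup_of <- c(rep(NA_character_, n_pairs), qname[dup_src])

    # render error-free fragments per (chrom, haplotype)
    frag <- character(n_all)
    ch_all <- chrom[idx_all]; s_all <- s[idx_all]; L_all <- L[idx_all]
    hap_all <- hap[idx_all]
    for (ch in unique(ch_all)) {
      hp <- haplotype_pair(genome$sequences[[ch]],
                           truth[truth$chrom == ch, , drop = FALSE])
      for (h in 1:2) {
        sel <- which(ch_all == ch & hap_all == h)
        if (length(sel))
          frag[sel] <- substring(hp[[h]], s_all[sel] + 1, s_all[sel] + L_all[sel])
      }
    }

    m_all <- pmin(R, L_all)
    pad <- function(read, adapter) {
      # adapter read-through; padded with A if the adapter itself runs out
      need <- pmax(R - nchar(read), 0L)
      fill <- substring(paste0(adapter, strrep("A", R)), 1, need)
      ifelse(need > 0, paste0(read, fill), read)
    }
    fwd_read <- pad(substr(frag, 1, m_all), profile$adapter1)
    rev_read <- pad(revcomp(substring(frag, L_all - m_all + 1, L_all)),
                    profile$adapter2)
    str1 <- strand1[idx_all]
    read1 <- ifelse(str1 == "+", fwd_read, rev_read)
    read2 <- ifelse(str1 == "+", rev_read, fwd_read)

    # planted errors + two-state qualities, independently per emitted read
    qm <- quality_model(profile$error_rate)
    apply_errors <- function(reads) {
      mat <- seq_matrix(reads)
      n <- length(reads)
      low <- matrix(stats::runif(n * R) < qm$p_low, n, R)
      qv <- matrix(qm$q_hi, n, R); qv[low] <- qm$q_lo
      ev <- matrix(qm$e_hi, n, R); ev[low] <- qm$e_lo
      err <- matrix(stats::runif(n * R) < ev, n, R)
      ei <- which(err)
      if (length(ei) > 0) {
        cur <- match(mat[ei], DNA_BASES) - 1L
        mat[ei] <- DNA_BASES[((cur + sample.int(3L, length(ei),
                                                replace = TRUE)) %% 4L) + 1L]
      }
      qchar <- matrix(strsplit(intToUtf8(33:108), "")[[1]][c(qv) + 1L], n, R)
      errpos <- rep("", n)
      if (length(ei) > 0) {
        rc <- arrayInd(ei, dim(err))
        sp <- split(rc[, 2], rc[, 1])
        errpos[as.integer(names(sp))] <-
          vapply(sp, function(v) paste(sort(v), collapse = ","), "")
      }
      list(seq = matrix_seq(mat), qual = matrix_seq(qchar), err = errpos)
    }
    e1 <- apply_errors(read1)
    e2 <- apply_errors(read2)

    # aligner-style records: positions/CIGARs of the insert-derived bases
    clip <- R - m_all
    cig_fwd <- ifelse(clip > 0, paste0(m_all, "M", clip, "S"),
                      paste0(m_all, "M"))
    cig_rev <- ifelse(clip > 0, paste0(clip, "S", m_all, "M"),
                      paste0(m_all, "M"))
    pos_fwd <- s_all
    pos_rev <- s_all + L_all - m_all
    pos1 <- ifelse(str1 == "+", pos_fwd, pos_rev)
    pos2 <- ifelse(str1 == "+", pos_rev, pos_fwd)
    cigar1 <- ifelse(str1 == "+", cig_fwd, cig_rev)
    cigar2 <- ifelse(str1 == "+", cig_rev, cig_fwd)
    mq_all <- mq[idx_all]

    pairs <- data.frame(
      qname = qname_all,
      chrom1 = ch_all, pos1 = pos1, strand1 = str1, mq1 = mq_all,
      cigar1 = cigar1, seq1 = e1$seq, qual1 = e1$qual,
      chrom2 = ch_all, pos2 = pos2, strand2 = ifelse(str1 == "+", "-", "+"),
      mq2 = mq_all, cigar2 = cigar2, seq2 = e2$seq, qual2 = e2$qual,
      stringsAsFactors = FALSE)
    truth_table <- data.frame(
      qname = qname_all, chrom = ch_all, insert_start = s_all,
      insert_len = L_all, strand1 = str1, hap = hap_all,
      on_probe = !off[idx_all], mq = mq_all, dup_of = dup_of,
      err1 = e1$err, err2 = e2$err, stringsAsFactors = FALSE)

    structure(list(pairs = pairs, truth = truth_table, seq_lengths = lens,
                   profile = profile, lane_id = lane_id,
                   seed = as.integer(seed)),
              class = "sim_lane")
  })
}

#' @export
print.sim_lane <- function(x, ...) {
  cat(sprintf(paste0("sim_lane '%s': %d read pairs (%d duplicates, ",
                     "%.1f%% off-probe)\n"),
              x$lane_id, nrow(x$pairs), sum(!is.na(x$truth$dup_of)),
              100 * mean(!x$truth$on_probe)))
  invisible(x)
}

# Does each query interval overlap the interval set at all?
interval_overlaps_any <- function(chrom, start, end, set) {
  out <- logical(length(chrom))
  irl <- .as_irl(set)
  for (ch in intersect(unique(chrom), names(irl))) {
    sel <- chrom == ch
    q <- IRanges::IRanges(start = start[sel] + 1, end = end[sel])
    out[sel] <- IRanges::overlapsAny(q, irl[[ch]])
  }
  out
}

# Aligned bases of each query read overlapping the interval set (total).
interval_overlap_bases <- function(chrom, start, end, set) {
  out <- integer(length(chrom))
  irl <- .as_irl(set)
  for (ch in intersect(unique(chrom), names(irl))) {
    sel <- which(chrom == ch)
    q <- IRanges::IRanges(start = start[sel] + 1, end = end[sel])
    hits <- IRanges::findOverlaps(q, irl[[ch]])
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      q[qi], irl[[ch]][S4Vectors::subjectHits(hits)]))
    agg <- rowsum(ov, qi)
    out[sel[as.integer(rownames(agg))]] <- agg[, 1]
  }
  out
}

#' Write a simulated lane to disk
#'
#' Emits the lane as FASTQ (mates 1 and 2, read orientation, Phred+33),
#' truth alignments as SAM, and the per-pair provenance table as TSV.
#'
#' @param lane a `sim_lane`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (defaults to the lane id).
#' @return named character vector of the paths written.
#' @export
write_lane <- function(lane, dir, prefix = lane$lane_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  write_pair_fastq(lane$pairs, p("_R1.fastq"), p("_R2.fastq"))
  write_sam_pairs(lane$pairs, p("_truth.sam"), lane$seq_lengths,
                  comments = sprintf("sim_lane %s seed=%d", lane$lane_id,
                                     lane$seed))
  utils::write.table(lane$truth, p("_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c(r1 = p("_R1.fastq"), r2 = p("_R2.fastq"), sam = p("_truth.sam"),
    truth = p("_truth.tsv"))
}

#' @rdname write_lane
#' @param sam,r1,r2 paths to the truth SAM and (optionally) the two FASTQ
#'   files; when FASTQs are given their read IDs are checked against the
#'   alignments.
#' @return `read_lane()` returns a list with `pairs` and `seq_lengths`
#'   usable by [run_lane()].
#' @export
read_lane <- function(sam, r1 = NULL, r2 = NULL) {
  pairs <- read_sam_pairs(sam)
  if (!is.null(r1)) {
    fq <- read_pair_fastq(r1, r2)
    if (!identical(sort(fq$qname), sort(pairs$qname)))
      stop("read IDs differ between FASTQ and alignments")
  }
  list(pairs = pairs, seq_lengths = attr(pairs, "seq_lengths"))
}
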