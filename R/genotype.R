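# Sample-level processing: lane merging, pileup over the target, and
# Bayesian diploid consensus genotype calling with Phred-scaled consensus
# qualities.

#' Prior model for diploid genotypes
#'
#' Prior probability mass for the genotype classes at a site, relative to
#' the reference base: heterozygous reference/non-reference sites share
#' `het`, homozygous non-reference sites share `hom_alt`, heterozygous
#' sites with two non-reference alleles share `het_nonref`; the remaining
#' mass is homozygous reference.
#'
#' @param het total prior for the three ref/alt heterozygous genotypes.
#' @param hom_alt total prior for the three homozygous-alternate genotypes.
#' @param het_nonref total prior for the three non-reference heterozygous
#'   genotypes.
#' @return a `prior_model` list.
#' @export
prior_model <- function(het = 1e-3, hom_alt = 5e-4, het_nonref = 1e-6) {
  stopifnot(het > 0, hom_alt > 0, het_nonref > 0,
            het + hom_alt + het_nonref < 1)
  structure(list(het = het, hom_alt = hom_alt, het_nonref = het_nonref),
            class = "prior_model")
}

# The 10 unordered diploid genotypes over A,C,G,T in lexicographic order.
GENO_A1 <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L)
GENO_A2 <- c(1L, 2L, 3L, 4L, 2L, 3L, 4L, 3L, 4L, 4L)
GENO_LABELS <- paste(c("A", "C", "G", "T")[GENO_A1],
                     c("A", "C", "G", "T")[GENO_A2], sep = "/")
# column of the homozygous genotype for each reference base index
HOMREF_COL <- c(1L, 5L, 8L, 10L)

#' Merge filtered lanes of one sample
#'
#' Multiset union of the lanes' collapsed read segments, normalized to
#' coordinate order. Lanes must agree on their reference sequences.
#'
#' @param lanes list of `lane_result` objects (or segment tables).
#' @return a list with `segments` and `seq_lengths`, usable wherever a
#'   single `lane_result` is.
#' @export
merge_lanes <- function(lanes) {
  stopifnot(length(lanes) >= 1)
  segs <- lapply(lanes, function(l) if (is.data.frame(l)) l else l$segments)
  lens <- lapply(lanes, function(l) if (is.data.frame(l)) NULL else l$seq_lengths)
  lens <- lens[!vapply(lens, is.null, TRUE)]
  if (length(lens) > 1) {
    for (l in lens[-1]) if (!identical(l, lens[[1]]))
      stop("lanes were aligned against different reference sequences")
  }
  out <- do.call(rbind, segs)
  out <- out[order(out$chrom, out$start, out$qname, out$mate), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(segments = out,
                 seq_lengths = if (length(lens)) lens[[1]] else NULL),
            class = "lane_result")
}

# Map genome positions to indices of the flattened target (NA off target).
# Returns a function of (chrom, pos0) plus the target row context.
target_index <- function(target) {
  target <- as_interval_set(target)
  if (total_bases(target) == 0) stop("empty target")
  width <- target$end - target$start
  offset <- cumsum(c(0, width[-length(width)]))
  list(target = target, offset = offset, total = sum(width),
       map = function(chrom, pos) {
         idx <- rep(NA_real_, length(pos))
         for (ch in unique(chrom)) {
           rows <- which(target$chrom == ch)
           if (length(rows) == 0) next
           sel <- which(chrom == ch)
           k <- findInterval(pos[sel], target$start[rows])
           ok <- k >= 1 & pos[sel] < target$end[rows][pmax(k, 1)]
           idx[sel[ok]] <- offset[rows][k[ok]] + pos[sel][ok] -
             target$start[rows][k[ok]] + 1
         }
         idx
       })
}

# Reference base at every flattened-target position.
target_ref_bases <- function(genome, tix) {
  t <- tix$target
  parts <- substring(genome$sequences[t$chrom], t$start + 1, t$end)
  strsplit(paste(parts, collapse = ""), "")[[1]]
}

# Expand segments to per-base observations over the target:
# data.frame(tidx, base (1..4), qual).
pileup_observations <- function(segments, tix) {
  if (nrow(segments) == 0)
    return(data.frame(tidx = numeric(0), base = integer(0), qual = integer(0)))
  lens <- nchar(segments$seq)
  rid <- rep.int(seq_len(nrow(segments)), lens)
  pos <- sequence(lens) - 1L + rep.int(segments$start, lens)
  base <- match(unlist(strsplit(segments$seq, "", fixed = TRUE),
                       use.names = FALSE), DNA_BASES)
  qual <- unlist(lapply(segments$qual, function(s) utf8ToInt(s) - 33L),
                 use.names = FALSE)
  tidx <- tix$map(rep.int(segments$chrom, lens), pos)
  keep <- !is.na(tidx) & !is.na(base)
  data.frame(tidx = tidx[keep], base = base[keep], qual = qual[keep])
}

#' Call consensus genotypes over a target
#'
#' A naive-Bayes diploid caller: at each target position with at least one
#' observation, per-base error probabilities are taken from the (collapsed)
#' Phred qualities, observations are treated as independent draws from the
#' two alleles of the true genotype, and the posterior is computed over all
#' ten unordered diploid genotypes with priors from [prior_model()]. The
#' maximum-posterior genotype is reported with consensus quality
#' `q_c = -10 log10 P(called genotype incorrect)`, capped at 255; ties are
#' broken towards homozygous reference, then lexicographically. Only calls
#' with `q_c >= min_quality` are emitted.
#'
#' @param alignments a `lane_result` (or merged lanes, or a segment table).
#' @param reference a `sim_genome` or path to a FASTA file.
#' @param target `interval_set` of positions to genotype.
#' @param priors a [prior_model()].
#' @param min_quality minimum consensus quality of emitted calls (default
#'   50, i.e. at most a 1e-5 probability of an incorrect genotype).
#' @param details also return per-position posterior matrices (for
#'   diagnostics; memory-heavy on large targets).
#' @return a `genotype_calls` data frame: `chrom`, `pos` (0-based), `ref`,
#'   `genotype` ("X/Y", alleles sorted), `qc`, `depth`. With
#'   `details = TRUE`, a list with `calls` (unfiltered), `posterior`,
#'   `tidx`.
#' @export
call_genotypes <- function(alignments, reference, target,
                           priors = prior_model(), min_quality = 50,
                           details = FALSE) {
  segments <- if (is.data.frame(alignments)) alignments
    else alignments$segments
  genome <- if (is.character(reference)) read_genome_fasta(reference)
    else reference
  tix <- target_index(target)
  refbase <- target_ref_bases(genome, tix)
  if (length(refbase) != tix$total)
    stop("reference does not cover the target")
  obs <- pileup_observations(segments, tix)
  if (any(!refbase[obs$tidx] %in% DNA_BASES))
    stop("observation at a position without a reference base")

  upos <- sort(unique(obs$tidx))
  if (length(upos) == 0) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), genotype = character(0),
                      qc = numeric(0), depth = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("genotype_calls", "data.frame")
    return(if (details) list(calls = out, posterior = NULL, tidx = tix)
           else out)
  }
  pidx <- match(obs$tidx, upos)
  np <- length(upos)
  e <- unphred(obs$qual)
  e <- pmax(e, 1e-10)
  l_match <- log1p(-e)
  l_half <- log(0.5 * (1 - e) + e / 6)
  l_miss <- log(e / 3)
  ll <- matrix(0, np, 10L)
  for (g in 1:10) {
    mcount <- (obs$base == GENO_A1[g]) + (obs$base == GENO_A2[g])
    val <- ifelse(mcount == 2L, l_match, ifelse(mcount == 1L, l_half, l_miss))
    agg <- rowsum(val, pidx)
    ll[as.integer(rownames(agg)), g] <- agg[, 1]
  }
  r <- match(refbase[upos], DNA_BASES)
  lp <- matrix(0, np, 10L)
  p0 <- 1 - priors$het - priors$hom_alt - priors$het_nonref
  for (g in 1:10) {
    nref <- (GENO_A1[g] == r) + (GENO_A2[g] == r)
    hom <- GENO_A1[g] == GENO_A2[g]
    lp[, g] <- ifelse(hom & nref == 2L, log(p0),
                 ifelse(hom, log(priors$hom_alt / 3),
                   ifelse(nref == 1L, log(priors$het / 3),
                          log(priors$het_nonref / 3))))
  }
  post <- ll + lp
  M <- post[cbind(seq_len(np), max.col(post, ties.method = "first"))]
  ex <- exp(post - M)
  tot <- rowSums(ex)
  best <- max.col(post, ties.method = "first")
  # tie-break towards homozygous reference
  hr <- HOMREF_COL[r]
  hr_is_max <- post[cbind(seq_len(np), hr)] == M
  best[hr_is_max] <- hr[hr_is_max]
  p_err <- (tot - ex[cbind(seq_len(np), best)]) / tot
  qc <- ifelse(p_err <= 0, 255, pmin(-10 * log10(p_err), 255))
  depth <- tabulate(pidx, np)

  t <- tix$target
  width <- t$end - t$start
  row_of <- findInterval(upos, cumsum(c(0, width[-length(width)])) + 1)
  genome_pos <- t$start[row_of] + (upos - 1 -
    cumsum(c(0, width[-length(width)]))[row_of])
  calls <- data.frame(
    chrom = t$chrom[row_of], pos = as.integer(genome_pos),
    ref = refbase[upos], genotype = GENO_LABELS[best],
    qc = qc, depth = depth, stringsAsFactors = FALSE)
  if (details) {
    posterior <- ex / tot
    colnames(posterior) <- GENO_LABELS
    return(list(calls = structure(calls,
                                  class = c("genotype_calls", "data.frame")),
                posterior = posterior, tidx = tix))
  }
  out <- calls[calls$qc >= min_quality, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("genotype_calls", "data.frame"))
}

#' @export
print.genotype_calls <- function(x, ...) {
  a1 <- substr(x$genotype, 1, 1); a2 <- substr(x$genotype, 3, 3)
  nvar <- sum(a1 != x$ref | a2 != x$ref)
  cat(sprintf("genotype_calls: %d calls (%d variant), mean q_c %.1f\n",
              nrow(x), nvar, if (nrow(x)) mean(x$qc) else NA))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}
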