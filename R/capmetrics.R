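# Capture performance metrics: per-base depth over the target, coverage
# breadth and uniformity, enrichment score, insert-size distributions,
# replicate depth correlation, and the raw-data-for-depth rule of thumb.

#' Per-base depth of coverage over a target
#'
#' Counts collapsed read bases at every target position (a read pair
#' contributes at most one observation per position after mate-overlap
#' collapsing).
#'
#' @param alignments a `lane_result`, merged lanes, or a segment table.
#' @param target `interval_set`.
#' @return a `depth_track`: list with `target`, `depth` (integer vector
#'   over the flattened target, one entry per target base).
#' @export
depth_track <- function(alignments, target) {
  segments <- if (is.data.frame(alignments)) alignments
    else alignments$segments
  tix <- target_index(target)
  depth <- integer(tix$total)
  if (nrow(segments) > 0) {
    lens <- nchar(segments$seq)
    pos <- sequence(lens) - 1L + rep.int(segments$start, lens)
    tidx <- tix$map(rep.int(segments$chrom, lens), pos)
    tidx <- tidx[!is.na(tidx)]
    depth <- tabulate(tidx, tix$total)
  }
  structure(list(target = tix$target, depth = depth),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track: %d target bases, mean depth %.2f\n",
              length(x$depth), mean(x$depth)))
  invisible(x)
}

#' Coverage breadth, mean depth and uniformity histogram
#'
#' Breadth at depth `d` is the fraction of target bases covered by at
#' least `d` collapsed read bases. Mean depth alone is a poor summary of a
#' capture experiment -- half a target at 10x and half at 30x has the same
#' mean as a uniform 20x but half the 20x breadth -- which is why breadth
#' at the thresholds (default 1x and 20x, the depth used to support
#' reliable variant detection) is reported alongside the full depth
#' histogram.
#'
#' @param track a `depth_track`.
#' @param thresholds positive, sorted depth thresholds.
#' @param max_bin last histogram bin (open-ended; default 300).
#' @return a `coverage_report`: list with `mean_depth`, `breadth` (named
#'   fraction per threshold), `bases_ge` (base counts per threshold),
#'   `histogram` (counts of target bases at depth 0..max_bin, last bin
#'   open), `target_bases`.
#' @export
coverage_report <- function(track, thresholds = c(1, 20), max_bin = 300) {
  if (length(track$depth) == 0) stop("empty target")
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  n <- length(track$depth)
  bases_ge <- vapply(thresholds, function(d) sum(track$depth >= d), 0)
  hist <- tabulate(pmin(track$depth, max_bin) + 1L, nbins = max_bin + 1L)
  names(hist) <- c(0:(max_bin - 1), paste0(max_bin, "+"))
  structure(list(
    mean_depth = sum(track$depth) / n,
    breadth = stats::setNames(bases_ge / n, paste0("ge", thresholds)),
    bases_ge = stats::setNames(bases_ge, paste0("ge", thresholds)),
    histogram = hist,
    target_bases = n), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage_report: %d target bases, mean depth %.2f\n",
              x$target_bases, x$mean_depth))
  for (nm in names(x$breadth))
    cat(sprintf("  breadth @%s: %.4f\n", sub("ge", "", nm), x$breadth[[nm]]))
  invisible(x)
}

#' Enrichment score of a lane
#'
#' The fraction of properly mapped read pairs that also map to probe
#' regions -- the principal measure of how specifically the capture
#' recovered the designed regions.
#'
#' @param stats a `lane_stats` from [run_lane()].
#' @return fraction in `[0, 1]`.
#' @export
enrichment_score <- function(stats) {
  if (stats$proper_total == 0)
    stop("enrichment score undefined: no proper pairs")
  stats$on_probe_proper / stats$proper_total
}

#' Insert-size distribution of proper pairs
#'
#' Insert length is the outer span of a proper pair. The histogram is
#' binned at 1 bp; `normalize = TRUE` rescales counts to a probability
#' distribution.
#'
#' @param x a `lane_stats` (uses the surviving pairs' insert lengths) or a
#'   numeric vector of insert lengths.
#' @param normalize return densities instead of counts.
#' @return an `insert_size_distribution`: list with `histogram` (data frame
#'   `length`/`count` or `density`), `mode`, `quantiles` (5%, 25%, 50%,
#'   75%, 95%), `n`.
#' @export
insert_size_distribution <- function(x, normalize = FALSE) {
  lens <- if (inherits(x, "lane_stats")) x$insert_lengths else x
  if (length(lens) < 1) stop("no proper pairs")
  tab <- table(lens)
  len <- as.integer(names(tab))
  cnt <- as.integer(tab)
  hist <- if (normalize)
    data.frame(length = len, density = cnt / sum(cnt))
  else data.frame(length = len, count = cnt)
  structure(list(histogram = hist,
                 mode = len[which.max(cnt)],
                 quantiles = stats::quantile(lens, c(.05, .25, .5, .75, .95)),
                 n = length(lens)),
            class = "insert_size_distribution")
}

#' @export
print.insert_size_distribution <- function(x, ...) {
  cat(sprintf("insert sizes: n=%d, mode=%d, median=%.0f\n",
              x$n, x$mode, x$quantiles[["50%"]]))
  invisible(x)
}

#' Correlation of depth between two tracks
#'
#' Per-base correlation of coverage depth over a shared target,
#' zero-depth bases included (used to compare replicate captures).
#'
#' @param a,b `depth_track`s over the identical target.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation coefficient.
#' @export
depth_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(as.data.frame(a$target), as.data.frame(b$target)))
    stop("depth tracks cover different targets")
  if (stats::sd(a$depth) == 0 || stats::sd(b$depth) == 0)
    stop("depth correlation undefined for a constant track")
  stats::cor(a$depth, b$depth, method = method)
}

#' Raw sequence needed for a given whole-genome depth
#'
#' The no-waste model: raw gigabases = genome size (Gb) times desired
#' fold-coverage, assuming no data are wasted or non-specific. Useful as
#' the optimistic baseline when comparing whole-genome sequencing against
#' targeted capture.
#'
#' @param depth desired fold-coverage (>= 0).
#' @param genome_size_gb genome size in gigabases (default 3).
#' @return gigabases of raw sequence.
#' @examples
#' raw_data_for_depth(20)    # 60 Gb
#' raw_data_for_depth(65.2)  # 195.6 Gb
#' @export
raw_data_for_depth <- function(depth, genome_size_gb = 3) {
  stopifnot(all(depth >= 0))
  depth * genome_size_gb
}

#' Export a depth track as BedGraph
#'
#' @param track a `depth_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  t <- track$target
  width <- t$end - t$start
  chrom <- rep.int(t$chrom, width)
  pos <- sequence(width) - 1L + rep.int(t$start, width)
  d <- track$depth
  # run-length encode consecutive equal-depth positions
  brk <- c(TRUE, d[-1] != d[-length(d)] | pos[-1] != pos[-length(pos)] + 1 |
             chrom[-1] != chrom[-length(chrom)])
  starts <- which(brk)
  ends <- c(starts[-1] - 1L, length(d))
  lines <- sprintf("%s\t%d\t%d\t%d", chrom[starts], pos[starts],
                   pos[ends] + 1L, d[starts])
  writeLines(c("track type=bedGraph", lines), path)
  invisible(path)
}
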