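#' Genomic interval sets
#'
#' An `interval_set` is the unit of all target/probe/gene arithmetic in this
#' package: a set of genomic bases represented as sorted, pairwise-disjoint
#' intervals in 0-based half-open (BED) coordinates. Construction always
#' normalizes: intervals are sorted by (chrom, start) and overlapping or
#' abutting intervals are merged, so two sets covering the same bases compare
#' equal regardless of how they were fragmented on input. SAM-style 1-based
#' positions are converted at the I/O boundary only.
#'
#' @param chrom character vector of chromosome names (non-empty strings,
#'   compared as exact strings -- no "chr" aliasing).
#' @param start,end integer-like vectors; 0-based inclusive start, exclusive
#'   end, with `0 <= start < end`.
#' @param label free-text name for the set (e.g. "intended target").
#' @return An object of class `interval_set`: a data frame with columns
#'   `chrom`, `start`, `end` and attribute `label`.
#' @examples
#' ts <- interval_set(c("chr1", "chr1"), c(0, 5), c(10, 15))
#' total_bases(ts)  # 15: the two intervals merge
#' @export
interval_set <- function(chrom = character(0), start = integer(0),
                         end = integer(0), label = "") {
  if (length(chrom) == 1L && length(start) > 1L)
    chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chromosome names must be non-empty strings")
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must not be NA")
  if (any(start < 0) || any(start >= end))
    stop("intervals require 0 <= start < end")
  x <- normalize_intervals(data.frame(chrom = chrom, start = start, end = end,
                                      stringsAsFactors = FALSE))
  structure(x, label = label, class = c("interval_set", "data.frame"))
}

# Sort by (chrom, start) and merge overlapping/abutting intervals.
# Idempotent; adjacent intervals merge because the semantics are base sets.
normalize_intervals <- function(x) {
  if (nrow(x) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  parts <- lapply(split(x[c("start", "end")], x$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(start = IRanges::start(r) - 1, end = IRanges::end(r))
  })
  out <- do.call(rbind, parts)
  out <- data.frame(chrom = rep(names(parts), vapply(parts, nrow, 0L)),
                    start = out$start, end = out$end,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

as_interval_set <- function(x, label = "") {
  if (inherits(x, "interval_set")) return(x)
  interval_set(x$chrom, x$start, x$end, label = label)
}

#' @export
as.data.frame.interval_set <- function(x, ...) {
  data.frame(chrom = x$chrom, start = x$start, end = x$end,
             stringsAsFactors = FALSE)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set '%s': %d intervals on %d sequence(s), %s bases\n",
              attr(x, "label") %||% "", nrow(x),
              length(unique(x$chrom)),
              format(total_bases(x), big.mark = ",")))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Total number of bases in an interval set
#'
#' @param x an `interval_set`.
#' @return numeric scalar, `sum(end - start)` after normalization.
#' @export
total_bases <- function(x) {
  if (nrow(x) == 0L) return(0)
  sum(x$end - x$start)
}

# Internal: per-chromosome IRanges view (1-based closed, IRanges convention).
.as_irl <- function(x) {
  lapply(split(x[c("start", "end")], x$chrom), function(d)
    IRanges::IRanges(start = d$start + 1, end = d$end))
}

.from_chrom_ranges <- function(by_chrom, label) {
  keep <- by_chrom[vapply(by_chrom, length, 0L) > 0L]
  if (length(keep) == 0L) return(interval_set(label = label))
  interval_set(
    chrom = rep(names(keep), vapply(keep, length, 0L)),
    start = unlist(lapply(keep, IRanges::start), use.names = FALSE) - 1,
    end = unlist(lapply(keep, IRanges::end), use.names = FALSE),
    label = label
  )
}

#' Interval set operations
#'
#' `interval_intersect()` returns exactly the bases present in both sets;
#' `interval_union()` the bases in either; `complement_within()` the bases of
#' `universe` not in `a`. All results are normalized.
#'
#' @param a,b,universe `interval_set` objects.
#' @return an `interval_set`.
#' @export
interval_intersect <- function(a, b) {
  a <- as_interval_set(a); b <- as_interval_set(b)
  ia <- .as_irl(a); ib <- .as_irl(b)
  common <- intersect(names(ia), names(ib))
  out <- lapply(common, function(ch) IRanges::intersect(ia[[ch]], ib[[ch]]))
  names(out) <- common
  .from_chrom_ranges(out, label = "intersection")
}

#' @rdname interval_intersect
#' @export
interval_union <- function(a, b) {
  a <- as_interval_set(a); b <- as_interval_set(b)
  interval_set(c(a$chrom, b$chrom), c(a$start, b$start), c(a$end, b$end),
               label = "union")
}

#' @rdname interval_intersect
#' @export
complement_within <- function(universe, a) {
  universe <- as_interval_set(universe); a <- as_interval_set(a)
  iu <- .as_irl(universe); ia <- .as_irl(a)
  out <- lapply(names(iu), function(ch) {
    if (ch %in% names(ia)) IRanges::setdiff(iu[[ch]], ia[[ch]]) else iu[[ch]]
  })
  names(out) <- names(iu)
  .from_chrom_ranges(out, label = "complement")
}

#' Fraction of one interval set contained in another
#'
#' The base-level containment used to compare capture designs, e.g. how much
#' of one kit's target is included in another's, or how much of a gene's CDS
#' lies inside the intended target.
#'
#' @param a,b `interval_set` objects; `a` must be non-empty.
#' @return scalar in `[0, 1]`: `total_bases(intersect(a, b)) / total_bases(a)`.
#' @export
fraction_contained <- function(a, b) {
  a <- as_interval_set(a)
  if (total_bases(a) == 0)
    stop("fraction_contained() is undefined for an empty set 'a'")
  total_bases(interval_intersect(a, b)) / total_bases(a)
}

#' Read and write BED interval files
#'
#' Reads 3+-column tab-separated BED (0-based half-open); `browser` and
#' `track` header lines and blank lines are skipped. Chromosome names are
#' taken verbatim; with `alias_chr = TRUE` bare numerals are mapped to
#' "chr"-prefixed names (an explicit opt-in, since silent aliasing hides
#' input errors). The writer emits the normalized (sorted, merged) records.
#'
#' @param path file path.
#' @param label label for the returned set (defaults to the file name).
#' @param alias_chr map "1" to "chr1" etc. when `TRUE`.
#' @return `read_bed()` returns an `interval_set`.
#' @export
read_bed <- function(path, label = basename(path), alias_chr = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(browser|track|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(interval_set(label = label))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf < 3L))
    stop("BED parse error at line ", idx[which(nf < 3L)[1]],
         ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0)
    stop("BED parse error at line ", idx[bad[1]],
         ": invalid coordinates (need integer 0 <= start < end)")
  if (alias_chr) {
    bare <- grepl("^([0-9]+|[XYM])$", chrom)
    chrom[bare] <- paste0("chr", chrom[bare])
  }
  interval_set(chrom, start, end, label = label)
}

#' @rdname read_bed
#' @param x an `interval_set` to write.
#' @export
write_bed <- function(x, path) {
  x <- as_interval_set(x)
  lines <- sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start),
                   as.integer(x$end))
  writeLines(lines, path)
  invisible(path)
}
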