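# Gene-level coverage accounting and coding-effect classification:
# refFlat gene models, per-gene targeted/genotyped percentages, and
# synonymous/non-synonymous calls for coding substitutions.

REFFLAT_COLS <- c("geneName", "name", "chrom", "strand", "txStart", "txEnd",
                  "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")

#' Read gene models from a refFlat table
#'
#' The refFlat dialect: 11 tab-separated columns (geneName, name, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds), 0-based half-open, exon lists comma-terminated. CDS exons
#' are the exon intervals clipped to `[cdsStart, cdsEnd)`. Non-coding
#' transcripts (cdsStart == cdsEnd) yield an empty CDS and are flagged
#' `coding = FALSE`; transcripts whose CDS length is not a codon multiple
#' are flagged `frame_ok = FALSE` rather than silently used.
#'
#' @param path refFlat TSV path (a header line starting with "geneName" or
#'   "#" is tolerated).
#' @return a list of `gene_model`s: each a list with `gene`, `name`,
#'   `chrom`, `strand`, `cds` (an `interval_set`), `cds_len`, `coding`,
#'   `frame_ok`.
#' @export
read_refflat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|geneName\t)", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(f, length, 0L)
  if (any(nf != 11L))
    stop("refFlat parse error at line ", which(nf != 11L)[1],
         ": expected 11 tab-separated columns, found ",
         nf[which(nf != 11L)[1]])
  lapply(seq_along(f), function(i) {
    v <- f[[i]]
    cds_s <- as.numeric(v[7]); cds_e <- as.numeric(v[8])
    ex_s <- as.numeric(strsplit(v[10], ",", fixed = TRUE)[[1]])
    ex_e <- as.numeric(strsplit(v[11], ",", fixed = TRUE)[[1]])
    if (length(ex_s) != length(ex_e) || length(ex_s) != as.integer(v[9]))
      stop("refFlat parse error at line ", i, ": exon list length mismatch")
    s <- pmax(ex_s, cds_s); e <- pmin(ex_e, cds_e)
    keep <- s < e
    cds <- if (any(keep)) interval_set(rep(v[3], sum(keep)), s[keep],
                                       e[keep], label = v[2])
      else interval_set(label = v[2])
    cds_len <- total_bases(cds)
    structure(list(gene = v[1], name = v[2], chrom = v[3], strand = v[4],
                   cds = cds, cds_len = cds_len,
                   coding = cds_len > 0,
                   frame_ok = cds_len > 0 && cds_len %% 3 == 0),
              class = "gene_model")
  })
}

#' Write gene models as refFlat
#'
#' @param annotation a refFlat-style data frame (as produced by
#'   [design_capture()]).
#' @param path output path.
#' @export
write_refflat <- function(annotation, path) {
  stopifnot(all(REFFLAT_COLS %in% names(annotation)))
  utils::write.table(annotation[REFFLAT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Union of CDS exons per gene name.
gene_cds_union <- function(models) {
  genes <- split(models, vapply(models, `[[`, "", "gene"))
  lapply(genes, function(ms) {
    parts <- do.call(rbind, lapply(ms, function(m) as.data.frame(m$cds)))
    if (is.null(parts) || nrow(parts) == 0)
      return(interval_set(label = ms[[1]]$gene))
    interval_set(parts$chrom, parts$start, parts$end,
                 label = ms[[1]]$gene)
  })
}

#' Gene-level coverage report
#'
#' For each gene (overlapping transcripts collapsed to the union of their
#' CDS exons): the coding length, the percent of coding bases included in
#' the capture target, and the percent of coding bases that received a
#' confident genotype call.
#'
#' @param models list of `gene_model`s from [read_refflat()].
#' @param target capture-target `interval_set`.
#' @param calls a `genotype_calls` data frame (confident calls; filter
#'   with `min_quality` first if needed).
#' @param min_quality consensus-quality threshold applied to `calls`.
#' @return data frame with one row per gene: `gene`, `coding_bases`,
#'   `pct_targeted`, `pct_genotyped`.
#' @export
gene_coverage_report <- function(models, target, calls, min_quality = 50) {
  stopifnot(length(models) >= 1)
  calls <- calls[calls$qc >= min_quality, , drop = FALSE]
  cds_by_gene <- gene_cds_union(models)
  call_pos <- split(calls$pos, calls$chrom)
  call_ir <- lapply(call_pos, function(p)
    IRanges::IRanges(start = p + 1, width = 1))
  rows <- lapply(names(cds_by_gene), function(g) {
    cds <- cds_by_gene[[g]]
    len <- total_bases(cds)
    if (len == 0)
      return(data.frame(gene = g, coding_bases = 0, pct_targeted = NA_real_,
                        pct_genotyped = NA_real_, stringsAsFactors = FALSE))
    n_called <- 0L
    for (ch in unique(cds$chrom)) {
      if (!ch %in% names(call_ir)) next
      sel <- cds$chrom == ch
      ir <- IRanges::IRanges(start = cds$start[sel] + 1, end = cds$end[sel])
      n_called <- n_called +
        sum(IRanges::countOverlaps(call_ir[[ch]], ir) > 0)
    }
    data.frame(gene = g, coding_bases = len,
               pct_targeted = 100 * fraction_contained(cds, target),
               pct_genotyped = 100 * n_called / len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the coding effect of a substitution
#'
#' Maps a reference-strand substitution into the CDS of a gene model
#' (reverse-complementing on minus-strand genes), substitutes the
#' alternate allele into its codon, and translates with the standard
#' genetic code. Stop gains/losses are folded into "non-synonymous".
#'
#' @param variant list or one-row data frame with `chrom`, `pos`
#'   (0-based), `ref`, `alt` (reference-strand alleles).
#' @param model a `gene_model`.
#' @param genome a `sim_genome` (or list with `sequences`).
#' @return `"synonymous"`, `"non-synonymous"` or `"non-coding"`.
#' @export
coding_effect <- function(variant, model, genome) {
  chrom <- variant$chrom; pos <- variant$pos
  refseq <- genome$sequences[[chrom]]
  if (is.null(refseq)) stop("unknown chromosome: ", chrom)
  if (substr(refseq, pos + 1, pos + 1) != variant$ref)
    stop("variant reference allele does not match the genome at ",
         chrom, ":", pos + 1)
  if (!model$coding || model$chrom != chrom) return("non-coding")
  cds <- model$cds
  inside <- cds$start <= pos & pos < cds$end
  if (!any(inside)) return("non-coding")
  # CDS coordinate on the plus strand
  width <- cds$end - cds$start
  offset <- cumsum(c(0, width[-length(width)]))
  k <- which(inside)
  cds_pos_plus <- offset[k] + (pos - cds$start[k])
  cds_seq <- paste(substring(refseq, cds$start + 1, cds$end), collapse = "")
  alt <- variant$alt
  if (model$strand == "-") {
    cds_seq <- revcomp(cds_seq)
    cds_pos <- nchar(cds_seq) - cds_pos_plus - 1
    alt <- revcomp(alt)
  } else {
    cds_pos <- cds_pos_plus
  }
  codon_i <- cds_pos %/% 3
  within <- cds_pos %% 3
  codon <- substr(cds_seq, codon_i * 3 + 1, codon_i * 3 + 3)
  if (nchar(codon) < 3) return("non-coding")  # trailing partial codon
  alt_codon <- codon
  substr(alt_codon, within + 1, within + 1) <- alt
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (identical(aa_ref, aa_alt)) "synonymous" else "non-synonymous"
}

#' Classify coding effects against a set of transcripts
#'
#' Applies [coding_effect()] to each transcript of the gene(s) overlapping
#' the variant and reports the most severe effect
#' (non-synonymous > synonymous > non-coding).
#'
#' @param variant as in [coding_effect()].
#' @param models list of `gene_model`s.
#' @param genome a `sim_genome`.
#' @return the most severe effect across transcripts.
#' @export
coding_effect_any <- function(variant, models, genome) {
  effects <- vapply(models, function(m) coding_effect(variant, m, genome), "")
  sev <- c("non-coding" = 0, "synonymous" = 1, "non-synonymous" = 2)
  names(sort(sev[unique(effects)], decreasing = TRUE))[1]
}
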