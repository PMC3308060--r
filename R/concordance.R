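# Gold-standard construction and genotype concordance metrics: percent
# genotyped, disagreement, variant and heterozygote sensitivity and false
# discovery rate, and the transition/transversion ratio.

geno_alleles <- function(genotype) {
  list(a1 = substr(genotype, 1, 1), a2 = substr(genotype, 3, 3))
}

is_variant_geno <- function(genotype, ref) {
  al <- geno_alleles(genotype)
  al$a1 != ref | al$a2 != ref
}

is_het_geno <- function(genotype) {
  al <- geno_alleles(genotype)
  al$a1 != al$a2
}

#' Build a gold standard from confident genotype calls
#'
#' Collects the positions genotyped with high confidence (default minimum
#' consensus quality 100) into a trusted reference set. The
#' `"comprehensive"` flavor keeps every confident call, which in practice
#' is mostly homozygous-reference; the `"variant_focused"` flavor keeps
#' only non-reference genotypes, emulating array-based standards that
#' assay polymorphic positions by design.
#'
#' @param calls a `genotype_calls` data frame.
#' @param min_quality minimum consensus quality for inclusion.
#' @param flavor `"comprehensive"` or `"variant_focused"`.
#' @return a `gold_standard` data frame (`chrom`, `pos`, `ref`,
#'   `genotype`) with attribute `flavor`.
#' @export
build_gold_standard <- function(calls, min_quality = 100,
                                flavor = c("comprehensive",
                                           "variant_focused")) {
  flavor <- match.arg(flavor)
  keep <- calls$qc >= min_quality
  if (flavor == "variant_focused")
    keep <- keep & is_variant_geno(calls$genotype, calls$ref)
  out <- calls[keep, c("chrom", "pos", "ref", "genotype"), drop = FALSE]
  rownames(out) <- NULL
  structure(out, flavor = flavor, class = c("gold_standard", "data.frame"))
}

#' Build a gold standard from simulated truth
#'
#' Converts a `diploid_truth` into a gold standard over a region of
#' interest. The `"variant_focused"` flavor contains the planted variant
#' positions and their genotypes; the `"comprehensive"` flavor contains
#' every region position, with homozygous-reference genotypes at
#' non-variant positions.
#'
#' @param truth a `diploid_truth` from [plant_variants()].
#' @param genome the `sim_genome` the truth was planted on.
#' @param region `interval_set` restricting the standard (e.g. the
#'   intended target).
#' @param flavor `"variant_focused"` or `"comprehensive"`.
#' @return a `gold_standard` data frame.
#' @export
truth_gold_standard <- function(truth, genome, region,
                                flavor = c("variant_focused",
                                           "comprehensive")) {
  flavor <- match.arg(flavor)
  tix <- target_index(region)
  int <- tix$map(truth$chrom, truth$pos)
  tv <- truth[!is.na(int), , drop = FALSE]
  if (flavor == "variant_focused") {
    out <- data.frame(chrom = tv$chrom, pos = tv$pos, ref = tv$ref,
                      genotype = truth_genotype_string(tv),
                      stringsAsFactors = FALSE)
  } else {
    refbase <- target_ref_bases(genome, tix)
    t <- tix$target
    width <- t$end - t$start
    out <- data.frame(
      chrom = rep.int(t$chrom, width),
      pos = sequence(width) - 1L + rep.int(t$start, width),
      ref = refbase,
      genotype = paste(refbase, refbase, sep = "/"),
      stringsAsFactors = FALSE)
    vi <- tix$map(tv$chrom, tv$pos)
    out$genotype[vi] <- truth_genotype_string(tv)
  }
  rownames(out) <- NULL
  structure(out, flavor = flavor, class = c("gold_standard", "data.frame"))
}

#' Genotype concordance against a gold standard
#'
#' Scores confident calls (consensus quality at least `min_quality`,
#' default 50) over the gold-standard positions:
#' \itemize{
#'   \item percent genotyped: gold positions that received a confident
#'     call;
#'   \item percent disagreement: called gold positions whose genotype
#'     differs from the gold genotype (called-positions denominator);
#'   \item variant sensitivity: gold positions with a variant genotype
#'     that were called as variants;
#'   \item variant FDR: variant calls over gold positions whose gold
#'     genotype is not a variant;
#'   \item heterozygote sensitivity/FDR/disagreement: the same three with
#'     "variant" replaced by "heterozygous";
#'   \item Ts/Tv of the confident variant calls (all calls, not only gold
#'     positions).
#' }
#' "Called as variant" means a confident call whose genotype contains at
#' least one non-reference allele; a heterozygote called homozygous-
#' alternate therefore counts as a detected variant but as a genotype
#' disagreement.
#'
#' @param calls a `genotype_calls` data frame.
#' @param gold a `gold_standard`.
#' @param min_quality consensus-quality threshold applied to `calls`.
#' @return a `concordance_report` list of percentages and the underlying
#'   counts.
#' @export
concordance_report <- function(calls, gold, min_quality = 50) {
  if (nrow(gold) == 0) stop("empty gold standard")
  calls <- calls[calls$qc >= min_quality, , drop = FALSE]
  key_g <- paste(gold$chrom, gold$pos)
  key_c <- paste(calls$chrom, calls$pos)
  m <- match(key_g, key_c)
  called <- !is.na(m)
  cg <- calls$genotype[m[called]]           # call genotype at gold positions
  gg <- gold$genotype[called]               # gold genotype at called positions
  gr <- gold$ref[called]
  n_gold <- nrow(gold)
  n_called <- sum(called)
  disagree <- cg != gg

  gold_var <- is_variant_geno(gold$genotype, gold$ref)
  call_var <- is_variant_geno(cg, gr)
  # sensitivity over all gold variant positions (uncalled counts as missed)
  n_gold_var <- sum(gold_var)
  n_var_detected <- sum(call_var & gold_var[called])
  n_var_calls <- sum(call_var)
  n_var_false <- sum(call_var & !is_variant_geno(gg, gr))

  gold_het <- is_het_geno(gold$genotype)
  call_het <- is_het_geno(cg)
  n_gold_het <- sum(gold_het)
  n_het_detected <- sum(call_het & gold_het[called])
  n_het_calls <- sum(call_het)
  n_het_false <- sum(call_het & !is_het_geno(gg))
  n_het_disagree <- sum(call_het & disagree)

  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tstv <- tryCatch(ts_tv_ratio(calls), error = function(e) NA_real_)
  structure(list(
    percent_genotyped = pct(n_called, n_gold),
    percent_disagreement = pct(sum(disagree), n_called),
    variant_sensitivity = pct(n_var_detected, n_gold_var),
    variant_fdr = pct(n_var_false, n_var_calls),
    het_sensitivity = pct(n_het_detected, n_gold_het),
    het_fdr = pct(n_het_false, n_het_calls),
    het_disagreement = pct(n_het_disagree, n_het_calls),
    ts_tv = tstv,
    counts = c(gold = n_gold, called = n_called, disagree = sum(disagree),
               gold_variant = n_gold_var, variant_detected = n_var_detected,
               variant_calls = n_var_calls, variant_false = n_var_false,
               gold_het = n_gold_het, het_detected = n_het_detected,
               het_calls = n_het_calls, het_false = n_het_false,
               het_disagree = n_het_disagree)),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report:\n")
  f <- function(nm, v) cat(sprintf("  %-22s %s\n", nm,
                                   ifelse(is.na(v), "NA",
                                          sprintf("%.4f", v))))
  f("percent genotyped", x$percent_genotyped)
  f("percent disagreement", x$percent_disagreement)
  f("variant sensitivity", x$variant_sensitivity)
  f("variant FDR", x$variant_fdr)
  f("het sensitivity", x$het_sensitivity)
  f("het FDR", x$het_fdr)
  f("het disagreement", x$het_disagreement)
  f("Ts/Tv", x$ts_tv)
  invisible(x)
}

#' Transition/transversion ratio of variant calls
#'
#' Transitions are A<->G and C<->T substitutions; all other substitutions
#' are transversions. Each non-reference allele of a genotype contributes
#' once (a heterozygote with two different non-reference alleles counts
#' both).
#'
#' @param calls a `genotype_calls` data frame (or any data frame with
#'   `ref` and `genotype` columns).
#' @return ratio of transition to transversion counts.
#' @export
ts_tv_ratio <- function(calls) {
  al <- geno_alleles(calls$genotype)
  # each distinct non-reference allele of a genotype contributes once
  take1 <- al$a1 != calls$ref
  take2 <- al$a2 != calls$ref & al$a2 != al$a1
  ref <- c(calls$ref[take1], calls$ref[take2])
  alt <- c(al$a1[take1], al$a2[take2])
  is_ts <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  n_tv <- sum(!is_ts)
  if (n_tv == 0) stop("Ts/Tv undefined: no transversions")
  sum(is_ts) / n_tv
}

#' Read and write gold standards as TSV
#'
#' Columns: chrom, 1-based position, reference base, genotype ("X/Y").
#'
#' @param gold a `gold_standard`.
#' @param path file path.
#' @param flavor flavor recorded on the read standard.
#' @export
write_gold_tsv <- function(gold, path) {
  d <- data.frame(chrom = gold$chrom, pos = gold$pos + 1L, ref = gold$ref,
                  genotype = gold$genotype)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gold_tsv
#' @export
read_gold_tsv <- function(path, flavor = "comprehensive") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(d$chrom), pos = d$pos - 1L,
                    ref = d$ref, genotype = d$genotype,
                    stringsAsFactors = FALSE)
  structure(out, flavor = flavor, class = c("gold_standard", "data.frame"))
}
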