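# Independent brute-force oracles. These deliberately share no code with
# the package internals: interval arithmetic is checked by enumerating
# covered bases one by one, the genotype model by direct probability
# arithmetic in linear space, concordance by explicit counting loops.

# -- interval oracles --------------------------------------------------------

# All covered bases of a raw (possibly overlapping) interval table, as
# "chrom:pos" strings.
enumerate_bases <- function(df) {
  if (nrow(df) == 0) return(character(0))
  unique(unlist(lapply(seq_len(nrow(df)), function(i) {
    if (df$end[i] <= df$start[i]) return(character(0))
    paste0(df$chrom[i], ":", seq(df$start[i], df$end[i] - 1))
  })))
}

oracle_union_bases <- function(a, b) {
  length(union(enumerate_bases(a), enumerate_bases(b)))
}

oracle_intersect_bases <- function(a, b) {
  length(intersect(enumerate_bases(a), enumerate_bases(b)))
}

oracle_diff_bases <- function(a, b) {
  length(setdiff(enumerate_bases(a), enumerate_bases(b)))
}

random_interval_table <- function(n, chroms = c("chr1", "chr2"),
                                  max_pos = 300, max_len = 40) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# -- genotype model oracle ---------------------------------------------------

# Posterior over the 10 diploid genotypes at a single pileup column,
# computed naively in linear space.
oracle_genotype_posterior <- function(bases, quals, ref,
                                      priors = prior_model()) {
  B <- c("A", "C", "G", "T")
  labels <- character(0)
  w <- numeric(0)
  for (i in 1:4) for (j in i:4) {
    g1 <- B[i]; g2 <- B[j]
    nref <- (g1 == ref) + (g2 == ref)
    pr <- if (i == j && g1 == ref)
      1 - priors$het - priors$hom_alt - priors$het_nonref
    else if (i == j) priors$hom_alt / 3
    else if (nref == 1) priors$het / 3
    else priors$het_nonref / 3
    lik <- 1
    for (k in seq_along(bases)) {
      e <- 10^(-quals[k] / 10)
      p_g1 <- if (bases[k] == g1) 1 - e else e / 3
      p_g2 <- if (bases[k] == g2) 1 - e else e / 3
      lik <- lik * (0.5 * p_g1 + 0.5 * p_g2)
    }
    labels <- c(labels, paste(g1, g2, sep = "/"))
    w <- c(w, pr * lik)
  }
  stats::setNames(w / sum(w), labels)
}

oracle_call_column <- function(bases, quals, ref, priors = prior_model()) {
  post <- oracle_genotype_posterior(bases, quals, ref, priors)
  best <- which.max(post)
  list(genotype = names(post)[best],
       qc = min(-10 * log10(max(1 - post[best], 0)), 255))
}

# -- dedup oracle ------------------------------------------------------------

# Expected retained count: one representative per coordinate/orientation
# group, by explicit grouping.
oracle_dedup_groups <- function(chrom, ostart, oend, orient) {
  length(unique(paste(chrom, ostart, oend, orient)))
}

# -- depth / breadth oracle --------------------------------------------------

# Per-position depth by looping over reads and positions.
oracle_depth <- function(segments, target_df) {
  pos_keys <- enumerate_bases(target_df)
  depth <- stats::setNames(integer(length(pos_keys)), pos_keys)
  for (i in seq_len(nrow(segments))) {
    len <- nchar(segments$seq[i])
    for (p in seq(segments$start[i], segments$start[i] + len - 1)) {
      k <- paste0(segments$chrom[i], ":", p)
      if (k %in% names(depth)) depth[k] <- depth[k] + 1L
    }
  }
  depth
}

# -- concordance oracle ------------------------------------------------------

oracle_concordance <- function(calls, gold) {
  n_gold <- nrow(gold); n_called <- 0; n_dis <- 0
  n_gvar <- 0; n_vdet <- 0; n_vcall <- 0; n_vfalse <- 0
  n_ghet <- 0; n_hdet <- 0; n_hcall <- 0; n_hfalse <- 0; n_hdis <- 0
  is_var <- function(g, r) {
    a <- strsplit(g, "/")[[1]]; any(a != r)
  }
  is_het <- function(g) {
    a <- strsplit(g, "/")[[1]]; a[1] != a[2]
  }
  for (i in seq_len(nrow(gold))) {
    gv <- is_var(gold$genotype[i], gold$ref[i])
    gh <- is_het(gold$genotype[i])
    if (gv) n_gvar <- n_gvar + 1
    if (gh) n_ghet <- n_ghet + 1
    j <- which(calls$chrom == gold$chrom[i] & calls$pos == gold$pos[i])
    if (length(j) == 0) next
    n_called <- n_called + 1
    cg <- calls$genotype[j]
    if (cg != gold$genotype[i]) n_dis <- n_dis + 1
    cv <- is_var(cg, gold$ref[i]); chh <- is_het(cg)
    if (cv) {
      n_vcall <- n_vcall + 1
      if (gv) n_vdet <- n_vdet + 1 else n_vfalse <- n_vfalse + 1
    }
    if (chh) {
      n_hcall <- n_hcall + 1
      if (gh) n_hdet <- n_hdet + 1 else n_hfalse <- n_hfalse + 1
      if (cg != gold$genotype[i]) n_hdis <- n_hdis + 1
    }
  }
  list(percent_genotyped = 100 * n_called / n_gold,
       percent_disagreement = 100 * n_dis / n_called,
       variant_sensitivity = 100 * n_vdet / n_gvar,
       variant_fdr = 100 * n_vfalse / n_vcall,
       het_sensitivity = 100 * n_hdet / n_ghet,
       het_fdr = 100 * n_hfalse / n_hcall,
       het_disagreement = 100 * n_hdis / n_hcall)
}

# -- translation oracle ------------------------------------------------------

CODON_TABLE <- local({
  b <- c("T", "C", "A", "G")
  # first base slowest, third base fastest: TTT, TTC, TTA, TTG, TCT, ...
  codons <- paste0(rep(b, each = 16), rep(b, each = 4, times = 4),
                   rep(b, times = 16))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stopifnot(identical(unname(stats::setNames(aas, codons)[c("ATG", "TGG",
                                                            "AAA")]),
                      c("M", "W", "K")))
  stats::setNames(aas, codons)
})

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3
  paste(CODON_TABLE[substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))],
        collapse = "")
}

rc_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Coding-effect oracle: rebuild the CDS, translate whole proteins with and
# without the substitution, and compare.
oracle_coding_effect <- function(variant, model, genome) {
  cds <- model$cds
  if (nrow(cds) == 0) return("non-coding")
  inside <- any(cds$start <= variant$pos & variant$pos < cds$end &
                  cds$chrom == variant$chrom)
  if (!inside) return("non-coding")
  seq <- genome$sequences[[variant$chrom]]
  mutseq <- seq
  substr(mutseq, variant$pos + 1, variant$pos + 1) <- variant$alt
  get_cds <- function(s) {
    out <- paste(substring(s, cds$start + 1, cds$end), collapse = "")
    if (model$strand == "-") rc_oracle(out) else out
  }
  p_ref <- oracle_translate(get_cds(seq))
  p_alt <- oracle_translate(get_cds(mutseq))
  if (p_ref == p_alt) "synonymous" else "non-synonymous"
}
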