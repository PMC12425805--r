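# Overlap-based enrichment analyses: AMPs in promoters of ASE genes,
# bQTL at GWAS hits versus matched backgrounds, bQTL-eQTL LD, and the
# allele-specific read counting rule.

#' AMP enrichment in promoters of ASE genes
#'
#' A gene is AMP-positive when at least one AMP lies in its strand-aware
#' promoter window (`promoter_bp` upstream of the TSS, closed at both
#' ends). Enrichment of AMP-positive genes in a focal class relative to a
#' background class is tested with the hypergeometric distribution
#' (over- and under-representation tails) over the background universe.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`, `class` (e.g. `"ASE"`, `"non-ASE"`, `"all-expressed"`).
#' @param amp_positions data.frame with `chrom`, `pos` (0-based) of AMPs.
#' @param focal_class,background_class Class labels; the universe is the
#'   background class (the focal class must be a subset of it).
#' @param promoter_bp Promoter length in bp (default 3000).
#' @return List with counts (`n_universe`, `n_positive`, `n_focal`,
#'   `n_focal_positive`), `enrichment` (ratio of AMP-positive fractions),
#'   `p_over`, `p_under`.
#' @export
promoter_ase_enrichment <- function(genes, amp_positions,
                                    focal_class = "ASE",
                                    background_class = "all-expressed",
                                    promoter_bp = 3000) {
  uni <- genes[genes$class %in% c(background_class, focal_class), ,
               drop = FALSE]
  focal <- genes$class == focal_class
  if (!any(focal) || !any(genes$class == background_class)) {
    stop("empty gene class", call. = FALSE)
  }
  win_start <- ifelse(uni$strand == "+", uni$tss - promoter_bp, uni$tss)
  win_end <- ifelse(uni$strand == "+", uni$tss, uni$tss + promoter_bp)
  win_gr <- GenomicRanges::GRanges(
    uni$chrom, IRanges::IRanges(pmax(win_start, 0) + 1L, win_end + 1L)
  )
  amp_gr <- .granges_from_positions(amp_positions$chrom, amp_positions$pos)
  positive <- IRanges::overlapsAny(win_gr, amp_gr)

  in_focal <- uni$class == focal_class
  N <- nrow(uni)
  K <- sum(positive)
  n <- sum(in_focal)
  k <- sum(positive & in_focal)
  bg_frac <- K / N
  list(
    n_universe = N, n_positive = K, n_focal = n, n_focal_positive = k,
    enrichment = if (bg_frac > 0) (k / n) / bg_frac else NA_real_,
    p_over = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    p_under = stats::phyper(k, K, N - K, n)
  )
}

#' bQTL enrichment at GWAS hits versus matched backgrounds
#'
#' Observed count of bQTL within `window_bp` of any GWAS hit (inclusive
#' on both sides) divided by the mean of the same count over matched
#' background sets; reported overall and, when distance strata are
#' supplied, per distance-to-gene stratum. Empirical significance is the
#' fraction of background sets with a count at least as large as
#' observed.
#'
#' @param bqtl_pos Integer vector of bQTL positions (one chromosome; use
#'   offsets to concatenate).
#' @param gwas_hits Integer vector of hit positions.
#' @param bg_sets List of integer vectors, one matched background set per
#'   permutation.
#' @param window_bp Window half width (default 100).
#' @param strata Optional factor over `bqtl_pos` (background sets must
#'   carry a parallel `strata` attribute or be matched positionally;
#'   overall enrichment only when omitted).
#' @return data.frame with `stratum`, `observed`, `expected`, `fold`,
#'   `p_empirical`.
#' @export
gwas_hit_enrichment <- function(bqtl_pos, gwas_hits, bg_sets,
                                window_bp = 100, strata = NULL) {
  if (length(bg_sets) < 1L) stop("need at least one background set",
                                 call. = FALSE)
  near <- function(pos) {
    if (length(pos) == 0L) return(logical(0))
    hit_gr <- GenomicRanges::GRanges(
      "chr", IRanges::IRanges(gwas_hits + 1L - window_bp,
                              gwas_hits + 1L + window_bp)
    )
    IRanges::overlapsAny(.granges_from_positions("chr", pos), hit_gr)
  }
  count_strata <- function(pos, st) {
    hits <- near(pos)
    if (is.null(st)) {
      c(overall = sum(hits))
    } else {
      c(overall = sum(hits), tapply(hits, st, sum))
    }
  }
  obs <- count_strata(bqtl_pos, strata)
  bg <- vapply(bg_sets, function(b) count_strata(b, strata), obs)
  bg <- matrix(bg, nrow = length(obs),
               dimnames = list(names(obs), NULL))
  expected <- rowMeans(bg)
  p_emp <- rowMeans(bg >= obs)
  data.frame(
    stratum = names(obs),
    observed = as.numeric(obs),
    expected = expected,
    fold = ifelse(expected > 0, obs / expected, NA_real_),
    p_empirical = p_emp,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Linkage disequilibrium r-squared between two markers
#'
#' Squared Pearson correlation of allele counts over shared individuals;
#' pairs with a missing value are dropped; `NA` when either marker has no
#' variance. Invariant to allele-label swaps.
#'
#' @param genotype_a,genotype_b Numeric genotype vectors over the same
#'   individuals.
#' @return r-squared in `[0, 1]` or `NA`.
#' @export
ld_r2 <- function(genotype_a, genotype_b) {
  ok <- !is.na(genotype_a) & !is.na(genotype_b)
  a <- genotype_a[ok]
  b <- genotype_b[ok]
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Allele-specific read counting over informative SNPs
#'
#' Implements the counting rule for haplotype-specific expression: SNPs
#' carrying reads on only one allele are dropped from the informative
#' set, and each read is counted once per gene and allele regardless of
#' how many informative SNPs it spans.
#'
#' @param overlaps data.frame of read-SNP assignments: `read_id`,
#'   `replicate`, `gene_id`, `snp_id`, `allele` (`"ref"`/`"pat"`).
#' @return data.frame with `gene_id`, `allele`, `replicate`, `count`
#'   (distinct reads); genes without informative SNPs are absent.
#' @export
ase_read_counting <- function(overlaps) {
  if (nrow(overlaps) == 0L) {
    return(data.frame(gene_id = character(0), allele = character(0),
                      replicate = integer(0), count = integer(0)))
  }
  alleles_per_snp <- tapply(overlaps$allele, overlaps$snp_id,
                            function(a) length(unique(a)))
  informative <- names(alleles_per_snp)[alleles_per_snp == 2L]
  keep <- overlaps[overlaps$snp_id %in% informative, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(data.frame(gene_id = character(0), allele = character(0),
                      replicate = integer(0), count = integer(0)))
  }
  # one count per distinct read within gene x allele x replicate
  dedup <- keep[!duplicated(keep[, c("gene_id", "allele", "replicate",
                                     "read_id")]), , drop = FALSE]
  out <- stats::aggregate(
    list(count = dedup$read_id),
    by = list(gene_id = dedup$gene_id, allele = dedup$allele,
              replicate = dedup$replicate),
    FUN = length
  )
  out[order(out$gene_id, out$allele, out$replicate), , drop = FALSE]
}
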