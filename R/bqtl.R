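# Local association mapping at MP loci: five linear models per site,
# per-model FDR selection, genotype/methylation/both attribution and 65 bp
# linkage-group clumping.

# Extract the two-sided coefficient t-test p-value for each non-intercept
# term of an lm fit; NA where the coefficient is inestimable or the
# residual variance is zero.
.coef_pvals <- function(fit, terms) {
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  p <- setNames(rep(NA_real_, length(terms)), terms)
  hit <- intersect(terms, rownames(co))
  vals <- co[hit, "Pr(>|t|)"]
  vals[!is.finite(vals)] <- NA_real_
  p[hit] <- vals
  # an (essentially) perfect fit leaves no residual df worth of noise;
  # the t-test is degenerate and the p-values are reported missing
  scale <- max(abs(fit$fitted.values), 1e-300)
  if (sm$sigma <= 1e-10 * scale) p[] <- NA_real_
  p
}

#' Fit the five local association models at one site
#'
#' Ordinary least squares of per-line binding frequency on, separately,
#' each methylation context (mCHH, mCG, mCHG), the genotype code, and the
#' full model `GT + mCG + mCHG + mCHH`. Lines with a missing response are
#' excluded; predictors without variance give missing p-values.
#'
#' @param site data.frame with one row per line: `binding_frequency`,
#'   `genotype` (0/1: paternal allele is the alternative), `mCG`, `mCHG`,
#'   `mCHH`.
#' @param min_lines Minimum number of lines with data required to fit.
#' @return Named list of p-values: `p_geno`, `p_mcg`, `p_mchg`, `p_mchh`
#'   (single-predictor models) and `p_full_geno`, `p_full_mcg`,
#'   `p_full_mchg`, `p_full_mchh` (coefficients of the full model).
#' @export
fit_local_models <- function(site, min_lines = 2L) {
  d <- site[!is.na(site$binding_frequency), , drop = FALSE]
  empty <- list(p_geno = NA_real_, p_mcg = NA_real_, p_mchg = NA_real_,
                p_mchh = NA_real_, p_full_geno = NA_real_,
                p_full_mcg = NA_real_, p_full_mchg = NA_real_,
                p_full_mchh = NA_real_, n_lines = nrow(d))
  if (nrow(d) < max(min_lines, 3L)) return(empty)  # < 3 points: no df for t
  single <- function(x) {
    if (length(unique(x)) < 2L) return(NA_real_)
    unname(.coef_pvals(stats::lm(d$binding_frequency ~ x), "x"))
  }
  out <- empty
  out$p_geno <- single(d$genotype)
  out$p_mcg <- single(d$mCG)
  out$p_mchg <- single(d$mCHG)
  out$p_mchh <- single(d$mCHH)
  full <- stats::lm(binding_frequency ~ genotype + mCG + mCHG + mCHH,
                    data = d)
  pf <- .coef_pvals(full, c("genotype", "mCG", "mCHG", "mCHH"))
  out$p_full_geno <- unname(pf["genotype"])
  out$p_full_mcg <- unname(pf["mCG"])
  out$p_full_mchg <- unname(pf["mCHG"])
  out$p_full_mchh <- unname(pf["mCHH"])
  out
}

#' Per-model FDR selection across sites
#'
#' Benjamini-Hochberg correction applied separately to each
#' single-predictor model across all tested sites. A site is
#' genotype-associated when the genotype model passes, and
#' methylation-associated when any of the three context models passes.
#' Missing p-values are never significant.
#'
#' @param records data.frame of per-site records with columns `p_geno`,
#'   `p_mcg`, `p_mchg`, `p_mchh`.
#' @param fdr FDR threshold (default 0.05).
#' @return The table with `q_*` columns and logical `geno_assoc`,
#'   `meth_assoc`.
#' @export
select_significant <- function(records, fdr = 0.05) {
  for (m in c("p_geno", "p_mcg", "p_mchg", "p_mchh")) {
    q <- rep(NA_real_, nrow(records))
    ok <- !is.na(records[[m]])
    q[ok] <- stats::p.adjust(records[[m]][ok], method = "BH")
    records[[sub("^p", "q", m)]] <- q
  }
  pass <- function(q) !is.na(q) & q < fdr
  records$geno_assoc <- pass(records$q_geno)
  records$meth_assoc <- pass(records$q_mcg) | pass(records$q_mchg) |
    pass(records$q_mchh)
  records
}

#' Attribute a bQTL to genotype, methylation or both
#'
#' @param geno_assoc,meth_assoc Logical vectors from
#'   [select_significant()].
#' @return Character vector in `{"geno_only","meth_only","both","none"}`.
#' @export
classify_bqtl <- function(geno_assoc, meth_assoc) {
  ifelse(geno_assoc & meth_assoc, "both",
         ifelse(geno_assoc, "geno_only",
                ifelse(meth_assoc, "meth_only", "none")))
}

#' Clump significant sites into 65 bp linkage groups
#'
#' Transitive chaining: consecutive significant sites at most `clump_bp`
#' apart (per chromosome) join one group. The lead of a group is the
#' member with the lowest lead-defining p-value (the minimum over its
#' significant models), ties broken by leftmost position.
#'
#' @param records data.frame with `pos`, `p_lead` and optionally `chrom`;
#'   only rows passed in are clumped (pass the significant subset).
#' @param clump_bp Maximum gap joining two sites (default 65).
#' @return The table with `group_id` and `is_lead` added, sorted by
#'   chromosome and position.
#' @export
clump_linkage_groups <- function(records, clump_bp = 65) {
  if (nrow(records) == 0L) {
    records$group_id <- character(0)
    records$is_lead <- logical(0)
    return(records)
  }
  chrom <- if ("chrom" %in% names(records)) records$chrom else {
    rep("chr1", nrow(records))
  }
  ord <- order(chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  chrom <- chrom[ord]
  gap_new <- c(TRUE, diff(records$pos) > clump_bp |
                 chrom[-1L] != chrom[-length(chrom)])
  gid <- cumsum(gap_new)
  records$group_id <- sprintf("%s_grp%05d", chrom, gid)
  records$is_lead <- FALSE
  for (g in unique(gid)) {
    i <- which(gid == g)
    p <- records$p_lead[i]
    p[is.na(p)] <- Inf
    records$is_lead[i[which.min(p)]] <- TRUE  # which.min: leftmost on ties
  }
  rownames(records) <- NULL
  records
}

#' Assemble per-site predictors for association mapping
#'
#' Joins pooled MP records (binding frequencies per line) with the
#' genotype matrix and per-line allelic methylation differences. The
#' methylation predictor per context is the paternal-minus-reference
#' windowed level, the quantity the occupancy difference can respond to.
#'
#' @param mps MP record table (one row per site x line) with
#'   `binding_frequency`.
#' @param genotypes Lines x sites genotype matrix.
#' @param methylomes Methylation window table (site_id, line_id, allele,
#'   mCG, mCHG, mCHH).
#' @param sites Site table with `site_id` and `pos`.
#' @return data.frame with one row per site x line: site_id, pos, line_id,
#'   binding_frequency, genotype, mCG, mCHG, mCHH.
#' @export
build_site_predictors <- function(mps, genotypes, methylomes, sites) {
  w <- methylomes
  key <- paste(w$site_id, w$line_id)
  ref <- w$allele == "ref"
  mk <- function(col) {
    r <- setNames(w[[col]][ref], key[ref])
    p <- setNames(w[[col]][!ref], key[!ref])
    k <- paste(mps$site_id, mps$line_id)
    p[k] - r[k]
  }
  data.frame(
    site_id = mps$site_id,
    pos = sites$pos[match(mps$site_id, sites$site_id)],
    line_id = mps$line_id,
    binding_frequency = mps$binding_frequency,
    genotype = genotypes[cbind(match(mps$line_id, rownames(genotypes)),
                               match(mps$site_id, colnames(genotypes)))],
    mCG = unname(mk("mCG")),
    mCHG = unname(mk("mCHG")),
    mCHH = unname(mk("mCHH")),
    stringsAsFactors = FALSE
  )
}

#' Map binding QTL across a panel
#'
#' Runs the five local models at every site tested in at least `min_lines`
#' lines, applies per-model FDR selection, attributes each significant
#' site to genotype, methylation or both, and clumps significant sites
#' into 65 bp linkage groups with lead selection.
#'
#' @param predictors Output of [build_site_predictors()] (rows restricted
#'   to MP records of one condition).
#' @param fdr FDR threshold (default 0.05).
#' @param clump_bp Linkage-group gap (default 65).
#' @param min_lines Minimum lines with data per site (default 2).
#' @return data.frame of per-site bQTL records with p/q values,
#'   `sig_class`, and for significant sites `group_id`/`is_lead`.
#' @export
map_bqtl <- function(predictors, fdr = 0.05, clump_bp = 65, min_lines = 2L) {
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) {
    stop("`fdr` must lie in (0, 1)", call. = FALSE)
  }
  sp <- split(predictors, predictors$site_id)
  fits <- lapply(sp, fit_local_models, min_lines = min_lines)
  rec <- data.frame(
    site_id = names(sp),
    pos = vapply(sp, function(d) d$pos[1L], numeric(1)),
    stringsAsFactors = FALSE
  )
  for (col in c("p_geno", "p_mcg", "p_mchg", "p_mchh", "p_full_geno",
                "p_full_mcg", "p_full_mchg", "p_full_mchh")) {
    rec[[col]] <- vapply(fits, function(f) f[[col]], numeric(1))
  }
  rec$n_lines <- vapply(fits, function(f) as.numeric(f$n_lines), numeric(1))
  rec <- select_significant(rec, fdr = fdr)
  rec$sig_class <- classify_bqtl(rec$geno_assoc, rec$meth_assoc)
  qs <- as.matrix(rec[, c("q_geno", "q_mcg", "q_mchg", "q_mchh")])
  ps <- as.matrix(rec[, c("p_geno", "p_mcg", "p_mchg", "p_mchh")])
  sig_mask <- !is.na(qs) & qs < fdr
  p_sig <- ps
  p_sig[!sig_mask] <- NA_real_
  rec$p_lead <- suppressWarnings(apply(p_sig, 1L, min, na.rm = TRUE))
  rec$p_lead[!is.finite(rec$p_lead)] <- NA_real_
  rec$group_id <- NA_character_
  rec$is_lead <- NA
  sig <- rec$sig_class != "none"
  if (any(sig)) {
    clumped <- clump_linkage_groups(rec[sig, , drop = FALSE],
                                    clump_bp = clump_bp)
    i <- match(clumped$site_id, rec$site_id)
    rec$group_id[i] <- clumped$group_id
    rec$is_lead[i] <- clumped$is_lead
  }
  rownames(rec) <- NULL
  rec
}
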