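# Allele-specific footprint occupancy: fragment-center tracks, RPGC
# scaling, binding frequencies, MP/AMP calling, WGS-control filtering,
# INDEL coverage windows and condition-response testing.

#' Fragment-center coverage track
#'
#' Shortens each mapped read to a 20 bp window centered on its middle base
#' and accumulates per-base coverage, scaled by
#' `effective_genome_size / n_mapped` (RPGC units). For reads with an even
#' number of bases one of the two middle bases is chosen at random; for
#' odd-length reads the window is `[m - 10, m + 10)` around the middle
#' base `m`. Window ends are clipped at the chromosome boundaries.
#'
#' Randomness for even-length reads is drawn from the current RNG stream;
#' seed beforehand for reproducibility.
#'
#' @param reads data.frame with `start`, `end` (0-based half-open).
#' @param effective_genome_size Effective genome size in bp.
#' @param n_mapped Number of uniquely mapped reads used for scaling.
#' @param genome_length Length of the chromosome the track spans.
#' @param chrom Chromosome name stored in the track.
#' @return An object of class `"coverage_track"`: list with per-base
#'   `coverage` (numeric, RPGC), `scale`, `effective_genome_size`,
#'   `n_mapped`, `chrom`.
#' @export
fragment_center_track <- function(reads, effective_genome_size, n_mapped,
                                  genome_length, chrom = "chr1") {
  stopifnot(n_mapped > 0, effective_genome_size > 0, genome_length > 0)
  cov <- numeric(genome_length)
  scale <- effective_genome_size / n_mapped
  if (nrow(reads) > 0) {
    len <- reads$end - reads$start
    if (any(len <= 0)) stop("reads must have positive length", call. = FALSE)
    odd <- len %% 2L == 1L
    m <- integer(nrow(reads))
    m[odd] <- reads$start[odd] + (len[odd] - 1L) %/% 2L
    if (any(!odd)) {
      pick <- stats::rbinom(sum(!odd), 1L, 0.5)  # lower or upper middle base
      m[!odd] <- reads$start[!odd] + len[!odd] %/% 2L - 1L + pick
    }
    ws <- pmax(m - 10L, 0L)
    we <- pmin(m + 10L, genome_length)
    delta <- numeric(genome_length + 1L)
    for (i in seq_along(ws)) {
      delta[ws[i] + 1L] <- delta[ws[i] + 1L] + 1
      delta[we[i] + 1L] <- delta[we[i] + 1L] - 1
    }
    cov <- cumsum(delta[seq_len(genome_length)]) * scale
  }
  structure(
    list(coverage = cov, scale = scale,
         effective_genome_size = effective_genome_size,
         n_mapped = n_mapped, chrom = chrom),
    class = "coverage_track"
  )
}

#' Binding frequency toward the reference allele
#'
#' `rpgc_ref / (rpgc_ref + rpgc_pat)`, `NA` where both alleles have zero
#' coverage (no reads at the locus).
#'
#' @param rpgc_ref,rpgc_pat Non-negative scaled coverages (vectorized).
#' @return Numeric vector in `[0, 1]` with `NA` at zero-coverage loci.
#' @export
binding_frequency <- function(rpgc_ref, rpgc_pat) {
  if (any(rpgc_ref < 0, na.rm = TRUE) || any(rpgc_pat < 0, na.rm = TRUE)) {
    stop("RPGC values must be >= 0", call. = FALSE)
  }
  tot <- rpgc_ref + rpgc_pat
  ifelse(tot > 0, rpgc_ref / tot, NA_real_)
}

#' Pool replicate coverage at variant sites
#'
#' Sums allele read counts over replicates and averages the RPGC values,
#' per site x line x condition, producing the per-line records MP calling
#' operates on.
#'
#' @param coverage Per-replicate coverage data.frame
#'   ([simulate_moa_counts()] layout).
#' @return data.frame with one row per site x line x condition and summed
#'   `reads_*` / averaged `rpgc_*` columns.
#' @export
aggregate_replicates <- function(coverage) {
  key <- interaction(coverage$site_id, coverage$line_id,
                     coverage$condition, drop = TRUE)
  idx <- !duplicated(key)
  out <- coverage[idx, c("site_id", "line_id", "condition")]
  sums <- function(v) as.numeric(tapply(v, key, sum))
  means <- function(v) as.numeric(tapply(v, key, mean))
  ord <- match(levels(droplevels(key)), key[idx])
  out <- out[ord, , drop = FALSE]
  out$reads_ref <- sums(coverage$reads_ref)
  out$reads_pat <- sums(coverage$reads_pat)
  out$rpgc_ref <- means(coverage$rpgc_ref)
  out$rpgc_pat <- means(coverage$rpgc_pat)
  rownames(out) <- NULL
  out
}

#' Call footprint polymorphisms (MPs)
#'
#' A site x line record is an MP iff the site lies inside a footprint
#' peak, one allele exceeds 7 RPGC (approximately more than 25 reads), and
#' the other allele carries at least one read. Adds the binding frequency.
#'
#' @param coverage Pooled per-line coverage ([aggregate_replicates()]
#'   layout) with columns reads_ref, reads_pat, rpgc_ref, rpgc_pat.
#' @param sites Site table with `site_id` and `in_peak`, or `NULL` if
#'   `coverage` already carries an `in_peak` column.
#' @param rpgc_min RPGC threshold (strict inequality).
#' @return data.frame of MP records: input columns plus
#'   `binding_frequency`, `is_mp` and placeholder AMP columns.
#' @export
call_mps <- function(coverage, sites = NULL, rpgc_min = 7) {
  if (!"in_peak" %in% names(coverage)) {
    if (is.null(sites) || !all(c("site_id", "in_peak") %in% names(sites))) {
      stop("peak membership missing: supply `sites` with an `in_peak` column",
           call. = FALSE)
    }
    coverage$in_peak <- sites$in_peak[match(coverage$site_id, sites$site_id)]
  }
  if (anyNA(coverage$in_peak)) {
    stop("sites without peak annotation present", call. = FALSE)
  }
  pass_ref <- coverage$rpgc_ref > rpgc_min
  pass_pat <- coverage$rpgc_pat > rpgc_min
  coverage$binding_frequency <- binding_frequency(coverage$rpgc_ref,
                                                  coverage$rpgc_pat)
  coverage$is_mp <- coverage$in_peak &
    ((pass_ref & coverage$reads_pat >= 1) |
     (pass_pat & coverage$reads_ref >= 1))
  coverage$p_binomial <- NA_real_
  coverage$q_fdr <- NA_real_
  coverage$is_amp <- FALSE
  coverage
}

# Two-sided exact binomial p at p0 = 0.5, the R binom.test "minlike" rule:
# sum of outcome probabilities not exceeding the observed one (with R's
# relative tolerance).
.binom_p_twosided <- function(x, n) {
  mapply(function(xi, ni) {
    if (ni == 0L) return(NA_real_)
    stats::binom.test(xi, ni, p = 0.5)$p.value
  }, x, n)
}

#' Call allele-specific MPs (AMPs)
#'
#' Exact two-sided binomial tests of the reference-allele read count
#' against an expected 1:1 ratio, Benjamini-Hochberg corrected across the
#' MPs of each line x condition; records with `q < fdr` become AMPs.
#' Testing uses read counts, not normalized coverage.
#'
#' @param mps MP record table from [call_mps()].
#' @param fdr FDR threshold (default 0.01).
#' @return The table with `p_binomial`, `q_fdr` and `is_amp` filled for MP
#'   rows.
#' @export
call_amps <- function(mps, fdr = 0.01) {
  if (!is.numeric(fdr) || length(fdr) != 1L || fdr <= 0 || fdr >= 1) {
    stop("`fdr` must lie in (0, 1)", call. = FALSE)
  }
  sel <- which(mps$is_mp)
  if (length(sel) > 0) {
    p <- .binom_p_twosided(mps$reads_ref[sel],
                           mps$reads_ref[sel] + mps$reads_pat[sel])
    mps$p_binomial[sel] <- p
    grp <- interaction(mps$line_id[sel], mps$condition[sel], drop = TRUE)
    q <- rep(NA_real_, length(sel))
    for (g in levels(grp)) {
      i <- grp == g
      q[i] <- stats::p.adjust(p[i], method = "BH")
    }
    mps$q_fdr[sel] <- q
    mps$is_amp[sel] <- !is.na(q) & q < fdr
  }
  mps
}

#' WGS-control filter for AMPs
#'
#' Computes the 5th and 95th percentile (linear interpolation between
#' order statistics) of the WGS control allelic ratio over all MPs and
#' strips the AMP flag from records whose ratio falls outside that range,
#' marking them `wgs_excluded`.
#'
#' @param mps MP/AMP record table.
#' @param wgs data.frame with `site_id` and `wgs_ratio`.
#' @param percentile Lower tail probability (default 0.05; upper is its
#'   complement).
#' @return The table with `wgs_ratio` and `wgs_excluded` columns and
#'   `is_amp` updated.
#' @export
wgs_control_filter <- function(mps, wgs, percentile = 0.05) {
  mps$wgs_ratio <- wgs$wgs_ratio[match(mps$site_id, wgs$site_id)]
  mp_ratio <- mps$wgs_ratio[mps$is_mp]
  if (anyNA(mp_ratio)) stop("WGS ratio missing for some MPs", call. = FALSE)
  if (length(mp_ratio) < 20L) {
    warning("fewer than 20 MPs: WGS percentile thresholds are unreliable")
  }
  thr <- stats::quantile(mp_ratio, c(percentile, 1 - percentile),
                         type = 7, names = FALSE)
  mps$wgs_excluded <- mps$is_amp &
    (mps$wgs_ratio < thr[1L] | mps$wgs_ratio > thr[2L])
  mps$is_amp <- mps$is_amp & !mps$wgs_excluded
  attr(mps, "wgs_thresholds") <- thr
  mps
}

#' Filter candidate INDELs
#'
#' Retains biallelic INDELs between 2 and 50 bp whose non-reference allele
#' occurs in at least two lines.
#'
#' @param indels data.frame with `length` (bp) and `n_alt_lines`.
#' @return The retained subset.
#' @export
filter_indels <- function(indels) {
  indels[indels$length >= 2 & indels$length <= 50 &
           indels$n_alt_lines >= 2, , drop = FALSE]
}

#' Per-allele coverage at an INDEL site
#'
#' The allele carrying the inserted sequence is scored as the mean RPGC
#' over the whole insertion span; the allele lacking it as the mean over a
#' 3 bp flank on each side of the deletion point (6 bases). Zero-coverage
#' bases count toward the averages. An allele interval of zero width marks
#' the deletion allele.
#'
#' @param indel List/row with `ref_start`, `ref_end`, `pat_start`,
#'   `pat_end` (0-based half-open allele intervals on the respective
#'   haplotype coordinates).
#' @param track_ref,track_pat `coverage_track` objects (or bare numeric
#'   per-base vectors) for the two haplotypes.
#' @return Named numeric vector `c(rpgc_ref=, rpgc_pat=)`.
#' @export
indel_site_coverage <- function(indel, track_ref, track_pat) {
  covvec <- function(tr) if (inherits(tr, "coverage_track")) tr$coverage else tr
  one <- function(cov, s, e) {
    n <- length(cov)
    if (e - s == 0L) {           # deletion allele: 3 bp flanks either side
      idx <- c(seq.int(max(s - 3L, 0L), s - 1L),
               seq.int(s, min(s + 3L, n) - 1L))
      idx <- idx[idx >= 0 & idx < n]
    } else {                     # insertion allele: the inserted span
      idx <- seq.int(s, e - 1L)
      idx <- idx[idx >= 0 & idx < n]
    }
    if (length(idx) == 0L) return(NA_real_)
    mean(cov[idx + 1L])
  }
  c(rpgc_ref = one(covvec(track_ref), indel$ref_start, indel$ref_end),
    rpgc_pat = one(covvec(track_pat), indel$pat_start, indel$pat_end))
}

#' Condition-response test on replicate coverages
#'
#' Two-sided Welch (unequal-variance) t-test comparing the per-replicate
#' mean coverages of a region between two conditions; the direction is the
#' sign of the drought-minus-control mean difference.
#'
#' @param coverage_ww,coverage_ds Numeric vectors of replicate coverages
#'   (at least 2 each).
#' @param alpha Significance threshold.
#' @return List with `t`, `p`, `direction` (`"increased"`/`"decreased"`/
#'   `"none"`), `significant`.
#' @export
treatment_response_test <- function(coverage_ww, coverage_ds, alpha = 0.05) {
  if (length(coverage_ww) < 2L || length(coverage_ds) < 2L) {
    stop("need at least 2 replicates per condition", call. = FALSE)
  }
  d <- mean(coverage_ds) - mean(coverage_ww)
  if (stats::sd(coverage_ww) == 0 && stats::sd(coverage_ds) == 0) {
    # identical constant samples: no evidence of change
    return(list(t = 0, p = 1, direction = "none", significant = FALSE))
  }
  tt <- stats::t.test(coverage_ds, coverage_ww, var.equal = FALSE)
  sig <- tt$p.value < alpha
  list(
    t = unname(tt$statistic),
    p = tt$p.value,
    direction = if (d > 0) "increased" else if (d < 0) "decreased" else "none",
    significant = sig
  )
}
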