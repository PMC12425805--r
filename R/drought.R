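# Condition-response classification of allele-specific sites and
# selection of high-confidence drought-responsive candidate loci.

#' Classify allele-specific sites across two conditions
#'
#' Sites that are AMPs in at least one condition fall into four response
#' groups: (I) detected in exactly one condition; (II) detected in both
#' with at least `bias_cut` occupancy bias toward the same allele in both;
#' (III) bias of at least `bias_cut` toward opposite alleles; (IV)
#' significant allele-specific bias (AMP) in one condition while the other
#' sits in the unbiased 40-60% band. The 60% rule (not a second test) is
#' used for the second condition to avoid stacking statistical cut-offs.
#'
#' @param pairs data.frame with one row per site x line:
#'   `detected_ww`, `detected_ds` (logical: signal above the detection
#'   limit), `freq_ww`, `freq_ds` (binding frequencies, may be `NA` when
#'   undetected), `amp_ww`, `amp_ds` (logical AMP calls).
#' @param bias_cut Allele-specific bias threshold (default 0.60).
#' @return Character vector: `"I"`, `"II"`, `"III"`, `"IV"`,
#'   `"unclassified"`, or `NA` for rows that are an AMP in neither
#'   condition.
#' @export
classify_condition_amps <- function(pairs, bias_cut = 0.60) {
  lo <- 1 - bias_cut
  n <- nrow(pairs)
  out <- rep(NA_character_, n)
  amp_w <- !is.na(pairs$amp_ww) & pairs$amp_ww
  amp_d <- !is.na(pairs$amp_ds) & pairs$amp_ds
  eligible <- amp_w | amp_d
  det_w <- !is.na(pairs$detected_ww) & pairs$detected_ww
  det_d <- !is.na(pairs$detected_ds) & pairs$detected_ds
  fw <- pairs$freq_ww
  fd <- pairs$freq_ds

  one <- eligible & xor(det_w, det_d)
  out[one] <- "I"

  both <- eligible & det_w & det_d & !is.na(fw) & !is.na(fd)
  same <- both & ((fw >= bias_cut & fd >= bias_cut) |
                    (fw <= lo & fd <= lo))
  opp <- both & ((fw >= bias_cut & fd <= lo) | (fw <= lo & fd >= bias_cut))
  band <- function(f) f > lo & f < bias_cut
  only_one <- both & ((amp_w & band(fd)) | (amp_d & band(fw)))
  out[both & same] <- "II"
  out[both & opp] <- "III"
  out[both & !same & !opp & only_one] <- "IV"
  out[eligible & is.na(out)] <- "unclassified"
  out
}

#' Select high-confidence drought-responsive candidate loci
#'
#' Candidates are bQTL that (a) lie within `window` bp of an AMP located
#' inside a significantly drought-responsive region, in at least
#' `min_lines` distinct lines; and (b) fall within `up` bp upstream or
#' `down` bp downstream (strand-aware, anchored at TSS/TTS) of a gene
#' whose transcripts are both haplotype-specific (ASE) and
#' drought-responsive.
#'
#' @param bqtl data.frame of bQTL with `site_id`, `chrom`, `pos`.
#' @param amps data.frame of AMPs with `chrom`, `pos`, `line_id`.
#' @param responsive_regions data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), `direction` (`"increased"`/`"decreased"`),
#'   `line_id`, `significant` (logical).
#' @param genes data.frame with `gene_id`, `chrom`, `strand`, `tss`,
#'   `tts` (0-based positions).
#' @param transcript_flags data.frame with `gene_id`, `ase`,
#'   `drought_responsive` (logical).
#' @param up,down Upstream/downstream windows in bp (defaults 5000/1000).
#' @param min_lines Minimum lines with responsive AMP support (default 2).
#' @param window bQTL-to-AMP overlap window in bp (default 65).
#' @return data.frame of candidates: `site_id`, `pos`, `gene_id`,
#'   `direction`, `n_lines`.
#' @export
select_drought_candidates <- function(bqtl, amps, responsive_regions, genes,
                                      transcript_flags, up = 5000,
                                      down = 1000, min_lines = 2L,
                                      window = 65) {
  if (anyNA(genes$strand) || !all(genes$strand %in% c("+", "-"))) {
    stop("gene strand missing or invalid", call. = FALSE)
  }
  rr <- responsive_regions[responsive_regions$significant, , drop = FALSE]
  if (nrow(rr) == 0L || nrow(amps) == 0L || nrow(bqtl) == 0L) {
    return(data.frame(site_id = character(0), pos = integer(0),
                      gene_id = character(0), direction = character(0),
                      n_lines = integer(0)))
  }
  # AMPs inside a region significantly responsive for the same line
  amp_gr <- .granges_from_positions(amps$chrom, amps$pos)
  rr_gr <- .granges_from_intervals(rr)
  ov <- GenomicRanges::findOverlaps(amp_gr, rr_gr)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  keep <- amps$line_id[qh] == rr$line_id[sh]
  resp_amps <- data.frame(
    pos = amps$pos[qh[keep]],
    line_id = amps$line_id[qh[keep]],
    direction = rr$direction[sh[keep]],
    chrom = amps$chrom[qh[keep]],
    stringsAsFactors = FALSE
  )
  if (nrow(resp_amps) == 0L) {
    return(data.frame(site_id = character(0), pos = integer(0),
                      gene_id = character(0), direction = character(0),
                      n_lines = integer(0)))
  }
  # bQTL within `window` bp of responsive AMPs, counting distinct lines
  bq_gr <- .granges_from_positions(bqtl$chrom, bqtl$pos)
  ra_gr <- GenomicRanges::GRanges(
    resp_amps$chrom,
    IRanges::IRanges(resp_amps$pos + 1L - window,
                     resp_amps$pos + 1L + window)
  )
  ov2 <- GenomicRanges::findOverlaps(bq_gr, ra_gr)
  q2 <- S4Vectors::queryHits(ov2)
  s2 <- S4Vectors::subjectHits(ov2)
  if (length(q2) == 0L) {
    return(data.frame(site_id = character(0), pos = integer(0),
                      gene_id = character(0), direction = character(0),
                      n_lines = integer(0)))
  }
  support <- stats::aggregate(
    list(n_lines = resp_amps$line_id[s2]),
    by = list(idx = q2),
    FUN = function(v) length(unique(v))
  )
  dir_per_bqtl <- vapply(split(resp_amps$direction[s2], q2), function(v) {
    names(sort(table(v), decreasing = TRUE))[1L]
  }, character(1))
  support$direction <- dir_per_bqtl[as.character(support$idx)]
  support <- support[support$n_lines >= min_lines, , drop = FALSE]
  if (nrow(support) == 0L) {
    return(data.frame(site_id = character(0), pos = integer(0),
                      gene_id = character(0), direction = character(0),
                      n_lines = integer(0)))
  }
  cand <- bqtl[support$idx, c("site_id", "chrom", "pos"), drop = FALSE]
  cand$direction <- support$direction
  cand$n_lines <- support$n_lines

  # strand-aware gene windows around flagged genes
  fl <- transcript_flags[transcript_flags$ase &
                           transcript_flags$drought_responsive, , drop = FALSE]
  g <- genes[genes$gene_id %in% fl$gene_id, , drop = FALSE]
  if (nrow(g) == 0L) {
    return(data.frame(site_id = character(0), pos = integer(0),
                      gene_id = character(0), direction = character(0),
                      n_lines = integer(0)))
  }
  win_start <- ifelse(g$strand == "+", g$tss - up, g$tts - down)
  win_end <- ifelse(g$strand == "+", g$tts + down, g$tss + up)
  win_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(win_start, 0) + 1L, win_end + 1L)
  )
  cand_gr <- .granges_from_positions(cand$chrom, cand$pos)
  ov3 <- GenomicRanges::findOverlaps(cand_gr, win_gr)
  q3 <- S4Vectors::queryHits(ov3)
  s3 <- S4Vectors::subjectHits(ov3)
  out <- data.frame(
    site_id = cand$site_id[q3],
    pos = cand$pos[q3],
    gene_id = g$gene_id[s3],
    direction = cand$direction[q3],
    n_lines = cand$n_lines[q3],
    stringsAsFactors = FALSE
  )
  out <- out[!duplicated(paste(out$site_id, out$gene_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
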