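# Windowed allelic methylation summaries, differential / strictly-equal
# classification and methylation-occupancy concordance.

#' Windowed methylation summary at a site
#'
#' Per context and allele, the arithmetic mean of per-cytosine methylation
#' levels within `site_pos +/- halfwidth` (closed on both ends); missing
#' where the window contains no cytosines of that context.
#'
#' @param calls data.frame of per-cytosine calls: `pos` (0-based),
#'   `context` (`"CG"`/`"CHG"`/`"CHH"`), `level` in `[0,1]`, `allele`
#'   (`"ref"`/`"pat"`), optionally `line_id`.
#' @param site_pos Site position (0-based).
#' @param halfwidth Window half width in bp (default 20).
#' @return data.frame with one row per (line x) allele and columns `mCG`,
#'   `mCHG`, `mCHH`.
#' @export
windowed_methylation <- function(calls, site_pos, halfwidth = 20) {
  w <- calls[calls$pos >= site_pos - halfwidth &
               calls$pos <= site_pos + halfwidth, , drop = FALSE]
  if (!"line_id" %in% names(w)) w$line_id <- "all"
  grp <- unique(w[, c("line_id", "allele")])
  if (nrow(grp) == 0L) {
    return(data.frame(line_id = character(0), allele = character(0),
                      mCG = numeric(0), mCHG = numeric(0),
                      mCHH = numeric(0)))
  }
  ctx_mean <- function(li, al, ctx) {
    v <- w$level[w$line_id == li & w$allele == al & w$context == ctx]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  grp$mCG <- mapply(ctx_mean, grp$line_id, grp$allele, "CG")
  grp$mCHG <- mapply(ctx_mean, grp$line_id, grp$allele, "CHG")
  grp$mCHH <- mapply(ctx_mean, grp$line_id, grp$allele, "CHH")
  rownames(grp) <- NULL
  grp
}

#' Differential allelic methylation call
#'
#' An allele pair is differentially methylated when one allele is below
#' 10% and the other above 70% methylated. Vectorized.
#'
#' @param m_ref,m_pat Windowed methylation levels of the two alleles.
#' @return Character vector in
#'   `{"ref_hypo","pat_hypo","not_differential"}`, `NA` where either
#'   input is missing.
#' @export
classify_differential <- function(m_ref, m_pat) {
  out <- rep(NA_character_, length(m_ref))
  ok <- !is.na(m_ref) & !is.na(m_pat)
  out[ok & m_ref < 0.10 & m_pat > 0.70] <- "ref_hypo"
  out[ok & m_pat < 0.10 & m_ref > 0.70] <- "pat_hypo"
  out[ok & is.na(out)] <- "not_differential"
  out
}

#' Strict equal-methylation call
#'
#' The stringent rule used for shared-site analyses: both alleles below
#' 10% or both above 70% methylated.
#'
#' @param m_ref,m_pat Windowed methylation levels.
#' @return Logical vector (`NA` where either input is missing).
#' @export
classify_equal_strict <- function(m_ref, m_pat) {
  ifelse(is.na(m_ref) | is.na(m_pat), NA,
         (m_ref < 0.10 & m_pat < 0.10) | (m_ref > 0.70 & m_pat > 0.70))
}

#' Concordance of allelic bias with hypomethylation
#'
#' Among AMPs at differentially methylated sites, counts how often the
#' allele with higher occupancy is the hypomethylated one. Records with a
#' binding frequency of exactly 0.5 carry no direction and are dropped.
#'
#' @param amps data.frame with `binding_frequency` (toward the reference
#'   allele) and `meth_class` (`"ref_hypo"`/`"pat_hypo"`; other values are
#'   ignored).
#' @return List with `n`, `n_concordant`, `fraction` (`NaN` when no
#'   eligible records).
#' @export
bias_concordance <- function(amps) {
  el <- amps[!is.na(amps$meth_class) &
               amps$meth_class %in% c("ref_hypo", "pat_hypo") &
               !is.na(amps$binding_frequency) &
               amps$binding_frequency != 0.5, , drop = FALSE]
  conc <- (el$binding_frequency > 0.5 & el$meth_class == "ref_hypo") |
    (el$binding_frequency < 0.5 & el$meth_class == "pat_hypo")
  list(n = nrow(el), n_concordant = sum(conc),
       fraction = if (nrow(el) > 0) mean(conc) else NaN)
}

#' Shared-site partition of AMP rates by methylation state
#'
#' At sites where, across the panel, at least `min_diff` lines are
#' differentially methylated, at least `min_eq` lines strictly equally
#' methylated and at least `min_amp` line is an AMP, computes per site the
#' fraction of differentially methylated lines that are AMPs and the
#' fraction of strictly-equal lines that are AMPs.
#'
#' @param records data.frame with one row per site x line: `site_id`,
#'   `is_diff`, `is_eq`, `is_amp` (logicals; `NA` treated as `FALSE`).
#' @param min_diff,min_eq,min_amp Eligibility thresholds (defaults 2, 2,
#'   1).
#' @return data.frame per eligible site: `site_id`, `n_diff`, `n_eq`,
#'   `frac_amp_diff`, `frac_amp_eq`.
#' @export
shared_site_partition <- function(records, min_diff = 2L, min_eq = 2L,
                                  min_amp = 1L) {
  f <- function(x) !is.na(x) & x
  sp <- split(records, records$site_id)
  rows <- lapply(sp, function(d) {
    nd <- sum(f(d$is_diff)); ne <- sum(f(d$is_eq)); na <- sum(f(d$is_amp))
    if (nd < min_diff || ne < min_eq || na < min_amp) return(NULL)
    data.frame(
      site_id = d$site_id[1L], n_diff = nd, n_eq = ne,
      frac_amp_diff = sum(f(d$is_amp) & f(d$is_diff)) / nd,
      frac_amp_eq = sum(f(d$is_amp) & f(d$is_eq)) / ne,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(site_id = character(0), n_diff = integer(0),
                      n_eq = integer(0), frac_amp_diff = numeric(0),
                      frac_amp_eq = numeric(0))
  }
  rownames(out) <- NULL
  out
}
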