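# End-to-end orchestration of the analysis stages on a simulated study,
# with a run manifest recording configuration, seed and per-stage record
# counts so filter attrition is auditable.

#' Run the full analysis pipeline on a simulated study
#'
#' Executes, in dependency order: data simulation, replicate pooling, MP
#' and AMP calling with the WGS-control filter (per condition), local
#' association mapping of bQTL, methylation-occupancy concordance,
#' condition-response classification, and a small variance-component
#' recovery run. Each stage's output is returned so stages can also be
#' run standalone; all randomness flows from the configuration seed.
#'
#' @param cfg A [sim_config()]; its validation is the configuration
#'   schema (invalid fields raise errors naming the field).
#' @param amp_fdr AMP FDR threshold (default 0.01).
#' @param bqtl_fdr bQTL FDR threshold (default 0.05).
#' @param out_dir Optional directory: when given, key tables are written
#'   as plain-text fixtures via [write_fixtures()].
#' @return List with `manifest` (config snapshot, seed, timestamps,
#'   per-stage record counts), `data`, `mps`, `bqtl`, `concordance`,
#'   `condition_groups`, `vcap`.
#' @export
run_pipeline <- function(cfg, amp_fdr = 0.01, bqtl_fdr = 0.05,
                         out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(amp_fdr) || amp_fdr <= 0 || amp_fdr >= 1) {
    stop("`amp_fdr` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(bqtl_fdr) || bqtl_fdr <= 0 || bqtl_fdr >= 1) {
    stop("`bqtl_fdr` must lie in (0, 1)", call. = FALSE)
  }
  t0 <- Sys.time()
  data <- simulate_moa_dataset(cfg)

  mps <- lapply(data$coverage, function(cov) {
    pooled <- aggregate_replicates(cov)
    m <- call_mps(pooled, data$sites)
    m <- call_amps(m, fdr = amp_fdr)
    wgs_control_filter(m, data$wgs)
  })

  pred <- build_site_predictors(mps[[1L]][mps[[1L]]$is_mp, , drop = FALSE],
                                data$genotypes, data$methylomes$windows,
                                data$sites)
  bqtl <- map_bqtl(pred, fdr = bqtl_fdr)

  # methylation-occupancy concordance at AMPs
  amp1 <- mps[[1L]][mps[[1L]]$is_amp, , drop = FALSE]
  w <- data$methylomes$windows
  key <- paste(w$site_id, w$line_id)
  ref <- w$allele == "ref"
  mcls <- classify_differential(
    setNames((w$mCG[ref] + w$mCHG[ref]) / 2, key[ref])[
      paste(amp1$site_id, amp1$line_id)],
    setNames((w$mCG[!ref] + w$mCHG[!ref]) / 2, key[!ref])[
      paste(amp1$site_id, amp1$line_id)]
  )
  amp1$meth_class <- mcls
  concord <- bias_concordance(amp1)

  # condition groups where a second condition exists
  groups <- NULL
  if (length(cfg$conditions) > 1L) {
    m1 <- mps[[1L]]; m2 <- mps[[2L]]
    k1 <- paste(m1$site_id, m1$line_id)
    k2 <- paste(m2$site_id, m2$line_id)
    i2 <- match(k1, k2)
    pairs <- data.frame(
      site_id = m1$site_id, line_id = m1$line_id,
      detected_ww = m1$is_mp, detected_ds = m2$is_mp[i2],
      freq_ww = m1$binding_frequency, freq_ds = m2$binding_frequency[i2],
      amp_ww = m1$is_amp, amp_ds = m2$is_amp[i2],
      stringsAsFactors = FALSE
    )
    pairs$group <- classify_condition_amps(pairs)
    groups <- pairs
  }

  # small heritability-recovery run on markers split by bQTL status
  vcap <- NULL
  sig_ids <- bqtl$site_id[bqtl$sig_class != "none"]
  if (length(sig_ids) >= 5L && ncol(data$genotypes) - length(sig_ids) >= 20L) {
    vcap <- .with_seed(.stage_seed(cfg, "traits"), {
      bg_ids <- sample_matched_background(sig_ids, data$sites)
      rest <- setdiff(colnames(data$genotypes), c(sig_ids, bg_ids))
      Ks <- list(
        bqtl = build_kinship(data$genotypes[, sig_ids, drop = FALSE]),
        bg = build_kinship(data$genotypes[, bg_ids, drop = FALSE]),
        rest = build_kinship(data$genotypes[, rest, drop = FALSE])
      )
      recovery_experiment(Ks, list(c(0.4, 0.2, 0.2)), n_traits_per_set = 5L)
    })
  }

  counts <- c(
    sites = nrow(data$sites),
    mp_records = sum(vapply(mps, function(m) sum(m$is_mp), numeric(1))),
    amp_records = sum(vapply(mps, function(m) sum(m$is_amp), numeric(1))),
    wgs_excluded = sum(vapply(mps, function(m) sum(m$wgs_excluded),
                              numeric(1))),
    bqtl_tested = nrow(bqtl),
    bqtl_significant = sum(bqtl$sig_class != "none"),
    linkage_groups = length(unique(stats::na.omit(bqtl$group_id)))
  )
  manifest <- list(
    config = unclass(cfg), seed = cfg$seed, counts = counts,
    started = t0, finished = Sys.time(),
    package_version = as.character(utils::packageVersion("pancistrome"))
  )
  if (!is.null(out_dir)) {
    write_fixtures(
      list(sites = data$sites, genotypes = data$genotypes,
           methylomes = data$methylomes$windows,
           mps_ww = mps[[1L]], bqtl = bqtl,
           peaks = data$annotation$peaks, genes = data$annotation$genes),
      out_dir
    )
  }
  list(manifest = manifest, data = data, mps = mps, bqtl = bqtl,
       concordance = concord, condition_groups = groups, vcap = vcap)
}
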