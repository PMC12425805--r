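# Synthetic population, footprint, methylome, and annotation generator.
#
# The generator encodes the causal structure the analysis assumes: occupancy
# of a TF footprint at a biallelic site can be shifted by the paternal
# genotype, by differential allelic DNA methylation (hypomethylated allele
# always at least as occupied), by both, or by nothing (null sites).
# Everything downstream of read alignment is emulated: scaled per-allele
# coverage (RPGC) at variant sites, windowed allelic methylation, gene and
# peak annotations on a linear chromosome, WGS control allelic ratios and
# condition (well-watered vs drought) occupancy shifts.

#' Simulation configuration
#'
#' Builds and validates the configuration object used by every `simulate_*`
#' generator. Defaults describe the study design the package targets: a
#' panel of 25 F1 hybrids sharing one reference parent, biallelic variants
#' whose minor allele occurs in at least two lines, overdispersed sequencing
#' depth, a bimodal allelic methylome and two watering conditions.
#'
#' @param n_lines Number of F1 lines in the panel (shared-mother design).
#' @param n_sites Number of biallelic variant sites to simulate.
#' @param n_genes Number of non-overlapping genes on the synthetic
#'   chromosome.
#' @param genome_length Length of the linear chromosome in bp; defaults to
#'   `max(200000, 200 * n_sites)` so sites do not crowd.
#' @param read_depth_mean Mean total read depth per site, line and
#'   replicate.
#' @param depth_dispersion Overdispersion of the negative-binomial depth
#'   model (`size = 1/depth_dispersion`); 0 gives Poisson depth.
#' @param n_replicates Biological replicates per condition.
#' @param rpgc_scale Scale converting reads to RPGC units (reads ×
#'   `rpgc_scale`); the default 0.3 makes ~25 reads correspond to ~7.5
#'   RPGC, so the MP coverage threshold is exercisable.
#' @param frac_cis_effect Fraction of sites with a genotype-driven
#'   occupancy effect.
#' @param frac_meth_effect Fraction of sites with a methylation-driven
#'   occupancy effect.
#' @param frac_both_effect Fraction of sites with both effects.
#' @param effect_size_delta Binding-frequency shift of a causal allele, in
#'   `[0, 0.5)`.
#' @param meth_high_level,meth_low_level Modes of the bimodal allelic
#'   methylation mixture; the defaults (0.85 / 0.02) keep the
#'   `<10%` / `>70%` differential rule cleanly separated from the modes.
#' @param conditions Character vector of condition labels.
#' @param drought_effect_frac Fraction of sites whose total occupancy is
#'   rescaled under the second condition (allelic bias preserved).
#' @param peak_fraction Fraction of the genome covered by footprint peaks.
#' @param frac_sites_in_peak Fraction of variant sites placed inside peaks.
#' @param wgs_artifact_frac Fraction of sites given an extreme (mapping
#'   artifact like) WGS control ratio.
#' @param n_gwas_hits Number of synthetic GWAS hit positions.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_lines = 25L,
                       n_sites = 1000L,
                       n_genes = 100L,
                       genome_length = NULL,
                       read_depth_mean = 100,
                       depth_dispersion = 0.1,
                       n_replicates = 3L,
                       rpgc_scale = 0.3,
                       frac_cis_effect = 0.05,
                       frac_meth_effect = 0.05,
                       frac_both_effect = 0,
                       effect_size_delta = 0.25,
                       meth_high_level = 0.85,
                       meth_low_level = 0.02,
                       conditions = c("WW", "DS"),
                       drought_effect_frac = 0.1,
                       peak_fraction = 0.02,
                       frac_sites_in_peak = 0.9,
                       wgs_artifact_frac = 0.02,
                       n_gwas_hits = 50L,
                       seed = 1L) {
  n_lines <- .assert_count(n_lines, "n_lines", min = 2L)
  n_sites <- .assert_count(n_sites, "n_sites", min = 1L)
  n_genes <- .assert_count(n_genes, "n_genes", min = 1L)
  n_replicates <- .assert_count(n_replicates, "n_replicates", min = 1L)
  if (is.null(genome_length)) {
    genome_length <- max(200000L, 200L * n_sites)
  }
  genome_length <- .assert_count(genome_length, "genome_length", min = 1000L)
  if (!is.numeric(read_depth_mean) || read_depth_mean <= 0) {
    stop("`read_depth_mean` must be > 0", call. = FALSE)
  }
  if (!is.numeric(depth_dispersion) || depth_dispersion < 0) {
    stop("`depth_dispersion` must be >= 0", call. = FALSE)
  }
  for (nm in c("frac_cis_effect", "frac_meth_effect", "frac_both_effect",
               "meth_high_level", "meth_low_level", "drought_effect_frac",
               "peak_fraction", "frac_sites_in_peak", "wgs_artifact_frac")) {
    .assert_proportion(get(nm), nm)
  }
  if (frac_cis_effect + frac_meth_effect + frac_both_effect > 1) {
    stop("causal fractions must sum to <= 1", call. = FALSE)
  }
  if (effect_size_delta < 0 || effect_size_delta >= 0.5) {
    stop("`effect_size_delta` must lie in [0, 0.5)", call. = FALSE)
  }
  if (length(conditions) < 1L) stop("need at least one condition")
  cfg <- list(
    n_lines = n_lines, n_sites = n_sites, n_genes = n_genes,
    genome_length = genome_length, read_depth_mean = read_depth_mean,
    depth_dispersion = depth_dispersion, n_replicates = n_replicates,
    rpgc_scale = rpgc_scale,
    frac_cis_effect = frac_cis_effect, frac_meth_effect = frac_meth_effect,
    frac_both_effect = frac_both_effect,
    effect_size_delta = effect_size_delta,
    meth_high_level = meth_high_level, meth_low_level = meth_low_level,
    conditions = as.character(conditions),
    drought_effect_frac = drought_effect_frac,
    peak_fraction = peak_fraction,
    frac_sites_in_peak = frac_sites_in_peak,
    wgs_artifact_frac = wgs_artifact_frac,
    n_gwas_hits = as.integer(n_gwas_hits),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d F1 lines, %d sites, %d genes on %s bp\n",
              x$n_lines, x$n_sites, x$n_genes,
              format(x$genome_length, big.mark = ",")))
  cat(sprintf("  depth %.0f (dispersion %.2g), %d replicates, conditions: %s\n",
              x$read_depth_mean, x$depth_dispersion, x$n_replicates,
              paste(x$conditions, collapse = "/")))
  cat(sprintf("  causal fractions geno/meth/both: %.2g/%.2g/%.2g, delta %.2g\n",
              x$frac_cis_effect, x$frac_meth_effect, x$frac_both_effect,
              x$effect_size_delta))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# Fixed per-stage seed offsets so stages are independently reproducible.
.SEED_OFFSETS <- c(
  annotations = 101L, genotypes = 211L, methylomes = 307L,
  binding = 401L, wgs = 701L, traits = 811L
)

.stage_seed <- function(cfg, stage) {
  (cfg$seed * 1000L + .SEED_OFFSETS[[stage]]) %% 2147483647L
}

#' Simulate gene, peak and GWAS-hit annotations
#'
#' Places non-overlapping genes and footprint peaks on a single linear
#' chromosome and draws GWAS hit positions. All intervals are 0-based
#' half-open. Peak widths are drawn around the ~100 bp footprint scale and
#' their number is chosen so that the requested genome fraction is covered.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genes` (gene_id, chrom, start, end, strand, tss,
#'   tts), `peaks` (chrom, start, end), `gwas_hits` (integer positions) and
#'   `genome_length`.
#' @export
simulate_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(.stage_seed(cfg, "annotations"), {
    L <- cfg$genome_length
    # genes: partition the chromosome into n_genes slots, one gene per slot
    slot <- L %/% cfg$n_genes
    glen <- pmin(pmax(round(stats::rnorm(cfg$n_genes, 3000, 800)), 500),
                 slot - 2L)
    gstart <- (seq_len(cfg$n_genes) - 1L) * slot +
      floor(stats::runif(cfg$n_genes) * (slot - glen))
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
      chrom = "chr1",
      start = as.integer(gstart),
      end = as.integer(gstart + glen),
      strand = strand,
      stringsAsFactors = FALSE
    )
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    genes$tts <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)

    # peaks: widths around the footprint scale, count set by target coverage
    target_bp <- cfg$peak_fraction * L
    widths <- integer(0)
    while (sum(widths) < target_bp) {
      widths <- c(widths, as.integer(round(stats::runif(256, 60, 140))))
    }
    widths <- widths[cumsum(widths) <= target_bp]
    if (length(widths) == 0L) widths <- as.integer(round(target_bp))
    n_peaks <- length(widths)
    # non-overlapping placement: spread starts over the free space
    free <- L - sum(widths)
    gaps <- stats::rmultinom(1, free, rep(1, n_peaks + 1L))[, 1L]
    starts <- cumsum(gaps[seq_len(n_peaks)] + c(0L, widths[-n_peaks]))
    peaks <- data.frame(
      chrom = "chr1",
      start = as.integer(starts),
      end = as.integer(starts + widths),
      stringsAsFactors = FALSE
    )
    gwas_hits <- sort(sample.int(L, cfg$n_gwas_hits) - 1L)
    list(genes = genes, peaks = peaks, gwas_hits = gwas_hits,
         genome_length = L)
  })
}

#' Simulate biallelic variant sites and the parental genotype matrix
#'
#' Sites are biallelic SNPs whose non-reference allele is carried by at
#' least two of the `n_lines` paternal parents (the retention rule of the
#' study design, implying a minimum minor allele frequency of
#' `2 / n_lines`). Each site is annotated with distance to the nearest gene
#' (0 if intragenic), peak membership and a hidden causal class used by the
#' binding model.
#'
#' @param cfg A [sim_config()].
#' @param annotation Optional output of [simulate_annotations()]; generated
#'   from `cfg` when omitted.
#' @return A list with `sites` (data.frame: site_id, chrom, pos, af,
#'   n_alt_lines, dist_to_gene, in_peak, causal_class) and `genotypes`
#'   (integer matrix lines x sites; 1 = paternal allele is the alternative
#'   allele).
#' @export
simulate_genotypes <- function(cfg, annotation = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_lines < 2L) stop("n_lines must be >= 2", call. = FALSE)
  if (is.null(annotation)) annotation <- simulate_annotations(cfg)
  .with_seed(.stage_seed(cfg, "genotypes"), {
    n <- cfg$n_sites
    L <- annotation$genome_length
    peaks <- annotation$peaks

    # site positions: a configured fraction inside peaks, the rest uniform
    n_in <- round(cfg$frac_sites_in_peak * n)
    pos_in <- integer(0)
    if (n_in > 0 && nrow(peaks) > 0) {
      w <- peaks$end - peaks$start
      pk <- sample.int(nrow(peaks), n_in, replace = TRUE, prob = w)
      pos_in <- peaks$start[pk] +
        floor(stats::runif(n_in) * w[pk])
    }
    pos_out <- if (n - length(pos_in) > 0) {
      sample.int(L, n - length(pos_in)) - 1L
    } else integer(0)
    pos <- sort(unique(as.integer(c(pos_in, pos_out))))
    while (length(pos) < n) { # resolve collisions
      extra <- sample.int(L, n - length(pos)) - 1L
      pos <- sort(unique(c(pos, extra)))
    }
    pos <- pos[seq_len(n)]

    # carrier counts >= 2: mild rare-allele skew over 2..n_lines
    kk <- 2:cfg$n_lines
    carriers <- kk[sample.int(length(kk), n, replace = TRUE, prob = 1 / kk)]
    G <- matrix(0L, nrow = cfg$n_lines, ncol = n,
                dimnames = list(sprintf("L%02d", seq_len(cfg$n_lines)),
                                sprintf("s%05d", seq_len(n))))
    for (j in seq_len(n)) {
      G[sample.int(cfg$n_lines, carriers[j]), j] <- 1L
    }

    classes <- sample(
      c("geno", "meth", "both", "null"), n, replace = TRUE,
      prob = c(cfg$frac_cis_effect, cfg$frac_meth_effect,
               cfg$frac_both_effect,
               1 - cfg$frac_cis_effect - cfg$frac_meth_effect -
                 cfg$frac_both_effect)
    )

    site_gr <- .granges_from_positions("chr1", pos)
    gene_gr <- .granges_from_intervals(annotation$genes)
    hit <- GenomicRanges::distanceToNearest(site_gr, gene_gr)
    dist <- rep(NA_integer_, n)
    # GRanges distance counts the gap (adjacent = 0); convert to base-pair
    # separation, keeping 0 for intragenic sites
    gap <- S4Vectors::mcols(hit)$distance
    inside <- IRanges::overlapsAny(site_gr, gene_gr)
    dist[S4Vectors::queryHits(hit)] <- gap + 1L
    dist[inside] <- 0L
    peak_gr <- .granges_from_intervals(peaks)
    in_peak <- IRanges::overlapsAny(site_gr, peak_gr)

    sites <- data.frame(
      site_id = colnames(G),
      chrom = "chr1",
      pos = pos,
      af = carriers / cfg$n_lines,
      n_alt_lines = carriers,
      dist_to_gene = dist,
      in_peak = in_peak,
      causal_class = classes,
      stringsAsFactors = FALSE
    )
    list(sites = sites, genotypes = G)
  })
}

#' Simulate windowed allelic methylomes
#'
#' Draws per-site, per-line, per-allele mean methylation levels in the CG,
#' CHG and CHH contexts from a bimodal mixture with modes near
#' `meth_low_level` and `meth_high_level`. Sites whose causal class
#' involves methylation are made differentially methylated: on haplotypes
#' carrying the alternative allele one allele sits below 10% and the other
#' above 70% methylation (CG and CHG; CHH is kept uniformly low, matching
#' the observation that CG/CHG account for essentially all allelic
#' methylation differences at footprint sites).
#'
#' @param sites Site table from [simulate_genotypes()].
#' @param cfg A [sim_config()].
#' @param genotypes Genotype matrix from [simulate_genotypes()].
#' @return A list with `windows` (data.frame: site_id, line_id, allele
#'   (`"ref"`/`"pat"`), mCG, mCHG, mCHH) and `truth` (data.frame: site_id,
#'   is_diff, hypo_allele).
#' @export
simulate_methylomes <- function(sites, cfg, genotypes) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(.stage_seed(cfg, "methylomes"), {
    n <- nrow(sites)
    lines <- rownames(genotypes)
    is_diff <- sites$causal_class %in% c("meth", "both")
    hypo <- ifelse(is_diff, sample(c("ref", "pat"), n, replace = TRUE),
                   NA_character_)
    # background state shared by both alleles at non-differential sites:
    # TF-footprint sites are mostly hypomethylated
    base_high <- stats::runif(n) < 0.25

    draw_low <- function(k) {
      pmin(pmax(stats::rnorm(k, cfg$meth_low_level, 0.015), 0), 0.08)
    }
    draw_high <- function(k) {
      pmin(pmax(stats::rnorm(k, cfg$meth_high_level, 0.04), 0.72), 1)
    }

    grid <- expand.grid(line = seq_along(lines), site = seq_len(n),
                        KEEP.OUT.ATTRS = FALSE)
    m <- nrow(grid)
    sd_site <- is_diff[grid$site]
    hy <- hypo[grid$site]
    hi_bg <- base_high[grid$site]

    # The maternal (reference) haplotype is one inbred shared by every F1,
    # so its state is constant across lines. Paternal epialleles segregate
    # across the diverse fathers independently of the site's own SNP
    # genotype (methylation is not determined by the local base), so at
    # differentially methylated sites each line's paternal haplotype
    # carries the variant epiallele with probability 1/2.
    epi <- stats::runif(m) < 0.5
    ref_high <- ifelse(sd_site, hy == "pat", hi_bg)
    pat_high <- ifelse(sd_site & epi, hy == "ref", ref_high)

    mk <- function(high) {
      cg <- ifelse(high, draw_high(m), draw_low(m))
      chg <- pmin(pmax(cg + stats::rnorm(m, 0, 0.02), 0), 1)
      chh <- pmin(pmax(stats::rnorm(m, 0.03, 0.01), 0), 1)
      list(cg = cg, chg = chg, chh = chh)
    }
    r <- mk(ref_high)
    p <- mk(pat_high)

    windows <- data.frame(
      site_id = rep(sites$site_id[grid$site], 2L),
      line_id = rep(lines[grid$line], 2L),
      allele = rep(c("ref", "pat"), each = m),
      mCG = c(r$cg, p$cg),
      mCHG = c(r$chg, p$chg),
      mCHH = c(r$chh, p$chh),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(site_id = sites$site_id, is_diff = is_diff,
                        hypo_allele = hypo, stringsAsFactors = FALSE)
    list(windows = windows, truth = truth)
  })
}

#' Simulate the true occupancy model
#'
#' Combines genotype and methylation effects into a per-site, per-line,
#' per-condition true binding frequency (fraction of occupancy on the
#' reference allele) through a logistic link:
#' `f = plogis(bG * genotype + bM * (m_pat - m_ref))`, with `bM > 0` so a
#' hypomethylated reference allele always pulls occupancy toward the
#' reference. Null sites have frequency 0.5 in every line. A configured
#' fraction of sites is drought-responsive: under the second condition
#' their total occupancy (expected depth) is rescaled while the allelic
#' bias is preserved.
#'
#' @param sites,genotypes Output of [simulate_genotypes()].
#' @param methylomes Output of [simulate_methylomes()].
#' @param cfg A [sim_config()].
#' @return An object of class `"synthetic_truth"`: list with `freq`
#'   (sites x lines matrix), `class` (per-site causal class), `effect_dir`
#'   (per-site sign of the genotype effect), `depth_mult` (sites x
#'   conditions matrix of depth multipliers), `drought_responsive`
#'   (logical), `meth_truth`.
#' @export
simulate_binding_model <- function(sites, genotypes, methylomes, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(.stage_seed(cfg, "binding"), {
    n <- nrow(sites)
    n_lines <- nrow(genotypes)
    delta <- cfg$effect_size_delta
    bG_mag <- stats::qlogis(0.5 + delta)
    bM <- stats::qlogis(0.5 + delta) / 0.8   # |m_pat - m_ref| ~ 0.8 at diff sites

    dir_g <- sample(c(-1, 1), n, replace = TRUE)
    has_g <- sites$causal_class %in% c("geno", "both")
    has_m <- sites$causal_class %in% c("meth", "both")

    w <- methylomes$windows
    mwide <- (w$mCG + w$mCHG) / 2
    key <- paste(w$site_id, w$line_id)
    ref <- w$allele == "ref"
    mref <- setNames(mwide[ref], key[ref])
    mpat <- setNames(mwide[!ref], key[!ref])
    kmat <- outer(sites$site_id, rownames(genotypes), paste)
    mdiff <- matrix(mpat[kmat] - mref[kmat], nrow = n, byrow = FALSE)

    eta <- matrix(0, n, n_lines)
    eta <- eta + (has_g * dir_g * bG_mag) * t(genotypes)
    eta <- eta + ifelse(matrix(has_m, n, n_lines), bM * mdiff, 0)
    freq <- stats::plogis(eta)
    dimnames(freq) <- list(sites$site_id, rownames(genotypes))

    resp <- stats::runif(n) < cfg$drought_effect_frac
    depth_mult <- matrix(1, n, length(cfg$conditions),
                         dimnames = list(sites$site_id, cfg$conditions))
    if (length(cfg$conditions) > 1L) {
      mult <- ifelse(stats::runif(n) < 0.5, stats::runif(n, 0.05, 0.5),
                     stats::runif(n, 2, 4))
      depth_mult[resp, 2L] <- mult[resp]
    }
    out <- list(freq = freq, class = sites$causal_class, effect_dir = dir_g,
                depth_mult = depth_mult, drought_responsive = resp,
                meth_truth = methylomes$truth)
    class(out) <- "synthetic_truth"
    out
  })
}

#' Simulate per-replicate allele-specific footprint coverage
#'
#' Total depth at each site x line x replicate follows an overdispersed
#' (negative binomial) count model around `read_depth_mean` (times the
#' site's condition depth multiplier); reference-allele reads are binomial
#' in the true binding frequency; RPGC values are reads times the
#' configured scale.
#'
#' @param truth A [simulate_binding_model()] result.
#' @param cfg A [sim_config()].
#' @param condition Condition label (must appear in `cfg$conditions`).
#' @return data.frame with columns site_id, line_id, condition, replicate,
#'   reads_ref, reads_pat, rpgc_ref, rpgc_pat.
#' @export
simulate_moa_counts <- function(truth, cfg, condition = cfg$conditions[1L]) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "synthetic_truth"))
  ci <- match(condition, cfg$conditions)
  if (is.na(ci)) stop("unknown condition: ", condition, call. = FALSE)
  .with_seed(.stage_seed(cfg, "binding") + 13L * ci, {
    n <- nrow(truth$freq)
    lines <- colnames(truth$freq)
    n_lines <- length(lines)
    reps <- cfg$n_replicates
    m <- n * n_lines * reps
    site_i <- rep(seq_len(n), times = n_lines * reps)
    line_i <- rep(rep(seq_len(n_lines), each = n), times = reps)
    rep_i <- rep(seq_len(reps), each = n * n_lines)
    mu <- cfg$read_depth_mean * truth$depth_mult[site_i, ci]
    depth <- if (cfg$depth_dispersion > 0) {
      stats::rnbinom(m, mu = mu, size = 1 / cfg$depth_dispersion)
    } else {
      stats::rpois(m, mu)
    }
    f <- truth$freq[cbind(site_i, line_i)]
    reads_ref <- stats::rbinom(m, depth, f)
    data.frame(
      site_id = rownames(truth$freq)[site_i],
      line_id = lines[line_i],
      condition = condition,
      replicate = rep_i,
      reads_ref = reads_ref,
      reads_pat = depth - reads_ref,
      rpgc_ref = reads_ref * cfg$rpgc_scale,
      rpgc_pat = (depth - reads_ref) * cfg$rpgc_scale,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate WGS control allelic ratios
#'
#' Genomic-DNA control ratios are centered at 0.5 (Beta distributed); a
#' configured fraction of sites emulates mapping artifacts with ratios far
#' in the tails, the situation the WGS percentile filter removes.
#'
#' @param sites Site table.
#' @param cfg A [sim_config()].
#' @param concentration Beta concentration of the central mass.
#' @return data.frame with site_id, wgs_ratio, is_artifact.
#' @export
simulate_wgs_controls <- function(sites, cfg, concentration = 100) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(.stage_seed(cfg, "wgs"), {
    n <- nrow(sites)
    ratio <- stats::rbeta(n, concentration, concentration)
    art <- stats::runif(n) < cfg$wgs_artifact_frac
    n_art <- sum(art)
    if (n_art > 0) {
      lo <- stats::runif(n_art) < 0.5
      extreme <- ifelse(lo, stats::rbeta(n_art, 2, 60),
                        stats::rbeta(n_art, 60, 2))
      ratio[art] <- extreme
    }
    data.frame(site_id = sites$site_id, wgs_ratio = ratio,
               is_artifact = art, stringsAsFactors = FALSE)
  })
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper running every generator in dependency order:
#' annotations, genotypes, methylomes, binding model, per-condition
#' per-replicate coverage, and WGS controls.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `config`, `annotation`, `sites`,
#'   `genotypes`, `methylomes`, `truth`, `coverage` (one data.frame per
#'   condition), `wgs`.
#' @export
simulate_moa_dataset <- function(cfg) {
  ann <- simulate_annotations(cfg)
  gt <- simulate_genotypes(cfg, ann)
  meth <- simulate_methylomes(gt$sites, cfg, gt$genotypes)
  truth <- simulate_binding_model(gt$sites, gt$genotypes, meth, cfg)
  cov <- lapply(setNames(cfg$conditions, cfg$conditions), function(cond) {
    simulate_moa_counts(truth, cfg, cond)
  })
  wgs <- simulate_wgs_controls(gt$sites, cfg)
  list(config = cfg, annotation = ann, sites = gt$sites,
       genotypes = gt$genotypes, methylomes = meth, truth = truth,
       coverage = cov, wgs = wgs)
}

#' Write simulated tables to plain-text fixtures
#'
#' Interval tables (`genes`, `peaks`) are written as BED (0-based
#' half-open, via rtracklayer); per-base tracks as bedGraph; everything
#' else as TSV with a header row. [read_fixtures()] round-trips the files.
#'
#' @param tables Named list; data.frames with chrom/start/end columns named
#'   `genes` or `peaks` become BED, elements of class `coverage_track`
#'   become bedGraph, remaining data.frames/matrices become TSV.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_fixtures <- function(tables, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  written <- character(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (inherits(x, "coverage_track")) {
      path <- file.path(dir, paste0(nm, ".bedGraph"))
      .write_bedgraph(x, path)
    } else if (is.data.frame(x) &&
               all(c("chrom", "start", "end") %in% names(x))) {
      path <- file.path(dir, paste0(nm, ".bed"))
      gr <- .granges_from_intervals(x)
      if ("gene_id" %in% names(x)) {
        gr$name <- x$gene_id
        gr$score <- 0L
      }
      rtracklayer::export(gr, path, format = "BED")
    } else {
      path <- file.path(dir, paste0(nm, ".tsv"))
      df <- if (is.matrix(x)) {
        data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
      } else x
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    written <- c(written, path)
  }
  invisible(written)
}

#' Read fixtures written by [write_fixtures()]
#'
#' @param dir Directory containing the fixture files.
#' @return Named list of data.frames (TSV/BED) and `coverage_track`
#'   run-length tables (bedGraph as chrom/start/end/value data.frames).
#' @export
read_fixtures <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  out <- list()
  for (f in files) {
    nm <- sub("\\.[^.]+$", "", basename(f))
    ext <- tolower(sub(".*\\.", "", f))
    out[[nm]] <- switch(
      ext,
      tsv = utils::read.table(f, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE),
      bed = .intervals_from_granges(rtracklayer::import(f, format = "BED")),
      bedgraph = {
        gr <- rtracklayer::import(f, format = "bedGraph")
        df <- .intervals_from_granges(gr)
        df$value <- gr$score
        df
      },
      stop("unrecognized fixture: ", f)
    )
  }
  out
}

.write_bedgraph <- function(track, path) {
  cov <- track$coverage
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values != 0
  df <- data.frame(chrom = track$chrom, start = starts[keep],
                   end = ends[keep], value = r$values[keep])
  gr <- .granges_from_intervals(df)
  gr$score <- df$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
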