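test_that("simulated genotypes obey the two-line retention rule", {
  cfg <- sim_config(n_lines = 25L, n_sites = 300L, seed = 2L)
  g <- simulate_genotypes(cfg)
  expect_true(all(colSums(g$genotypes) >= 2))
  expect_equal(min(g$sites$af), 2 / 25)
  expect_equal(g$sites$af, colSums(g$genotypes) / 25, ignore_attr = TRUE)
  expect_true(all(g$sites$pos >= 0 & g$sites$pos < cfg$genome_length))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_sites = 60L, seed = 7L)
  expect_identical(simulate_moa_dataset(cfg), simulate_moa_dataset(cfg))
  cfg2 <- sim_config(n_sites = 60L, seed = 8L)
  expect_false(identical(simulate_genotypes(cfg)$genotypes,
                         simulate_genotypes(cfg2)$genotypes))
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(n_lines = 1L), "n_lines")
  expect_error(sim_config(effect_size_delta = 0.6), "effect_size_delta")
  expect_error(sim_config(frac_cis_effect = 1.4), "frac_cis_effect")
  expect_error(sim_config(read_depth_mean = 0), "read_depth_mean")
})

test_that("differentially methylated sites satisfy the <10%/>70% rule", {
  cfg <- sim_config(n_sites = 400L, frac_meth_effect = 0.3, seed = 5L)
  g <- simulate_genotypes(cfg)
  meth <- simulate_methylomes(g$sites, cfg, g$genotypes)
  w <- meth$windows
  truth <- meth$truth
  diff_sites <- truth$site_id[truth$is_diff]
  # at each differential site some line must show one allele < 0.10 and
  # the other > 0.70 (in CG), and the direction must match the truth
  for (s in head(diff_sites, 20)) {
    ref <- w[w$site_id == s & w$allele == "ref", ]
    pat <- w[w$site_id == s & w$allele == "pat", ]
    pat <- pat[match(ref$line_id, pat$line_id), ]
    cls <- classify_differential(ref$mCG, pat$mCG)
    expect_true(any(cls != "not_differential"))
    hypo <- truth$hypo_allele[truth$site_id == s]
    expect_true(all(cls[cls != "not_differential"] ==
                      paste0(hypo, "_hypo")))
  }
  # CHH never drives differences
  expect_true(all(w$mCHH < 0.10))
})

test_that("no differential methylation when the effect fraction is zero", {
  cfg <- sim_config(n_sites = 300L, frac_meth_effect = 0,
                    frac_both_effect = 0, seed = 9L)
  g <- simulate_genotypes(cfg)
  meth <- simulate_methylomes(g$sites, cfg, g$genotypes)
  w <- meth$windows
  ref <- w[w$allele == "ref", ]
  pat <- w[w$allele == "pat", ]
  pat <- pat[match(paste(ref$site_id, ref$line_id),
                   paste(pat$site_id, pat$line_id)), ]
  cls <- classify_differential(ref$mCG, pat$mCG)
  expect_true(all(cls == "not_differential"))
})

test_that("binding model is null at null sites and directional at
           methylation-driven sites", {
  cfg <- sim_config(n_sites = 300L, frac_meth_effect = 0.2, seed = 4L)
  g <- simulate_genotypes(cfg)
  meth <- simulate_methylomes(g$sites, cfg, g$genotypes)
  truth <- simulate_binding_model(g$sites, g$genotypes, meth, cfg)
  null_sites <- g$sites$causal_class == "null"
  expect_true(all(truth$freq[null_sites, ] == 0.5))
  # hypomethylated allele never has lower expected occupancy
  w <- meth$windows
  key <- paste(w$site_id, w$line_id)
  ref <- w$allele == "ref"
  md <- setNames(w$mCG[!ref] + w$mCHG[!ref], key[!ref]) -
    setNames(w$mCG[ref] + w$mCHG[ref], key[ref])[key[!ref]]
  for (s in which(g$sites$causal_class == "meth")) {
    for (l in colnames(truth$freq)) {
      d <- md[paste(g$sites$site_id[s], l)]
      f <- truth$freq[s, l]
      if (d > 0) expect_gte(f, 0.5) else if (d < 0) expect_lte(f, 0.5)
    }
  }
})

test_that("null-site observed allele frequency is calibrated at 0.5", {
  cfg <- sim_config(n_sites = 2000L, frac_cis_effect = 0,
                    frac_meth_effect = 0, frac_both_effect = 0,
                    read_depth_mean = 50, seed = 21L)
  d <- simulate_moa_dataset(cfg)
  cov <- d$coverage$WW
  tot <- sum(cov$reads_ref) + sum(cov$reads_pat)
  fhat <- sum(cov$reads_ref) / tot
  se <- sqrt(0.25 / tot)
  expect_lt(abs(fhat - 0.5), 3 * se + 1e-12)
})

test_that("zero depth gives zero counts and coverage", {
  cfg <- sim_config(n_sites = 40L, read_depth_mean = 1e-9,
                    depth_dispersion = 0, seed = 3L)
  d <- simulate_moa_dataset(cfg)
  cov <- d$coverage$WW
  expect_true(all(cov$reads_ref == 0 & cov$reads_pat == 0))
  expect_true(all(cov$rpgc_ref == 0 & cov$rpgc_pat == 0))
})

test_that("peaks cover the configured genome fraction", {
  cfg <- sim_config(n_sites = 100L, genome_length = 1000000L,
                    peak_fraction = 0.02, seed = 6L)
  ann <- simulate_annotations(cfg)
  covered <- sum(ann$peaks$end - ann$peaks$start) / ann$genome_length
  expect_lt(abs(covered - 0.02), 0.005)
  # non-overlapping, valid intervals
  expect_true(all(ann$peaks$end > ann$peaks$start))
  o <- order(ann$peaks$start)
  expect_true(all(diff(ann$peaks$start[o]) >=
                    (ann$peaks$end - ann$peaks$start)[o][-nrow(ann$peaks)]))
  # genes non-overlapping too
  og <- order(ann$genes$start)
  expect_true(all(ann$genes$start[og][-1] >= ann$genes$end[og][-length(og)]))
})

test_that("site annotations agree with interval arithmetic", {
  d <- small_data()
  ann <- d$annotation
  for (i in sample(nrow(d$sites), 25)) {
    pos <- d$sites$pos[i]
    inp <- any(pos >= ann$peaks$start & pos < ann$peaks$end)
    expect_identical(d$sites$in_peak[i], inp)
    dd <- pmax(0, pmax(ann$genes$start - pos, pos - (ann$genes$end - 1)))
    expect_equal(d$sites$dist_to_gene[i], min(dd), ignore_attr = TRUE)
  }
})

test_that("WGS controls center at 0.5 with artifacts in the tails", {
  cfg <- sim_config(n_sites = 2000L, wgs_artifact_frac = 0, seed = 12L)
  g <- simulate_genotypes(cfg)
  w0 <- simulate_wgs_controls(g$sites, cfg)
  expect_false(any(w0$is_artifact))
  expect_lt(abs(mean(w0$wgs_ratio) - 0.5), 0.01)
  cfg2 <- sim_config(n_sites = 2000L, wgs_artifact_frac = 0.05, seed = 12L)
  w1 <- simulate_wgs_controls(g$sites, cfg2)
  qs <- quantile(w0$wgs_ratio, c(0.05, 0.95))
  art <- w1$wgs_ratio[w1$is_artifact]
  expect_true(all(art < qs[1] | art > qs[2]))
})

test_that("fixtures round-trip through BED/bedGraph/TSV", {
  d <- small_data()
  td <- withr::local_tempdir()
  track <- fragment_center_track(data.frame(start = c(10L, 40L),
                                            end = c(41L, 81L)),
                                 1000, 2, 500)
  write_fixtures(list(sites = d$sites, genotypes = d$genotypes,
                      peaks = d$annotation$peaks,
                      genes = d$annotation$genes,
                      track = track), td)
  r <- read_fixtures(td)
  expect_equal(r$sites, d$sites)
  expect_equal(as.matrix(r$genotypes[, -1]), d$genotypes,
               ignore_attr = TRUE)
  expect_equal(r$peaks[, c("chrom", "start", "end")], d$annotation$peaks)
  expect_setequal(r$genes$name, d$annotation$genes$gene_id)
  # bedGraph mass equals track mass
  expect_equal(sum((r$track$end - r$track$start) * r$track$value),
               sum(track$coverage))
  # empty table: header-only file read back empty
  write_fixtures(list(empty = d$sites[0, ]), td)
  expect_identical(nrow(read_fixtures(td)$empty), 0L)
})
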