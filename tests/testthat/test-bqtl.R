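test_that("local model p-values match the normal-equations oracle", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 20
    site <- data.frame(
      binding_frequency = runif(n),
      genotype = rbinom(n, 1, 0.4),
      mCG = runif(n), mCHG = runif(n), mCHH = runif(n, 0, 0.1)
    )
    f <- fit_local_models(site)
    expect_equal(f$p_geno,
                 unname(oracle_ols_p(site$binding_frequency,
                                     site$genotype)),
                 tolerance = 1e-10)
    expect_equal(f$p_mcg,
                 unname(oracle_ols_p(site$binding_frequency, site$mCG)),
                 tolerance = 1e-10)
    pf <- oracle_ols_p(site$binding_frequency,
                       as.matrix(site[, c("genotype", "mCG", "mCHG",
                                          "mCHH")]))
    expect_equal(c(f$p_full_geno, f$p_full_mcg, f$p_full_mchg,
                   f$p_full_mchh),
                 unname(pf), tolerance = 1e-10)
  }
})

test_that("clear genotype effects are detected and degenerate predictors
           give missing p-values", {
  site <- data.frame(
    binding_frequency = c(0.50, 0.52, 0.48, 0.80, 0.82, 0.78),
    genotype = c(0, 0, 0, 1, 1, 1),
    mCG = c(0.1, 0.12, 0.09, 0.11, 0.10, 0.12),
    mCHG = c(0.1, 0.12, 0.09, 0.11, 0.10, 0.12),
    mCHH = c(0.02, 0.02, 0.03, 0.02, 0.02, 0.03)
  )
  f <- fit_local_models(site)
  expect_lt(f$p_geno, 0.01)
  # constant genotype -> missing
  site$genotype <- 1
  expect_true(is.na(fit_local_models(site)$p_geno))
  # constant response -> all missing
  site$binding_frequency <- 0.5
  f3 <- fit_local_models(site)
  expect_true(all(is.na(unlist(f3[startsWith(names(f3), "p_")]))))
  # all responses missing -> record with all p missing
  site$binding_frequency <- NA_real_
  f4 <- fit_local_models(site)
  expect_true(all(is.na(unlist(f4[startsWith(names(f4), "p_")]))))
})

test_that("per-model FDR selection and attribution behave as a partition", {
  rec <- data.frame(
    p_geno = c(0.001, 0.5, 0.002, NA),
    p_mcg = c(0.9, 0.001, 0.003, 0.2),
    p_mchg = c(0.8, 0.9, 0.9, 0.9),
    p_mchh = c(0.7, 0.8, 0.9, 0.9)
  )
  out <- select_significant(rec, fdr = 0.05)
  expect_equal(out$q_geno[!is.na(out$q_geno)],
               p.adjust(rec$p_geno[!is.na(rec$p_geno)], "BH"))
  cls <- classify_bqtl(out$geno_assoc, out$meth_assoc)
  expect_identical(cls, c("geno_only", "meth_only", "both", "none"))
  # missing p never significant
  expect_false(out$geno_assoc[4])
})

test_that("null sites are selected at roughly the nominal rate", {
  set.seed(99)
  n <- 1000
  p <- data.frame(p_geno = runif(n), p_mcg = runif(n),
                  p_mchg = runif(n), p_mchh = runif(n))
  out <- select_significant(p, fdr = 0.05)
  # BH under the full null: expected false selections ~ 0
  expect_lte(sum(out$geno_assoc), 0.05 * n)
})

test_that("linkage-group clumping equals the transitive-closure oracle", {
  # worked example: 100,150,300 with p .001,.0005,.01
  rec <- data.frame(pos = c(100L, 150L, 300L),
                    p_lead = c(0.001, 0.0005, 0.01))
  out <- clump_linkage_groups(rec)
  expect_identical(out$group_id[1], out$group_id[2])
  expect_false(out$group_id[3] == out$group_id[1])
  expect_identical(out$pos[out$is_lead], c(150L, 300L))
  # boundary: gaps of exactly 65 chain transitively
  rec2 <- data.frame(pos = c(0L, 65L, 130L), p_lead = c(0.5, 0.4, 0.3))
  out2 <- clump_linkage_groups(rec2)
  expect_identical(length(unique(out2$group_id)), 1L)
  # randomized positions against the brute-force oracle
  set.seed(41)
  for (rep in 1:10) {
    n <- 40
    pos <- sort(sample.int(2000, n))
    p <- runif(n)
    rec3 <- data.frame(pos = pos, p_lead = p)
    out3 <- clump_linkage_groups(rec3)
    oc <- oracle_clump(pos, p)
    # identical partitions
    expect_identical(
      as.integer(factor(out3$group_id, levels = unique(out3$group_id))),
      as.integer(factor(oc$component, levels = unique(oc$component)))
    )
    expect_identical(out3$is_lead, oc$is_lead)
  }
  # adjacent-group leads are > 65 apart, members <= 65 apart
  set.seed(42)
  pos <- sort(sample.int(5000, 100))
  out4 <- clump_linkage_groups(data.frame(pos = pos,
                                          p_lead = runif(100)))
  sp <- split(out4$pos, out4$group_id)
  expect_true(all(unlist(lapply(sp, function(x) diff(x) <= 65))))
  gstart <- vapply(sp, min, numeric(1))
  gend <- vapply(sp, max, numeric(1))
  o <- order(gstart)
  expect_true(all(gstart[o][-1] - gend[o][-length(o)] > 65))
})

test_that("map_bqtl recovers planted effects end to end", {
  cfg <- sim_config(n_sites = 400L, frac_cis_effect = 0.1,
                    frac_meth_effect = 0.1, seed = 31L)
  d <- simulate_moa_dataset(cfg)
  m <- call_amps(call_mps(aggregate_replicates(d$coverage$WW), d$sites))
  pred <- build_site_predictors(m[m$is_mp, ], d$genotypes,
                                d$methylomes$windows, d$sites)
  b <- map_bqtl(pred)
  truth <- d$sites$causal_class[match(b$site_id, d$sites$site_id)]
  geno_sites <- truth == "geno"
  expect_gt(mean(b$sig_class[geno_sites] %in% c("geno_only", "both")), 0.8)
  # every significant site has a group, exactly one lead per group
  sig <- b[b$sig_class != "none", ]
  expect_false(anyNA(sig$group_id))
  leads <- tapply(sig$is_lead, sig$group_id, sum)
  expect_true(all(leads == 1))
  expect_error(map_bqtl(pred, fdr = 2), "fdr")
})
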