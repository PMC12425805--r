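test_that("fragment-center windows follow the 20 bp middle-base rule", {
  # odd-length read [100,151): middle base 125, window [115,135)
  set.seed(1)
  tr <- fragment_center_track(data.frame(start = 100L, end = 151L),
                              effective_genome_size = 300,
                              n_mapped = 1, genome_length = 300)
  covered <- which(tr$coverage > 0) - 1L
  expect_identical(range(covered), c(115L, 134L))
  expect_identical(length(covered), 20L)
  # even-length read [100,150): window [114,134) or [115,135)
  hit <- replicate(50, {
    t2 <- fragment_center_track(data.frame(start = 100L, end = 150L),
                                300, 1, 300)
    min(which(t2$coverage > 0)) - 1L
  })
  expect_true(all(hit %in% c(114L, 115L)))
  expect_true(length(unique(hit)) == 2L)  # both middles occur
  # mass conservation: one read, scale s -> total 20 * s
  expect_equal(sum(tr$coverage), 20 * 300)
  expect_error(fragment_center_track(data.frame(start = 10L, end = 10L),
                                     300, 1, 300),
               "positive length")
})

test_that("binding frequency is the B73 share of scaled coverage", {
  expect_equal(binding_frequency(7.5, 2.5), 0.75)
  expect_equal(binding_frequency(0, 5), 0)
  expect_true(is.na(binding_frequency(0, 0)))
  expect_error(binding_frequency(-1, 2), ">= 0")
  # allele swap maps f to 1 - f
  x <- runif(20); y <- runif(20)
  expect_equal(binding_frequency(x, y), 1 - binding_frequency(y, x))
})

test_that("MP calls require peak membership, >7 RPGC and an opposite read", {
  cov <- data.frame(
    site_id = sprintf("s%d", 1:5), line_id = "L01", condition = "WW",
    reads_ref = c(27, 23, 165, 0, 3), reads_pat = c(2, 23, 165, 55, 50),
    rpgc_ref = c(8.0, 7.0, 50, 0, 0.9), rpgc_pat = c(0.6, 7.0, 50, 16.5, 15),
    in_peak = c(TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  m <- call_mps(cov)
  # site 4: the passing allele has no partner read on the other allele
  expect_identical(m$is_mp, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # 7.0 is not > 7; out-of-peak site never an MP
  cov$in_peak <- NA
  expect_error(call_mps(cov), "peak annotation")
  expect_error(call_mps(cov[, setdiff(names(cov), "in_peak")]),
               "in_peak")
})

test_that("AMP p-values equal the exhaustive binomial oracle", {
  # exact match for all outcomes at depths <= 20
  for (n in c(1, 5, 12, 20)) {
    for (x in 0:n) {
      expect_equal(pancistrome:::.binom_p_twosided(x, n),
                   oracle_binom_p(x, n), tolerance = 1e-12)
    }
  }
  # frozen oracle value for the lopsided example
  expect_equal(oracle_binom_p(50, 55), 2.135842768e-10, tolerance = 1e-6)
  mps <- data.frame(
    site_id = c("a", "b"), line_id = "L01", condition = "WW",
    reads_ref = c(25, 50), reads_pat = c(25, 5),
    rpgc_ref = c(7.5, 15), rpgc_pat = c(7.5, 1.5),
    in_peak = TRUE
  )
  m <- call_amps(call_mps(mps))
  expect_equal(m$p_binomial[1], 1.0)
  expect_false(m$is_amp[1])
  expect_true(m$is_amp[2])
  expect_error(call_amps(m, fdr = 1.5), "fdr")
})

test_that("AMP is a subset of MP and BH is applied within line", {
  d <- small_data()
  m <- call_amps(call_mps(aggregate_replicates(d$coverage$WW), d$sites))
  expect_true(all(m$is_mp[m$is_amp]))
  one <- m[m$line_id == "L01" & m$is_mp, ]
  expect_equal(one$q_fdr, p.adjust(one$p_binomial, "BH"))
})

test_that("allele swap preserves AMP p-values", {
  d <- small_data()
  m <- call_mps(aggregate_replicates(d$coverage$WW), d$sites)
  sw <- m
  sw[, c("reads_ref", "reads_pat")] <- m[, c("reads_pat", "reads_ref")]
  sw[, c("rpgc_ref", "rpgc_pat")] <- m[, c("rpgc_pat", "rpgc_ref")]
  sw <- call_mps(sw[, setdiff(names(sw), c("binding_frequency", "is_mp",
                                           "p_binomial", "q_fdr",
                                           "is_amp"))])
  expect_equal(sw$binding_frequency, 1 - m$binding_frequency)
  expect_identical(sw$is_mp, m$is_mp)
  expect_equal(call_amps(sw)$p_binomial, call_amps(m)$p_binomial)
})

test_that("WGS filter drops AMPs outside the 5th-95th percentile band", {
  set.seed(33)
  n <- 400
  mps <- data.frame(
    site_id = sprintf("s%03d", 1:n), line_id = "L01", condition = "WW",
    reads_ref = 60, reads_pat = 10, rpgc_ref = 18, rpgc_pat = 3,
    in_peak = TRUE
  )
  mps <- call_amps(call_mps(mps))
  wgs <- data.frame(site_id = mps$site_id,
                    wgs_ratio = runif(n, 0.4, 0.6))
  wgs$wgs_ratio[1] <- 0.62   # artifact-like site
  wgs$wgs_ratio[2] <- median(wgs$wgs_ratio)
  out <- wgs_control_filter(mps, wgs)
  thr <- attr(out, "wgs_thresholds")
  expect_equal(thr, quantile(wgs$wgs_ratio, c(0.05, 0.95), type = 7,
                             names = FALSE))
  expect_gt(thr[1], 0.40); expect_lt(thr[1], 0.43)
  expect_true(out$wgs_excluded[1])
  expect_false(out$is_amp[1])
  expect_false(out$wgs_excluded[2])  # at the median: retained
  # no AMPs -> nothing excluded
  mps2 <- mps; mps2$is_amp <- FALSE
  expect_false(any(wgs_control_filter(mps2, wgs)$wgs_excluded))
  expect_warning(
    wgs_control_filter(mps[1:5, ], wgs[1:5, ]), "fewer than 20")
})

test_that("INDEL windows use flank means for deletions and span means for
           insertions", {
  cov_ref <- rep(4.0, 300)
  # deletion allele on pat (zero-width there), span on ref [200,210)
  indel <- list(ref_start = 200L, ref_end = 210L,
                pat_start = 150L, pat_end = 150L)
  cov_pat <- rep(4.0, 300)
  out <- indel_site_coverage(indel, cov_ref, cov_pat)
  expect_equal(unname(out["rpgc_pat"]), 4.0)   # 6 flank bases, all 4.0
  expect_equal(unname(out["rpgc_ref"]), 4.0)
  # insertion of length 10, one hot base
  cov_ref2 <- rep(2.0, 300); cov_ref2[201:210] <- c(12, rep(2, 9))
  out2 <- indel_site_coverage(list(ref_start = 200L, ref_end = 210L,
                                   pat_start = 100L, pat_end = 100L),
                              cov_ref2, cov_pat)
  expect_equal(unname(out2["rpgc_ref"]), (9 * 2 + 12) / 10)
  # length filter
  ind <- data.frame(length = c(1, 2, 50, 55), n_alt_lines = c(5, 5, 5, 5))
  expect_equal(filter_indels(ind)$length, c(2, 50))
  ind2 <- data.frame(length = c(10, 10), n_alt_lines = c(1, 2))
  expect_equal(filter_indels(ind2)$n_alt_lines, 2)
})

test_that("condition-response test matches the Welch oracle", {
  ww <- c(10, 11, 9); ds <- c(10, 11, 9)
  r <- treatment_response_test(ww, ds)
  expect_equal(r$p, 1.0)
  expect_false(r$significant)
  ww2 <- c(10.0, 10.2, 9.8); ds2 <- c(20.0, 19.5, 20.5)
  r2 <- treatment_response_test(ww2, ds2)
  o <- oracle_welch(ds2, ww2)
  expect_equal(r2$t, o$t, tolerance = 1e-12)
  expect_equal(r2$p, o$p, tolerance = 1e-12)
  expect_identical(r2$direction, "increased")
  expect_true(r2$significant)
  expect_error(treatment_response_test(5, c(6, 7)), "2 replicates")
})
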