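# pancistrome

Quantitative analysis of haplotype-specific transcription-factor (TF)
footprint occupancy in panels of F1 hybrids that share a common reference
parent, in R.

In a shared-mother F1 design both haplotypes sit in the same nuclei, so
allelic differences in small MNase footprints at heterozygous sites
measure *cis*-regulatory variation free of *trans*, batch and technical
effects. `pancistrome` implements the statistical chain that turns
per-allele footprint coverage into a map of functional *cis*-variants and
a heritability decomposition:

* **Footprint quantification** — 20 bp fragment-center coverage tracks,
  RPGC scaling (effective genome size / mapped reads), per-allele
  binding frequencies `RPGC_ref / (RPGC_ref + RPGC_pat)`.
* **MP and AMP calling** — footprint polymorphisms (variant in a peak,
  one allele > 7 RPGC, at least one read on the other allele) and
  allele-specific MPs by exact binomial test on read counts against 1:1,
  Benjamini–Hochberg at 1% FDR per line × condition, plus a
  whole-genome-sequencing control filter (AMPs outside the 5th–95th
  percentile of the control allelic ratio are removed).
* **bQTL mapping** — five per-site linear models of binding frequency
  across the panel (`MP = GT`, `= mCG`, `= mCHG`, `= mCHH`, and
  `GT + mCG + mCHG + mCHH`), per-model BH at 5% FDR, attribution to
  genotype / methylation / both, and 65 bp linkage-group clumping with
  lowest-p leads.
* **Methylation** — ±20 bp windowed allelic methylation, the
  `<10% / >70%` differential rule, strict equal-methylation rule, and
  occupancy–hypomethylation concordance summaries.
* **Condition response** — classification of allele-specific sites
  across two conditions (e.g. well-watered vs drought) into groups
  I–IV, Welch tests on replicate coverages, and selection of
  drought-responsive candidate loci near responsive, allele-specific
  genes.
* **Heritability partitioning (VCAP)** — centered cross-product kinship
  matrices for bQTL / matched-background / rest-of-genome SNP sets,
  allele-frequency × distance-to-gene matched background sampling with
  exact histogram equality, multi-component average-information REML
  with EM fallback, multivariate-normal trait simulation and a
  permutation scheme over background sets.
* **Enrichment** — hypergeometric AMP enrichment in promoters of
  allele-specifically expressed genes, bQTL enrichment at GWAS hits
  versus matched backgrounds, LD r², and the allele-specific read
  counting rule (reads spanning several SNPs count once; SNPs without
  reads on both alleles are dropped).

A first-class synthetic-data module (`sim_config()`,
`simulate_moa_dataset()` and friends) generates populations, methylomes,
annotations, coverage and traits with the causal structure the analysis
assumes, so the full pipeline runs and is tested without any external
data. See the methods vignette
(`vignettes/pancistrome-methods.Rmd`) for the models, rule-level
decisions and known limitations.

## Worked example

```r
library(pancistrome)

cfg <- sim_config(n_sites = 1000, seed = 42)
cfg
#> Synthetic study configuration
#>   25 F1 lines, 1000 sites, 100 genes on 200,000 bp
#>   depth 100 (dispersion 0.1), 3 replicates, conditions: WW/DS
#>   causal fractions geno/meth/both: 0.05/0.05/0, delta 0.25
#>   seed 42

d   <- simulate_moa_dataset(cfg)
mps <- call_amps(call_mps(aggregate_replicates(d$coverage$WW), d$sites))
mps <- wgs_control_filter(mps, d$wgs)
sum(mps$is_mp); sum(mps$is_amp); sum(mps$wgs_excluded)
#> [1] 20047
#> [1] 789
#> [1] 88

pred <- build_site_predictors(mps[mps$is_mp, ], d$genotypes,
                              d$methylomes$windows, d$sites)
bqtl <- map_bqtl(pred, fdr = 0.05)
table(bqtl$sig_class)
#>      both geno_only meth_only      none
#>         1        37        41       723
```

Of the 1,000 simulated sites, 20,047 site × line records pass the MP
coverage rule, 789 show significant allelic imbalance (AMPs), and 88 of
those are discarded by the WGS control filter. Association mapping then
attributes 79 sites to genotype, methylation or both — close to the 100
causal sites planted by the generator (5% genotype-driven, 5%
methylation-driven), with the shortfall at low-frequency alleles where
the cross-line regression has little leverage. Each significant site
carries its linkage group and lead flag:

```r
head(subset(bqtl, sig_class != "none"),
     c("site_id", "pos", "q_geno", "sig_class", "group_id", "is_lead"))
#>    site_id  pos       q_geno sig_class      group_id is_lead
#> 7   s00014 5051 8.420319e-01 meth_only chr1_grp00001    TRUE
#> 11  s00018 5074 9.914216e-17 geno_only chr1_grp00001   FALSE
```

`run_pipeline(cfg)` composes every stage (simulation, MP/AMP calling per
condition, bQTL mapping, methylation concordance, condition-response
groups, a small REML recovery) and returns a manifest with per-stage
record counts.

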