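---
title: "Models and methods behind pancistrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pancistrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancistrome)
```

# The analysis problem

`pancistrome` analyses haplotype-specific transcription-factor (TF)
footprint occupancy in a panel of F1 hybrids that share one reference
mother (in maize, B73 crossed to a set of diverse fathers). Because both
haplotypes of an F1 sit in the same nuclei, differences between the two
alleles' footprint coverage at a heterozygous site cannot come from
*trans*-acting factors, biological batch or technical variation: they
measure *cis*-regulatory variation directly. The package covers the full
chain from scaled coverage to heritability partitioning:

1. **Footprint quantification** — fragment-center coverage tracks,
   reads-per-genome-coverage (RPGC) scaling, per-allele binding
   frequencies.
2. **MP/AMP calling** — footprint polymorphisms (MPs: variants inside
   footprint peaks with adequate coverage) and allele-specific MPs
   (AMPs: binomial allelic imbalance at 1% FDR, with a genomic-DNA
   control filter).
3. **bQTL mapping** — per-site linear models of binding frequency on
   genotype and DNA methylation across the panel, 5% FDR, 65 bp
   linkage-group clumping.
4. **Methylation analysis** — windowed allelic methylation, the
   `<10% / >70%` differential rule, and occupancy-methylation
   concordance.
5. **Condition response** — classification of allele-specific sites
   across two watering conditions into four response groups, and
   selection of drought-responsive candidate loci near responsive genes.
6. **Heritability partitioning** — genomic relatedness matrices for
   bQTL, matched-background and rest-of-genome SNP sets; multi-component
   REML; matched sampling with exact histogram equality; permutation
   scheme; trait simulation for validation.

A synthetic-data module generates populations with this exact causal
structure so that every stage is testable offline, with known truth.

# The synthetic study and its assumptions

`sim_config()` fixes the study conditions. The defaults describe the
design the package targets: 25 F1 lines, biallelic variants whose minor
allele is carried by at least two paternal lines (hence a minimum minor
allele frequency of 2/25 = 0.08), three replicates, two conditions
(well-watered and drought), and footprint peaks covering about 2% of the
genome.

The generative model for occupancy is a logistic effect model,

$$ f_{il} = \mathrm{logit}^{-1}\!\big(\beta_G\, g_{il} + \beta_M\,
   (m^{pat}_{il} - m^{ref}_{il})\big), $$

where $f_{il}$ is the true binding frequency (share of occupancy on the
reference allele) of site $i$ in line $l$, $g_{il}$ the paternal
genotype code, and $m$ the windowed allelic methylation. No generative
model for occupancy is implied by the measurement itself; the logistic
form is this package's own artifact choice, made because it keeps
frequencies in $(0,1)$, makes null sites exactly 0.5, and lets genotype
and methylation effects compose additively on the log-odds scale.
$\beta_M > 0$ encodes the biological direction that hypomethylated DNA
is bound more readily, so the generator reproduces, by construction, the
strong empirical association between hypomethylation and higher
occupancy; sampling noise is the only source of discordance.

Three generator choices deserve emphasis:

* **Depth model.** Total depth per site, line and replicate is negative
  binomial with mean `read_depth_mean` and dispersion
  `depth_dispersion` (Poisson at dispersion 0). Sequencing depth is
  overdispersed in practice; the dispersion default (0.1) is mild.
* **Methylation mixture.** Allelic methylation is bimodal with modes at
  0.02 and 0.85. The classification rule (`<10%` vs `>70%`) is part of
  the analysis, not of the generator; the modes are placed so the rule
  separates them cleanly, and CHH is kept uniformly low because CG and
  CHG account for essentially all allelic methylation differences at
  footprint sites.
* **Epialleles segregate independently of the local SNP.** The maternal
  haplotype is one shared inbred, so its methylation state is constant
  across lines. The paternal epiallele at a differentially methylated
  site is drawn per line with probability 1/2, *independent* of the
  site's own SNP genotype. Without this independence, genotype and
  methylation would be perfectly collinear across lines and the
  attribution of bQTL to genotype versus methylation would be
  undefined — the generator makes the attribution question answerable,
  which is also the situation the real analysis assumes when it reports
  the two classes separately.

What the generator does **not** emulate: mapping bias and alignability
(the WGS control ratios are drawn, not derived from reads), linkage
disequilibrium between neighbouring sites (sites are independent),
peak-calling uncertainty (peak membership is exact), and any
*trans*-effects. Tests passing on synthetic data therefore demonstrate
the correctness of the statistical machinery under the stated model, not
robustness to alignment artifacts or LD structure in real data.

# Numerical and rule-level decisions

* **Fragment centering.** Reads are shortened to exactly 20 bp around
  the middle base: window $[m-10, m+10)$ for odd-length reads, and one
  of the two middle bases chosen at random for even-length reads. A
  21 bp reading ("extend 10 bp to each side") was rejected in favour of
  the explicit 20 bp statement.
* **MP rule.** A site×line record is an MP iff it lies in a peak, one
  allele exceeds 7 RPGC (strict inequality; roughly 25 reads), and the
  *other* allele has at least one read. Requiring the read on the
  opposite allele makes the binomial test well-defined; this is the
  reading adopted for the ambiguous "at least one read in the
  corresponding allele".
* **Binomial test.** `stats::binom.test` (two-sided "minlike" rule) on
  back-converted read counts, never on normalized coverage;
  Benjamini–Hochberg within each line × condition. Reads are recovered
  from RPGC by the inverse scale factor with round-half-away-from-zero.
* **WGS percentile filter.** 5th/95th percentiles with linear
  interpolation between order statistics (`quantile(type = 7)`),
  computed over all MPs; AMPs strictly outside the band are excluded.
  Below 20 MPs the thresholds are flagged unreliable.
* **bQTL models.** Five OLS fits per site (`MP = mCHH`, `= mCG`,
  `= mCHG`, `= GT`, and the full `GT + mCG + mCHG + mCHH`), two-sided
  coefficient t-tests. FDR is controlled per model across sites, not
  pooled over the five models, keeping per-feature error rates
  interpretable. "Methylation-associated" means significant in any of
  the three single-context models; the full model's coefficients are
  reported but do not drive the classification. Both choices are open
  in principle; these defaults are the package's resolution.
* **Degenerate fits.** Predictors without variance and (essentially)
  perfect fits yield missing p-values — never significance.
* **Clumping.** Transitive chaining of significant sites with gaps
  ≤ 65 bp; the lead is the member with the lowest p-value among its
  significant models, ties broken leftmost.
* **Windows and boundaries.** Methylation windows are closed on both
  ends (±20 bp); promoter windows (3 kb) and the GWAS hit window
  (±100 bp) are closed; drought candidate gene windows span 5 kb
  upstream of the TSS to 1 kb downstream of the TTS, strand-aware,
  including the gene body. Coordinates are 0-based half-open internally,
  BED conventions at the file boundary.
* **Condition groups.** Group I/II/III/IV classification uses the AMP
  call in at least one condition plus a 60% bias rule (not a second
  test) in the other, avoiding stacked statistical cut-offs. Sites
  biased ≥ 60% in both conditions go to II (same allele) or III
  (opposite alleles); an AMP in one condition with the other in the
  40–60% band goes to IV.

# The REML engine

Heritability partitioning fits
$y = \mu + \sum_k u_k + e$, $u_k \sim N(0, \sigma^2_k K_k)$,
$e \sim N(0, \sigma^2_e I)$, by restricted maximum likelihood with an
intercept-only fixed effect. Kinships are centered cross-products
$K = ZZ'/c$ scaled to mean diagonal 1. Updates use the
average-information matrix with step-halving; any step that cannot
ascend the restricted likelihood falls back to an EM update (guaranteed
ascent). Components are constrained non-negative; a component that
repeatedly lands on the zero floor with a non-positive score is pinned
there and dropped from the active set — without this, EM crawls toward
zero boundaries at a geometric rate and convergence within a reasonable
iteration budget is not reliable. Convergence is declared when the
relative change of the restricted log-likelihood falls below `tol`
(default 1e-6). The implementation is this package's own; it does not
claim numerical identity to external REML tools, and the test suite
audits it against a derivative-free box-constrained maximization of the
same restricted likelihood.

Two properties of the constrained estimator are worth knowing. First,
null components have positively biased means (estimates cannot go
negative), so a pure-noise trait yields small positive component
estimates and a correspondingly shrunken residual. Second, when the
kinship matrices are built from independent random markers they are all
close to the identity and the components are only weakly separable;
per-trait estimates then spread substantially (standard deviations
around 0.1 at n = 400 with 1000 markers per component) even though means
recover the truth. Structured populations with linkage make the
partition better identified in real data.

The matched-background sampler draws, per bQTL SNP, one non-bQTL SNP
without replacement from the identical allele-frequency (0.1 bins) ×
distance-to-gene (intragenic, 0–1 kb, …, 9–10 kb, >10 kb) cell, so
bin-cell histograms agree exactly in every permutation. When a cell runs
empty the nearest non-empty distance bin in the same AF bin is used, with
a warning; at genome scale this happens essentially never, at demo scale
occasionally. Traits for validation are simulated as sums of multivariate
normal draws with covariances $h^2_k K_k$ plus an $h^2_e I$ residual,
heritabilities summing to one.

# Problem sizes used by the tests

The shipped test and acceptance runs use deliberately small designs: a
few hundred sites for unit tests; 10,000 null sites at depth 50 for the
AMP FDR calibration; 5,000 sites × 25 lines with 10% causal sites
(binding-frequency shift 0.25, depth 100) for bQTL operating
characteristics; and n = 400 individuals with 1,000 markers per
component, four heritability sets and 20 traits per set for the REML
recovery design. These sizes give stable Monte-Carlo answers for the
properties being checked while keeping a complete run in the order of a
minute or two per stage.

# Known limitations

* Peak calling, alignment and genome-alignment-based variant discovery
  are out of scope; peaks, variants and ASE flags are inputs.
* INDEL handling covers the coverage-window rule and the length/carrier
  filters; INDEL discovery and liftover are not reimplemented.
* The bQTL models are ordinary least squares across lines, as in the
  original analysis; no kinship correction is applied at this step.
* The drought candidate selector works from caller-supplied responsive
  regions with per-line significance; it does not call differential
  peaks itself (the Welch test on replicate coverages is provided for
  that purpose).
* The 60% bias rule makes groups I and IV sensitive to the detection
  threshold by construction; conclusions should rest on groups II and
  III, which are detection-stable.
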