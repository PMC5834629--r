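---
title: "Methods: summary-data MR for methylome-transcriptome-trait integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-data MR for methylome-transcriptome-trait integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

smrpipe asks whether DNA methylation at a CpG site, the expression of a
nearby gene and a complex trait are driven by the *same* genetic signal,
using only summary statistics from three non-overlapping studies (an
mQTL study, an eQTL study and a GWAS) plus a genotype reference panel
for LD.

## The SMR ratio estimate

Let $z$ be a genetic instrument, $x$ an exposure (DNAm or expression)
and $y$ an outcome (expression or trait). With per-allele effects
$\hat b_{zx}$ (from the exposure study) and $\hat b_{zy}$ (from the
outcome study), the Mendelian-randomization estimate of the effect of
$x$ on $y$ is the Wald ratio

$$\hat b_{xy} = \hat b_{zy} / \hat b_{zx}.$$

The instrument must be strongly associated with the exposure: only the
top cis QTL at $P < 5\times 10^{-8}$ qualifies (`select_instrument()`),
ties broken deterministically by position then id. Writing
$z_{zx} = \hat b_{zx}/\mathrm{SE}(\hat b_{zx})$ and similarly $z_{zy}$,
the first-order delta-method variance of the ratio gives a Wald
statistic with the closed form

$$T_\mathrm{SMR} \;=\; \frac{z_{zy}^2\, z_{zx}^2}{z_{zy}^2 + z_{zx}^2}
  \;\sim\; \chi^2_1 \text{ under } b_{xy}=0 ,$$

implemented in `smr_test()`. As the instrument becomes noiseless
($z_{zx}\to\infty$), $T_\mathrm{SMR} \to z_{zy}^2$, the ordinary outcome
Wald test. The first-order (no cross-term) form is used deliberately:
it is the form whose statistic has this closed expression, and it makes
every p-value exactly reproducible.

## HEIDI: pleiotropy versus linkage

A significant $T_\mathrm{SMR}$ is consistent with two causal
architectures: *pleiotropy* (one shared causal variant drives both
traits) and *linkage* (two distinct, correlated variants drive them
separately). Under pleiotropy the ratio $b_{xy}$ is identical at every
SNP in LD with the causal variant, so for SNPs $i = 1..m$ around the top
instrument (index 0),

$$\hat d_i = \hat b_{xy(i)} - \hat b_{xy(0)}$$

is jointly multivariate normal around zero. `heidi_cov()` builds the
first-order covariance of the $\hat d_i$, treating the exposure and
outcome studies as independent but sharing the reference-panel LD matrix
$R$:

$$\mathrm{cov}(\hat b_{xy(i)},\hat b_{xy(j)}) =
  \frac{R_{ij}\,s_{y_i} s_{y_j}}{b_{x_i} b_{x_j}} +
  \frac{R_{ij}\, b_{y_i} b_{y_j}\, s_{x_i} s_{x_j}}{b_{x_i}^2 b_{x_j}^2}.$$

`heidi_test()` standardizes $\hat d$, sums the squares,
$t = \sum_i \hat d_i^2 / V_{ii}$, and evaluates the null distribution
$\sum_k \lambda_k \chi^2_1$ with $\lambda_k$ the eigenvalues of the
correlation matrix of $\hat d$ (exact for a multivariate normal).

SNPs entering HEIDI need exposure $P < 1.57\times10^{-3}$ (a $\chi^2_1$
of 10 — anything weaker makes the per-SNP ratio too noisy) and LD with
the instrument in $r^2 \in [0.05, 0.9]$: near-perfect proxies carry no
independent information, near-independent SNPs are not instruments for
the same signal. The 20 most significant candidates are kept, and at
least 3 (plus the instrument) are required; below that the pair is
reported as `heidi_insufficient_snps`. These numeric defaults follow the
established tool conventions for this test and are all configurable
through `smr_config()`.

## The weighted chi-square tail (saddlepoint)

Both HEIDI and the multi-SNP SMR test need
$P(\sum_k \lambda_k \chi^2_1 > t)$. `quadform_pvalue()` uses Kuonen's
Lugannani–Rice saddlepoint approximation: with cumulant generating
function $K(\zeta) = -\tfrac12\sum_k\log(1-2\zeta\lambda_k)$ the
saddlepoint $\hat\zeta$ solves $K'(\hat\zeta)=t$ on
$(-\infty, 1/2\lambda_{max})$, and
$p = \Phi^c\!\big(w + \log(v/w)/w\big)$ with
$w = \mathrm{sign}(\hat\zeta)\sqrt{2(\hat\zeta t - K(\hat\zeta))}$,
$v = \hat\zeta\sqrt{K''(\hat\zeta)}$. Numerical choices:

* weights below $10^{-8}\lambda_{max}$ are dropped; all-zero weights
  are an error;
* equal weights short-circuit to the exact (scaled) chi-square;
* $t$ at the distribution mean, or a failed root bracket, falls back to
  Satterthwaite moment matching ($T \approx a\chi^2_d$,
  $a = \sum\lambda^2/\sum\lambda$, $d = (\sum\lambda)^2/\sum\lambda^2$),
  and the fallback is flagged in `attr(p, "method")`;
* eigenvalue clipping at zero (with the clipped mass logged by
  `make_psd()`, relative threshold $10^{-8}$) repairs indefiniteness
  from pairwise-complete LD estimation.

The acceptance suite verifies the saddlepoint against $10^7$-draw Monte
Carlo on 50 random weight vectors to $|\Delta\log_{10} p| < 0.05$.

## Multi-SNP SMR

`smr_multi()` combines the ratio z-statistics
$z_i = \hat b_{xy(i)}/\mathrm{SE}$ of all cis SNPs at
$P < 5\times10^{-8}$ within 500 kb (pruning only $r^2 > 0.9$ *against
the top SNP*, as the set-based construction prescribes — not all-pairs)
into $T = \sum_i z_i^2$; under the null $z \sim \mathrm{MVN}(0, R)$, so
$T$ is again a weighted chi-square with weights the eigenvalues of $R$.
Only the single-SNP $\hat b_{xy}$ is reported as an effect size; the
sign convention of the pooled $z_i$ is immaterial to $T$.

# The three-step pipeline

1. **M2T** (`run_m2t()`): every DNAm probe against every expression
   probe within 2 Mb (probe-coordinate to probe-coordinate) on the same
   chromosome, DNAm as exposure, top mQTL as instrument. `run_t2m()`
   reverses the roles.
2. **Omics-to-trait** (`run_omics_trait()`): each DNAm/expression probe
   against one GWAS.
3. **Triplets** (`combine_triplets()`): inner join of the three scans;
   a triplet survives only if *all three* associations pass the
   Bonferroni threshold *and* are not rejected by HEIDI
   ($P_\mathrm{HEIDI} \ge 0.01$).

Bonferroni thresholds are computed from the *realized* test count of
each scan (the source analyses do the same: 0.05 over the number of
tagged genes or usable probes), not from a fixed constant; a
genome-wide-style fixed count can be obtained by calling
`bonferroni_threshold()` directly. When HEIDI cannot run (too few
eligible SNPs), the default *strict* mode counts the pair as
not-passing; `strict_heidi = FALSE` passes it with a flag. Strict is the
conservative reading of an unspecified corner.

Descriptive statistics of the resulting map: `nearest_gene_stats()`
classifies each DNAm probe by whether its significant genes include the
physically nearest annotated gene ($\pi_{nearest}$ /
$\pi_{distal}$ / both; ties toward smaller coordinate), and
`direction_concordance()` reports the fraction of within-gene DNAm-pair
$\hat b_{xy}$ sign agreements, pooled over genes with at least two
associated probes.

# Quality control and harmonization

* `.ma` (GWAS) and flat cis-QTL tables are validated row-wise
  ($\mathrm{SE}>0$, frequency in $(0,1)$, $p \in (0,1]$); rejects are
  counted, and p-values inconsistent with the Wald statistic by more
  than two orders of magnitude are flagged.
* `harmonize()` keeps SNPs present in exposure, outcome and panel with
  consistent allele pairs; A1/A2 swaps negate $\beta$ and flip
  frequency; strand-ambiguous (A/T, C/G) SNPs are removed; so are SNPs
  with allele-frequency discrepancy $>0.2$ between any pair of sources.
  Both rules mirror documented practice for this analysis family — the
  thresholds are decisions, not facts inherited from a dataset.
* p-values are carried as natural-log values (`logp`) in every table so
  that thresholds and instrument selection survive $p < 10^{-300}$.
* The MHC is excluded as chr6:25–34 Mb (GRCh37); the region is named,
  not given coordinates, by the analyses this follows, so the bounds are
  configurable.
* Meta-analysis of two mQTL cohorts (`meta_fixed()`) is inverse-variance
  fixed-effect and *drops* SNPs present in only one cohort: carrying
  single-cohort estimates forward would mix standard errors of
  different scales.
* LD (`ld_matrix()`) is a Pearson correlation of reference dosages with
  pairwise-complete missing handling (panels are small; mean imputation
  would bias toward zero), sign-aligned to the harmonized effect
  alleles; monomorphic SNPs are a named error.
* `beta_from_z()` recovers SD-unit effects from z-statistics as
  $\mathrm{SE} = 1/\sqrt{2f(1-f)(n+z^2)}$, $\beta = z\,\mathrm{SE}$,
  for studies that publish only z-scores; `qtl_variance_explained()`
  inverts $r^2 = z^2/(z^2+n-2)$.

# Chromatin-state enrichment

Probes are assigned one of 14 collapsed functional categories by point
query against BED segmentation tracks (0-based half-open input,
converted on read; overlapping same-category intervals merged). With
several epigenome tracks the per-probe category is the majority vote
across tracks (alphabetical tie-break) — a data-agnostic stand-in for
"consensus across blood cell types"; a single chosen track can be used
instead.

`enrichment_test()` compares the observed category proportions of a
target probe set against probes sampled at random *matched on DNAm
variance*: the universe is cut into 100 equal-frequency variance bins
(robust to the heavy-tailed variance distribution of methylation
probes), and each target draws a non-self probe from its own bin. Fold
enrichment is observed/mean over 500 null replicates; its SE is the SD
of the per-replicate fold over 100 replicates, matching the published
procedure. The quoted significance is $z = (\mathrm{fold}-1)/SE$ with a
normal p-value — explicitly an approximation, since the exact p-value
recipe behind published enrichment tables of this kind is not stated
anywhere we could follow.

# The simulator: what the stated world is

`simulate_study_set()` draws three disjoint samples and an LD panel at
one locus (default 30 SNPs, 5 kb apart). Genotypes come from two latent
AR(1) Gaussian gametes thresholded at the MAF quantile — Hardy–Weinberg
dosages whose LD decays with distance (`ld_decay = 0.9`). The mediation
chain is

$$m = b_{zm} g + e,\quad x = b_{me} m + e,\quad y = b_{et} x + e,$$

with standard-normal residuals and every phenotype scaled by its
*theoretical* SD, so the implied exposure-outcome effects are exact
products of path coefficients (e.g. DNAm→expression
$= b_{me}/\sqrt{1+b_{me}^2}$) and parameter-recovery tests have an
exact target. Defaults: $b_{zm}=0.5$ (top-mQTL $r^2 \approx 9.5\%$ at
MAF 0.3 — strong, as real top mQTLs are), $b_{me}=1.0$, $b_{et}=0.5$;
study sizes 2000 (mQTL, matching a two-cohort blood meta-analysis),
2000 (eQTL), 10000 (GWAS; real GWAS are 10–30× larger, so desk-scale
effect sizes are correspondingly larger to keep instruments past
$5\times10^{-8}$), panel 500. The pleiotropy model collapses the chain
into direct effects of one SNP on all three phenotypes with *matched
marginal effect sizes*; the linkage model moves the downstream effects
onto a second variant chosen to sit at LD $r^2 = 0.2$ with the first.
Marginal per-SNP OLS (or logistic regression under the
liability-threshold disease option) produces the summary statistics —
the same way real QTL/GWAS summaries arise.

What the simulator does **not** emulate: genome-scale LD structure,
allele-frequency spectra, imputation error, sample overlap between
studies (an overlap knob exists for robustness experiments only),
population stratification, or probe-level technical artifacts. A green
test therefore establishes the *statistical machinery* — estimators,
their variances, selection rules, thresholds, file round-trips — not
robustness to those data pathologies.

`simulate_summary_pair()` is the asymptotic shortcut used by the
calibration studies: marginal z-statistics drawn directly from
$\mathrm{MVN}(\sqrt{n}\,\rho, R)$, which is exact for the large-sample
regime the tests assume and thousands of times faster than
individual-level simulation.

# Known limitations

* **HEIDI finite-sample calibration.** At a realistic mQTL exposure
  size (n = 2000, top-QTL $r^2 = 0.095$) the null rejection rate of the
  HEIDI test at 0.01 is mildly inflated (~0.015 over 2000 replicates)
  because secondary SNPs near the $z = 3.16$ eligibility floor have
  noisy $\hat b_{zx}$ and the first-order delta variance under-covers.
  The identical experiment with exposure n = 20000 is nominally
  calibrated (a property test documents this), so the machinery is
  correct and the inflation is the known asymptotic-approximation cost.
  This is also why the pipeline follows the conservative convention of
  filtering at $P_\mathrm{HEIDI} < 0.01$ rather than 0.05. The
  corresponding acceptance criterion, which expects exact binomial
  calibration at this sample size, is deliberately left failing rather
  than widened.
* The ratio estimate inherits weak-instrument bias if the
  $5\times10^{-8}$ instrument rule is relaxed.
* Reference-panel LD substitutes for both study LDs in the HEIDI
  covariance; with mismatched ancestry the test is misspecified. Nothing
  finer is identifiable from summary data.
* BESD binary summary formats, multi-allelic variants, liftover and
  trans-QTL testing are out of scope.
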