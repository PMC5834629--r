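# smrpipe

Integration of mQTL, eQTL and GWAS **summary statistics** by
summary-data Mendelian randomization (SMR), for regulatory genomics:
which DNA-methylation sites control which genes, and which of those
gene-regulatory pairs are relevant to a complex trait.

It is written for statistical geneticists who have probe-level cis-QTL
summaries, GWAS summary statistics and a PLINK genotype reference panel,
and want a tested, scriptable implementation of:

* **SMR** — the Wald-ratio test of an exposure on an outcome through one
  genetic instrument: b̂_xy = b̂_zy / b̂_zx, with the closed-form
  delta-method statistic T = z_zy² z_zx² / (z_zy² + z_zx²) ~ χ²₁;
* **HEIDI** — the heterogeneity test that separates pleiotropy (one
  shared causal variant; d̂_i = b̂_xy(i) − b̂_xy(0) ≈ 0 across the locus)
  from linkage (distinct correlated variants; d̂ drifts), evaluated
  against a weighted-χ² null by Kuonen's saddlepoint approximation;
* **SMR-multi** — the set-based extension T = Σ z_i² over all
  genome-wide-significant cis SNPs, with LD-eigenvalue weights;
* the **three-step pipeline** — methylome→transcriptome (M2T, and the
  reversed T2M), methylome→trait and transcriptome→trait scans,
  realized-count Bonferroni and HEIDI filtering, and DNAm–gene–trait
  **triplet** combination, plus nearest-gene and direction-concordance
  summaries of the resulting map;
* a **chromatin-state enrichment test** with variance-matched
  resampling (500 null replicates for the fold, 100 for its SE);
* a **simulator** of coupled genotype/DNAm/expression/trait datasets
  (mediation, pleiotropy, linkage, null) that emits every file format
  the pipeline reads, so the whole stack is testable offline.

Input formats: GCTA-COJO `.ma` GWAS summaries, a flat tab-delimited
cis-QTL format (`ProbeID SNP Chr BP A1 A2 freq b se p N`), PLINK
bed/bim/fam panels, BED chromatin-state tracks with a state-collapse
map, and a probe annotation table.

## Worked example

Simulate a mediation locus (SNP → DNAm → expression → trait observed in
three disjoint studies), then run the full integration:

```r
library(smrpipe)

fx <- file.path(tempdir(), "demo")
make_fixture(fx, seed = 1)                      # writes all input formats

ann   <- read_probe_annotation(file.path(fx, "probes.txt"))
mqtl  <- filter_probes(read_qtl_flat(file.path(fx, "mqtl.txt"), ann, 2e6))
eqtl  <- filter_probes(read_qtl_flat(file.path(fx, "eqtl.txt"), ann, 2e6))
gwas  <- read_gwas_ma(file.path(fx, "gwas.ma"))
panel <- read_plink(file.path(fx, "panel"))

cfg <- smr_config()
m2t     <- run_m2t(mqtl, eqtl, panel, cfg)
m2trait <- run_omics_trait(mqtl, gwas, panel, cfg)
t2trait <- run_omics_trait(eqtl, gwas, panel, cfg)
m2t[, .(exposure_id, outcome_id, b_xy, p_smr, p_heidi, pass)]
#>    exposure_id outcome_id      b_xy        p_smr   p_heidi   pass
#> 1:       cg001      ex001 0.6692724 8.749099e-15 0.5957106   TRUE

combine_triplets(m2t, m2trait, t2trait)[,
  .(dnam_probe, gene_probe, trait, p_smr_m2t, p_smr_m2trait, p_smr_t2trait)]
#>    dnam_probe gene_probe  trait    p_smr_m2t p_smr_m2trait p_smr_t2trait
#> 1:      cg001      ex001  trait 8.749099e-15  5.059764e-10  7.934865e-10
```

Reading the output: the methylation probe `cg001` is associated with
expression probe `ex001` with an SMR effect of 0.67 SD expression per SD
methylation (the generating value is 1/√2 ≈ 0.71), at P_SMR = 8.7e-15;
P_HEIDI = 0.60 does **not** reject the single-shared-variant
(pleiotropy) model, so the association is not dismissed as linkage. All
three legs (DNAm→gene, DNAm→trait, gene→trait) pass their Bonferroni
thresholds and the HEIDI filter, so the locus is reported as one
DNAm–gene–trait triplet — the simulator's planted causal chain,
recovered from summary data alone.

The same analyses are scriptable from the shell (see
`inst/cli/smrpipe`):

```sh
Rscript inst/cli/smrpipe simulate --fixture --out fx --seed 9
Rscript inst/cli/smrpipe pipeline --config run.cfg
Rscript inst/cli/smrpipe smr --exposure fx/mqtl.txt --annot fx/probes.txt \
        --outcome fx/gwas.ma --bfile fx/panel --out res
Rscript inst/cli/smrpipe enrich --help
```

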