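# cmsscan

Composite-of-multiple-signals selection scans for a target population
against reference breeds, with a forward Wright–Fisher sweep simulator
providing ground truth for every stage.

The package addresses the standard question of livestock and human
population genomics at high altitude: *which SNPs and genes in an adapted
population (here, a Tibetan-pig-like target) show evidence of positive
selection, and do they associate with adaptive blood phenotypes?* It is
aimed at analysts who have phased biallelic SNP panels for a target and two
reference populations, a sample manifest with altitudes, blood indices, a
gene/feature annotation and an organ eQTL map — or who want to validate
such a pipeline on simulated data before touching real samples.

## The method

For each SNP the pipeline computes five selection statistics —

* FST (Hudson `[(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] /
  [p1(1-p2)+p2(1-p1)]`, or Weir–Cockerham),
* iHS `ln(iHH_A/iHH_D)`, XPEHH `ln(iHH_target/iHH_ref)`,
  ΔiHH `iHH_D − iHH_A`, and nSL (segment lengths in site units),
  all standardized in derived-allele-frequency bins (XPEHH genome-wide)

— and combines them into a composite score
`CMS = (5/k) Σ_i ln f_sel(s_i)/f_neu(s_i)` using densities calibrated from
labelled simulations. SNPs above the genome-wide top-1‰ quantile are
clumped PLINK-style (SP2 top-1%, r² ≥ 0.2, 500 kb radius; regions with
more than 5 members survive) and the gene containing each peak SNP becomes
a candidate gene. Candidate SNPs are tested against blood phenotypes with
an additive model (age, sex, altitude covariates) and max-T permutation
adjustment; candidate genes are tested for organ enrichment with one-sided
Fisher exact tests on eQTL-interval overlap.

## Worked example

```r
library(cmsscan)

# CMS calibration: labelled neutral and sweep simulations from the
# package's reference world; the neutral composite scores double as the
# null reference for the genome-wide thresholds
neutral <- lapply(1:3, function(i) {
  s <- simulate_populations(sim_config(s = 0, sweep_start_gen = 0),
                            seed = 100 + i)
  p <- pooled_maf_filter(s$panels)
  list(target = p$TBP, ref = p$DUROC)
})
sweep <- lapply(1:4, function(i) {
  s <- simulate_populations(sim_config(), seed = 200 + i)
  p <- pooled_maf_filter(s$panels)
  list(target = p$TBP, ref = p$DUROC, sweep_pos = s$truth$sweep_pos)
})
calib <- calibrate_cms(neutral, sweep, flank = 2.5e4, min_values = 50)
null_cms <- unlist(lapply(neutral, function(pp)
  cms_score(compute_site_scores(pp$target, pp$ref), calib)$cms))

# a complete synthetic study: three populations, a hard sweep in TBP,
# phenotypes with a blunted altitude response, annotations, organ map
study <- simulate_study(sim_config(), seed = 3)
study$panels$TBP
#> <haplotype_panel> TBP: 120 haplotypes x 6966 sites

scan <- run_scan(study, dists = calib, null_cms = null_cms)
nrow(scan$scores)          # SNPs after the pooled MAF >= 0.05 filter
#> [1] 1803
round(scan$threshold, 2)   # neutral-referenced top-1-permille threshold
#> [1] 5.26
scan$candidate_regions$n_members
#> [1] 11
scan$genes$gene            # peak-SNP candidate gene
#> [1] "GENE004"
study$truth$sweep_gene     # ground truth
#> [1] "GENE004"
```

So the clump with 11 SP2 members around the peak SNP maps to the gene that
truly carries the planted sweep. The association stage, on a 1,000-sample
cohort with a planted effect of −8 g/L haemoglobin per derived copy:

```r
set.seed(11)
hb <- cbind(rbinom(2000, 1, 0.4), rbinom(2000, 1, 0.5))
pan <- haplotype_panel(hb, variant_sites("1", c(1e5, 2e5),
                                         ancestral = "ref"),
                       sprintf("TBP_%04d", 1:1000), "TBP")
man <- simulate_manifest(list(TBP = pan), target = "TBP")
ph <- simulate_phenotypes(list(TBP = pan), man,
                          causal_id = pan$sites$id[1], target = "TBP",
                          beta = -8)
g <- colSums(matrix(hb[, 1], nrow = 2))
fit <- fit_additive(ph$pheno$HGB, g,
                    data.frame(age = ph$pheno$age, sex = ph$pheno$sex,
                               altitude = ph$pheno$altitude))
round(c(beta = fit$beta, se = fit$se, p = fit$p), 4)
#>    beta      se       p
#> -7.7487  0.7898  0.0000
round(variance_explained(fit$beta, g, ph$pheno$HGB), 4)
#> [1] 0.0883
```

The fitted effect (−7.75 ± 0.79 g/L) recovers the planted −8 within one
standard error, and the SNP explains ~9% of phenotypic variance in this
construction.

The same stages are scriptable through the command-line entry point
installed under the package's `exec/` directory:

```sh
CLI=$(Rscript -e 'cat(file.path(find.package("cmsscan"), "exec", "cmsscan"))')
Rscript "$CLI" simulate --seed 1 --out-dir study/
Rscript "$CLI" qc --vcf study/panel_TBP.vcf --manifest study/manifest.tsv --out-prefix qc
```

with further `scores`, `cms`, `clump`, `pheno`, `gwas` and `enrich`
subcommands operating on the emitted files.

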