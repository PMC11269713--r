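---
title: "Methods: composite selection scans with simulated ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite selection scans with simulated ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Populations that colonise high-altitude environments — Tibetan pigs are the
canonical livestock example — accumulate adaptive alleles under positive selection.
`cmsscan` implements a complete desk-scale pipeline for detecting such
alleles from phased SNP data of a target population and two lowland
reference breeds, associating the candidate SNPs with blood phenotypes
(haemoglobin, red-cell counts), and mapping candidate genes to
organs/systems. Because the raw livestock data sets behind such studies are
rarely redistributable, the package ships a forward Wright–Fisher simulator
that produces complete synthetic studies with known ground truth, so every
pipeline stage is verifiable end to end.

# The selection statistics

All statistics are computed per SNP on phased, derived-coded haplotype
panels (`1` = derived allele where the ancestral state is known).

* **FST** — allele-frequency differentiation between target and reference.
  The default estimator is Hudson's, with sample-size correction,
  `[(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] / [p1(1-p2) + p2(1-p1)]`;
  a haploid-sample Weir–Cockerham theta-hat is available. Note the finite
  sample correction makes the estimate slightly negative when `p1 = p2`;
  estimates are not clipped unless requested.
* **EHH / iHH** — extended haplotype homozygosity around a core site:
  the probability that two random carriers of the core allele are identical
  at every site from the core through distance *x*, computed site-by-site
  outward by refining carrier groups. iHH is the trapezoidal integral of
  EHH over physical distance, each side integrated until EHH crosses 0.05
  (interpolated), a gap of more than 200 kb is met, or the chromosome ends
  (flagged truncated). Physical distance is used because no genetic map is
  assumed; the distance column is pluggable.
* **iHS** — `ln(iHH_ancestral / iHH_derived)`, standardized within
  derived-allele-frequency bins (2% bins merged to a minimum occupancy of
  20). A sweep on the derived allele drives iHS negative.
* **XPEHH** — `ln(iHH_target / iHH_reference)` with iHH computed from all
  haplotypes of each population (the core site included in the identity
  span) and a common per-side stopping point chosen where the *pooled*
  two-population EHH crosses 0.05 — symmetric truncation avoids biasing the
  ratio. Standardized genome-wide.
* **ΔiHH** — `iHH_derived - iHH_ancestral`, bin-standardized like iHS;
  oriented so sweeps give positive values.
* **nSL** — the iHS analogue in site-count space: for each allele class the
  mean over carrier pairs of the number of consecutive sites (counting the
  core) over which the pair is identical; `ln(SL_A / SL_D)`,
  bin-standardized. No distance cutoff applies.

iHS and nSL are computed where the ancestral allele is known and target MAF
is at least 0.05; ΔiHH wherever the ancestral allele is known; XPEHH at all
sites segregating in either population. Before any statistic is computed
the scan applies a dataset-level MAF ≥ 0.05 filter across the pooled
samples, mirroring locus-level QC in chip/WGS pipelines.

# The composite score

The five statistics are combined per SNP as a composite of multiple
signals. For each statistic a pair of binned histogram densities is
calibrated — `f_sel` from simulated sweeps (scores within a flank of the
swept site) and `f_neu` from neutral simulations — with 64 bins spanning
the pooled range and a floor of `1/(10 n)` on empty bins so
log-likelihood ratios stay finite. The per-SNP score is

```
CMS = (5 / k) * sum_i ln( f_sel(s_i) / f_neu(s_i) )
```

over the `k` defined components, requiring `k >= 3` (iHS, nSL and ΔiHH are
jointly undefined where the ancestral allele is unknown, so requiring all
five would silently drop such sites). The `5/k` scaling keeps scores
comparable across SNPs. Absolute CMS values depend entirely on the
calibration, so significance is defined by the genome-wide top-1‰ quantile,
never by a fixed constant. When no simulations are available an
`empirical-tail` fallback calibrates `f_sel` from the selected-direction
top 1% of each statistic; this is an approximation (the tail is mostly
neutral SNPs) and is labelled as such in the calibration metadata.

# Candidate regions and genes

Significant SNPs (top 1‰) seed PLINK-style greedy clumps: indexes in
descending CMS order (ties broken toward smaller position) claim unclaimed
SNPs within 500 kb that reach the top-1% threshold and have `r² ≥ 0.2` with
the index in the target panel. Regions with **more than 5** members (i.e.
at least 6, as printed) survive; the gene whose body contains the index
(peak) SNP becomes a candidate gene. Peaks in no gene are reported with a
missing gene rather than dropped; peaks in overlapping genes yield one row
per gene flagged ambiguous; duplicated genes keep the occurrence with the
highest CMS.

On a short simulated chromosome the sweep itself occupies a sizeable
fraction of all SNPs, so quantiles computed from the scanned chromosome are
contaminated by the signal — unlike a real genome-wide scan where the
quantile is effectively neutral. `run_scan(null_cms = ...)` therefore
accepts composite scores from neutral reference simulations and takes the
index/SP2/significance thresholds as quantiles of that null distribution.
This is the desk-scale analogue of "top 1‰/1% across the whole genome".

# Association and enrichment

Candidate SNPs are tested against blood phenotypes with an additive linear
model (dosage 0/1/2) adjusting for age, sex (0/1) and altitude (metres).
Permutation adjustment uses Freedman–Lane residual permutation with max-T
family-wise control over the SNP set: the reported adjusted p for SNP *j*
is `(1 + #{b : max_j' |t*_bj'| >= |t_j|}) / (B + 1)`; a per-SNP
(non-family) permutation p is emitted alongside, since reports of
permutation-adjusted GWAS p-values often leave the scheme unstated. Production-scale B is 100,000; tests run
at B = 200–1,000. Variance explained is `beta² Var(g) / Var(y)`, clipped to
[0, 1].

Organ enrichment maps genes to organs by ≥ 1 bp interval overlap with an
eQTL map (BED4, half-open), and tests each organ with a one-sided
(greater) Fisher exact test from the hypergeometric tail,
Benjamini–Hochberg across organs. The background gene set defaults to all
genes of the supplied annotation; published analyses of this kind rarely state their
background.

# Quality control

The canonical order is: GATK-style hard filter on site INFO annotations
(`QD < 2, MQ < 40, FS > 60, SOR > 3, MQRankSum < -12.5,
ReadPosRankSum < -8`, all strict, absent keys never fire), sample
missingness (> 5%), sample heterozygosity outside mean ± 3 SD (vacuous when
the SD is 0), iterative PCA outlier flagging within declared populations
(Patterson-scaled genotypes, mean ± 6 SD on PC1/PC2), then variant-level
filters: Hardy–Weinberg exact test p < 1e-6, missing rate > 5%, MAF < 0.05.
The MAF default is 0.05 and the threshold is configurable.
The HWE test is the exact conditional test: the p-value sums the
probabilities of all heterozygote counts no more probable than the observed
one.

# The synthetic world

`sim_config()` describes the reference world; every stochastic choice flows
from one seed through R's RNG (the compiled core uses `unif_rand`), so a
seed fixes the entire study bit-for-bit.

* **Demography** — one ancestral diploid population of N = 500 burnt in for
  2N generations from an empty chromosome (mutation–drift balance is
  approached within a few percent; the truncation is a deliberate runtime
  trade-off), splitting into the target lineage 300 generations ago and the
  two reference populations 150 generations ago. Population sizes stay N
  per branch (instantaneous copying at splits).
* **Genome** — L = 2 Mb with infinite-sites-style mutation on a continuous
  coordinate axis at μ = 2e-7 per bp per generation and crossover rate
  ρ = 2.5e-8 per bp. After N-rescaling this gives θ = 4Nμ = 4e-4/bp,
  deliberately *below* real pig nucleotide diversity (~2e-3), and LD
  somewhat stronger than real data — enough SNPs (~1,200–1,500 after the
  MAF filter) that the top-1% SP2 pool and the ">5 members" clump rule are
  non-degenerate, while keeping a full study under ~20 s.
* **Sweep** — a hard sweep from standing variation: at 100 generations
  before present the most haplotype-coherent standing variant (carriers
  sharing one haplotype over ±100 kb; frequency 0.04–0.10; central half of
  the chromosome) gains multiplicative fitness 1 + s per copy (s = 0.05) in
  the target. Runs where the allele is lost or stalls below frequency 0.8
  retry the sweep phase from its starting state (bounded, recorded in the
  truth record). The 0.8 establishment condition matches the frequency
  range of the target-enriched alleles at reported selected loci
  (0.83–1.00); without it a sizeable fraction of runs carry a half-finished
  sweep that no method should be expected to fine-map.
* **Annotations** — non-overlapping gene bodies of 400 kb tiled on a
  480 kb period, with UTR/CDS/intron structure (~5% CDS) and
  regulatory intervals in the gaps; the tiling phase guarantees one gene
  spans the realized sweep site. The body size matches the scale of the
  reported candidate regions in published Tibetan-pig scans (up to ~1 Mb), not a typical pig gene; peak-SNP gene assignment at simulator
  resolution (~±200 kb) would be meaningless against 20 kb genes.
* **Phenotypes** — haemoglobin is
  `intercept + slope_pop·altitude + β·dosage + load·latent + noise` with
  the altitude slope positive in references (+0.02 g/L per m) and zero
  (blunted) in the target; RBC and HCT share the latent factor, inducing
  the HGB–RBC–HCT correlation block; the remaining six indices are
  independent noise around typical porcine values. When a variance-explained
  target is requested, β is derived from the realized non-genetic variance.
  Altitudes: target 3,000–4,300 m, references 1,000–4,000 m, so the
  blunting interaction is identifiable.

What a green test does **not** establish: the simulator has no chip error
model, no missingness, no imputation artefacts, a single chromosome, no
background selection, and unrealistically uniform gene geometry. Recovery
rates measured here say the pipeline plumbing and statistics behave as
designed on an established hard sweep — not that any particular published
gene list is correct.

# Numerical choices

* EHH refinement drops singleton carrier groups (they can never contribute
  a pair), making long scans linear in the surviving carriers.
* iHH interpolates the cutoff crossing linearly and flags truncation by
  chromosome end or inter-site gaps > 200 kb; truncated values are kept.
* Standardization bins merge left-to-right until each holds ≥ 20 values;
  a trailing underfull bin folds into its neighbour.
* Quantiles are type-7 throughout; clump ties break toward smaller
  position, so output is deterministic.
* The permutation floor is `1/(B+1)`; adjusted p never falls below it.
* Histogram densities clamp query values into the calibrated range, so
  out-of-range scores get the edge-bin density rather than zero.

# Known limitations

* The composite's absolute scale is calibration-specific; only ranks and
  quantile thresholds transfer across calibrations.
* iHS/nSL lose definition as sweeps approach fixation (MAF floor); the
  composite then rests on FST, XPEHH and ΔiHH, which is why
  `min_components = 3`.
* The Weir–Cockerham estimator is the haploid-sample variant; with very
  unequal sample sizes it differs noticeably from Hudson's.
* Clumping semantics follow PLINK's greedy algorithm; a SNP claimed by a
  stronger index never joins a later region even if closer to it.
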