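# dgeqtl

eQTL mapping on RNA-seq counts, two ways — and a comparison of the two.

An eQTL (expression quantitative trait locus) is a genetic variant whose
genotype associates with a gene's transcript abundance. RNA-seq gives
counts, which are overdispersed and far from normal, so the analyst must
choose: force the data to normality and use fast linear models (the
GTEx-style recipe), or keep the counts and use the machinery built for
differential gene expression. `dgeqtl` implements both, end to end, for
anyone mapping eQTLs from a multi-sample VCF and a raw count matrix —
and for anyone who wants to measure how much the choice matters.

**Framework 1 (linear):** TMM normalization → CPM on effective library
sizes → per-gene rank-based inverse normal transform
`Φ⁻¹((r − 3/8)/(n + 1/4))` → vectorized additive (genotype 0/1/2,
t-test) and ANOVA (3-level factor, 2-df F-test) scans.

**Framework 2 (negative binomial):** per-gene NB GLM on raw counts,
`log μ = Xβ + log(effective size)`, variance `μ + φμ²`, Cox–Reid
dispersion estimation with shrinkage toward the common value, and
quasi-likelihood F-tests with a model-based deviance-scale correction
that keeps the null calibrated at n ≈ 41. A two-tier procedure first
tests the genotype as a factor, then pseudo-codes tier-1 hits into two
contrasts — AA vs {AB, BB} and {AA, AB} vs BB — and classifies each
significant eQTL as **additive** or **dominance** (with the dominant
allele identified), reporting overlapping hits once.

Around the scans: the full SNP QC cascade (site depth ≥ 20, biallelic
SNPs only, ≥ 20 samples called, ≥ 5 per genotype class, MAF > 0.15,
exact Levene–Haldane Hardy–Weinberg test at FDR 0.05), expression QC
(≥ 1M reads/sample, CPM > 2 in ≥ 5 samples, protein-coding, robust-z
outlier-gene removal), TPM for plotting, proximity/cis-trans annotation
from GFF3, a two-framework overlap report, a synthetic-data generator
with known additive/dominant effects, and calibration/power drivers.
Significance is nominal p < 5 × 10⁻⁸ (−log10 ≈ 7.3) throughout, with BH
q-values per scan.

## Worked example

Simulate the default desk-scale study (41 samples, 200 genes × 50 SNPs)
with one completely dominant eQTL (4-fold expression shift whenever the
alternate allele is present), then run both frameworks:

```r
library(dgeqtl)

eff <- data.frame(gene = 1, snp = 1, mode = "dominance_alt", beta = log(4))
sim <- simulate_counts(simulation_scenario(effects = eff, maf = 0.4,
                                           dispersion = 0.05, seed = 42))
nf   <- tmm_factors(sim$counts)

## framework 2: NB GLM two-tier scan + classification
t1  <- nb_anova_tier1(sim$counts, sim$genotypes, sim$site, nf)
t2  <- nb_contrast_tier2(t1, sim$counts, sim$genotypes, sim$site, nf)
add <- nb_additive(sim$counts, sim$genotypes, sim$site, nf,
                   dispersion = attr(t1, "dispersion"))
common <- intersect(names(t1), names(t2))
classify_modes(rbind(t1[, common], t2[, common]), add)
#>    gene_id variant_id      mode dominant_allele           source_tests
#> 1 gene0001     snp001 dominance             alt anova+contrast_ref_dom

## framework 1: INT + linear additive scan on the same data
expr <- inverse_normal(tmm_cpm(sim$counts, nf))
lin  <- additive_scan_linear(expr, sim$genotypes)
head(lin[, c("gene_id", "variant_id", "effect", "statistic", "p")], 1)
#>    gene_id variant_id    effect statistic            p
#> 1 gene0001     snp001 0.8292166  5.512289 2.461824e-06

compare_frameworks(lin, add)
#> Framework comparison at p < 5e-08
#>   significant pairs: linear_int = 0 , nb_glm = 1
#>   intersection = 0 ; Jaccard = 0
```

The NB ANOVA test finds the planted dominance eQTL at p = 8.5 × 10⁻¹⁶
and tier 2 identifies the alternate allele as dominant; the
inverse-normal linear scan ranks the same pair first but, at
p = 2.5 × 10⁻⁶, misses the genome-wide threshold — the rank transform
shrinks the very separation between genotype groups that the count model
exploits. `compare_frameworks()` quantifies the (here empty) overlap.

A command-line interface wraps the same functions
(`inst/exec/dgeqtl <subcommand>`): `simulate`, `filter-snps`,
`normalize`, `scan-linear`, `scan-nb`, `classify`, `annotate`,
`compare`, `calibrate`. All outputs are TSVs with provenance headers;
identical configs give byte-identical files.

See `vignettes/eqtl-frameworks.Rmd` for the models, parameter choices,
calibration details and limitations.

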