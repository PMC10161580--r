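nb_sim <- function(effects = NULL, seed = 1, n_genes = 30, n_snps = 4,
                   dispersion = 0.05, maf = 0.4) {
  sc <- simulation_scenario(n_genes = n_genes, n_snps = n_snps,
                            dispersion = dispersion, maf = maf,
                            effects = effects, seed = seed)
  sim <- simulate_counts(sc)
  sim$nf <- tmm_factors(sim$counts)
  sim
}

test_that("tier-2 contrasts use the documented pseudo-codings", {
  g <- c(0, 1, 2)
  r1 <- dgeqtl:::.nb_regressor(g, "contrast_ref_dom")
  expect_equal(unname(r1$X[, 1]), c(0, 1, 1))
  r2 <- dgeqtl:::.nb_regressor(g, "contrast_alt_dom")
  expect_equal(unname(r2$X[, 1]), c(0, 0, 1))
  expect_equal(dgeqtl:::.nb_regressor(rep(1, 3), "additive")$reason,
               "constant_genotype")
})

test_that("tier-2 tests are computed only for tier-1-significant pairs", {
  eff <- data.frame(gene = 1, snp = 1, mode = "dominance_alt",
                    beta = log(4))
  sim <- nb_sim(effects = eff, seed = 3)
  t1 <- nb_anova_tier1(sim$counts, sim$genotypes, sim$site, sim$nf)
  expect_true(any(t1$significant))
  t2 <- nb_contrast_tier2(t1, sim$counts, sim$genotypes, sim$site, sim$nf)
  gated <- attr(t2, "tested_pairs")
  expect_equal(nrow(gated), sum(t1$significant))
  expect_true(all(paste(t2$gene_id, t2$variant_id) %in%
                    paste(gated$gene_id, gated$variant_id)))
})

test_that("complete dominance of the alt allele fires only the
           AA-vs-rest contrast and is classified as dominance", {
  eff <- data.frame(gene = 1, snp = 1, mode = "dominance_alt",
                    beta = log(4))
  sim <- nb_sim(effects = eff, seed = 4)
  t1 <- nb_anova_tier1(sim$counts, sim$genotypes, sim$site, sim$nf)
  t2 <- nb_contrast_tier2(t1, sim$counts, sim$genotypes, sim$site, sim$nf)
  add <- nb_additive(sim$counts, sim$genotypes, sim$site, sim$nf,
                     dispersion = attr(t1, "dispersion"))
  calls <- classify_modes(combine_tiers(t1, t2), add)
  hit <- calls[calls$gene_id == "gene0001" & calls$variant_id == "snp001", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mode, "dominance")
  expect_equal(hit$dominant_allele, "alt")
})

test_that("an additive log-linear pattern is classified additive and the
           per-allele effect is recovered", {
  eff <- data.frame(gene = 2, snp = 2, mode = "additive", beta = log(3.5))
  sim <- nb_sim(effects = eff, seed = 5)
  phi <- rep(0.05, 30)
  add <- nb_additive(sim$counts, sim$genotypes, sim$site, sim$nf,
                     dispersion = phi)
  hit <- add[add$gene_id == "gene0002" & add$variant_id == "snp002", ]
  expect_true(hit$significant)
  expect_equal(hit$effect_log2, log2(3.5), tolerance = 0.25)
  t1 <- nb_anova_tier1(sim$counts, sim$genotypes, sim$site, sim$nf,
                       dispersion = phi)
  t2 <- nb_contrast_tier2(t1, sim$counts, sim$genotypes, sim$site,
                          sim$nf, dispersion = phi)
  calls <- classify_modes(combine_tiers(t1, t2), add)
  hitc <- calls[calls$gene_id == "gene0002" & calls$variant_id == "snp002", ]
  expect_equal(nrow(hitc), 1)   # overlap rule: one call only
  expect_equal(hitc$mode, "additive")
})

test_that("classify_modes applies the reporting rules on constructed
           results", {
  mk <- function(gene, variant, model, p) {
    data.frame(gene_id = gene, variant_id = variant, model = model, p = p,
               stringsAsFactors = FALSE)
  }
  anova_tier <- rbind(
    mk("gA", "v1", "anova", 1e-10),            # dominance alt pattern
    mk("gA", "v1", "contrast_ref_dom", 1e-9),
    mk("gA", "v1", "contrast_alt_dom", 0.2),
    mk("gB", "v2", "anova", 1e-10),            # dominance ref pattern
    mk("gB", "v2", "contrast_ref_dom", 0.4),
    mk("gB", "v2", "contrast_alt_dom", 1e-9),
    mk("gC", "v3", "anova", 1e-10),            # neither contrast
    mk("gC", "v3", "contrast_ref_dom", 0.5),
    mk("gC", "v3", "contrast_alt_dom", 0.5),
    mk("gD", "v4", "anova", 1e-10),            # both + additive
    mk("gD", "v4", "contrast_ref_dom", 1e-9),
    mk("gD", "v4", "contrast_alt_dom", 1e-9))
  additive <- rbind(
    mk("gD", "v4", "additive", 1e-9),
    mk("gE", "v5", "additive", 1e-9),          # additive-only pair
    mk("gA", "v1", "additive", 1e-9))          # overlaps tier-1 pair gA/v1
  calls <- classify_modes(anova_tier, additive)
  expect_equal(nrow(calls), 5)
  expect_equal(anyDuplicated(calls[, c("gene_id", "variant_id")]), 0)
  modes <- setNames(calls$mode, paste(calls$gene_id, calls$variant_id))
  expect_equal(unname(modes["gA v1"]), "dominance")
  expect_equal(calls$dominant_allele[calls$gene_id == "gA"], "alt")
  expect_equal(unname(modes["gB v2"]), "dominance")
  expect_equal(calls$dominant_allele[calls$gene_id == "gB"], "ref")
  expect_equal(unname(modes["gC v3"]), "unresolved")
  expect_equal(unname(modes["gD v4"]), "additive")
  expect_equal(unname(modes["gE v5"]), "additive")
  expect_equal(calls$source_tests[calls$gene_id == "gE"], "additive_only")
})

test_that("NB scans skip constant genotypes and log reasons", {
  sim <- nb_sim(seed = 6, n_snps = 2)
  sim$genotypes$codes[1, ] <- 1L
  add <- nb_additive(sim$counts, sim$genotypes, sim$site, sim$nf,
                     dispersion = rep(0.05, 30))
  expect_false("snp001" %in% add$variant_id)
  expect_equal(attr(add, "skips")$reason, "constant_genotype")
  expect_equal(attr(add, "skips")$variant_id, "snp001")
})

test_that("site covariate levels are ordered lexicographically and a
           strong site effect does not inflate the genotype test", {
  eff <- NULL
  sc <- simulation_scenario(n_genes = 60, n_snps = 8, site_levels = 2,
                            site_effect = 1.5, dispersion = 0.1, maf = 0.4,
                            seed = 7)
  sim <- simulate_counts(sc)
  nf <- tmm_factors(sim$counts)
  t1 <- nb_anova_tier1(sim$counts, sim$genotypes, sim$site, nf)
  rate <- mean(t1$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(t1)) + 0.01)
  X <- dgeqtl:::.site_design(factor(c("b", "a", "a", "b")), 4)
  expect_equal(colnames(X)[2], "fb")   # first level "a" is the reference
})
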