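make_scan_fixture <- function(n_genes = 10, n_snps = 6, n = 41, seed = 1,
                              miss = 0) {
  set.seed(seed)
  codes <- t(replicate(n_snps, simulate_genotypes(n, 0.35)))
  if (miss > 0) codes[sample(length(codes), miss)] <- NA
  gm <- toy_gm(codes)
  Y <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n))))
  list(gm = gm, Y = Y)
}

test_that("additive scan: perfect fit and orthogonal response behave", {
  g <- c(rep(0, 14), rep(1, 14), rep(2, 13))
  gm <- toy_gm(matrix(g, 1))
  Y <- rbind(gene_perfect = g,
             gene_flat = rep(c(-1, 1), length.out = 41))
  colnames(Y) <- paste0("s", 1:41)
  res <- additive_scan_linear(Y, gm)
  perfect <- res[res$gene_id == "gene_perfect", ]
  expect_equal(perfect$effect, 1, tolerance = 1e-12)
  expect_true(perfect$p_floored)
  expect_equal(perfect$p, .Machine$double.xmin)
  flat <- res[res$gene_id == "gene_flat", ]
  expect_lt(abs(flat$effect), 0.1)
  expect_gt(flat$p, 0.5)
})

test_that("vectorized scans equal the per-pair lm oracle", {
  fx <- make_scan_fixture(n_genes = 10, n_snps = 5, miss = 12)
  covar <- data.frame(site = factor(rep(c("a", "b"), length.out = 41)))
  add <- additive_scan_linear(fx$Y, fx$gm, covariates = covar)
  anv <- anova_scan_linear(fx$Y, fx$gm, covariates = covar)
  for (i in sample(nrow(add), 25)) {
    r <- add[i, ]
    g <- fx$gm$codes[match(r$variant_id, variant_ids(fx$gm)), ]
    y <- fx$Y[r$gene_id, ]
    d <- data.frame(y = y, g = g, site = covar$site)
    fit <- summary(lm(y ~ g + site, data = d))$coefficients
    expect_equal(r$effect, fit["g", 1], tolerance = 1e-8)
    expect_equal(r$statistic, fit["g", 3], tolerance = 1e-8)
    expect_equal(r$p, fit["g", 4], tolerance = 1e-8)
  }
  for (i in sample(nrow(anv), 15)) {
    r <- anv[i, ]
    g <- fx$gm$codes[match(r$variant_id, variant_ids(fx$gm)), ]
    d <- data.frame(y = fx$Y[r$gene_id, ], g = factor(g),
                    site = covar$site)
    d <- d[!is.na(g), ]
    a <- anova(lm(y ~ site, data = d), lm(y ~ site + g, data = d))
    expect_equal(r$statistic, a$F[2], tolerance = 1e-8)
    expect_equal(r$p, a$`Pr(>F)`[2], tolerance = 1e-8)
  }
})

test_that("ANOVA scan: equal group means give F = 0 and matches hand
           computation on a 9-value toy", {
  g <- rep(0:2, each = 3)
  gm <- toy_gm(matrix(g, 1))
  Y <- rbind(equal = rep(1:3, times = 3),
             shifted = c(0, 0, 0, 0, 0, 0, 5, 5, 5))
  colnames(Y) <- paste0("s", 1:9)
  res <- anova_scan_linear(Y, gm)
  eq <- res[res$gene_id == "equal", ]
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1)
  sh <- res[res$gene_id == "shifted", ]
  # textbook one-way ANOVA: SSB = 50/3*2... between SS = sum n_k(mean_k-gm)^2
  gmn <- mean(Y["shifted", ])
  ssb <- sum(3 * (tapply(Y["shifted", ], g, mean) - gmn)^2)
  ssw <- sum((Y["shifted", ] - rep(tapply(Y["shifted", ], g, mean),
                                   each = 3))^2)
  expect_equal(ssw, 0)
  expect_true(sh$p_floored)
  expect_equal(sh$mean_AA, 0)
  expect_equal(sh$mean_BB, 5)
})

test_that("additive model is nested in the factor model: anova RSS never
           exceeds additive RSS", {
  fx <- make_scan_fixture(n_genes = 8, n_snps = 4, seed = 5)
  add <- additive_scan_linear(fx$Y, fx$gm)
  anv <- anova_scan_linear(fx$Y, fx$gm)
  key <- function(d) paste(d$gene_id, d$variant_id)
  m <- match(key(add), key(anv))
  # reconstruct residual SS from sigma2: rss = s2 * df2 where s2 from t-test
  # is not carried; instead compare via F statistics on shared df
  n <- 41
  rss_add <- vapply(seq_len(nrow(add)), function(i) {
    g <- fx$gm$codes[match(add$variant_id[i], variant_ids(fx$gm)), ]
    y <- fx$Y[add$gene_id[i], ]
    sum(resid(lm(y ~ g))^2)
  }, numeric(1))
  rss_anv <- vapply(seq_len(nrow(add)), function(i) {
    g <- fx$gm$codes[match(add$variant_id[i], variant_ids(fx$gm)), ]
    y <- fx$Y[add$gene_id[i], ]
    sum(resid(lm(y ~ factor(g)))^2)
  }, numeric(1))
  expect_true(all(rss_anv <= rss_add + 1e-10))
})

test_that("scans drop variants lacking all three genotype classes", {
  codes <- rbind(c(rep(0, 20), rep(1, 21)),       # two classes only
                 c(rep(0, 14), rep(1, 14), rep(2, 13)))
  gm <- toy_gm(codes)
  Y <- matrix(rnorm(2 * 41), 2, 41,
              dimnames = list(c("a", "b"), paste0("s", 1:41)))
  add <- additive_scan_linear(Y, gm)
  expect_setequal(unique(add$variant_id), "v2")
  sk <- attr(add, "skips")
  expect_equal(sk$variant_id, "v1")
  expect_match(sk$reason, "distinct")
  anv <- anova_scan_linear(Y, gm)
  expect_equal(attr(anv, "skips")$reason, "empty_genotype_class")
})

test_that("BH adjustment and thresholding follow their definitions", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  res <- data.frame(p = c(5e-8, 4.9e-8, 0.2))
  out <- apply_threshold(res)
  expect_equal(out$significant, c(FALSE, TRUE, FALSE))   # strict <
  expect_equal(attr(out, "neglog10_threshold"), -log10(5e-8))
  expect_equal(round(attr(out, "neglog10_threshold"), 1), 7.3)
})

test_that("results are ordered by p with deterministic ties and carry q", {
  fx <- make_scan_fixture(n_genes = 6, n_snps = 3, seed = 8)
  res <- additive_scan_linear(fx$Y, fx$gm)
  expect_false(is.unsorted(res$p))
  expect_equal(res$q, bh_fdr(res$p))
  expect_true(all(res$q >= res$p - 1e-15))
  expect_true(all(res$q <= 1))
})
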