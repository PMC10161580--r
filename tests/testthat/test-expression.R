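test_that("drop_shallow_samples removes columns below the read floor", {
  counts <- cbind(a = c(999999, 0), b = c(1000000, 0), c = c(2e6, 5))
  cm <- toy_cm(counts)
  out <- suppressMessages(drop_shallow_samples(cm))
  expect_equal(attr(out, "removed_samples"), "s1")
  expect_equal(length(out$samples), 2)
  expect_error(drop_shallow_samples(toy_cm(matrix(1, 2, 2))), "below")
})

test_that("a 42-sample matrix with one shallow library yields 41 samples", {
  set.seed(3)
  counts <- matrix(rpois(50 * 42, 30000), 50, 42)
  counts[, 13] <- rpois(50, 10000)  # ~0.5M total, below the floor
  out <- suppressMessages(drop_shallow_samples(toy_cm(counts)))
  expect_equal(length(out$samples), 41)
})

test_that("cpm scales counts per million and conserves column sums", {
  cm <- toy_cm(rbind(c(250, 0), c(499750, 100)))
  v <- cpm(cm, sizes = c(500000, 100))$values
  expect_equal(v[1, 1], 500)
  expect_equal(v[1, 2], 0)
  full <- cpm(cm)$values
  expect_equal(unname(colSums(full)), c(1e6, 1e6))
  expect_error(cpm(cm, sizes = c(0, 1)), "> 0")
})

test_that("filter_genes applies strict CPM cut, sample count and biotype", {
  n <- 6
  counts <- rbind(
    rep(2, n),            # CPM exactly at threshold -> removed
    c(rep(50, 5), 0),     # CPM > 2 in exactly 5 -> retained
    rep(100, n),          # high but wrong biotype -> removed
    rep(1000, n))
  counts <- rbind(counts, matrix(1e6, 2, n))  # bulk so cpm is stable
  cm <- toy_cm(counts, biotype = c("protein_coding", "protein_coding",
                                   "lncRNA", "protein_coding",
                                   "protein_coding", "protein_coding"))
  # make gene 1 sit exactly at CPM 2: total per column must be 1e6 * k
  tot <- colSums(cm$counts)
  thr <- 1e6 * cm$counts[1, ] / tot  # actual CPM of gene 1
  out <- filter_genes(cm, cpm_threshold = max(thr), min_samples = 5)
  expect_false("g1" %in% out$genes$gene_id)   # boundary is strict
  expect_true("g2" %in% out$genes$gene_id)
  expect_false("g3" %in% out$genes$gene_id)   # lncRNA
})

test_that("tpm normalizes rates to one million per sample", {
  one <- toy_cm(matrix(c(7, 3), 1, 2), exonic_length = 123L)
  expect_equal(unname(tpm(one)$values[1, ]), c(1e6, 1e6))
  two <- toy_cm(matrix(c(100, 100), 2, 1), exonic_length = c(1000L, 2000L))
  expect_equal(unname(tpm(two)$values[, 1]),
               c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  degenerate <- toy_cm(cbind(c(5, 5), c(0, 0)))
  expect_warning(v <- tpm(degenerate)$values, "all-zero")
  expect_equal(unname(v[, 2]), c(0, 0))
  bad <- toy_cm(matrix(1, 1, 2))
  bad$genes$exonic_length <- NA
  expect_error(tpm(bad), "g1")
  set.seed(1)
  big <- toy_cm(matrix(rpois(600, 40), 100, 6),
                exonic_length = sample(200:5000, 100))
  expect_equal(unname(colSums(tpm(big)$values)), rep(1e6, 6),
               tolerance = 1e-6)
})

test_that("TMM factors are 1 for proportional libraries and match the
           trimmed weighted-mean formula on a toy", {
  eq <- toy_cm(cbind(rep(1000, 8), rep(1000, 8)))
  expect_equal(tmm_factors(eq)$tmm_factor, c(1, 1))
  prop <- toy_cm(cbind(rep(1000, 8), rep(2000, 8)))
  expect_equal(tmm_factors(prop)$tmm_factor, c(1, 1))
  # one gene 10-fold higher in sample B, the rest equal
  toy <- cbind(A = c(1000, 500, 800, 1200, 300, 900),
               B = c(10000, 500, 800, 1200, 300, 900))
  f <- tmm_factors(toy_cm(toy))$tmm_factor
  expect_equal(f, unname(tmm_two_sample_oracle(toy)), tolerance = 1e-10)
})

test_that("TMM factors: geometric mean 1, scale invariance, permutation", {
  set.seed(9)
  counts <- matrix(rnbinom(200 * 5, mu = 150, size = 2), 200, 5) + 1
  cm <- toy_cm(counts)
  f <- tmm_factors(cm)$tmm_factor
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-8)
  f2 <- tmm_factors(toy_cm(counts * 3))$tmm_factor
  expect_equal(f, f2, tolerance = 1e-10)
  perm <- c(2, 1, 3, 5, 4)
  f3 <- tmm_factors(toy_cm(counts[, perm]))$tmm_factor
  expect_equal(f3, f[perm], tolerance = 1e-10)
})

test_that("tmm_cpm uses effective sizes and reduces to cpm at unit factors", {
  set.seed(2)
  cm <- toy_cm(matrix(rpois(50 * 3, 500), 50, 3))
  nf <- tmm_factors(cm)
  nf_unit <- nf
  nf_unit$tmm_factor <- rep(1, 3)
  nf_unit$effective_size <- nf$library_size
  expect_equal(tmm_cpm(cm, nf_unit)$values, cpm(cm)$values)
  nf_two <- nf_unit
  nf_two$library_size <- rep(1e6, 3)
  nf_two$tmm_factor <- rep(2, 3)
  nf_two$effective_size <- rep(2e6, 3)
  cm100 <- toy_cm(matrix(100, 2, 3))
  expect_equal(unname(tmm_cpm(cm100, nf_two)$values[1, 1]), 50)
})

test_that("inverse normal transformation maps ranks to normal quantiles", {
  m3 <- matrix(c(5, 1, 9), 1, 3)         # middle value is the first entry
  expect_equal(inverse_normal(m3)$values[1, 1], qnorm(0.5))
  expect_equal(inverse_normal(m3)$values[1, 2], qnorm(0.625 / 3.25))
  m5 <- matrix(c(10, 20, 30, 40, 50), 1, 5)
  expect_equal(inverse_normal(m5)$values[1, 1],
               qnorm((1 - 0.375) / (5 - 0.75 + 1)))
  expect_equal(inverse_normal(m5)$values[1, 1], -1.1798, tolerance = 1e-4)
  # rank invariance: shuffling the input permutes the same output multiset
  set.seed(4)
  x <- rnorm(41)
  perm <- sample(41)
  a <- inverse_normal(matrix(x, 1))$values
  b <- inverse_normal(matrix(x[perm], 1))$values
  expect_equal(a[perm], b[1, ])
  expect_true(all(diff(a[order(x)]) > 0))          # monotone
  expect_lt(abs(mean(a)), 1e-8)
  expect_lt(abs(var(as.numeric(a)) - 1), 0.1)
  expect_warning(z <- inverse_normal(matrix(1, 1, 5)), "constant")
  expect_equal(unname(z$values[1, ]), rep(0, 5))
})

test_that("outlier-gene removal drops spikes, keeps constants, and is
           conservative under the null", {
  set.seed(6)
  n <- 41  # MAD needs a realistic sample count to be stable
  # BCV ~ 0.32 (phi = 0.1), a typical biological-replicate dispersion; the
  # false-positive rate of the robust-z rule grows with skewness/dispersion
  counts <- matrix(rnbinom(1000 * n, mu = 200, size = 10), 1000, n)
  counts[1, 4] <- counts[1, 4] * 1000 + 1000          # extreme spike
  counts[2, ] <- 300                                  # constant gene
  cm <- toy_cm(counts)
  nf <- tmm_factors(cm)
  out <- remove_outlier_genes(cm, nf)
  removed <- attr(out, "outlier_rule")$removed
  expect_true("g1" %in% removed)
  expect_false("g2" %in% removed)
  expect_lt(length(removed) / 1000, 0.02)
})
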