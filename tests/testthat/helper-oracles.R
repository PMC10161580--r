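# Independent oracles and small programmatic fixtures shared by the tests.

# Exact Hardy-Weinberg p-value by direct enumeration of the Levene-Haldane
# pmf from its closed form (lfactorial), independent of the package's
# recurrence implementation. Same probability-ordering rule with relative
# tie tolerance.
hwe_oracle_p <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  n_alt <- 2 * nBB + nAB
  n_minor <- min(n_alt, 2 * n - n_alt)
  n_major <- 2 * n - n_minor
  if (n_minor == 0) return(1)
  hets <- seq.int(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    a <- (n_minor - h) / 2
    b <- (n_major - h) / 2
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) + lfactorial(n_minor) + lfactorial(n_major) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  p_obs <- p[match(nAB, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Direct evaluation of the TMM formula for a two-sample matrix: doubly
# trimmed, inverse-variance-weighted mean of M values against the
# reference column, factors rescaled to geometric mean 1.
tmm_two_sample_oracle <- function(counts, logratio_trim = 0.3,
                                  abs_trim = 0.05) {
  N <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / N
  ref <- which.min(abs(f75 - mean(f75)))
  obs <- 3 - ref
  yo <- counts[, obs]; yr <- counts[, ref]
  keep <- yo > 0 & yr > 0
  M <- log2((yo[keep] / N[obs]) / (yr[keep] / N[ref]))
  A <- 0.5 * log2((yo[keep] / N[obs]) * (yr[keep] / N[ref]))
  w <- (N[obs] - yo[keep]) / (N[obs] * yo[keep]) +
    (N[ref] - yr[keep]) / (N[ref] * yr[keep])
  if (max(abs(M)) < 1e-6) {
    f_obs <- 1
  } else {
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    k <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f_obs <- 2^(sum(M[k] / w[k]) / sum(1 / w[k]))
  }
  f <- c(1, 1); f[obs] <- f_obs
  f / exp(mean(log(f)))
}

# Tiny genotype/count builders used across tests.
toy_gm <- function(codes, chrom = "1", pos = NULL, depth = 100,
                   ref = "A", alt = "G") {
  codes <- as.matrix(codes)
  nv <- nrow(codes)
  if (is.null(pos)) pos <- seq_len(nv) * 1000L
  sites <- data.frame(chrom = chrom, pos = pos,
                      id = paste0("v", seq_len(nv)), ref = ref, alt = alt,
                      depth = depth, stringsAsFactors = FALSE)
  genotype_matrix(sites, paste0("s", seq_len(ncol(codes))), codes)
}

toy_cm <- function(counts, biotype = "protein_coding",
                   exonic_length = 1000L, chrom = "1") {
  counts <- as.matrix(counts)
  ng <- nrow(counts)
  genes <- data.frame(gene_id = paste0("g", seq_len(ng)), chrom = chrom,
                      start = seq_len(ng) * 10000L,
                      end = seq_len(ng) * 10000L + 500L,
                      exonic_length = exonic_length,
                      biotype = rep_len(biotype, ng),
                      stringsAsFactors = FALSE)
  count_matrix(genes, paste0("s", seq_len(ncol(counts))), counts)
}

# A small multi-sample VCF written in code (3 samples unless more given).
write_toy_vcf <- function(path,
                          records = c(
  "1\t100\trs1\tA\tG\t50\tPASS\tDP=60\tGT\t0/0\t0/1\t1/1",
  "1\t200\trs2\tC\tT\t50\tPASS\tDP=25\tGT\t0/0\t./.\t0/1",
  "1\t300\trs3\tG\tA\t50\tPASS\tDP=19\tGT\t0/0\t0/1\t0/1",
  "1\t400\trs4\tA\tG,T\t50\tPASS\tDP=99\tGT\t0/0\t0/1\t1/1",
  "1\t500\trs5\tAT\tA\t50\tPASS\tDP=80\tGT\t0/0\t0/1\t0/0"),
                          samples = c("s1", "s2", "s3")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

# rbind tier-1 and tier-2 NB results on their shared columns (the tier-1
# ANOVA table carries extra per-genotype effect columns).
combine_tiers <- function(t1, t2) {
  common <- intersect(names(t1), names(t2))
  rbind(t1[, common], t2[, common])
}
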