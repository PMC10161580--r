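#' Basic variant filters: depth, SNP-only, call rate
#'
#' First stage of the SNP QC cascade: keep sites supported by at least
#' `min_depth` reads, genotyped in at least `min_called` samples, and (when
#' `snp_only`) with single-nucleotide ref and alt alleles.
#'
#' @param gm `GenotypeMatrix`.
#' @param min_depth minimum site-level read depth (default 20).
#' @param min_called minimum number of samples with a called genotype
#'   (default 20).
#' @param snp_only drop sites whose ref or alt is not a single A/C/G/T.
#' @return filtered `GenotypeMatrix`, input order preserved; attribute
#'   `funnel` records counts before/after each rule.
#' @export
filter_variants <- function(gm, min_depth = 20L, min_called = 20L,
                            snp_only = TRUE) {
  if (nrow(gm$codes) == 0) stop("empty GenotypeMatrix")
  nuc <- c("A", "C", "G", "T")
  depth_ok <- !is.na(gm$sites$depth) & gm$sites$depth >= min_depth
  snp_ok <- if (snp_only) {
    gm$sites$ref %in% nuc & gm$sites$alt %in% nuc
  } else rep(TRUE, nrow(gm$sites))
  n_called <- rowSums(!is.na(gm$codes))
  called_ok <- n_called >= min_called
  keep <- depth_ok & snp_ok & called_ok
  out <- subset_gm(gm, keep)
  attr(out, "funnel") <- c(
    input = nrow(gm$codes),
    depth_pass = sum(depth_ok),
    snp_pass = sum(depth_ok & snp_ok),
    called_pass = sum(keep)
  )
  out
}

#' Per-variant genotype class counts
#'
#' @param gm `GenotypeMatrix`.
#' @return data.frame with `n_AA` (reference homozygotes), `n_AB`
#'   (heterozygotes), `n_BB` (alternate homozygotes) and `n_called`,
#'   one row per variant; missing genotypes are excluded from all counts.
#' @export
genotype_counts <- function(gm) {
  codes <- gm$codes
  n_AA <- rowSums(codes == 0L, na.rm = TRUE)
  n_AB <- rowSums(codes == 1L, na.rm = TRUE)
  n_BB <- rowSums(codes == 2L, na.rm = TRUE)
  data.frame(variant_id = variant_ids(gm), n_AA = n_AA, n_AB = n_AB,
             n_BB = n_BB, n_called = n_AA + n_AB + n_BB,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Minor allele frequency from genotype counts
#'
#' @param gc data.frame (or single row) with `n_AA`, `n_AB`, `n_BB`, as from
#'   [genotype_counts()]. Frequencies use called genotypes only.
#' @return numeric vector of MAFs in \[0, 0.5\].
#' @export
minor_allele_frequency <- function(gc) {
  n_called <- gc$n_AA + gc$n_AB + gc$n_BB
  if (any(n_called == 0)) stop("MAF undefined: variant with no called genotypes")
  p_alt <- (2 * gc$n_BB + gc$n_AB) / (2 * n_called)
  pmin(p_alt, 1 - p_alt)
}

# Levene-Haldane conditional pmf over heterozygote counts, computed by the
# standard ratio recurrence (numerically stable, no factorials). n = called
# individuals, n_minor = minor allele count. Returns probabilities indexed by
# het counts seq(h_min, n_minor, by = 2).
hwe_het_pmf <- function(n, n_minor) {
  h_min <- n_minor %% 2L
  hets <- seq.int(h_min, n_minor, by = 2L)
  n_major <- 2L * n - n_minor
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1L]
    a <- (n_minor - h) / 2          # minor homozygotes at h
    b <- (n_major - h) / 2          # major homozygotes at h
    # P(h + 2) / P(h) = 4 a b / ((h + 1)(h + 2))
    lp[k] <- lp[k - 1L] + log(4 * a * b) - log((h + 1) * (h + 2))
  }
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Exact Hardy-Weinberg test p-value
#'
#' Two-sided exact test conditioning on the allele counts: the p-value is
#' the total Levene-Haldane probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (probability-ordering definition, no mid-p correction).
#'
#' @param gc data.frame with `n_AA`, `n_AB`, `n_BB` (vectorized over rows).
#' @return numeric vector of p-values in (0, 1\].
#' @export
hwe_exact_p <- function(gc) {
  if (any(gc$n_AA < 0 | gc$n_AB < 0 | gc$n_BB < 0)) {
    stop("genotype counts must be non-negative")
  }
  mapply(function(nAA, nAB, nBB) {
    n <- nAA + nAB + nBB
    if (n == 0) stop("HWE test undefined: no called genotypes")
    n_alt <- 2L * nBB + nAB
    n_minor <- min(n_alt, 2L * n - n_alt)
    if (n_minor == 0L) return(1.0)
    pmf <- hwe_het_pmf(n, n_minor)
    hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
    p_obs <- pmf[match(nAB, hets)]
    # relative tolerance so exactly-tied classes are included deterministically
    min(1.0, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
  }, gc$n_AA, gc$n_AB, gc$n_BB)
}

#' Variant QC table
#'
#' Computes, for every variant, the quantities used by the eQTL SNP filter:
#' genotype class counts, MAF, exact HWE p-value and its BH-adjusted q-value
#' across all variants, together with pass flags.
#'
#' @inheritParams eqtl_snp_set
#' @return data.frame, one row per variant, with columns `variant_id`,
#'   `chrom`, `pos`, `depth`, `n_called`, `n_AA`, `n_AB`, `n_BB`, `maf`,
#'   `hwe_p`, `hwe_q`, `pass_class`, `pass_maf`, `pass_hwe`, `pass`.
#' @export
variant_qc_table <- function(gm, min_per_class = 5L, maf_threshold = 0.15,
                             hwe_fdr = 0.05) {
  gc <- genotype_counts(gm)
  tested <- gc$n_called > 0
  maf <- rep(NA_real_, nrow(gc))
  maf[tested] <- minor_allele_frequency(gc[tested, , drop = FALSE])
  hwe_p <- rep(NA_real_, nrow(gc))
  hwe_p[tested] <- hwe_exact_p(gc[tested, , drop = FALSE])
  hwe_q <- rep(NA_real_, nrow(gc))
  hwe_q[tested] <- bh_fdr(hwe_p[tested])
  pass_class <- gc$n_AA >= min_per_class & gc$n_AB >= min_per_class &
    gc$n_BB >= min_per_class
  pass_maf <- !is.na(maf) & maf > maf_threshold
  pass_hwe <- !is.na(hwe_q) & hwe_q >= hwe_fdr
  data.frame(
    variant_id = gc$variant_id,
    chrom = gm$sites$chrom, pos = gm$sites$pos, depth = gm$sites$depth,
    n_called = gc$n_called, n_AA = gc$n_AA, n_AB = gc$n_AB, n_BB = gc$n_BB,
    maf = maf, hwe_p = hwe_p, hwe_q = hwe_q,
    pass_class = pass_class, pass_maf = pass_maf, pass_hwe = pass_hwe,
    pass = pass_class & pass_maf & pass_hwe,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Select the SNP set used for eQTL scans
#'
#' Applies the association-ready SNP filter: at least `min_per_class`
#' individuals in each of the three genotype classes, minor allele frequency
#' strictly above `maf_threshold`, and no Hardy-Weinberg rejection after
#' Benjamini-Hochberg adjustment of the exact-test p-values across all
#' variants at `hwe_fdr`.
#'
#' @param gm `GenotypeMatrix`, typically output of [filter_variants()].
#' @param min_per_class minimum individuals per genotype class (default 5).
#' @param maf_threshold MAF must exceed this (strict; default 0.15).
#' @param hwe_fdr FDR level for the HWE rejection (default 0.05).
#' @return filtered `GenotypeMatrix`; attribute `qc` holds the full
#'   [variant_qc_table()].
#' @export
eqtl_snp_set <- function(gm, min_per_class = 5L, maf_threshold = 0.15,
                         hwe_fdr = 0.05) {
  qc <- variant_qc_table(gm, min_per_class, maf_threshold, hwe_fdr)
  out <- subset_gm(gm, qc$pass)
  attr(out, "qc") <- qc
  out
}
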