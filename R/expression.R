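#' Drop samples with shallow sequencing
#'
#' Removes samples whose total mapped count falls below `min_total` reads.
#'
#' @param cm `CountMatrix`.
#' @param min_total minimum column sum (default one million reads).
#' @return `CountMatrix` without the shallow columns; removals are messaged
#'   and recorded in the `removed_samples` attribute.
#' @export
drop_shallow_samples <- function(cm, min_total = 1e6) {
  totals <- colSums(cm$counts)
  keep <- totals >= min_total
  if (!any(keep)) stop("all samples fall below min_total = ", min_total)
  if (any(!keep)) {
    message("drop_shallow_samples: removed ",
            paste(cm$samples[!keep], collapse = ", "))
  }
  out <- subset_cm(cm, keep_samples = which(keep))
  attr(out, "removed_samples") <- cm$samples[!keep]
  out
}

#' Counts per million
#'
#' @param cm `CountMatrix`.
#' @param sizes per-sample denominators; defaults to raw library sizes
#'   (column sums). Pass effective sizes for TMM-CPM.
#' @return `TransformedExpression` with transform `"cpm"`.
#' @export
cpm <- function(cm, sizes = colSums(cm$counts)) {
  if (any(sizes <= 0)) stop("cpm: all size denominators must be > 0")
  if (length(sizes) != length(cm$samples)) stop("cpm: sizes length mismatch")
  values <- sweep(cm$counts, 2, sizes, "/") * 1e6
  new_transformed(values, "cpm", list(sizes = sizes))
}

#' Expression-level gene filter
#'
#' Retains genes of the requested biotype whose CPM (computed on raw library
#' sizes) exceeds `cpm_threshold` (strict) in at least `min_samples` samples.
#'
#' @param cm `CountMatrix`.
#' @param cpm_threshold CPM must exceed this (default 2).
#' @param min_samples in at least this many samples (default 5).
#' @param biotype biotype label to keep (default `"protein_coding"`); `NULL`
#'   disables the biotype rule.
#' @return filtered `CountMatrix` with a `funnel` attribute.
#' @export
filter_genes <- function(cm, cpm_threshold = 2, min_samples = 5L,
                         biotype = "protein_coding") {
  cpm_vals <- cpm(cm)$values
  expr_ok <- rowSums(cpm_vals > cpm_threshold) >= min_samples
  bio_ok <- if (is.null(biotype)) rep(TRUE, nrow(cm$counts)) else
    cm$genes$biotype == biotype
  keep <- expr_ok & bio_ok
  out <- subset_cm(cm, keep_genes = which(keep))
  attr(out, "funnel") <- c(input = nrow(cm$counts),
                           biotype_pass = sum(bio_ok),
                           retained = sum(keep))
  out
}

#' Transcripts per million
#'
#' Length-normalized abundance: per-gene count rates (count / exonic length)
#' rescaled so each sample sums to one million.
#'
#' @param cm `CountMatrix` with `exonic_length` known for every gene.
#' @return `TransformedExpression` with transform `"tpm"`. An all-zero
#'   sample yields zeros with a warning rather than NaN.
#' @export
tpm <- function(cm) {
  len <- cm$genes$exonic_length
  bad <- is.na(len) | len <= 0
  if (any(bad)) {
    stop("tpm: missing/invalid exonic_length for gene(s): ",
         paste(cm$genes$gene_id[bad], collapse = ", "))
  }
  rate <- cm$counts / len
  denom <- colSums(rate)
  zero_col <- denom == 0
  if (any(zero_col)) {
    warning("tpm: all-zero sample(s) set to 0: ",
            paste(cm$samples[zero_col], collapse = ", "))
    denom[zero_col] <- 1
  }
  values <- sweep(rate, 2, denom, "/") * 1e6
  new_transformed(values, "tpm", list())
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scale factors (Robinson-Oshlack): log expression
#' ratios against a reference sample are doubly trimmed by M and A quantiles
#' and averaged with inverse asymptotic-variance weights; factors are
#' rescaled to geometric mean 1. The computation is performed by
#' `edgeR::calcNormFactors(method = "TMM")`, the reference implementation of
#' this procedure; trim fractions are exposed here and recorded.
#'
#' @param cm `CountMatrix` (at least 2 samples, no all-zero column).
#' @param logratio_trim two-sided trim fraction on M values (default 0.30).
#' @param abs_trim two-sided trim fraction on A values (default 0.05).
#' @param a_cutoff genes with A below this are dropped before trimming.
#' @return object of class `NormFactors`: per-sample `library_size`,
#'   `tmm_factor`, `effective_size` (= library_size * tmm_factor).
#' @export
tmm_factors <- function(cm, logratio_trim = 0.30, abs_trim = 0.05,
                        a_cutoff = -1e10) {
  counts <- cm$counts
  if (ncol(counts) < 2) stop("tmm_factors needs at least 2 samples")
  if (any(colSums(counts) == 0)) stop("tmm_factors: all-zero sample column")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim,
                              doWeighting = TRUE, Acutoff = a_cutoff)
  lib <- colSums(counts)
  structure(list(samples = cm$samples, library_size = lib,
                 tmm_factor = as.numeric(f),
                 effective_size = lib * as.numeric(f),
                 params = list(logratio_trim = logratio_trim,
                               abs_trim = abs_trim, a_cutoff = a_cutoff)),
            class = "NormFactors")
}

#' @export
print.NormFactors <- function(x, ...) {
  cat("NormFactors for", length(x$samples), "samples; tmm_factor range",
      paste(signif(range(x$tmm_factor), 4), collapse = " - "), "\n")
  invisible(x)
}

#' TMM-normalized counts per million
#'
#' CPM on effective library sizes (library size times TMM factor).
#'
#' @param cm `CountMatrix`.
#' @param nf `NormFactors` from [tmm_factors()] for the same samples.
#' @return `TransformedExpression` with transform `"tmm_cpm"`.
#' @export
tmm_cpm <- function(cm, nf) {
  if (!identical(nf$samples, cm$samples)) {
    stop("tmm_cpm: NormFactors samples do not match CountMatrix samples")
  }
  out <- cpm(cm, sizes = nf$effective_size)
  out$transform <- "tmm_cpm"
  out$provenance$tmm <- nf$params
  out
}

#' Rank-based inverse normal transformation
#'
#' Per gene across samples, values are replaced by normal quantiles of their
#' offset-adjusted ranks: `qnorm((rank - k) / (n - 2k + 1))`, with average
#' ranks for ties and the Blom offset k = 3/8 by default.
#'
#' @param values `TransformedExpression` or numeric matrix (genes x samples,
#'   n >= 3).
#' @param offset_k rank offset k (default 0.375).
#' @return `TransformedExpression` with transform `"int"`. Constant rows map
#'   to all zeros with a warning.
#' @export
inverse_normal <- function(values, offset_k = 0.375) {
  m <- as_values(values)
  n <- ncol(m)
  if (n < 3) stop("inverse_normal needs at least 3 samples")
  const <- apply(m, 1, function(x) all(x == x[1]))
  out <- t(apply(m, 1, function(x) {
    r <- rank(x, ties.method = "average")
    qnorm((r - offset_k) / (n - 2 * offset_k + 1))
  }))
  if (any(const)) {
    warning("inverse_normal: ", sum(const),
            " constant row(s) mapped to zeros")
    out[const, ] <- 0
  }
  dimnames(out) <- dimnames(m)
  new_transformed(out, "int", list(offset_k = offset_k))
}

#' Remove genes with outlying abundance values
#'
#' Flags genes for which any sample's `log2(TMM-CPM + 1)` lies more than
#' `z_cutoff` robust z-units (median/MAD across samples) from the gene's
#' median. Genes with MAD 0 are never flagged. The rule and cutoff are
#' recorded in the result's provenance; this is a documented interpretation,
#' not a published rule.
#'
#' @param cm `CountMatrix`.
#' @param nf `NormFactors` for `cm`.
#' @param z_cutoff robust z cutoff (default 5).
#' @return filtered `CountMatrix`; attribute `outlier_rule` records the
#'   parameters and the removed gene ids.
#' @export
remove_outlier_genes <- function(cm, nf, z_cutoff = 5) {
  l <- log2(tmm_cpm(cm, nf)$values + 1)
  med <- apply(l, 1, median)
  md <- apply(l, 1, mad)  # normal-consistent constant 1.4826
  dev <- abs(l - med)
  flag <- md > 0 & (apply(dev, 1, max) / pmax(md, .Machine$double.eps)) >
    z_cutoff
  out <- subset_cm(cm, keep_genes = which(!flag))
  attr(out, "outlier_rule") <- list(
    rule = "robust z on log2(TMM-CPM + 1), median/MAD across samples",
    z_cutoff = z_cutoff, removed = cm$genes$gene_id[flag])
  out
}
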