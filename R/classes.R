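#' Construct a genotype matrix
#'
#' Container for coded genotypes at biallelic SNPs: a variants x samples
#' integer matrix counting copies of the alternate allele (0/1/2, `NA` =
#' missing), with per-variant metadata.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`, `depth` (site-level read depth supporting the call).
#' @param samples character vector of sample ids.
#' @param codes integer matrix, `nrow(sites)` x `length(samples)`, values in
#'   `{0, 1, 2, NA}`.
#' @return object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(sites, samples, codes) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "id", "ref", "alt", "depth")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols)) {
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) != nrow(sites) || ncol(codes) != length(samples)) {
    stop("codes must be nrow(sites) x length(samples)")
  }
  bad <- codes[!is.na(codes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  rownames(codes) <- variant_ids(sites)
  colnames(codes) <- samples
  structure(list(sites = sites, samples = as.character(samples),
                 codes = codes),
            class = "GenotypeMatrix")
}

#' Stable variant identifiers
#'
#' Uses the VCF ID field where present, otherwise `chrom:pos`.
#'
#' @param x a `GenotypeMatrix` or its `sites` data.frame.
#' @return character vector of identifiers.
#' @export
variant_ids <- function(x) {
  sites <- if (inherits(x, "GenotypeMatrix")) x$sites else x
  ids <- as.character(sites$id)
  fallback <- paste0(sites$chrom, ":", sites$pos)
  ifelse(is.na(ids) | ids == "." | ids == "", fallback, ids)
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", nrow(x$codes), "variants x",
      length(x$samples), "samples\n")
  n_missing <- sum(is.na(x$codes))
  cat("  missing genotype cells:", n_missing, "\n")
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$codes)

subset_gm <- function(gm, keep) {
  genotype_matrix(gm$sites[keep, , drop = FALSE], gm$samples,
                  gm$codes[keep, , drop = FALSE])
}

subset_gm_samples <- function(gm, keep) {
  genotype_matrix(gm$sites, gm$samples[keep],
                  gm$codes[, keep, drop = FALSE])
}

#' Construct a count matrix
#'
#' Genes x samples raw counts with the gene annotation needed for TPM and
#' biotype filtering.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `exonic_length` (nt, > 0), `biotype`.
#' @param samples character vector of sample ids.
#' @param counts non-negative integer matrix, genes x samples.
#' @return object of class `CountMatrix`.
#' @export
count_matrix <- function(genes, samples, counts) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  needed <- c("gene_id", "chrom", "start", "end", "exonic_length", "biotype")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols)) {
    stop("genes is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(genes) || ncol(counts) != length(samples)) {
    stop("counts must be nrow(genes) x length(samples)")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"  # keeps headroom for large libraries
  rownames(counts) <- genes$gene_id
  colnames(counts) <- samples
  structure(list(genes = genes, samples = as.character(samples),
                 counts = counts),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", length(x$samples),
      "samples\n")
  cat("  library sizes:", paste(range(colSums(x$counts)), collapse = " - "),
      "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

subset_cm <- function(cm, keep_genes = NULL, keep_samples = NULL) {
  genes <- cm$genes
  counts <- cm$counts
  samples <- cm$samples
  if (!is.null(keep_genes)) {
    genes <- genes[keep_genes, , drop = FALSE]
    counts <- counts[keep_genes, , drop = FALSE]
  }
  if (!is.null(keep_samples)) {
    samples <- samples[keep_samples]
    counts <- counts[, keep_samples, drop = FALSE]
  }
  count_matrix(genes, samples, counts)
}

new_transformed <- function(values, transform, provenance = list()) {
  structure(list(values = values, transform = transform,
                 provenance = provenance),
            class = "TransformedExpression")
}

#' @export
print.TransformedExpression <- function(x, ...) {
  cat("TransformedExpression (", x$transform, "): ",
      nrow(x$values), " genes x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

# Accept either a TransformedExpression or a bare matrix.
as_values <- function(x) {
  if (inherits(x, "TransformedExpression")) x$values else as.matrix(x)
}
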