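#' Read genotypes from a VCF
#'
#' Parses a multi-sample VCF 4.x (plain or bgzipped) into a
#' [genotype_matrix()]. Only biallelic single-nucleotide records are kept:
#' multi-allelic records and indels are excluded and counted. Genotypes are
#' coded as the number of alternate alleles; `./.` and half-calls become
#' missing. Site depth is taken from INFO/DP, falling back to the sum of
#' per-sample FORMAT/DP when INFO/DP is absent.
#'
#' @param path VCF file path.
#' @return `GenotypeMatrix`; attribute `exclusions` holds counts of excluded
#'   multi-allelic and non-SNP records.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF parse error in ", path, ": ",
                                         conditionMessage(e)))
  gt_cols <- colnames(v@gt)
  samples <- setdiff(gt_cols, "FORMAT")
  if (length(samples) == 0) stop("VCF has no sample columns: ", path)

  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ref <- fix$REF
  alt <- fix$ALT
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  nuc <- c("A", "C", "G", "T")
  snp <- !multi & !is.na(alt) & ref %in% nuc & alt %in% nuc
  n_multi <- sum(multi)
  n_nonsnp <- sum(!snp & !multi)
  keep <- which(snp)
  if (n_multi + n_nonsnp > 0) {
    message("read_vcf: excluded ", n_multi, " multi-allelic and ",
            n_nonsnp, " non-SNP record(s)")
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  gt[] <- gsub("|", "/", gt, fixed = TRUE)
  code_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  codes <- matrix(code_map[gt], nrow = nrow(gt), ncol = ncol(gt))
  colnames(codes) <- colnames(gt)
  codes <- codes[, samples, drop = FALSE]

  depth <- suppressWarnings(vcfR::extract.info(v, element = "DP",
                                               as.numeric = TRUE))
  if (is.null(depth) || all(is.na(depth))) {
    dp_fmt <- tryCatch(
      suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                        as.numeric = TRUE)),
      error = function(e) NULL)
    depth <- if (is.null(dp_fmt)) rep(NA_real_, nrow(fix)) else
      rowSums(dp_fmt, na.rm = TRUE)
  }

  sites <- data.frame(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    id = fix$ID[keep],
    ref = ref[keep],
    alt = alt[keep],
    depth = as.numeric(depth[keep]),
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(sites, samples, codes)
  attr(gm, "exclusions") <- c(multiallelic = n_multi, non_snp = n_nonsnp)
  gm
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits VCF 4.2 with INFO/DP and a GT-only FORMAT, suitable for passing the
#' filtered variant set to downstream tools.
#'
#' @param gm `GenotypeMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=dgeqtl",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  ), con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(gm$sites))) {
    s <- gm$sites[i, ]
    g <- gm$codes[i, ]
    gts <- ifelse(is.na(g), "./.", gt_map[g + 1L])
    id <- if (is.na(s$id) || s$id == "") "." else s$id
    dp <- if (is.na(s$depth)) "." else paste0("DP=", round(s$depth))
    writeLines(paste(c(s$chrom, s$pos, id, s$ref, s$alt, ".", "PASS",
                       dp, "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}
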