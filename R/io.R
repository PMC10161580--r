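# TSV / GFF3 plumbing and provenance headers. Every file the tool writes
# starts with '#'-prefixed provenance lines (version, config hash,
# thresholds) so a run can be reproduced from its outputs.

provenance_header <- function(config = list()) {
  cfg <- config[!vapply(config, is.null, logical(1))]
  if (length(cfg)) cfg <- cfg[order(names(cfg))]
  hash <- config_hash(cfg)
  c(paste0("# dgeqtl ", as.character(packageVersion("dgeqtl"))),
    paste0("# config_hash=", hash),
    if (length(cfg)) paste0("# ", names(cfg), "=",
                            vapply(cfg, function(x)
                              paste(format(x), collapse = ","), "")))
}

config_hash <- function(config) {
  if (length(config)) config <- config[order(names(config))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a result table as TSV with a provenance header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param config named list echoed into the header (thresholds, seeds, ...).
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_result_tsv()]
#'
#' @param path file path.
#' @return data.frame (provenance lines skipped).
#' @export
read_result_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a counts TSV plus gene annotation into a `CountMatrix`
#'
#' The counts file has genes as rows, first column the gene id, header =
#' sample ids. Gene metadata comes from a TSV sidecar (columns `gene_id`,
#' `chrom`, `start`, `end`, `exonic_length`, `biotype`) or from a GFF3 file
#' (gene features; exonic length = union-exon length per gene).
#'
#' @param counts_path counts TSV.
#' @param genes_path gene metadata TSV or GFF3 (suffix .gff/.gff3).
#' @return `CountMatrix` restricted to genes present in both files.
#' @export
read_counts_tsv <- function(counts_path, genes_path) {
  raw <- read.delim(counts_path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- ids
  genes <- if (grepl("\\.gff3?$", genes_path, ignore.case = TRUE)) {
    gene_table_from_gff3(genes_path)
  } else {
    read.delim(genes_path, comment.char = "#", stringsAsFactors = FALSE)
  }
  common <- intersect(ids, genes$gene_id)
  if (!length(common)) stop("no gene ids shared by counts and annotation")
  genes <- genes[match(common, genes$gene_id), , drop = FALSE]
  count_matrix(genes, colnames(counts), counts[common, , drop = FALSE])
}

#' Write a `CountMatrix` as counts TSV plus gene metadata TSV
#'
#' @param cm `CountMatrix`.
#' @param counts_path,genes_path output paths.
#' @param config provenance entries for the header.
#' @return invisible vector of the two paths.
#' @export
write_counts_tsv <- function(cm, counts_path, genes_path, config = list()) {
  df <- data.frame(gene_id = cm$genes$gene_id, cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_result_tsv(df, counts_path, config)
  write_result_tsv(cm$genes, genes_path, config)
  invisible(c(counts_path, genes_path))
}

#' Gene table from a GFF3 file
#'
#' Extracts gene features (id, chromosome, span, biotype) and computes each
#' gene's exonic length as the width of its reduced (union) exons.
#'
#' @param path GFF3 file.
#' @return data.frame usable as [count_matrix()] gene metadata.
#' @export
gene_table_from_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  gid <- genes$ID
  if (is.null(gid)) gid <- genes$gene_id
  biotype <- genes$biotype
  if (is.null(biotype)) biotype <- genes$gene_biotype
  if (is.null(biotype)) biotype <- rep(NA_character_, length(genes))
  exons <- gr[gr$type == "exon"]
  exlen <- rep(NA_real_, length(genes))
  if (length(exons)) {
    parent <- as.character(exons$Parent)
    # parent may point at transcripts; strip the transcript suffix
    by_gene <- GenomicRanges::reduce(
      S4Vectors::split(exons,
        factor(.exon_gene_id(parent, gid), levels = gid)))
    exlen <- vapply(gid, function(g) {
      w <- sum(IRanges::width(by_gene[[g]]))
      if (w > 0) w else NA_real_
    }, numeric(1))
  }
  gdf <- as.data.frame(genes)
  no_exon <- is.na(exlen)
  exlen[no_exon] <- gdf$width[no_exon]
  data.frame(
    gene_id = gid,
    chrom = as.character(gdf$seqnames),
    start = gdf$start,
    end = gdf$end,
    exonic_length = exlen,
    biotype = biotype,
    stringsAsFactors = FALSE)
}

# Map exon Parent attributes (gene or transcript ids like <gene>.t1) onto
# gene ids.
.exon_gene_id <- function(parent, gene_ids) {
  hit <- parent %in% gene_ids
  out <- parent
  out[!hit] <- sub("\\.[^.]*$", "", parent[!hit])
  out
}
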