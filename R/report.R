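# Proximity annotation, cis/trans labeling and the two-framework
# comparison report.

.gene_table <- function(genes) {
  if (is.data.frame(genes)) return(genes)
  if (is.character(genes)) return(gene_table_from_gff3(genes))
  if (inherits(genes, "CountMatrix")) return(genes$genes)
  stop("genes must be a data.frame, a CountMatrix or a GFF3 path")
}

#' Annotate result variants with nearby genes
#'
#' A variant is annotated to a gene when its position lies within the gene
#' model or within `flank` nucleotides on each side (same chromosome,
#' 1-based inclusive coordinates on both sides). All qualifying genes are
#' listed, nearest first.
#'
#' @param results scan results with `variant_chrom` and `variant_pos`
#'   columns.
#' @param genes gene models: data.frame (`gene_id`, `chrom`, `start`,
#'   `end`), `CountMatrix`, or GFF3 path.
#' @param flank flank width in nt (default 1000).
#' @return `results` with `annotated_genes` (comma-joined, nearest first),
#'   `nearest_gene` and `nearest_distance` columns. Warns when variant
#'   chromosomes never occur in the annotation.
#' @export
annotate_proximity <- function(results, genes, flank = 1000L) {
  gt <- .gene_table(genes)
  unmatched <- setdiff(unique(results$variant_chrom), unique(gt$chrom))
  if (length(unmatched)) {
    warning("annotate_proximity: ",
            sum(results$variant_chrom %in% unmatched),
            " result row(s) on chromosome(s) absent from the annotation: ",
            paste(unmatched, collapse = ", "))
  }
  snp_gr <- GenomicRanges::GRanges(results$variant_chrom,
                                   IRanges::IRanges(results$variant_pos,
                                                    results$variant_pos))
  gene_gr <- GenomicRanges::GRanges(gt$chrom,
                                    IRanges::IRanges(gt$start - flank,
                                                     gt$end + flank))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  dist <- pmax(0L, pmax(gt$start[sh] - results$variant_pos[qh],
                        results$variant_pos[qh] - gt$end[sh]))
  results$annotated_genes <- NA_character_
  results$nearest_gene <- NA_character_
  results$nearest_distance <- NA_integer_
  for (i in unique(qh)) {
    sel <- qh == i
    ord <- order(dist[sel], gt$gene_id[sh[sel]])
    ids <- gt$gene_id[sh[sel]][ord]
    results$annotated_genes[i] <- paste(ids, collapse = ",")
    results$nearest_gene[i] <- ids[1]
    results$nearest_distance[i] <- sort(dist[sel])[1]
  }
  results
}

#' Label results as cis or trans
#'
#' A pair is cis when the variant lies within `window` nt of the tested
#' gene's span on the same chromosome (inclusive boundaries), else trans.
#'
#' @param results scan results with `gene_id`, `variant_chrom`,
#'   `variant_pos`.
#' @param gene_positions gene coordinates (data.frame/`CountMatrix`/GFF3).
#' @param window cis window in nt (default 1e6).
#' @return `results` with a `cis_trans` column (`NA` with a warning for
#'   genes whose coordinates are unknown).
#' @export
cis_trans_label <- function(results, gene_positions, window = 1e6) {
  gt <- .gene_table(gene_positions)
  idx <- match(results$gene_id, gt$gene_id)
  if (anyNA(idx)) {
    warning("cis_trans_label: unknown coordinates for ",
            length(unique(results$gene_id[is.na(idx)])), " gene(s)")
  }
  same <- results$variant_chrom == gt$chrom[idx]
  within <- results$variant_pos >= gt$start[idx] - window &
    results$variant_pos <= gt$end[idx] + window
  results$cis_trans <- ifelse(is.na(idx), NA_character_,
                              ifelse(same & within, "cis", "trans"))
  results
}

#' Compare the two frameworks' significant eQTL sets
#'
#' Checks that both scans tested the same gene x variant universe, then
#' reports the significant set per framework/model, their intersection, the
#' Jaccard index, and a p-versus-p table for matched models.
#'
#' @param results_linear INT-linear scan results (one or both models).
#' @param results_nb NB-GLM scan results (tier-1/additive).
#' @param threshold nominal significance threshold (default 5e-8).
#' @return list of class `framework_comparison`: `sets` (significant pair
#'   keys per framework), `intersection`, `jaccard`, `p_table` (pair,
#'   model, p in each framework).
#' @export
compare_frameworks <- function(results_linear, results_nb,
                               threshold = 5e-8) {
  key <- function(df) paste(df$gene_id, df$variant_id, df$model, sep = "\r")
  pk_lin <- key(results_linear)
  pk_nb <- key(results_nb)
  only_lin <- setdiff(pk_lin, pk_nb)
  only_nb <- setdiff(pk_nb, pk_lin)
  if (length(only_lin) || length(only_nb)) {
    stop("compare_frameworks: test universes differ; e.g. ",
         paste(gsub("\r", "/", head(c(only_lin, only_nb), 5)),
               collapse = "; "))
  }
  sig_pairs <- function(df) {
    unique(paste(df$gene_id, df$variant_id, sep = ":")[df$p < threshold])
  }
  s_lin <- sig_pairs(results_linear)
  s_nb <- sig_pairs(results_nb)
  inter <- intersect(s_lin, s_nb)
  uni <- union(s_lin, s_nb)
  p_table <- merge(
    results_linear[, c("gene_id", "variant_id", "model", "p")],
    results_nb[, c("gene_id", "variant_id", "model", "p")],
    by = c("gene_id", "variant_id", "model"),
    suffixes = c("_linear", "_nb"))
  structure(list(
    n_significant = c(linear_int = length(s_lin), nb_glm = length(s_nb)),
    sets = list(linear_int = s_lin, nb_glm = s_nb),
    intersection = inter,
    jaccard = if (length(uni)) length(inter) / length(uni) else NA_real_,
    p_table = p_table,
    threshold = threshold
  ), class = "framework_comparison")
}

#' @export
print.framework_comparison <- function(x, ...) {
  cat("Framework comparison at p <", format(x$threshold), "\n")
  cat("  significant pairs: linear_int =", x$n_significant["linear_int"],
      ", nb_glm =", x$n_significant["nb_glm"], "\n")
  cat("  intersection =", length(x$intersection),
      "; Jaccard =", signif(x$jaccard, 4), "\n")
  invisible(x)
}
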