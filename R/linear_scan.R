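# Approach 1: fast OLS scans on inverse-normal-transformed expression.
# All genes are tested against one variant with a single set of matrix
# operations (the design is shared across genes), which is what makes the
# exhaustive gene x SNP scan cheap.

.align_expr_gm <- function(values, gm) {
  es <- colnames(values)
  if (!is.null(es) && !identical(es, gm$samples)) {
    if (!setequal(es, gm$samples)) {
      stop("expression and genotype samples do not match")
    }
    gm <- subset_gm_samples(gm, match(es, gm$samples))
  } else if (is.null(es) && ncol(values) != length(gm$samples)) {
    stop("expression and genotype sample counts differ")
  }
  gm
}

.covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  C <- if (is.data.frame(covariates)) {
    model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  } else as.matrix(covariates)
  if (nrow(C) != n) stop("covariates rows must match samples")
  C
}

.p_floor <- function(p) {
  floored <- p < .Machine$double.xmin
  p[floored] <- .Machine$double.xmin
  list(p = p, floored = floored)
}

.finish_scan <- function(res, skips, threshold) {
  res <- res[order(res$p, res$gene_id, res$variant_id), , drop = FALSE]
  rownames(res) <- NULL
  res$q <- bh_fdr(res$p)
  res <- apply_threshold(res, threshold)
  attr(res, "skips") <- skips
  res
}

#' Additive linear eQTL scan on transformed expression
#'
#' For every gene x variant pair, ordinary least squares of (typically
#' inverse-normal-transformed) expression on the genotype coded 0/1/2, plus
#' optional covariates, with a two-sided t-test on the genotype slope.
#' Samples with a missing genotype are dropped per variant; a variant with
#' fewer than three distinct genotype values after dropping is skipped with
#' a reason code.
#'
#' @param expr `TransformedExpression` (or matrix), genes x samples.
#' @param gm `GenotypeMatrix` on the same samples.
#' @param covariates optional data.frame/matrix of sample covariates
#'   (default none).
#' @param threshold nominal significance threshold (default 5e-8, strict
#'   `<`).
#' @return data.frame of per-pair results (slope, t, df, p, BH q within the
#'   scan, significance flag), sorted by p with deterministic tie order;
#'   attribute `skips` lists skipped variants with reasons.
#' @export
additive_scan_linear <- function(expr, gm, covariates = NULL,
                                 threshold = 5e-8) {
  Y <- as_values(expr)
  gm <- .align_expr_gm(Y, gm)
  C <- .covariate_matrix(covariates, ncol(Y))
  vids <- variant_ids(gm)
  genes <- rownames(Y)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(Y)))
  out <- vector("list", nrow(gm$codes))
  skips <- list()
  for (v in seq_len(nrow(gm$codes))) {
    g <- gm$codes[v, ]
    obs <- !is.na(g)
    if (length(unique(g[obs])) < 3) {
      skips[[length(skips) + 1L]] <-
        data.frame(variant_id = vids[v],
                   reason = "fewer_than_3_distinct_genotypes")
      next
    }
    X <- cbind(intercept = 1, genotype = g[obs])
    if (!is.null(C)) X <- cbind(X, C[obs, , drop = FALSE])
    Yv <- Y[, obs, drop = FALSE]
    XtXinv <- solve(crossprod(X))
    B <- XtXinv %*% crossprod(X, t(Yv))          # p x G
    resid <- t(Yv) - X %*% B
    rss <- colSums(resid^2)
    df2 <- nrow(X) - ncol(X)
    sigma2 <- rss / df2
    se <- sqrt(sigma2 * XtXinv[2, 2])
    tstat <- B[2, ] / se
    p <- 2 * pt(abs(tstat), df2, lower.tail = FALSE)
    p[se == 0] <- 0  # perfect fit; floored below
    pf_ <- .p_floor(p)
    out[[v]] <- data.frame(
      gene_id = genes, variant_id = vids[v],
      variant_chrom = gm$sites$chrom[v], variant_pos = gm$sites$pos[v],
      framework = "linear_int", model = "additive",
      effect = B[2, ], statistic = tstat, df1 = 1L, df2 = df2,
      p = pf_$p, p_floored = pf_$floored,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no testable variants in additive scan")
  .finish_scan(res, do.call(rbind, skips), threshold)
}

#' ANOVA linear eQTL scan on transformed expression
#'
#' Per pair, an F-test with 2 numerator df comparing expression modeled on
#' the genotype as a 3-level factor (plus covariates) against the
#' covariates-only model. Per-genotype group means are reported as effects.
#' Variants with an empty genotype class after missing-drop are skipped.
#'
#' @inheritParams additive_scan_linear
#' @return data.frame of per-pair results (group means, F, df, p, q,
#'   significance), sorted by p; attribute `skips` as in
#'   [additive_scan_linear()].
#' @export
anova_scan_linear <- function(expr, gm, covariates = NULL,
                              threshold = 5e-8) {
  Y <- as_values(expr)
  gm <- .align_expr_gm(Y, gm)
  C <- .covariate_matrix(covariates, ncol(Y))
  vids <- variant_ids(gm)
  genes <- rownames(Y)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(Y)))
  out <- vector("list", nrow(gm$codes))
  skips <- list()
  for (v in seq_len(nrow(gm$codes))) {
    g <- gm$codes[v, ]
    obs <- !is.na(g)
    if (!all(0:2 %in% g[obs])) {
      skips[[length(skips) + 1L]] <-
        data.frame(variant_id = vids[v], reason = "empty_genotype_class")
      next
    }
    gv <- g[obs]
    X1 <- cbind(intercept = 1, het = as.numeric(gv == 1),
                hom_alt = as.numeric(gv == 2))
    X0 <- cbind(intercept = rep(1, length(gv)))
    if (!is.null(C)) {
      X1 <- cbind(X1, C[obs, , drop = FALSE])
      X0 <- cbind(X0, C[obs, , drop = FALSE])
    }
    Yv <- t(Y[, obs, drop = FALSE])              # n x G
    rss1 <- .rss_ols(X1, Yv)
    rss0 <- .rss_ols(X0, Yv)
    df1 <- ncol(X1) - ncol(X0)
    df2 <- nrow(X1) - ncol(X1)
    Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
    p <- pf(Fstat, df1, df2, lower.tail = FALSE)
    p[rss1 == 0 & rss0 > 0] <- 0
    pf_ <- .p_floor(p)
    out[[v]] <- data.frame(
      gene_id = genes, variant_id = vids[v],
      variant_chrom = gm$sites$chrom[v], variant_pos = gm$sites$pos[v],
      framework = "linear_int", model = "anova",
      effect = NA_real_,
      mean_AA = colMeans(Yv[gv == 0, , drop = FALSE]),
      mean_AB = colMeans(Yv[gv == 1, , drop = FALSE]),
      mean_BB = colMeans(Yv[gv == 2, , drop = FALSE]),
      statistic = Fstat, df1 = df1, df2 = df2,
      p = pf_$p, p_floored = pf_$floored,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no testable variants in ANOVA scan")
  .finish_scan(res, do.call(rbind, skips), threshold)
}

.rss_ols <- function(X, Y) {
  B <- solve(crossprod(X), crossprod(X, Y))
  colSums((Y - X %*% B)^2)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up BH adjustment with monotonicity enforcement (delegates to
#' `stats::p.adjust`).
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return vector of adjusted values (empty in, empty out).
#' @export
bh_fdr <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Flag significant results at a nominal threshold
#'
#' @param results scan result data.frame with a `p` column.
#' @param threshold strict nominal threshold (default 5e-8).
#' @return `results` with a `significant` column (`p < threshold`, strict);
#'   attributes `threshold` and `neglog10_threshold` are set.
#' @export
apply_threshold <- function(results, threshold = 5e-8) {
  results$significant <- results$p < threshold
  attr(results, "threshold") <- threshold
  attr(results, "neglog10_threshold") <- -log10(threshold)
  results
}
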