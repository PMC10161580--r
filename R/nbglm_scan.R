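# Approach 2: eQTL scans with NB GLMs on raw counts, TMM offsets, a
# collection-site covariate, and quasi-likelihood F-tests. Dispersion is
# estimated once per gene under the covariates-only design and reused for
# every SNP model of that gene.

.site_design <- function(site, n) {
  if (is.null(site)) {
    matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  } else {
    f <- factor(as.character(site))  # lexicographic levels, first = reference
    if (length(f) != n) stop("site covariate length must match samples")
    model.matrix(~ f)
  }
}

.align_cm_gm <- function(cm, gm) {
  if (!identical(cm$samples, gm$samples)) {
    if (!setequal(cm$samples, gm$samples)) {
      stop("count and genotype samples do not match")
    }
    gm <- subset_gm_samples(gm, match(cm$samples, gm$samples))
  }
  gm
}

# Genotype recodings for the four NB models. Returns regressor columns or
# NULL with a skip reason.
.nb_regressor <- function(g, model) {
  switch(model,
    anova = {
      if (!all(0:2 %in% g)) return(list(reason = "empty_genotype_class"))
      list(X = cbind(geno_AB = as.numeric(g == 1),
                     geno_BB = as.numeric(g == 2)))
    },
    additive = {
      if (length(unique(g)) < 2) return(list(reason = "constant_genotype"))
      list(X = cbind(geno_add = as.numeric(g)))
    },
    contrast_ref_dom = {
      x <- as.numeric(g >= 1)  # AA vs {AB, BB}
      if (length(unique(x)) < 2) return(list(reason = "constant_contrast"))
      list(X = cbind(geno_refdom = x))
    },
    contrast_alt_dom = {
      x <- as.numeric(g == 2)  # {AA, AB} vs BB
      if (length(unique(x)) < 2) return(list(reason = "constant_contrast"))
      list(X = cbind(geno_altdom = x))
    },
    stop("unknown NB model: ", model)
  )
}

# Core scan: one NB model over gene x variant pairs. `pairs` optionally
# restricts testing to a set of (gene_id, variant_id) pairs (tier 2).
.nb_scan <- function(cm, gm, site, nf, model, dispersion, threshold,
                     pairs = NULL) {
  gm <- .align_cm_gm(cm, gm)
  Y <- cm$counts
  n <- ncol(Y)
  X0_full <- .site_design(site, n)
  offsets <- log(nf$effective_size)
  if (!identical(nf$samples, cm$samples)) {
    stop("NormFactors samples do not match CountMatrix samples")
  }
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(Y, X0_full, offsets)
  }
  dev_scale <- attr(dispersion, "dev_scale")
  dispersion <- rep_len(as.numeric(dispersion), nrow(Y))
  if (is.null(dev_scale)) {
    dev_scale <- nb_dev_scale(Y, X0_full, offsets, dispersion)
  }
  attr(dispersion, "dev_scale") <- dev_scale
  vids <- variant_ids(gm)
  genes <- cm$genes$gene_id
  reduced_cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(gm$codes))
  skips <- list()

  for (v in seq_len(nrow(gm$codes))) {
    gene_idx <- seq_along(genes)
    if (!is.null(pairs)) {
      gene_idx <- which(genes %in% pairs$gene_id[pairs$variant_id == vids[v]])
      if (!length(gene_idx)) next
    }
    g <- gm$codes[v, ]
    obs <- which(!is.na(g))
    reg <- .nb_regressor(g[obs], model)
    if (is.null(reg$X)) {
      skips[[length(skips) + 1L]] <-
        data.frame(variant_id = vids[v], reason = reg$reason)
      next
    }
    X0 <- X0_full[obs, , drop = FALSE]
    X1 <- cbind(X0, reg$X)
    if (qr(X1)$rank < ncol(X1)) {
      skips[[length(skips) + 1L]] <-
        data.frame(variant_id = vids[v], reason = "rank_deficient_design")
      next
    }
    Yv <- Y[gene_idx, obs, drop = FALSE]
    phi <- dispersion[gene_idx]
    off <- offsets[obs]

    key <- paste(obs, collapse = ",")
    red <- reduced_cache[[key]]
    if (is.null(red) || !is.null(pairs)) {
      redfit <- nb_fit_matrix(Y[gene_idx, obs, drop = FALSE], X0, off, phi)
      red <- list(dev = redfit$deviance, idx = gene_idx)
      if (is.null(pairs)) reduced_cache[[key]] <- red
    }
    full <- nb_fit_matrix(Yv, X1, off, phi)

    df1 <- ncol(X1) - ncol(X0)
    df2 <- length(obs) - ncol(X1)
    s2 <- full$deviance / (dev_scale[gene_idx] * df2)
    dd <- pmax(red$dev - full$deviance, 0)
    Fstat <- (dd / df1) / s2
    p <- pf(Fstat, df1, df2, lower.tail = FALSE)
    pf_ <- .p_floor(p)

    beta <- full$beta
    k0 <- ncol(X0)
    eff <- switch(model,
      anova = NA_real_,
      additive = beta[, k0 + 1],
      contrast_ref_dom = beta[, k0 + 1],
      contrast_alt_dom = beta[, k0 + 1])
    res <- data.frame(
      gene_id = genes[gene_idx], variant_id = vids[v],
      variant_chrom = gm$sites$chrom[v], variant_pos = gm$sites$pos[v],
      framework = "nb_glm", model = model,
      effect = eff,
      effect_log2 = eff / log(2),
      statistic = Fstat, df1 = df1, df2 = df2,
      p = pf_$p, p_floored = pf_$floored,
      dispersion = phi, quasi_dispersion = s2,
      converged = as.logical(full$converged),
      row.names = NULL, stringsAsFactors = FALSE)
    if (model == "anova") {
      res$effect_AB <- beta[, k0 + 1]
      res$effect_BB <- beta[, k0 + 2]
    }
    out[[v]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), variant_id = character(),
                      model = character(), p = numeric(),
                      stringsAsFactors = FALSE)
    res$q <- numeric()
    res$significant <- logical()
    attr(res, "skips") <- do.call(rbind, skips)
    attr(res, "dispersion") <- dispersion
    return(res)
  }
  res <- .finish_scan(res, do.call(rbind, skips), threshold)
  attr(res, "dispersion") <- dispersion
  res
}

#' NB ANOVA eQTL scan (tier 1)
#'
#' For every gene x variant pair, a 2-df quasi-likelihood F-test of the NB
#' GLM with genotype as a 3-level factor plus the site covariate, against
#' the site-only model, with offsets `log(effective_size)`. Dispersion is
#' estimated per gene under the covariates-only design unless supplied.
#'
#' @param cm `CountMatrix` (already outlier-filtered for this framework).
#' @param gm `GenotypeMatrix` (typically from [eqtl_snp_set()]).
#' @param site optional collection-site covariate (factor/character per
#'   sample; lexicographic level order, first level is the reference).
#' @param nf `NormFactors` for `cm`.
#' @param dispersion optional per-gene dispersion vector (recycled); when
#'   `NULL`, estimated once per gene with [estimate_dispersion()].
#' @param threshold nominal significance threshold (default 5e-8).
#' @return result data.frame (framework `nb_glm`, model `anova`) with
#'   per-genotype log-fold-change effects, F, df, p, q, significance,
#'   dispersion columns; attributes `skips` and `dispersion`.
#' @export
nb_anova_tier1 <- function(cm, gm, site = NULL, nf, dispersion = NULL,
                           threshold = 5e-8) {
  .nb_scan(cm, gm, site, nf, "anova", dispersion, threshold)
}

#' Pseudo-coded dominance contrasts (tier 2)
#'
#' For pairs significant in the tier-1 ANOVA scan, two 1-df QL F-tests with
#' the genotype pseudo-coded as binary contrasts: `contrast_ref_dom`
#' compares AA versus \{AB, BB\} (recode 0,1,1) and `contrast_alt_dom`
#' compares \{AA, AB\} versus BB (recode 0,0,1), each with the site
#' covariate and offsets.
#'
#' @param tier1_hits result of [nb_anova_tier1()]; only rows with
#'   `significant == TRUE` are tested unless `all_pairs = TRUE`.
#' @inheritParams nb_anova_tier1
#' @param all_pairs test every pair regardless of tier-1 significance
#'   (used by calibration studies).
#' @return combined result data.frame for both contrasts; attribute
#'   `tested_pairs` records the gated pair set.
#' @export
nb_contrast_tier2 <- function(tier1_hits, cm, gm, site = NULL, nf,
                              dispersion = NULL, threshold = 5e-8,
                              all_pairs = FALSE) {
  pairs <- if (all_pairs) NULL else
    tier1_hits[tier1_hits$significant, c("gene_id", "variant_id"),
               drop = FALSE]
  if (!all_pairs && nrow(pairs) == 0) {
    out <- data.frame()
    attr(out, "tested_pairs") <- pairs
    return(out)
  }
  if (is.null(dispersion)) dispersion <- attr(tier1_hits, "dispersion")
  r1 <- .nb_scan(cm, gm, site, nf, "contrast_ref_dom", dispersion,
                 threshold, pairs)
  r2 <- .nb_scan(cm, gm, site, nf, "contrast_alt_dom", dispersion,
                 threshold, pairs)
  out <- rbind(r1, r2)
  attr(out, "skips") <- rbind(attr(r1, "skips"), attr(r2, "skips"))
  attr(out, "tested_pairs") <- pairs
  attr(out, "threshold") <- threshold
  out
}

#' NB additive eQTL scan
#'
#' 1-df QL F-test of the genotype coded 0/1/2 as a numeric regressor, with
#' site covariate and offsets; the effect is the per-allele natural-log
#' fold change (also reported in log2).
#'
#' @inheritParams nb_anova_tier1
#' @return result data.frame (model `additive`).
#' @export
nb_additive <- function(cm, gm, site = NULL, nf, dispersion = NULL,
                        threshold = 5e-8) {
  .nb_scan(cm, gm, site, nf, "additive", dispersion, threshold)
}

#' Classify significant eQTLs as additive or dominance
#'
#' Applies the reporting rules of the two-tier procedure. A pair significant
#' in the tier-1 ANOVA scan yields one call: mode `dominance` when exactly
#' one tier-2 contrast is significant (dominant allele = alt when the
#' AA-versus-rest contrast fires, ref when the BB-versus-rest contrast
#' fires); mode `additive` when both contrasts and the additive scan are
#' significant (an additive pattern lights up both contrasts); otherwise
#' `unresolved`. Pairs significant only in the additive scan are mode
#' `additive`. A pair significant in both scans is reported once, from the
#' ANOVA tier.
#'
#' @param anova_tier_results tier-1 and tier-2 rows combined (rbind of
#'   [nb_anova_tier1()] and [nb_contrast_tier2()] outputs).
#' @param additive_results output of [nb_additive()] (or the linear additive
#'   scan, for that framework).
#' @param threshold nominal significance threshold (default 5e-8).
#' @return data.frame of `AllelicModeCall`s: `gene_id`, `variant_id`,
#'   `mode` in \{additive, dominance, unresolved\}, `dominant_allele`
#'   (ref/alt/NA), `source_tests`; no (gene, variant) pair appears twice.
#' @export
classify_modes <- function(anova_tier_results, additive_results,
                           threshold = 5e-8) {
  sig <- function(df, model) {
    if (is.null(df) || nrow(df) == 0) return(character(0))
    rows <- df$model == model & df$p < threshold
    paste(df$gene_id[rows], df$variant_id[rows], sep = "\r")
  }
  t1 <- sig(anova_tier_results, "anova")
  cr <- sig(anova_tier_results, "contrast_ref_dom")
  ca <- sig(anova_tier_results, "contrast_alt_dom")
  add <- sig(additive_results, "additive")

  calls <- list()
  for (pair in t1) {
    in_cr <- pair %in% cr
    in_ca <- pair %in% ca
    if (xor(in_cr, in_ca)) {
      calls[[pair]] <- list(mode = "dominance",
                            dominant_allele = if (in_cr) "alt" else "ref",
                            source = paste0("anova+",
                              if (in_cr) "contrast_ref_dom" else
                                "contrast_alt_dom"))
    } else if (in_cr && in_ca && pair %in% add) {
      calls[[pair]] <- list(mode = "additive", dominant_allele = NA_character_,
                            source = "anova+both_contrasts+additive")
    } else {
      calls[[pair]] <- list(mode = "unresolved",
                            dominant_allele = NA_character_,
                            source = if (in_cr || in_ca)
                              "anova+both_contrasts" else "anova_only")
    }
  }
  for (pair in setdiff(add, t1)) {
    calls[[pair]] <- list(mode = "additive", dominant_allele = NA_character_,
                          source = "additive_only")
  }
  if (!length(calls)) {
    return(data.frame(gene_id = character(), variant_id = character(),
                      mode = character(), dominant_allele = character(),
                      source_tests = character(), stringsAsFactors = FALSE))
  }
  keys <- names(calls)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    gene_id = vapply(parts, `[`, "", 1),
    variant_id = vapply(parts, `[`, "", 2),
    mode = vapply(calls, `[[`, "", "mode"),
    dominant_allele = vapply(calls, `[[`, "", "dominant_allele"),
    source_tests = vapply(calls, `[[`, "", "source"),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$gene_id, out$variant_id), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
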