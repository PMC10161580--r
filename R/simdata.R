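# Synthetic genotype/count generator with known allelic effects. The
# defaults describe the desk-scale study emulated throughout the package:
# 41 samples, 200 genes x 50 SNPs, MAF 0.3, NB dispersion 0.2.

#' Define a simulation scenario
#'
#' @param n_samples number of samples (default 41).
#' @param maf minor (alternate) allele frequency in (0, 0.5\] (default 0.3).
#' @param n_genes,n_snps matrix dimensions (defaults 200 and 50).
#' @param baseline_mu mean count at the reference genotype before library
#'   and site effects (default 100).
#' @param dispersion NB dispersion phi, var = mu + phi mu^2 (default 0.2;
#'   0 gives Poisson counts).
#' @param libsize_range multiplicative library-size factor range; factors
#'   are drawn log-uniformly within it (default c(0.5, 2)).
#' @param site_levels number of collection sites (default 2).
#' @param site_effect natural-log expression shift per site level beyond
#'   the first (default 0.25).
#' @param effects data.frame with columns `gene` (index), `snp` (index),
#'   `mode` in \{additive, dominance_alt, dominance_ref\}, `beta`
#'   (natural-log effect); default none (pure null).
#' @param seed integer RNG seed.
#' @return list of class `SimulationScenario`.
#' @export
simulation_scenario <- function(n_samples = 41L, maf = 0.3, n_genes = 200L,
                                n_snps = 50L, baseline_mu = 100,
                                dispersion = 0.2,
                                libsize_range = c(0.5, 2),
                                site_levels = 2L, site_effect = 0.25,
                                effects = NULL, seed = 1L) {
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (baseline_mu <= 0) stop("baseline_mu must be > 0")
  if (is.null(effects)) {
    effects <- data.frame(gene = integer(), snp = integer(),
                          mode = character(), beta = numeric(),
                          stringsAsFactors = FALSE)
  }
  ok_modes <- c("additive", "dominance_alt", "dominance_ref")
  if (nrow(effects)) {
    if (!all(effects$mode %in% ok_modes)) {
      stop("effect mode must be one of: ", paste(ok_modes, collapse = ", "))
    }
    if (any(effects$gene < 1 | effects$gene > n_genes) ||
        any(effects$snp < 1 | effects$snp > n_snps)) {
      stop("effect gene/snp indices out of range")
    }
  }
  structure(list(n_samples = n_samples, maf = maf, n_genes = n_genes,
                 n_snps = n_snps, baseline_mu = baseline_mu,
                 dispersion = dispersion, libsize_range = libsize_range,
                 site_levels = site_levels, site_effect = site_effect,
                 effects = effects, seed = as.integer(seed)),
            class = "SimulationScenario")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate one genotype column under Hardy-Weinberg proportions
#'
#' Genotypes drawn with probabilities ((1-p)^2, 2p(1-p), p^2) for codes
#' 0/1/2, where p is the alternate-allele frequency.
#'
#' @param n number of samples.
#' @param maf alternate-allele frequency in (0, 0.5\].
#' @param seed optional seed (draws are taken from the current RNG stream
#'   when `NULL`).
#' @return integer vector of genotype codes.
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]")
  draw <- function() {
    probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    sample(0:2, n, replace = TRUE, prob = probs)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

.effect_term <- function(mode, beta, g) {
  switch(mode,
    additive = beta * g,
    dominance_alt = beta * (g >= 1),
    dominance_ref = beta * (g == 2),
    stop("unknown effect mode: ", mode))
}

#' Simulate a genotype matrix and NB count matrix with known eQTLs
#'
#' Counts are drawn as NB(mean = baseline_mu * L_j * exp(site_j + effect),
#' dispersion phi), with per-sample library factors L_j log-uniform in
#' `libsize_range`, a categorical site shift, and genotype effects on the
#' log-mean scale that are additive (`beta * g`), completely dominant for
#' the alternate allele (`beta * 1{g >= 1}`) or for the reference allele
#' (`beta * 1{g = 2}`). Reproducible under the scenario seed.
#'
#' @param scenario a [simulation_scenario()].
#' @return list with `counts` (`CountMatrix`), `genotypes`
#'   (`GenotypeMatrix`), `site` (factor), and `truth` (`TruthRecord`: the
#'   effects table, realized genotype class counts per SNP, realized
#'   library factors, and the scenario).
#' @export
simulate_counts <- function(scenario) {
  stopifnot(inherits(scenario, "SimulationScenario"))
  s <- scenario
  with_seed(s$seed, {
    G <- matrix(0L, s$n_snps, s$n_samples)
    for (v in seq_len(s$n_snps)) {
      G[v, ] <- simulate_genotypes(s$n_samples, s$maf)
    }
    L <- exp(runif(s$n_samples, log(s$libsize_range[1]),
                   log(s$libsize_range[2])))
    site <- factor(paste0("site", rep_len(seq_len(s$site_levels),
                                          s$n_samples)))
    site_shift <- s$site_effect * (as.integer(site) - 1L)

    log_mu <- matrix(log(s$baseline_mu), s$n_genes, s$n_samples)
    log_mu <- sweep(log_mu, 2, log(L) + site_shift, "+")
    if (nrow(s$effects)) {
      for (i in seq_len(nrow(s$effects))) {
        e <- s$effects[i, ]
        log_mu[e$gene, ] <- log_mu[e$gene, ] +
          .effect_term(e$mode, e$beta, G[e$snp, ])
      }
    }
    mu <- exp(log_mu)
    counts <- if (s$dispersion == 0) {
      matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
    } else {
      matrix(rnbinom(length(mu), size = 1 / s$dispersion, mu = mu),
             nrow(mu), ncol(mu))
    }

    samples <- sprintf("sample%02d", seq_len(s$n_samples))
    gene_meta <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(s$n_genes)),
      chrom = "1",
      start = seq_len(s$n_genes) * 50000L,
      end = seq_len(s$n_genes) * 50000L + 2000L,
      exonic_length = 1500L, biotype = "protein_coding",
      stringsAsFactors = FALSE)
    sites <- data.frame(
      chrom = "1", pos = seq_len(s$n_snps) * 100000L + 17L,
      id = sprintf("snp%03d", seq_len(s$n_snps)),
      ref = "A", alt = "G", depth = 100, stringsAsFactors = FALSE)

    cm <- count_matrix(gene_meta, samples, counts)
    gm <- genotype_matrix(sites, samples, G)
    gc <- genotype_counts(gm)
    truth <- structure(list(
      effects = transform(s$effects,
        gene_id = gene_meta$gene_id[s$effects$gene],
        variant_id = sites$id[s$effects$snp]),
      genotype_counts = gc,
      library_factors = L,
      scenario = unclass(s)[setdiff(names(s), "effects")]
    ), class = "TruthRecord")
    list(counts = cm, genotypes = gm, site = site, truth = truth)
  })
}

#' Type-I error and power study across scenarios
#'
#' Runs both frameworks (INT-linear additive/ANOVA; NB QL F-test ANOVA,
#' additive and both pseudo-coded contrasts, contrasts evaluated on all
#' pairs) on replicate simulations of each scenario and tabulates, per
#' (method, model, scenario, alpha) cell, the fraction of null-pair tests
#' below alpha (type-I error) and of effect-pair tests below alpha (power),
#' plus truth-scored confusion counts at the genome-wide threshold.
#'
#' @param scenarios named list of [simulation_scenario()]s; include a
#'   pure-null member for calibration.
#' @param alpha significance levels to tabulate (default 0.05).
#' @param n_reps replicates per scenario (default 3).
#' @param seed master seed; replicate seeds are derived from it.
#' @param threshold genome-wide threshold used for confusion counts.
#' @return list with `table` (per-cell rates) and `confusion` (TP/FP/TN/FN
#'   per method/model/scenario at `threshold`).
#' @export
run_calibration_study <- function(scenarios, alpha = 0.05, n_reps = 3L,
                                  seed = 1L, threshold = 5e-8) {
  if (is.null(names(scenarios))) {
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  }
  rows <- list()
  conf <- list()
  for (sc_name in names(scenarios)) {
    sc <- scenarios[[sc_name]]
    acc <- list()
    for (rep_i in seq_len(n_reps)) {
      sc_rep <- sc
      sc_rep$seed <- (seed * 1000L + rep_i * 131L +
                        match(sc_name, names(scenarios))) %% .Machine$integer.max
      sim <- simulate_counts(sc_rep)
      res <- .run_all_models(sim, threshold)
      truth_keys <- paste(sim$truth$effects$gene_id,
                          sim$truth$effects$variant_id, sep = "\r")
      for (nm in names(res)) {
        r <- res[[nm]]
        keys <- paste(r$gene_id, r$variant_id, sep = "\r")
        is_effect <- keys %in% truth_keys
        acc[[length(acc) + 1L]] <- data.frame(
          method = sub("_.*", "", nm), model = sub("^[^_]*_", "", nm),
          rep = rep_i, p = r$p, is_effect = is_effect,
          stringsAsFactors = FALSE)
      }
    }
    acc <- do.call(rbind, acc)
    for (a in alpha) {
      agg <- aggregate(cbind(lt = acc$p < a),
                       by = list(method = acc$method, model = acc$model,
                                 is_effect = acc$is_effect), FUN = mean)
      for (i in seq_len(nrow(agg))) {
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc_name, method = agg$method[i], model = agg$model[i],
          alpha = a,
          metric = if (agg$is_effect[i]) "power" else "type1_error",
          value = agg$lt[i], stringsAsFactors = FALSE)
      }
    }
    cagg <- aggregate(cbind(sig = acc$p < threshold),
                      by = list(method = acc$method, model = acc$model,
                                is_effect = acc$is_effect), FUN = sum)
    ntot <- aggregate(cbind(n = rep(1, nrow(acc))),
                      by = list(method = acc$method, model = acc$model,
                                is_effect = acc$is_effect), FUN = sum)
    cagg$n <- ntot$n
    for (mm in unique(paste(cagg$method, cagg$model))) {
      sel <- paste(cagg$method, cagg$model) == mm
      eff <- cagg[sel & cagg$is_effect, ]
      nul <- cagg[sel & !cagg$is_effect, ]
      conf[[length(conf) + 1L]] <- data.frame(
        scenario = sc_name,
        method = strsplit(mm, " ")[[1]][1],
        model = strsplit(mm, " ")[[1]][2],
        TP = if (nrow(eff)) eff$sig else 0L,
        FN = if (nrow(eff)) eff$n - eff$sig else 0L,
        FP = if (nrow(nul)) nul$sig else 0L,
        TN = if (nrow(nul)) nul$n - nul$sig else 0L,
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), confusion = do.call(rbind, conf))
}

# Run every scan of both frameworks on one simulated dataset.
.run_all_models <- function(sim, threshold) {
  nf <- tmm_factors(sim$counts)
  int_expr <- inverse_normal(tmm_cpm(sim$counts, nf))
  X0 <- .site_design(sim$site, ncol(sim$counts$counts))
  off <- log(nf$effective_size)
  phi <- estimate_dispersion(sim$counts$counts, X0, off)
  attr(phi, "dev_scale") <- nb_dev_scale(sim$counts$counts, X0, off,
                                         rep_len(as.numeric(phi),
                                                 nrow(sim$counts$counts)))
  t1 <- nb_anova_tier1(sim$counts, sim$genotypes, sim$site, nf,
                       dispersion = phi, threshold = threshold)
  t2 <- nb_contrast_tier2(t1, sim$counts, sim$genotypes, sim$site, nf,
                          dispersion = phi, threshold = threshold,
                          all_pairs = TRUE)
  list(
    linear_additive = additive_scan_linear(int_expr, sim$genotypes,
                                           threshold = threshold),
    linear_anova = anova_scan_linear(int_expr, sim$genotypes,
                                     threshold = threshold),
    nb_anova = t1,
    nb_additive = nb_additive(sim$counts, sim$genotypes, sim$site, nf,
                              dispersion = phi, threshold = threshold),
    nb_contrast_ref_dom = t2[t2$model == "contrast_ref_dom", ],
    nb_contrast_alt_dom = t2[t2$model == "contrast_alt_dom", ]
  )
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits a VCF, a counts TSV, a gene-annotation TSV, a sample covariate TSV
#' and a truth-record JSON, so the whole CLI pipeline can be exercised from
#' generated files alone.
#'
#' @param sim output of [simulate_counts()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    counts = file.path(dir, "counts.tsv"),
    genes = file.path(dir, "genes.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    truth = file.path(dir, "truth.json"))
  write_genotype_vcf(sim$genotypes, paths["vcf"])
  write_counts_tsv(sim$counts, paths["counts"], paths["genes"])
  write.table(data.frame(sample = sim$counts$samples,
                         site = as.character(sim$site)),
              paths["covariates"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(unclass(sim$truth), paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
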