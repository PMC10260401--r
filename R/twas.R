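#' Train an elastic-net transcriptome prediction model for one gene
#'
#' Nested cross-validation in the PredictDB style: outer folds hold out
#' samples for an honest estimate of prediction performance while the
#' penalty is chosen by inner cross-validation on the training part;
#' `rho_avg` is the mean across outer folds of the Pearson correlation
#' between predicted and observed expression, and `zscore_pval` the
#' one-sided p-value of the fold-correlation z statistic (mean over
#' standard error of the fold correlations). The final weights come from
#' an inner-CV fit on all samples. A model passes the standard filters
#' when `rho_avg > 0.1`, `zscore_pval < 0.05` and the gene's
#' heritability LRT p (if supplied) is below 0.05.
#'
#' @param dosage n x m cis dosage matrix (column names = variant ids);
#'   variants below `maf_min` are dropped.
#' @param y Corrected expression vector.
#' @param alpha_mixing Elastic-net mixing parameter (default 0.5).
#' @param n_folds Outer folds (default 10).
#' @param nested_folds Inner folds (default 5).
#' @param maf_min MAF filter (default 0.01).
#' @param h2_p Optional heritability LRT p for the filter.
#' @param gene_id Optional label.
#' @param local_anc_covariates Optional matrix of local ancestry counts
#'   residualized out of the expression before training (sensitivity
#'   mode).
#' @param seed Integer seed (controls fold assignment).
#' @return Object of class `twas_model`: `weights` (named, nonzero),
#'   `effect_allele`, `rho_avg`, `zscore_pval`, `h2_p`,
#'   `passed_filters`, `fold_rho`.
#' @export
train_twas_model <- function(dosage, y, alpha_mixing = 0.5, n_folds = 10,
                             nested_folds = 5, maf_min = 0.01, h2_p = NA,
                             gene_id = NA_character_,
                             local_anc_covariates = NULL, seed = 1) {
  dosage <- as.matrix(dosage)
  n <- length(y)
  if (n < n_folds) stop("fewer samples than folds")
  keep <- maf_from_dosage(dosage) >= maf_min & apply(dosage, 2, stats::sd) > 0
  G <- dosage[, keep, drop = FALSE]
  if (ncol(G) < 2) stop("need at least two informative cis variants")
  if (!is.null(local_anc_covariates)) {
    y <- stats::lm.fit(cbind(1, as.matrix(local_anc_covariates)), y)$residuals
  }

  with_seed(substream_seed(seed, paste0("twas_", gene_id)), {
    fold <- sample(rep_len(seq_len(n_folds), n))
    fold_rho <- rep(NA_real_, n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- !tr
      cvfit <- glmnet::cv.glmnet(G[tr, , drop = FALSE], y[tr],
                                 alpha = alpha_mixing, nfolds = nested_folds,
                                 standardize = TRUE)
      pred <- as.numeric(stats::predict(cvfit, G[te, , drop = FALSE],
                                        s = "lambda.min"))
      fold_rho[f] <- if (stats::sd(pred) > 0)
        stats::cor(pred, y[te]) else 0
    }
    rho_avg <- mean(fold_rho)
    se_rho <- stats::sd(fold_rho) / sqrt(n_folds)
    zstat <- if (se_rho > 0) rho_avg / se_rho else Inf * sign(rho_avg)
    zscore_pval <- stats::pnorm(zstat, lower.tail = FALSE)

    final <- glmnet::cv.glmnet(G, y, alpha = alpha_mixing,
                               nfolds = nested_folds, standardize = TRUE)
    w <- as.numeric(stats::coef(final, s = "lambda.min"))[-1]
    names(w) <- colnames(G)
    w <- w[w != 0]

    passed <- isTRUE(rho_avg > 0.1 && zscore_pval < 0.05 &&
                     (is.na(h2_p) || h2_p < 0.05))
    structure(list(gene_id = gene_id, weights = w,
                   effect_allele = stats::setNames(rep("B", length(w)), names(w)),
                   other_allele = stats::setNames(rep("A", length(w)), names(w)),
                   rho_avg = rho_avg, zscore_pval = zscore_pval, h2_p = h2_p,
                   passed_filters = passed, fold_rho = fold_rho,
                   alpha = alpha_mixing),
              class = "twas_model")
  })
}

#' Summary-statistic TWAS association for one gene model
#'
#' Computes the gene z-score from GWAS summary statistics and an LD
#' reference: `z_gene = sum_l w_l (sigma_l / sigma_g) z_l`, where
#' `sigma_l` is the dosage standard deviation of variant l in the
#' reference and `sigma_g^2 = w' Gamma w` the predicted-expression
#' variance from the reference dosage covariance. Summary-statistic
#' alleles are aligned to the model's effect alleles (z flipped on an
#' allele swap; other mismatches dropped).
#'
#' @param model A `twas_model`.
#' @param sumstats `gwas_sumstats` data.frame (`variant_id`,
#'   `effect_allele`, `other_allele`, `z`, ...).
#' @param ld_ref_dosage n x m reference dosage matrix with variant-id
#'   column names covering the model variants.
#' @return One-row data.frame: `gene_id`, `z`, `p`, `n_variants_used`,
#'   `reason` (NA on success).
#' @export
spredixcan <- function(model, sumstats, ld_ref_dosage) {
  stopifnot(inherits(model, "twas_model"))
  w_all <- model$weights
  m <- match(names(w_all), sumstats$variant_id)
  present <- !is.na(m)
  if (!any(present))
    return(data.frame(gene_id = model$gene_id, z = NA_real_, p = NA_real_,
                      n_variants_used = 0L,
                      reason = "no model variants in summary statistics",
                      stringsAsFactors = FALSE))
  ids <- names(w_all)[present]
  ss <- sumstats[m[present], ]
  zl <- ss$z
  # allele alignment
  ea <- model$effect_allele[ids]; oa <- model$other_allele[ids]
  same <- ss$effect_allele == ea & ss$other_allele == oa
  flip <- ss$effect_allele == oa & ss$other_allele == ea
  usable <- same | flip
  zl[flip] <- -zl[flip]
  ids <- ids[usable]; zl <- zl[usable]
  if (!length(ids))
    return(data.frame(gene_id = model$gene_id, z = NA_real_, p = NA_real_,
                      n_variants_used = 0L, reason = "allele mismatch",
                      stringsAsFactors = FALSE))
  w <- w_all[ids]
  R <- as.matrix(ld_ref_dosage[, ids, drop = FALSE])
  sigma_l <- apply(R, 2, stats::sd)
  Gamma <- stats::cov(R)
  sigma_g <- sqrt(drop(t(w) %*% Gamma %*% w))
  if (!is.finite(sigma_g) || sigma_g <= 0)
    stop("predicted-expression variance is zero in the LD reference")
  z_gene <- sum(w * sigma_l * zl) / sigma_g
  data.frame(gene_id = model$gene_id, z = z_gene,
             p = 2 * stats::pnorm(abs(z_gene), lower.tail = FALSE),
             n_variants_used = length(ids), reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Summary-statistic TWAS over a set of gene models
#'
#' @param models List of `twas_model` objects.
#' @param sumstats `gwas_sumstats` table.
#' @param ld_ref_dosage Reference dosage matrix.
#' @param filtered_only Use only models passing the standard filters.
#' @return data.frame of class `twas_association`: per gene `z`, `p`
#'   and BH `q` across genes.
#' @export
twas_associations <- function(models, sumstats, ld_ref_dosage,
                              filtered_only = FALSE) {
  if (filtered_only)
    models <- Filter(function(m) isTRUE(m$passed_filters), models)
  rows <- lapply(models, function(m)
    tryCatch(spredixcan(m, sumstats, ld_ref_dosage),
             error = function(e) data.frame(gene_id = m$gene_id, z = NA_real_,
                                            p = NA_real_, n_variants_used = 0L,
                                            reason = conditionMessage(e),
                                            stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  class(out) <- c("twas_association", "data.frame")
  out
}

#' Compare two sets of TWAS associations
#'
#' Reports, per set, the number of FDR-significant genes, their overlap,
#' the z-score correlation over the union of significant genes shared by
#' both sets, and genes unavailable in the other set.
#'
#' @param assoc_a,assoc_b `twas_association` tables for the same trait.
#' @param fdr FDR level (default 0.05).
#' @return List with `n_sig_a`, `n_sig_b`, `overlap`, `z_cor`,
#'   `only_in_a`, `only_in_b`, `unavailable_in_b`, `unavailable_in_a`.
#' @export
compare_model_sets <- function(assoc_a, assoc_b, fdr = 0.05) {
  sig_a <- assoc_a$gene_id[!is.na(assoc_a$q) & assoc_a$q < fdr]
  sig_b <- assoc_b$gene_id[!is.na(assoc_b$q) & assoc_b$q < fdr]
  union_sig <- union(sig_a, sig_b)
  both <- intersect(intersect(union_sig, assoc_a$gene_id[!is.na(assoc_a$z)]),
                    assoc_b$gene_id[!is.na(assoc_b$z)])
  z_cor <- if (length(both) >= 2)
    stats::cor(assoc_a$z[match(both, assoc_a$gene_id)],
               assoc_b$z[match(both, assoc_b$gene_id)]) else NA_real_
  list(n_sig_a = length(sig_a), n_sig_b = length(sig_b),
       overlap = length(intersect(sig_a, sig_b)),
       z_cor = z_cor,
       only_in_a = setdiff(sig_a, sig_b), only_in_b = setdiff(sig_b, sig_a),
       unavailable_in_b = setdiff(assoc_a$gene_id, assoc_b$gene_id),
       unavailable_in_a = setdiff(assoc_b$gene_id, assoc_a$gene_id))
}

#' Export TWAS models as a flat weight table
#'
#' @param models List of `twas_model` objects.
#' @return data.frame: gene, variant, effect_allele, other_allele,
#'   weight (one row per nonzero weight).
#' @export
twas_weight_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    if (!length(m$weights)) return(NULL)
    data.frame(gene_id = m$gene_id, variant_id = names(m$weights),
               effect_allele = unname(m$effect_allele[names(m$weights)]),
               other_allele = unname(m$other_allele[names(m$weights)]),
               weight = unname(m$weights), stringsAsFactors = FALSE)
  }))
}
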