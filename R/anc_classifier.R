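#' Classify one gene's lead eQTL signal into anc-eQTL tiers
#'
#' Implements the tiered decision tree comparing fine-mapped credible
#' sets between a high (>50%) and low (<10%) global-ancestry group:
#' \itemize{
#' \item nonoverlapping credible sets, lead high-group variant common
#'   (MAF >= 0.01) in the high group but rare (< 0.01) or monomorphic
#'   in the low group: \strong{tier1} (allele-frequency driven);
#' \item nonoverlapping sets, variant common in both groups: evaluated
#'   against the cross-population configuration posterior —
#'   \strong{tier2} when all high-group credible-set variants have
#'   `pp_high > pp_low` and `pp_high > pp_shared` and the maximum
#'   `pp_high` exceeds 0.8 (LD driven);
#' \item overlapping sets: \strong{tier3} when every credible-set
#'   variant with a heterogeneity test has Cochran's Q p below the
#'   Bonferroni threshold `0.05 / n_gene`; otherwise \strong{shared};
#' \item anything else: \strong{none}.
#' }
#' A gene with no detectable low-group signal (no credible set there) is
#' treated as nonoverlapping and flagged `low_group_silent`.
#'
#' @param cs_high High-group `credible_set`.
#' @param cs_low Low-group `credible_set`, or NULL if the low group has
#'   no signal.
#' @param maf_high,maf_low Named MAF vectors (by variant id) in each
#'   group; variants absent from a group may be missing or NA (treated
#'   as monomorphic).
#' @param config Optional data.frame from [config_posterior()] with
#'   rownames = variant ids (required only to assign tier2).
#' @param het Optional data.frame with columns `variant`, `p` from
#'   [cochran_q()] per credible-set variant (required only for tier3).
#' @param n_gene Number of genes entering the heterogeneity step (the
#'   Bonferroni divisor).
#' @param tier1_mode How the MAF rule is applied over the high-group
#'   credible set: `"any"` (default; the gene is tier1 if any member is
#'   a tier-1 anc-eQTL, i.e. common-high and rare-low, matching the
#'   per-eQTL definition "genes containing at least one tier-1
#'   anc-eQTL"), `"lead"` (only the highest-PP member is examined) or
#'   `"all"` (every member must satisfy the rule).
#' @return One-row data.frame of class `anc_eqtl_call`; `lead_variant`
#'   is the highest-PP variant satisfying the rule for tier1 calls and
#'   the overall highest-PP member otherwise.
#' @export
classify_gene <- function(cs_high, cs_low, maf_high, maf_low,
                          config = NULL, het = NULL, n_gene = 1,
                          tier1_mode = c("any", "lead", "all")) {
  tier1_mode <- match.arg(tier1_mode)
  if (is.null(cs_high)) stop("missing high-group credible set")
  members <- cs_high$members$variant
  lead <- members[1]
  maf_l <- function(v) {
    x <- maf_low[v]
    x[is.na(x)] <- 0  # absent/monomorphic in the low group
    unname(x)
  }
  maf_h <- function(v) unname(maf_high[v])

  silent <- is.null(cs_low)
  overlap <- !silent && credible_sets_overlap(cs_high, cs_low)

  call <- "none"
  max_pp_high <- NA_real_
  max_q_p <- NA_real_

  if (!overlap) {
    qual <- maf_h(members) >= 0.01 & maf_l(members) < 0.01
    qual[is.na(qual)] <- FALSE
    t1 <- switch(tier1_mode,
                 any = any(qual),
                 lead = qual[1],
                 all = all(qual))
    if (t1) {
      call <- "tier1"
      lead <- members[which(qual)[1]]  # members are PP-sorted
    } else if (!is.null(config)) {
      avail <- intersect(members, rownames(config))
      if (length(avail)) {
        cf <- config[avail, , drop = FALSE]
        dominant <- all(cf$pp_high > cf$pp_low & cf$pp_high > cf$pp_shared)
        max_pp_high <- max(cf$pp_high)
        if (dominant && max_pp_high > 0.8) call <- "tier2"
      }
    }
  } else {
    if (!is.null(het) && nrow(het)) {
      tested <- het[het$variant %in% members, , drop = FALSE]
      if (nrow(tested)) {
        max_q_p <- max(tested$p)
        if (all(tested$p < 0.05 / n_gene)) call <- "tier3" else call <- "shared"
      } else call <- "shared"
    } else call <- "shared"
  }

  out <- data.frame(call = call, lead_variant = lead,
                    maf_high_lead = maf_h(lead), maf_low_lead = maf_l(lead),
                    overlap = overlap, low_group_silent = silent,
                    max_pp_high = max_pp_high, max_q_p = max_q_p,
                    n_gene = n_gene, stringsAsFactors = FALSE)
  class(out) <- c("anc_eqtl_call", "data.frame")
  out
}

# prune variants so no pair has r2 > threshold in BOTH groups; keeps the
# variant with the smaller high-group p of each removed pair
.prune_both_groups <- function(ids, G_high, G_low, p_high, r2 = 0.95) {
  keep <- rep(TRUE, length(ids))
  ord <- order(p_high)
  for (i in seq_along(ord)) {
    a <- ord[i]
    if (!keep[a]) next
    for (j in seq_along(ord)) {
      b <- ord[j]
      if (b == a || !keep[b] || p_high[b] < p_high[a]) next
      r2h <- suppressWarnings(stats::cor(G_high[, a], G_high[, b]))^2
      r2l <- suppressWarnings(stats::cor(G_low[, a], G_low[, b]))^2
      if (!is.na(r2h) && !is.na(r2l) && r2h > r2 && r2l > r2) keep[b] <- FALSE
    }
  }
  keep
}

#' Run the full anc-eQTL classification over a simulated study
#'
#' End-to-end pipeline for a two-group contrast: corrects expression per
#' group, maps cis-eQTLs with permutation calibration in the high and
#' low global-ancestry groups, fine-maps the high-group signal of every
#' eligible gene (heritable eGene in the high group), compares 95%
#' credible sets, computes the cross-population configuration posterior
#' for nonoverlapping common signals and Cochran's Q for overlapping
#' ones, and emits one tier call per gene.
#'
#' @param cohort An `admixed_cohort`.
#' @param expression An `expression_dataset`.
#' @param samples_high,samples_low Sample indices of the two groups.
#' @param genes Gene indices to classify (default all).
#' @param fdr eGene FDR (default 0.05).
#' @param level Credible-set level (default 0.95).
#' @param prior_sd Fine-mapping prior effect sd (default 0.15).
#' @param maf_min MAF filter within each group (default 0.01).
#' @param max_permutations Permutations per gene (default 1000).
#' @param heritable_p Heritability LRT p cut-off for eligibility.
#' @param tier1_mode See [classify_gene()].
#' @param low_rule When the low group is considered to have a mappable
#'   lead signal whose credible set enters the overlap comparison:
#'   `"egene"` (default; the gene is an eGene in the low group at the
#'   study FDR) or `"pbeta"` (beta-approximated gene p < 0.05).
#' @param seed Integer seed.
#' @return List of class `anc_eqtl_result`: `calls` (per-gene
#'   data.frame with eligibility and evidence columns), `n_gene_tier3`,
#'   `catalog_high`, `catalog_low`, `h2_high`.
#' @export
classify_anc_eqtls <- function(cohort, expression, samples_high, samples_low,
                               genes = NULL, fdr = 0.05, level = 0.95,
                               prior_sd = 0.15, maf_min = 0.01,
                               max_permutations = 1000, heritable_p = 0.05,
                               tier1_mode = "any",
                               low_rule = c("egene", "pbeta"),
                               seed = 1) {
  low_rule <- match.arg(low_rule)
  panel <- cohort$panel
  genes <- genes %||% seq_len(nrow(panel$genes))
  covs <- cohort$covariates[, c("age", "sex", "asthma")]

  ce_high <- prepare_expression(expression$expr[, samples_high, drop = FALSE],
                                covs[samples_high, ])
  ce_low <- prepare_expression(expression$expr[, samples_low, drop = FALSE],
                               covs[samples_low, ])
  # widen back so map_cis_eqtls can index columns by global sample index
  wide <- function(ce, idx) {
    M <- matrix(NA_real_, nrow(ce), nrow(cohort$dosage))
    rownames(M) <- rownames(ce)
    M[, idx] <- ce
    M
  }
  cat_high <- map_cis_eqtls(cohort, wide(ce_high, samples_high), samples_high,
                            genes = genes, maf_min = maf_min,
                            max_permutations = max_permutations, fdr = fdr,
                            seed = substream_seed(seed, "map_high"),
                            masked_variants = expression$masked_variants)
  cat_low <- map_cis_eqtls(cohort, wide(ce_low, samples_low), samples_low,
                           genes = genes, maf_min = maf_min,
                           max_permutations = max_permutations, fdr = fdr,
                           seed = substream_seed(seed, "map_low"),
                           masked_variants = expression$masked_variants)
  h2_high <- estimate_cis_h2(cohort, expression, samples = samples_high,
                             genes = genes)

  n_high <- length(samples_high); n_low <- length(samples_low)
  gene_ids <- panel$genes$gene_id[genes]

  # first pass: eligibility, credible sets, branch
  stage <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]; gid <- gene_ids[i]
    cal_h <- cat_high$calibration[cat_high$calibration$gene_id == gid, ]
    herit <- h2_high$lrt_p[h2_high$gene_id == gid]
    eligible <- isTRUE(cal_h$egene) && !is.na(herit) && herit < heritable_p
    if (!eligible) {
      stage[[gid]] <- list(eligible = FALSE)
      next
    }
    sc_h <- cat_high$scans[[gid]]
    pp_h <- single_causal_posterior(sc_h$t, n_high, prior_sd)
    cs_h <- credible_set(pp_h, level = level, pos = sc_h$pos, ids = sc_h$variant)

    cal_l <- cat_low$calibration[cat_low$calibration$gene_id == gid, ]
    sc_l <- cat_low$scans[[gid]]
    has_low <- nrow(cal_l) == 1 && !is.na(cal_l$p_beta) && !is.null(sc_l) &&
      (if (low_rule == "egene") isTRUE(cal_l$egene) else cal_l$p_beta < 0.05)
    cs_l <- NULL
    if (has_low) {
      pp_l <- single_causal_posterior(sc_l$t, n_low, prior_sd)
      cs_l <- credible_set(pp_l, level = level, pos = sc_l$pos, ids = sc_l$variant)
    }
    vars_g <- which(panel$gene_of_variant == g)
    maf_h <- maf_from_dosage(cohort$dosage[samples_high, vars_g, drop = FALSE])
    maf_l <- maf_from_dosage(cohort$dosage[samples_low, vars_g, drop = FALSE])
    names(maf_h) <- names(maf_l) <- panel$variant_id[vars_g]
    stage[[gid]] <- list(eligible = TRUE, g = g, cs_high = cs_h, cs_low = cs_l,
                         sc_high = sc_h, sc_low = sc_l,
                         maf_high = maf_h, maf_low = maf_l,
                         overlap = !is.null(cs_l) && credible_sets_overlap(cs_h, cs_l))
  }
  n_gene_tier3 <- sum(vapply(stage, function(s)
    isTRUE(s$eligible) && isTRUE(s$overlap), TRUE))
  n_gene_tier3 <- max(n_gene_tier3, 1L)

  calls <- list()
  for (gid in names(stage)) {
    s <- stage[[gid]]
    if (!isTRUE(s$eligible)) {
      calls[[gid]] <- data.frame(gene_id = gid, eligible = FALSE, call = "none",
                                 lead_variant = NA, maf_high_lead = NA,
                                 maf_low_lead = NA, overlap = NA,
                                 low_group_silent = NA, max_pp_high = NA,
                                 max_q_p = NA, n_gene = n_gene_tier3,
                                 stringsAsFactors = FALSE)
      next
    }
    config <- NULL
    het <- NULL
    if (s$overlap) {
      shared <- intersect(s$sc_high$variant, s$sc_low$variant)
      if (length(shared)) {
        ih <- match(shared, s$sc_high$variant)
        il <- match(shared, s$sc_low$variant)
        het <- data.frame(variant = shared,
                          cochran_q(s$sc_high$beta[ih], s$sc_high$se[ih],
                                    s$sc_low$beta[il], s$sc_low$se[il]),
                          stringsAsFactors = FALSE)
      }
    } else {
      # variants common (MAF >= 0.01) in both groups, aligned across scans
      shared <- intersect(s$sc_high$variant, s$sc_low$variant)
      shared <- shared[s$maf_high[shared] >= 0.01 & s$maf_low[shared] >= 0.01]
      if (length(shared) > 1) {
        gidx <- match(shared, panel$variant_id)
        Gh <- cohort$dosage[samples_high, gidx, drop = FALSE]
        Gl <- cohort$dosage[samples_low, gidx, drop = FALSE]
        ph <- s$sc_high$p[match(shared, s$sc_high$variant)]
        keep <- .prune_both_groups(shared, Gh, Gl, ph)
        shared <- shared[keep]
      }
      if (length(shared)) {
        zh <- s$sc_high$t[match(shared, s$sc_high$variant)]
        zl <- s$sc_low$t[match(shared, s$sc_low$variant)]
        config <- config_posterior(zh, zl, n_high, n_low, prior_sd = prior_sd)
        rownames(config) <- shared
      }
    }
    cl <- classify_gene(s$cs_high, s$cs_low, s$maf_high, s$maf_low,
                        config = config, het = het, n_gene = n_gene_tier3,
                        tier1_mode = tier1_mode)
    calls[[gid]] <- cbind(data.frame(gene_id = gid, eligible = TRUE,
                                     stringsAsFactors = FALSE), cl)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  structure(list(calls = calls, n_gene_tier3 = n_gene_tier3,
                 catalog_high = cat_high, catalog_low = cat_low,
                 h2_high = h2_high),
            class = "anc_eqtl_result")
}

#' Prevalence of anc-eQTL tiers over a gene universe
#'
#' @param calls data.frame of per-gene calls (from
#'   [classify_anc_eqtls()] or assembled by hand; needs `call` and
#'   optionally `eligible`).
#' @param heritable_only If TRUE (default) the denominator is the
#'   eligible genes; otherwise all genes in `calls`.
#' @return data.frame with counts and fractions per tier and any-tier.
#' @export
prevalence <- function(calls, heritable_only = TRUE) {
  if (!nrow(calls)) stop("empty gene universe")
  universe <- if (heritable_only && "eligible" %in% names(calls))
    calls[calls$eligible %in% TRUE, , drop = FALSE] else calls
  denom <- nrow(universe)
  if (!denom) stop("empty gene universe after eligibility filtering")
  tiers <- c("tier1", "tier2", "tier3")
  counts <- vapply(tiers, function(t) sum(universe$call == t), 1L)
  any_tier <- sum(universe$call %in% tiers)
  data.frame(class = c(tiers, "any_tier", "shared", "none"),
             count = c(counts, any_tier,
                       sum(universe$call == "shared"),
                       sum(universe$call == "none")),
             fraction = c(counts, any_tier,
                          sum(universe$call == "shared"),
                          sum(universe$call == "none")) / denom,
             denominator = denom,
             stringsAsFactors = FALSE)
}
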