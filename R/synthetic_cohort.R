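#' Simulate an ancestral reference panel with divergent allele frequencies
#'
#' Builds per-population allele frequencies for a set of cis-regions (one
#' per gene) under the Balding-Nichols model: each variant has a shared
#' base frequency and population frequencies are Beta-distributed around
#' it with differentiation parameter `F`. A configurable fraction of
#' variants is forced to be population-private (common in exactly one
#' ancestry, essentially absent in the others), the architecture that
#' gives rise to allele-frequency-driven ancestry-specific eQTLs.
#' Variants are organized into LD blocks; within a block, haplotype
#' alleles are later drawn through a Gaussian copula with a
#' per-population latent correlation, so LD strength can differ between
#' ancestries.
#'
#' @param n_pops Number of ancestral populations (>= 2).
#' @param n_variants Total variant count, split evenly across genes.
#' @param n_genes Number of genes (cis-regions).
#' @param block_size Variants per LD block.
#' @param rho_per_pop Numeric vector of length `n_pops`: latent
#'   within-block correlation for each ancestry, each in [0, 1).
#' @param F Balding-Nichols differentiation parameter in (0, 1);
#'   `F -> 0` collapses all populations onto the base frequency.
#' @param private_frac Fraction of variants forced population-private.
#' @param asym_ld_genes Integer indices of genes whose central LD block
#'   receives ancestry-asymmetric correlation (strong in `high_pop`,
#'   weak elsewhere); used to plant LD-driven ancestry-specific signals.
#' @param high_pop Index of the high-diversity ancestry (default 1).
#' @param pop_labels Ancestry names; defaults to AFR, EUR, IAM, ...
#' @param seed Integer seed; the panel is a pure function of its
#'   arguments and this seed.
#' @return An object of class `ancestral_panel`.
#' @export
simulate_ancestral_panel <- function(n_pops = 2, n_variants = 1000, n_genes = 5,
                                     block_size = 20,
                                     rho_per_pop = rep(0.5, n_pops),
                                     F = 0.15, private_frac = 0.05,
                                     asym_ld_genes = integer(0), high_pop = 1L,
                                     pop_labels = NULL, seed = 1) {
  if (n_pops < 2) stop("n_pops must be >= 2")
  if (!(F > 0 && F < 1)) stop("F must be in (0, 1)")
  if (any(rho_per_pop < 0 | rho_per_pop >= 1)) stop("rho_per_pop must be in [0, 1)")
  if (length(rho_per_pop) != n_pops) stop("rho_per_pop must have length n_pops")
  if (is.null(pop_labels))
    pop_labels <- c("AFR", "EUR", "IAM", paste0("POP", seq_len(max(0, n_pops - 3))))[seq_len(n_pops)]

  with_seed(substream_seed(seed, "panel"), {
    # distribute variants across genes
    m_per_gene <- rep(n_variants %/% n_genes, n_genes)
    extra <- n_variants %% n_genes
    if (extra > 0) m_per_gene[seq_len(extra)] <- m_per_gene[seq_len(extra)] + 1L
    gene_of_variant <- rep(seq_len(n_genes), m_per_gene)

    # genomic layout: variants evenly spaced inside each gene's region,
    # regions far enough apart that +/- 1 Mb cis windows never overlap
    pos <- integer(n_variants)
    tss <- integer(n_genes)
    offset <- 10000L
    for (g in seq_len(n_genes)) {
      m <- m_per_gene[g]
      spacing <- max(1L, min(2000L, as.integer(2e6 / (m + 1))))
      p <- offset + spacing * seq_len(m)
      pos[gene_of_variant == g] <- p
      tss[g] <- p[ceiling(m / 2)]
      offset <- p[m] + 2200000L
    }

    # LD blocks nested within genes
    block <- integer(n_variants)
    nb <- 0L
    for (g in seq_len(n_genes)) {
      idx <- which(gene_of_variant == g)
      b <- (seq_along(idx) - 1L) %/% block_size
      block[idx] <- nb + b + 1L
      nb <- nb + max(b) + 1L
    }
    n_blocks <- nb
    rho <- matrix(rep(rho_per_pop, each = n_blocks), n_blocks, n_pops)

    # ancestry-asymmetric LD in the central block of selected genes
    asym_block <- rep(NA_integer_, n_genes)
    for (g in asym_ld_genes) {
      blocks_g <- unique(block[gene_of_variant == g])
      b <- blocks_g[ceiling(length(blocks_g) / 2)]
      rho[b, ] <- 0.05
      rho[b, high_pop] <- 0.9
      asym_block[g] <- b
    }

    # Balding-Nichols frequencies around a shared base frequency
    p0 <- stats::runif(n_variants, 0.05, 0.95)
    shape <- (1 - F) / F
    freq <- matrix(NA_real_, n_variants, n_pops,
                   dimnames = list(NULL, pop_labels))
    for (k in seq_len(n_pops))
      freq[, k] <- stats::rbeta(n_variants, p0 * shape, (1 - p0) * shape)

    # population-private common variants, allocated within each gene so
    # every cis-region carries some (at least one per ancestry when the
    # fraction allows)
    private_pop <- integer(n_variants)
    if (private_frac > 0) {
      for (g in seq_len(n_genes)) {
        idx <- which(gene_of_variant == g)
        n_priv <- max(n_pops, round(private_frac * length(idx)))
        n_priv <- min(n_priv, length(idx))
        priv_idx <- sample(idx, n_priv)
        owner <- rep(seq_len(n_pops), length.out = n_priv)
        for (i in seq_len(n_priv)) {
          j <- priv_idx[i]; k <- owner[i]
          # essentially absent outside the owner ancestry, mirroring
          # post-bottleneck loss of ancestry-private common variants
          freq[j, ] <- stats::runif(n_pops, 0, 0.002)
          freq[j, k] <- stats::runif(1, 0.05, 0.15)
          private_pop[j] <- k
        }
      }
    }

    structure(list(
      pop_labels = pop_labels,
      freq = freq,
      chrom = rep("1", n_variants),
      pos = pos,
      variant_id = sprintf("snp%06d", seq_len(n_variants)),
      block = block,
      rho = rho,
      gene_of_variant = gene_of_variant,
      genes = data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                         chrom = "1", tss = tss,
                         stringsAsFactors = FALSE),
      private_pop = private_pop,
      asym_block = asym_block,
      high_pop = as.integer(high_pop),
      F = F, block_size = block_size, seed = seed
    ), class = "ancestral_panel")
  })
}

#' Draw per-individual global ancestry proportions
#'
#' For two populations, the first-ancestry proportion is Beta-distributed
#' around `mean` with the given concentration; for more populations a
#' Dirichlet draw with mean vector `mean` is used. Rows sum to 1.
#'
#' @param n Number of individuals.
#' @param mean Target mean ancestry proportion(s); scalar (first
#'   population, two-population case) or a vector over populations.
#' @param concentration Dirichlet/Beta concentration (larger = tighter).
#' @param n_pops Number of populations.
#' @param seed Integer seed.
#' @return An `n` x `n_pops` matrix of ancestry proportions.
#' @export
simulate_theta <- function(n, mean = 0.8, concentration = 30, n_pops = 2, seed = 1) {
  if (length(mean) == 1) mean <- c(mean, rep((1 - mean) / (n_pops - 1), n_pops - 1))
  stopifnot(length(mean) == n_pops, abs(sum(mean) - 1) < 1e-8)
  with_seed(substream_seed(seed, "theta"), {
    a <- mean * concentration
    G <- matrix(stats::rgamma(n * n_pops, shape = rep(a, each = n)), n, n_pops)
    G / rowSums(G)
  })
}

#' Simulate genotypes and local ancestry for an admixed cohort
#'
#' For each gene and haplotype, a local ancestry is drawn from the
#' individual's global proportions theta; the haplotype's alleles across
#' the gene's cis-region are then drawn from that ancestry's allele
#' frequencies with block LD induced by a Gaussian copula using the
#' block's latent correlation for that ancestry. Dosage is the sum of the
#' two haplotypes, so dosages, local ancestry and haplotypes are mutually
#' consistent by construction.
#'
#' @param panel An `ancestral_panel`.
#' @param n_individuals Cohort size (>= 2).
#' @param theta Either an `n x n_pops` matrix of ancestry proportions or
#'   a function `f(n)` returning one.
#' @param seed Integer seed.
#' @return An object of class `admixed_cohort` with elements `dosage`
#'   (n x variants), `hap1`/`hap2`, `theta`, `local_anc` (n x genes x
#'   pops allele counts), `hap_anc1`/`hap_anc2`, `covariates` (age in
#'   years, sex and asthma status as 0/1), and the generating `panel`.
#' @export
simulate_admixed_genotypes <- function(panel, n_individuals, theta, seed = 1) {
  stopifnot(inherits(panel, "ancestral_panel"))
  if (n_individuals < 2) stop("n_individuals must be >= 2")
  n <- n_individuals
  n_pops <- length(panel$pop_labels)
  if (is.function(theta)) theta <- theta(n)
  theta <- as.matrix(theta)
  stopifnot(nrow(theta) == n, ncol(theta) == n_pops)
  if (any(abs(rowSums(theta) - 1) > 1e-12)) stop("theta rows must sum to 1")

  with_seed(substream_seed(seed, "genotypes"), {
    V <- length(panel$pos)
    n_genes <- nrow(panel$genes)
    hap1 <- matrix(0L, n, V)
    hap2 <- matrix(0L, n, V)
    anc1 <- matrix(0L, n, n_genes)
    anc2 <- matrix(0L, n, n_genes)

    draw_hap <- function(gene_vars, anc_g) {
      A <- matrix(0L, n, length(gene_vars))
      blocks <- panel$block[gene_vars]
      for (k in seq_len(n_pops)) {
        I <- which(anc_g == k)
        if (!length(I)) next
        for (b in unique(blocks)) {
          J <- which(blocks == b)
          rho <- panel$rho[b, k]
          s <- stats::rnorm(length(I))
          E <- matrix(stats::rnorm(length(I) * length(J)), length(I), length(J))
          Z <- sqrt(rho) * s + sqrt(1 - rho) * E
          p <- panel$freq[gene_vars[J], k]
          A[I, J] <- (stats::pnorm(Z) < rep(p, each = length(I))) + 0L
        }
      }
      A
    }

    for (g in seq_len(n_genes)) {
      gene_vars <- which(panel$gene_of_variant == g)
      # local ancestry of each haplotype at this gene's cis-region
      u1 <- stats::runif(n); u2 <- stats::runif(n)
      cum <- t(apply(theta, 1, cumsum))
      anc1[, g] <- 1L + rowSums(u1 > cum[, -n_pops, drop = FALSE])
      anc2[, g] <- 1L + rowSums(u2 > cum[, -n_pops, drop = FALSE])
      hap1[, gene_vars] <- draw_hap(gene_vars, anc1[, g])
      hap2[, gene_vars] <- draw_hap(gene_vars, anc2[, g])
    }

    local_anc <- array(0L, dim = c(n, n_genes, n_pops),
                       dimnames = list(NULL, panel$genes$gene_id, panel$pop_labels))
    for (k in seq_len(n_pops))
      local_anc[, , k] <- (anc1 == k) + (anc2 == k)

    covariates <- data.frame(
      age = stats::runif(n, 8, 21),
      sex = stats::rbinom(n, 1, 0.5),
      asthma = stats::rbinom(n, 1, 0.5)
    )

    dosage <- hap1 + hap2
    colnames(dosage) <- panel$variant_id

    structure(list(
      sample_id = sprintf("S%05d", seq_len(n)),
      dosage = dosage, hap1 = hap1, hap2 = hap2,
      theta = theta, hap_anc1 = anc1, hap_anc2 = anc2,
      local_anc = local_anc, covariates = covariates,
      panel = panel, seed = seed
    ), class = "admixed_cohort")
  })
}

#' Build a per-gene scenario table for expression simulation
#'
#' @param scenario Character vector (recycled over genes) with values in
#'   `null`, `shared`, `tier1`, `tier2`, `tier3`.
#' @param n_genes Number of genes; defaults to `length(scenario)`.
#' @param h2 Target cis-heritability per gene (recycled).
#' @param effect_ratio High- vs low-diversity ancestry effect-size ratio
#'   for `tier3` genes.
#' @return A data.frame consumed by [simulate_expression()].
#' @export
scenario_config <- function(scenario, n_genes = length(scenario), h2 = 0.1,
                            effect_ratio = 2) {
  scenario <- rep_len(scenario, n_genes)
  bad <- setdiff(scenario, c("null", "shared", "tier1", "tier2", "tier3"))
  if (length(bad)) stop("unknown scenario: ", paste(bad, collapse = ", "))
  data.frame(gene = seq_len(n_genes), scenario = scenario,
             h2 = rep_len(h2, n_genes),
             effect_ratio = rep_len(effect_ratio, n_genes),
             stringsAsFactors = FALSE)
}

#' Simulate gene expression with labeled ancestry-specific architecture
#'
#' Expression for each gene is a causal-variant genetic value plus
#' optional covariate effects plus Gaussian noise, scaled so the genetic
#' component explains the target heritability of a unit-variance trait.
#' Scenarios plant distinct architectures: `tier1` uses a causal variant
#' common only in the high-diversity ancestry; `tier2` uses a causal
#' variant common everywhere but masked from the typed panel and tagged
#' strongly only in the high-diversity ancestry (LD-driven specificity);
#' `tier3` gives the same causal variant ancestry-dependent effect sizes
#' at the haplotype level; `shared` uses one effect everywhere; `null`
#' has no genetic effect.
#'
#' @param cohort An `admixed_cohort`.
#' @param scenarios Data frame from [scenario_config()]; one row per gene
#'   of the cohort's panel. Optional columns `beta` (explicit allelic
#'   effect, overrides `h2` scaling) and `noise_var` (residual variance,
#'   default `1 - h2`).
#' @param seed Integer seed.
#' @param covar_beta Named effects of `age`, `sex`, `asthma` on
#'   expression (default all zero).
#' @return An `expression_dataset`: `expr` (genes x samples), `truth`
#'   (per-gene scenario, causal id, per-ancestry betas, true h2) and
#'   `masked_variants` (causal ids hidden from the typed panel).
#' @export
simulate_expression <- function(cohort, scenarios, seed = 1,
                                covar_beta = c(age = 0, sex = 0, asthma = 0)) {
  stopifnot(inherits(cohort, "admixed_cohort"))
  panel <- cohort$panel
  n_genes <- nrow(panel$genes)
  if (nrow(scenarios) != n_genes)
    stop("scenarios must have one row per panel gene")
  if (any(scenarios$h2 >= 1 | scenarios$h2 < 0)) stop("h2 must be in [0, 1)")
  n <- nrow(cohort$dosage)
  n_pops <- length(panel$pop_labels)
  high <- panel$high_pop

  with_seed(substream_seed(seed, "expression"), {
    expr <- matrix(NA_real_, n_genes, n,
                   dimnames = list(panel$genes$gene_id, cohort$sample_id))
    beta_mat <- matrix(0, n_genes, n_pops,
                       dimnames = list(NULL, paste0("beta_", panel$pop_labels)))
    causal_id <- rep(NA_character_, n_genes)
    h2_true <- numeric(n_genes)
    masked <- character(0)

    covar_part <- as.matrix(cohort$covariates[, c("age", "sex", "asthma")]) %*%
      covar_beta[c("age", "sex", "asthma")]

    for (g in seq_len(n_genes)) {
      sc <- scenarios$scenario[g]
      h2 <- scenarios$h2[g]
      gene_vars <- which(panel$gene_of_variant == g)
      causal <- NA_integer_

      if (sc != "null") {
        if (sc == "tier1") {
          cand <- gene_vars[panel$private_pop[gene_vars] == high]
          if (!length(cand))
            stop("gene ", g, ": no population-private variant available for tier1; ",
                 "increase private_frac in the panel")
        } else if (sc == "tier2") {
          b <- panel$asym_block[g]
          if (is.na(b))
            stop("gene ", g, ": tier2 requires an asymmetric-LD block; ",
                 "regenerate the panel with this gene in asym_ld_genes")
          in_b <- gene_vars[panel$block[gene_vars] == b]
          fq <- panel$freq[in_b, , drop = FALSE]
          cand <- in_b[apply(fq >= 0.05 & fq <= 0.95, 1, all)]
          if (!length(cand))
            stop("gene ", g, ": no variant common in all ancestries in the ",
                 "asymmetric-LD block")
        } else { # shared / tier3: common in every ancestry, not private
          fq <- panel$freq[gene_vars, , drop = FALSE]
          cand <- gene_vars[panel$private_pop[gene_vars] == 0 &
                            apply(fq >= 0.05 & fq <= 0.95, 1, all)]
          if (!length(cand)) stop("gene ", g, ": no shared-common variant available")
        }
        causal <- if (length(cand) == 1) cand else sample(cand, 1)
      }

      if (sc == "null") {
        G <- rep(0, n)
        h2_true[g] <- 0
      } else if (sc == "tier3") {
        ratio <- scenarios$effect_ratio[g]
        b_pop <- rep(1, n_pops); b_pop[high] <- ratio
        G0 <- b_pop[cohort$hap_anc1[, g]] * cohort$hap1[, causal] +
              b_pop[cohort$hap_anc2[, g]] * cohort$hap2[, causal]
        v <- stats::var(G0)
        s <- if (v > 0) sqrt(h2 / v) else 0
        G <- G0 * s
        beta_mat[g, ] <- b_pop * s
        h2_true[g] <- if (v > 0) h2 else 0
      } else {
        d <- cohort$dosage[, causal]
        v <- stats::var(d)
        if (!is.null(scenarios$beta) && !is.na(scenarios$beta[g])) {
          b <- scenarios$beta[g]
        } else {
          if (v <= 0) stop("gene ", g, ": causal variant monomorphic in cohort")
          b <- sqrt(h2 / v)
        }
        G <- b * d
        beta_mat[g, ] <- b
        h2_true[g] <- stats::var(G) / (stats::var(G) + (1 - h2))
      }

      noise_var <- if (!is.null(scenarios$noise_var) && !is.na(scenarios$noise_var[g]))
        scenarios$noise_var[g] else 1 - h2
      e <- if (noise_var > 0) stats::rnorm(n, 0, sqrt(noise_var)) else rep(0, n)
      expr[g, ] <- G + covar_part[, 1] + e
      if (!is.na(causal)) {
        causal_id[g] <- panel$variant_id[causal]
        if (sc == "tier2") masked <- c(masked, panel$variant_id[causal])
        if (sc != "tier3") {
          # recompute true h2 against the realized noise variance
          h2_true[g] <- stats::var(G) / (stats::var(G) + noise_var)
        }
      }
    }

    truth <- data.frame(gene_id = panel$genes$gene_id,
                        scenario = scenarios$scenario,
                        causal_id = causal_id,
                        beta_mat,
                        h2_true = h2_true,
                        masked = panel$genes$gene_id %in%
                          panel$genes$gene_id[scenarios$scenario == "tier2"],
                        stringsAsFactors = FALSE)

    structure(list(expr = expr, truth = truth, masked_variants = masked),
              class = "expression_dataset")
  })
}

#' Typed (observable) variant indices of a cohort
#'
#' Variants masked by the expression simulation (hidden causal variants
#' of LD-driven scenarios) are excluded, mirroring a genotyping panel
#' that does not include every causal site.
#'
#' @param cohort An `admixed_cohort`.
#' @param expression Optional `expression_dataset` whose masked variants
#'   are dropped.
#' @return Integer indices into the cohort's variant set.
#' @export
typed_variants <- function(cohort, expression = NULL) {
  ids <- cohort$panel$variant_id
  if (is.null(expression)) seq_along(ids)
  else which(!(ids %in% expression$masked_variants))
}

#' Simulate GWAS summary statistics for a trait mediated by expression
#'
#' A fresh population is drawn from the same ancestral panel; the trait
#' is the sum over genes of `alpha[g]` times the gene's genetic value
#' (from the recorded simulation truth) plus Gaussian noise. Marginal
#' per-variant regressions of the trait on dosage give effect sizes,
#' standard errors and z-scores in the usual summary-statistic form.
#'
#' @param panel An `ancestral_panel`.
#' @param truth Truth table from an `expression_dataset`.
#' @param alpha Per-gene effect of genetic expression value on the trait.
#' @param n_gwas GWAS sample size (>= 100).
#' @param theta Ancestry proportions for the GWAS population (matrix or
#'   function, as in [simulate_admixed_genotypes()]).
#' @param noise_var Residual trait variance (default 1).
#' @param seed Integer seed.
#' @return A data.frame of class `gwas_sumstats` with columns
#'   `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`, `z`,
#'   `n`, restricted to typed variants.
#' @export
simulate_gwas_sumstats <- function(panel, truth, alpha, n_gwas, theta,
                                   noise_var = 1, seed = 1) {
  if (n_gwas < 100) stop("n_gwas must be >= 100")
  n_genes <- nrow(panel$genes)
  alpha <- rep_len(alpha, n_genes)
  pop <- simulate_admixed_genotypes(panel, n_gwas, theta,
                                    seed = substream_seed(seed, "gwas_pop"))
  with_seed(substream_seed(seed, "gwas_trait"), {
    y <- stats::rnorm(n_gwas, 0, sqrt(noise_var))
    n_pops <- length(panel$pop_labels)
    for (g in seq_len(n_genes)) {
      if (alpha[g] == 0 || is.na(truth$causal_id[g])) next
      causal <- match(truth$causal_id[g], panel$variant_id)
      b_pop <- as.numeric(truth[g, paste0("beta_", panel$pop_labels)])
      if (length(unique(b_pop)) == 1) {
        Gval <- b_pop[1] * pop$dosage[, causal]
      } else {
        Gval <- b_pop[pop$hap_anc1[, g]] * pop$hap1[, causal] +
                b_pop[pop$hap_anc2[, g]] * pop$hap2[, causal]
      }
      y <- y + alpha[g] * Gval
    }

    keep <- which(!(panel$variant_id %in% truth$causal_id[truth$masked]))
    marginal_sumstats(pop$dosage[, keep, drop = FALSE], y,
                      variant_ids = panel$variant_id[keep])
  })
}

#' Marginal per-variant GWAS summary statistics
#'
#' Simple regression of a trait on each variant's dosage, reported in
#' standard summary-statistic form (effect allele = the dosage-counted
#' ALT allele "B").
#'
#' @param dosage n x m dosage matrix.
#' @param y Trait vector.
#' @param variant_ids Variant ids (defaults to column names).
#' @return `gwas_sumstats` data.frame: `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `z`, `n`; monomorphic variants are
#'   dropped.
#' @export
marginal_sumstats <- function(dosage, y, variant_ids = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  n <- length(y)
  stopifnot(nrow(dosage) == n)
  Gc <- sweep(dosage, 2, colMeans(dosage))
  yc <- y - mean(y)
  ss <- colSums(Gc^2)
  ok <- ss > 0
  beta <- se <- rep(NA_real_, ncol(dosage))
  beta[ok] <- as.numeric(crossprod(Gc[, ok, drop = FALSE], yc)) / ss[ok]
  rss <- sum(yc^2) - beta[ok]^2 * ss[ok]
  se[ok] <- sqrt(pmax(rss, 0) / ((n - 2) * ss[ok]))
  out <- data.frame(variant_id = variant_ids %||% seq_len(ncol(dosage)),
                    effect_allele = "B", other_allele = "A",
                    beta = beta, se = se, z = beta / se, n = n,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$se) & out$se > 0, ]
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}

#' One-call simulation of a two-group admixed eQTL study
#'
#' Convenience orchestrator: builds a panel (with asymmetric-LD blocks
#' for any tier2 genes), draws a cohort whose individuals split into a
#' high-ancestry group (mean global ancestry ~0.8 for the high-diversity
#' population) and a low-ancestry group (~0.05), and simulates
#' expression under the given scenario labels.
#'
#' @param scenario Character vector of per-gene scenario labels.
#' @param n_high,n_low Individuals in the high/low global-ancestry groups.
#' @param variants_per_gene Variants per cis-region.
#' @param block_size LD block size.
#' @param rho_per_pop Latent block correlations per ancestry.
#' @param F Balding-Nichols differentiation.
#' @param h2 Target heritability for non-null genes.
#' @param effect_ratio Tier3 effect-size ratio.
#' @param private_frac Fraction of population-private variants.
#' @param seed Integer seed.
#' @return List with `panel`, `cohort`, `expression`, and `group`
#'   (character vector: "high", "low" or "mid" per individual, from the
#'   >50% / <10% global-ancestry cut-offs).
#' @export
simulate_study <- function(scenario, n_high = 300, n_low = 300,
                           variants_per_gene = 100, block_size = 20,
                           rho_per_pop = c(0.5, 0.5), F = 0.15,
                           h2 = 0.1, effect_ratio = 2,
                           private_frac = 0.08, seed = 1) {
  n_genes <- length(scenario)
  panel <- simulate_ancestral_panel(
    n_pops = length(rho_per_pop),
    n_variants = n_genes * variants_per_gene,
    n_genes = n_genes, block_size = block_size,
    rho_per_pop = rho_per_pop, F = F, private_frac = private_frac,
    asym_ld_genes = which(scenario == "tier2"),
    seed = substream_seed(seed, "study_panel"))
  n <- n_high + n_low
  th_high <- simulate_theta(n_high, mean = 0.8, concentration = 40,
                            n_pops = length(rho_per_pop),
                            seed = substream_seed(seed, "theta_high"))
  th_low <- simulate_theta(n_low, mean = 0.03, concentration = 40,
                           n_pops = length(rho_per_pop),
                           seed = substream_seed(seed, "theta_low"))
  theta <- rbind(th_high, th_low)
  cohort <- simulate_admixed_genotypes(panel, n, theta,
                                       seed = substream_seed(seed, "study_geno"))
  expression <- simulate_expression(
    cohort, scenario_config(scenario, h2 = h2, effect_ratio = effect_ratio),
    seed = substream_seed(seed, "study_expr"))
  group <- ifelse(theta[, panel$high_pop] > 0.5, "high",
                  ifelse(theta[, panel$high_pop] < 0.1, "low", "mid"))
  list(panel = panel, cohort = cohort, expression = expression, group = group)
}
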