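#' Empirical coverage of single-causal credible sets
#'
#' Simulates cis-regions each carrying exactly one causal eQTL, runs the
#' marginal cis scan, forms single-causal posteriors from the z-scores
#' and builds credible sets at the requested level; returns the fraction
#' of regions whose credible set contains the true causal variant. This
#' is the package's standing calibration benchmark for the fine-mapping
#' stage.
#'
#' @param n_regions Number of simulated cis-regions.
#' @param n_variants Variants per region (default 200).
#' @param n Individuals (default 600).
#' @param rho Latent block LD correlation (default 0.6).
#' @param h2_range Range of per-region causal variance explained
#'   (default 5-10%).
#' @param level Credible level (default 0.95).
#' @param prior_sd Fine-mapping prior effect sd (default 0.15).
#' @param block_size LD block size (default 20).
#' @param seed Integer seed.
#' @return List: `coverage` (fraction in [0, 1]), `n_regions`, `hits`
#'   (logical per region).
#' @export
credible_set_coverage <- function(n_regions = 500, n_variants = 200, n = 600,
                                  rho = 0.6, h2_range = c(0.05, 0.1),
                                  level = 0.95, prior_sd = 0.15,
                                  block_size = 20, seed = 1) {
  batch <- 50L
  hits <- logical(0)
  n_batches <- ceiling(n_regions / batch)
  for (b in seq_len(n_batches)) {
    nb <- min(batch, n_regions - (b - 1L) * batch)
    panel <- simulate_ancestral_panel(
      n_pops = 2, n_variants = nb * n_variants, n_genes = nb,
      block_size = block_size, rho_per_pop = c(rho, rho),
      F = 0.15, private_frac = 0,
      seed = substream_seed(seed, paste0("cov_panel", b)))
    theta <- matrix(rep(c(1, 0), each = n), n)
    coh <- simulate_admixed_genotypes(
      panel, n, theta, seed = substream_seed(seed, paste0("cov_geno", b)))
    h2 <- with_seed(substream_seed(seed, paste0("cov_h2_", b)),
                    stats::runif(nb, h2_range[1], h2_range[2]))
    ex <- simulate_expression(coh, scenario_config(rep("shared", nb), h2 = h2),
                              seed = substream_seed(seed, paste0("cov_expr", b)))
    for (g in seq_len(nb)) {
      vars <- which(panel$gene_of_variant == g)
      G <- coh$dosage[, vars, drop = FALSE]
      colnames(G) <- panel$variant_id[vars]
      sc <- cis_scan(G, inverse_normal(ex$expr[g, ]))
      pp <- single_causal_posterior(sc$t, n, prior_sd = prior_sd)
      cs <- credible_set(pp, level = level,
                         pos = panel$pos[match(sc$variant, panel$variant_id)],
                         ids = sc$variant)
      hits <- c(hits, ex$truth$causal_id[g] %in% cs$members$variant)
    }
  }
  list(coverage = mean(hits), n_regions = n_regions, hits = hits)
}
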