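test_that("divergence-free limit collapses population frequencies", {
  panel <- simulate_ancestral_panel(n_pops = 3, n_variants = 400, n_genes = 2,
                                    rho_per_pop = rep(0, 3), F = 1e-6,
                                    private_frac = 0, seed = 1)
  spread <- apply(panel$freq, 1, function(x) max(x) - min(x))
  expect_lt(stats::median(spread), 0.01)
})

test_that("parameter validation rejects invalid F and rho", {
  expect_error(simulate_ancestral_panel(F = 0, seed = 1), "F must be")
  expect_error(simulate_ancestral_panel(F = 1.2, seed = 1), "F must be")
  expect_error(simulate_ancestral_panel(rho_per_pop = c(0.5, 1), seed = 1),
               "rho_per_pop")
  expect_error(simulate_admixed_genotypes(small_cohort()$panel, 1,
                                          matrix(c(1, 0), 1)),
               "n_individuals")
  expect_error(simulate_expression(small_cohort(),
                                   scenario_config(rep("shared", 5), h2 = 1)),
               "h2")
})

test_that("Balding-Nichols differentiation matches a Hudson FST oracle", {
  F <- 0.15
  panel <- simulate_ancestral_panel(n_pops = 2, n_variants = 10000,
                                    n_genes = 10, rho_per_pop = c(0, 0),
                                    F = F, private_frac = 0, seed = 7)
  # independent oracle: Hudson estimator on binomially sampled haplotypes
  set.seed(77)
  n_hap <- 10000
  p1 <- stats::rbinom(10000, n_hap, panel$freq[, 1]) / n_hap
  p2 <- stats::rbinom(10000, n_hap, panel$freq[, 2]) / n_hap
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n_hap - 1) - p2 * (1 - p2) / (n_hap - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- sum(num) / sum(den)
  expect_lt(abs(fst - F), 0.02)
})

test_that("panel, genotypes, expression and sumstats are deterministic in the seed", {
  p1 <- simulate_ancestral_panel(seed = 5)
  p2 <- simulate_ancestral_panel(seed = 5)
  expect_identical(p1, p2)
  th <- simulate_theta(50, 0.7, seed = 5)
  c1 <- simulate_admixed_genotypes(p1, 50, th, seed = 9)
  c2 <- simulate_admixed_genotypes(p2, 50, th, seed = 9)
  expect_identical(c1$dosage, c2$dosage)
  sc <- scenario_config(rep("shared", 5), h2 = 0.1)
  e1 <- simulate_expression(c1, sc, seed = 3)
  e2 <- simulate_expression(c2, sc, seed = 3)
  expect_identical(e1$expr, e2$expr)
  s1 <- simulate_gwas_sumstats(p1, e1$truth, alpha = c(1, 0, 0, 0, 0),
                               n_gwas = 200, theta = function(n)
                                 simulate_theta(n, 0.8, seed = 4), seed = 8)
  s2 <- simulate_gwas_sumstats(p2, e2$truth, alpha = c(1, 0, 0, 0, 0),
                               n_gwas = 200, theta = function(n)
                                 simulate_theta(n, 0.8, seed = 4), seed = 8)
  expect_identical(s1, s2)
})

test_that("cohort invariants hold: theta, local ancestry, dosage", {
  coh <- small_cohort()
  expect_true(all(abs(rowSums(coh$theta) - 1) < 1e-12))
  expect_true(all(apply(coh$local_anc, c(1, 2), sum) == 2))
  expect_true(all(coh$dosage >= 0 & coh$dosage <= 2))
  expect_identical(unname(coh$dosage), coh$hap1 + coh$hap2)
})

test_that("pure-ancestry cohort has local ancestry fixed at 2", {
  panel <- simulate_ancestral_panel(n_variants = 100, n_genes = 2, seed = 2)
  theta <- matrix(rep(c(1, 0), each = 40), 40)
  coh <- simulate_admixed_genotypes(panel, 40, theta, seed = 2)
  expect_true(all(coh$local_anc[, , 1] == 2))
  expect_true(all(coh$local_anc[, , 2] == 0))
})

test_that("local ancestry counts follow the Binomial(2, theta) law", {
  panel <- simulate_ancestral_panel(n_variants = 200, n_genes = 4, seed = 3)
  theta <- matrix(rep(c(0.8, 0.2), each = 1000), 1000)
  coh <- simulate_admixed_genotypes(panel, 1000, theta, seed = 3)
  means <- colMeans(coh$local_anc[, , 1])  # per gene, oracle E = 2 * 0.8
  expect_true(all(abs(means - 1.6) < 0.05))
})

test_that("allele frequencies are preserved in the cohort", {
  panel <- simulate_ancestral_panel(n_variants = 100, n_genes = 2,
                                    rho_per_pop = c(0, 0), private_frac = 0,
                                    seed = 4)
  panel$freq[] <- 0.5
  theta <- simulate_theta(1000, 0.5, seed = 4)
  coh <- simulate_admixed_genotypes(panel, 1000, theta, seed = 4)
  emp <- colMeans(coh$dosage) / 2
  expect_true(all(abs(emp - 0.5) < 0.03))
})

test_that("null scenario yields h2 = 0 and no dosage correlation", {
  coh <- small_cohort()
  ex <- small_expression()
  g <- which(ex$truth$scenario == "null")
  expect_equal(ex$truth$h2_true[g], 0)
  vars <- which(coh$panel$gene_of_variant == g)
  cors <- abs(apply(coh$dosage[, vars], 2, function(d)
    if (stats::sd(d) > 0) stats::cor(d, ex$expr[g, ]) else 0))
  expect_lt(stats::quantile(cors, 0.95), 0.2)
})

test_that("genetic variance matches the analytic 2p(1-p)beta^2 law", {
  panel <- simulate_ancestral_panel(n_variants = 60, n_genes = 1,
                                    rho_per_pop = c(0, 0), private_frac = 0,
                                    seed = 6)
  panel$freq[] <- 0.3
  theta <- simulate_theta(5000, 0.5, seed = 6)
  coh <- simulate_admixed_genotypes(panel, 5000, theta, seed = 6)
  beta <- sqrt(0.1 / (2 * 0.3 * 0.7))
  sc <- scenario_config("shared", h2 = 0.1)
  sc$beta <- beta
  sc$noise_var <- 0.9
  ex <- simulate_expression(coh, sc, seed = 7)
  causal <- match(ex$truth$causal_id[1], panel$variant_id)
  vg <- stats::var(beta * coh$dosage[, causal])
  expect_lt(abs(vg - 0.1), 0.01)
  expect_lt(abs(ex$truth$h2_true[1] - 0.1), 0.02)
})

test_that("noiseless expression is an exact affine function of the causal dosage", {
  coh <- small_cohort()
  sc <- scenario_config(rep("shared", 5), h2 = 0.5)
  sc$noise_var <- 0
  ex <- simulate_expression(coh, sc, seed = 8)
  causal <- match(ex$truth$causal_id[1], coh$panel$variant_id)
  expect_equal(abs(stats::cor(ex$expr[1, ], coh$dosage[, causal])), 1,
               tolerance = 1e-12)
})

test_that("genetic variance is monotone in causal-variant heterozygosity", {
  vg_at <- function(p) {
    panel <- simulate_ancestral_panel(n_variants = 40, n_genes = 1,
                                      rho_per_pop = c(0, 0), private_frac = 0,
                                      seed = 9)
    panel$freq[] <- p
    theta <- simulate_theta(2000, 0.5, seed = 9)
    coh <- simulate_admixed_genotypes(panel, 2000, theta, seed = 9)
    sc <- scenario_config("shared", h2 = 0.1)
    sc$beta <- 0.5  # fixed effect size across p
    ex <- simulate_expression(coh, sc, seed = 10)
    causal <- match(ex$truth$causal_id[1], panel$variant_id)
    stats::var(0.5 * coh$dosage[, causal])
  }
  vgs <- vapply(c(0.05, 0.2, 0.5), vg_at, 1)
  expect_true(all(diff(vgs) > 0))
})

test_that("null GWAS summary statistics are calibrated", {
  panel <- simulate_ancestral_panel(n_variants = 6000, n_genes = 12,
                                    private_frac = 0, seed = 11)
  sc_truth <- data.frame(gene_id = panel$genes$gene_id, scenario = "null",
                         causal_id = NA, beta_AFR = 0, beta_EUR = 0,
                         h2_true = 0, masked = FALSE)
  ss <- simulate_gwas_sumstats(panel, sc_truth, alpha = 0, n_gwas = 400,
                               theta = function(n) simulate_theta(n, 0.8, seed = 11),
                               seed = 11)
  expect_gt(nrow(ss), 5000)
  expect_lt(abs(mean(ss$z)), 0.05)
  expect_lt(abs(stats::var(ss$z) - 1), 0.1)
  expect_true(all(abs(ss$z - ss$beta / ss$se) < 1e-8))
})

test_that("a mediating gene's causal variant tops its cis window in GWAS", {
  top_hits <- 0L
  n_rep <- 40L
  panel <- simulate_ancestral_panel(n_variants = 50, n_genes = 1,
                                    rho_per_pop = c(0.5, 0.5),
                                    private_frac = 0, seed = 12)
  coh0 <- simulate_admixed_genotypes(panel, 100, simulate_theta(100, 0.8, seed = 12),
                                     seed = 12)
  ex <- simulate_expression(coh0, scenario_config("shared", h2 = 0.05), seed = 12)
  for (r in seq_len(n_rep)) {
    ss <- simulate_gwas_sumstats(panel, ex$truth, alpha = 1, n_gwas = 10000,
                                 theta = function(n) simulate_theta(n, 0.8, seed = 500 + r),
                                 seed = 500 + r)
    top_hits <- top_hits +
      (ss$variant_id[which.max(abs(ss$z))] == ex$truth$causal_id[1])
  }
  expect_gte(top_hits / n_rep, 0.9)
})

test_that("written cohort round-trips exactly through VCF/BED/TSV", {
  coh <- small_cohort()
  ex <- small_expression()
  dir <- tempfile("cohort")
  paths <- write_cohort(coh, ex, dir)
  back <- read_cohort(dir)
  typed <- typed_variants(coh, ex)
  expect_identical(unname(back$dosage),
                   unname(coh$dosage[, typed, drop = FALSE]))
  expect_equal(unname(back$expr), unname(ex$expr))
  expect_identical(back$gene_info$gene_id, rownames(ex$expr))
  # format contract: sorted biallelic records
  expect_true(!is.unsorted(back$variant_pos$pos))
  expect_true(all(back$variant_pos$ref %in% c("A", "C", "G", "T")))
  expect_true(all(nchar(back$variant_pos$alt) == 1))
  th <- back$theta
  expect_equal(unname(th), unname(coh$theta), tolerance = 1e-15)
})

test_that("an empty expression table writes without error", {
  coh <- small_cohort()
  ex <- small_expression()
  ex0 <- ex
  ex0$expr <- ex$expr[0, , drop = FALSE]
  ex0$truth <- ex$truth[0, , drop = FALSE]
  dir <- tempfile("cohort0")
  expect_silent(write_cohort(coh, ex0, dir))
  bed <- readLines(file.path(dir, "expression.bed"))
  expect_length(bed, 1L)  # header only
})
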