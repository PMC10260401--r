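test_that("a perfect predictor gene is learned with dominant weight", {
  coh <- small_cohort()
  vars <- which(coh$panel$gene_of_variant == 1)
  G <- coh$dosage[, vars]
  colnames(G) <- coh$panel$variant_id[vars]
  j <- which(apply(G, 2, stats::sd) > 0.4)[1]
  y <- G[, j]
  m <- train_twas_model(G, y, gene_id = "g", seed = 1)
  expect_gt(m$rho_avg, 0.99)
  expect_true(m$passed_filters)
  expect_equal(names(which.max(abs(m$weights))), colnames(G)[j])
  expect_error(train_twas_model(G[1:5, ], y[1:5], seed = 1), "folds")
})

test_that("null expression rarely passes the nested-CV filters", {
  set.seed(51)
  coh <- small_cohort()
  vars <- which(coh$panel$gene_of_variant == 2)
  G <- coh$dosage[, vars]
  colnames(G) <- coh$panel$variant_id[vars]
  n_genes <- 40
  res <- vapply(seq_len(n_genes), function(i) {
    y <- stats::rnorm(nrow(G))
    m <- train_twas_model(G, y, gene_id = paste0("null", i), seed = 100 + i)
    c(m$rho_avg > 0.1, m$passed_filters)
  }, c(TRUE, TRUE))
  expect_lte(mean(res[1, ]), 0.15)
  expect_lte(mean(res[2, ]), 0.10)
})

test_that("cross-fold correlation approaches the sqrt(h2) ceiling", {
  n <- 600
  panel <- simulate_ancestral_panel(n_variants = 10 * 50, n_genes = 10, seed = 501)
  coh <- simulate_admixed_genotypes(panel, n, simulate_theta(n, 0.8, seed = 501),
                                    seed = 501)
  ex <- simulate_expression(coh, scenario_config(rep("shared", 10), h2 = 0.2),
                            seed = 502)
  ce <- prepare_expression(ex, as.matrix(coh$covariates))
  rho <- vapply(1:10, function(g) {
    vars <- which(panel$gene_of_variant == g)
    G <- coh$dosage[, vars]; colnames(G) <- panel$variant_id[vars]
    train_twas_model(G, ce[g, ], gene_id = panel$genes$gene_id[g],
                     seed = 500 + g)$rho_avg
  }, 1)
  expect_lt(abs(mean(rho) - sqrt(0.2)), 0.1)
})

test_that("single-variant model reduces S-PrediXcan to the variant z", {
  set.seed(52)
  ref <- matrix(stats::rbinom(500, 2, 0.3), 500, 1,
                dimnames = list(NULL, "snpX"))
  model <- structure(list(gene_id = "g", weights = c(snpX = 2),
                          effect_allele = c(snpX = "B"),
                          other_allele = c(snpX = "A"),
                          rho_avg = 0.5, zscore_pval = 0.01, h2_p = 0.01,
                          passed_filters = TRUE), class = "twas_model")
  ss <- data.frame(variant_id = "snpX", effect_allele = "B",
                   other_allele = "A", beta = 0.2, se = 0.05, z = 4, n = 1000)
  out <- spredixcan(model, ss, ref)
  expect_equal(out$z, 4, tolerance = 1e-12)
  expect_equal(out$p, 2 * stats::pnorm(-4), tolerance = 1e-12)
  # allele-orientation antisymmetry
  ss_flip <- transform(ss, effect_allele = "A", other_allele = "B")
  expect_equal(spredixcan(model, ss_flip, ref)$z, -4, tolerance = 1e-12)
  # missing variants reported, not fatal
  ss_none <- transform(ss, variant_id = "other")
  expect_true(is.na(spredixcan(model, ss_none, ref)$z))
})

test_that("summary-based TWAS matches individual-level regression", {
  n_genes <- 15
  panel <- simulate_ancestral_panel(n_variants = n_genes * 40, n_genes = n_genes,
                                    seed = 503)
  train <- simulate_admixed_genotypes(panel, 400,
                                      simulate_theta(400, 0.8, seed = 503),
                                      seed = 503)
  ex <- simulate_expression(train, scenario_config(rep("shared", n_genes),
                                                   h2 = 0.25), seed = 504)
  ce <- prepare_expression(ex, as.matrix(train$covariates))
  models <- lapply(seq_len(n_genes), function(g) {
    vars <- which(panel$gene_of_variant == g)
    G <- train$dosage[, vars]; colnames(G) <- panel$variant_id[vars]
    train_twas_model(G, ce[g, ], gene_id = panel$genes$gene_id[g],
                     seed = 600 + g)
  })
  models <- Filter(function(m) length(m$weights) > 0, models)
  gwas_pop <- simulate_admixed_genotypes(panel, 2500,
                                         simulate_theta(2500, 0.8, seed = 505),
                                         seed = 505)
  alpha <- rep(c(0.3, 0), length.out = n_genes)
  set.seed(506)
  y <- stats::rnorm(2500)
  for (g in seq_len(n_genes)) {
    if (alpha[g] == 0) next
    causal <- match(ex$truth$causal_id[g], panel$variant_id)
    y <- y + alpha[g] * ex$truth$beta_AFR[g] * gwas_pop$dosage[, causal]
  }
  # summary statistics computed in the same population used as LD reference
  Gc <- sweep(gwas_pop$dosage, 2, colMeans(gwas_pop$dosage))
  yc <- y - mean(y)
  ss_var <- colSums(Gc^2)
  ok <- ss_var > 0
  beta <- rep(NA_real_, ncol(Gc)); se <- rep(NA_real_, ncol(Gc))
  beta[ok] <- as.numeric(crossprod(Gc[, ok], yc)) / ss_var[ok]
  se[ok] <- sqrt(pmax(sum(yc^2) - beta[ok]^2 * ss_var[ok], 0) /
                 ((2500 - 2) * ss_var[ok]))
  ss <- data.frame(variant_id = panel$variant_id[ok], effect_allele = "B",
                   other_allele = "A", beta = beta[ok], se = se[ok],
                   z = beta[ok] / se[ok], n = 2500)
  assoc <- twas_associations(models, ss, gwas_pop$dosage)
  z_ind <- vapply(models, function(m) {
    pred <- as.numeric(gwas_pop$dosage[, names(m$weights), drop = FALSE] %*%
                         m$weights)
    if (stats::sd(pred) == 0) return(NA_real_)
    summary(stats::lm(y ~ pred))$coefficients[2, 3]
  }, 1)
  ok2 <- !is.na(assoc$z) & !is.na(z_ind)
  expect_gt(sum(ok2), 8)
  expect_gt(stats::cor(assoc$z[ok2], z_ind[ok2]), 0.99)
})

test_that("model-set comparison reports overlap and correlation", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"), z = c(5, -4, 0.2),
                  p = c(1e-6, 1e-4, 0.8), q = c(1e-5, 1e-3, 0.8))
  cmp <- compare_model_sets(a, a)
  expect_equal(cmp$overlap, 2L)
  expect_equal(cmp$z_cor, 1)
  b <- data.frame(gene_id = c("g4", "g5"), z = c(1, 2), p = c(0.3, 0.04),
                  q = c(0.3, 0.08))
  cmp2 <- compare_model_sets(a, b)
  expect_equal(cmp2$overlap, 0L)
  expect_identical(sort(cmp2$unavailable_in_b), c("g1", "g2", "g3"))
})

test_that("weight tables are tidy and finite", {
  coh <- small_cohort()
  vars <- which(coh$panel$gene_of_variant == 1)
  G <- coh$dosage[, vars]; colnames(G) <- coh$panel$variant_id[vars]
  ex <- small_expression()
  m <- train_twas_model(G, inverse_normal(ex$expr[1, ]), gene_id = "gene0001",
                        seed = 3)
  tab <- twas_weight_table(list(m))
  expect_true(all(is.finite(tab$weight)))
  expect_true(all(tab$variant_id %in% colnames(G)))
})
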