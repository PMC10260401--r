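test_that("expression preparation reduces to covariate residuals with 0 factors", {
  coh <- small_cohort()
  ex <- small_expression()
  covs <- as.matrix(coh$covariates)
  ce <- prepare_expression(ex, covs, n_hidden_factors = 0)
  # oracle: per-gene INT then lm residuals
  g <- 1
  oracle <- stats::lm.fit(cbind(1, covs), inverse_normal(ex$expr[g, ]))$residuals
  expect_equal(unname(ce[g, ]), unname(oracle), tolerance = 1e-10)
  expect_error(prepare_expression(ex, covs, n_hidden_factors = 150),
               "n_hidden_factors")
})

test_that("one hidden factor removes a planted global batch shift", {
  set.seed(21)
  n <- 400; n_genes <- 60
  batch <- stats::rnorm(n)
  Y <- matrix(stats::rnorm(n_genes * n), n_genes, n) +
    outer(stats::runif(n_genes, 0.8, 1.2), batch)
  mean_cor <- function(M) {
    cc <- stats::cor(t(M))
    mean(abs(cc[upper.tri(cc)]))
  }
  ce0 <- prepare_expression(Y, NULL, n_hidden_factors = 0)
  ce1 <- prepare_expression(Y, NULL, n_hidden_factors = 1)
  expect_gt(mean_cor(ce0), 0.2)
  expect_lt(mean_cor(ce1), 0.05)
})

test_that("the inverse-normal transform preserves sample ranks", {
  x <- c(3.2, -1, 7, 0.5, 2)
  expect_identical(rank(inverse_normal(x)), rank(x))
})

test_that("cis scan matches a closed-form regression oracle", {
  G <- cbind(v1 = c(0, 1, 2, 0, 1, 2), v2 = c(2, 2, 1, 0, 1, 0))
  y <- c(0.3, 1.1, 2.2, -0.4, 0.8, 2.5)
  sc <- cis_scan(G, y)
  for (j in 1:2) {
    fit <- summary(stats::lm(y ~ G[, j]))$coefficients
    expect_equal(sc$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(sc$se[j], fit[2, 2], tolerance = 1e-10)
    expect_equal(sc$p[j], fit[2, 4], tolerance = 1e-10)
  }
  expect_true(all(abs(sc$t - sc$beta / sc$se) < 1e-8))
})

test_that("a noiseless signal variant attains slope 1 and the minimum p", {
  coh <- small_cohort()
  vars <- which(coh$panel$gene_of_variant == 1)
  G <- coh$dosage[, vars]
  colnames(G) <- coh$panel$variant_id[vars]
  j <- which(apply(G, 2, stats::sd) > 0.3)[1]
  y <- G[, j]
  sc <- cis_scan(G, y)
  hit <- match(colnames(G)[j], sc$variant)
  expect_equal(sc$beta[hit], 1, tolerance = 1e-10)
  expect_equal(which.min(sc$p), hit)
  # zero-variance variants are skipped
  G0 <- cbind(G, mono = rep(1, nrow(G)))
  expect_false("mono" %in% cis_scan(G0, y)$variant)
})

test_that("nominal p-values are uniform under permutation of expression", {
  set.seed(22)
  G <- matrix(stats::rbinom(300 * 2000, 2, 0.3), 300, 2000)
  y <- stats::rnorm(300)
  sc <- cis_scan(G, y)
  expect_gt(stats::ks.test(sc$p, "punif")$p.value, 0.01)
})

test_that("a signal-free gene gets an empirical permutation p of 1", {
  set.seed(23)
  G <- matrix(stats::rbinom(100 * 20, 2, 0.4), 100, 20)
  # project the phenotype out of the dosage column space: observed
  # association is weaker than any permutation can produce
  y <- stats::lm.fit(cbind(1, G), stats::rnorm(100))$residuals
  pc <- permute_calibrate(G, y, max_permutations = 200, seed = 1)
  expect_equal(pc$p_empirical, 1, tolerance = 1e-12)
  expect_gt(pc$p_beta, 0.5)
})

test_that("permutation minima follow the Beta(1, M) order-statistic law", {
  set.seed(24)
  M <- 50
  G <- matrix(stats::rnorm(250 * M), 250, M)  # independent variants
  y <- stats::rnorm(250)
  pc <- permute_calibrate(G, y, max_permutations = 1000,
                          min_exceed = .Machine$integer.max, seed = 2)
  expect_equal(pc$n_permutations, 1000)
  expect_lt(abs(pc$a - 1) / 1, 0.2)
  expect_lt(abs(pc$b - M) / M, 0.2)
})

test_that("permutation calibration is deterministic and adaptive", {
  set.seed(25)
  G <- matrix(stats::rbinom(150 * 30, 2, 0.3), 150, 30)
  y <- stats::rnorm(150)
  p1 <- permute_calibrate(G, y, seed = 7)
  p2 <- permute_calibrate(G, y, seed = 7)
  expect_identical(p1$minima, p2$minima)
  expect_lt(p1$n_permutations, 1000)  # null gene stops early
})

test_that("BH step-up over gene p-values matches hand enumeration", {
  cal <- data.frame(gene_id = c("g1", "g2", "g3"), a = 1, b = 50,
                    p_beta = c(0.001, 0.02, 0.9))
  out <- egene_fdr(cal, fdr = 0.05)
  # step-up oracle: q = cummin over descending ranks of p * n / rank
  q_oracle <- stats::p.adjust(cal$p_beta, method = "BH")
  expect_identical(out$egene, q_oracle < 0.05)
  expect_identical(out$egene, c(TRUE, TRUE, FALSE))
  # all-null input yields zero eGenes
  cal1 <- data.frame(gene_id = c("a", "b"), a = 1, b = 10, p_beta = c(1, 1))
  expect_equal(sum(egene_fdr(cal1)$egene), 0)
  expect_error(egene_fdr(cal[0, ]), "empty")
  # output invariant to input order
  perm <- c(3, 1, 2)
  out2 <- egene_fdr(cal[perm, ])
  expect_identical(out2$egene[match(cal$gene_id, out2$gene_id)], out$egene)
})

test_that("greedy LD clumping handles the extreme-LD limits and matches replay", {
  set.seed(26)
  n <- 200
  base <- stats::rbinom(n, 2, 0.4)
  G_perfect <- matrix(rep(base, 5), n, 5)
  cl <- clump(stats::runif(5), G_perfect, pos = 1:5 * 1000)
  expect_equal(max(cl$clump), 1L)
  G_indep <- matrix(stats::rbinom(n * 5, 2, 0.4), n, 5)
  cl2 <- clump(sort(stats::runif(5)), G_indep, pos = 1:5 * 1000)
  expect_equal(max(cl2$clump), 5L)
  # brute-force greedy replay oracle on a structured 10-variant set
  G10 <- matrix(stats::rbinom(n * 10, 2, 0.4), n, 10)
  G10[, 2] <- G10[, 1]; G10[, 7] <- G10[, 6]; G10[, 8] <- G10[, 6]
  p <- stats::runif(10)
  pos <- (1:10) * 1000
  cl3 <- clump(p, G10, pos)
  replay <- function(p, G, pos) {
    rem <- order(p); k <- 0L; cid <- integer(length(p))
    while (length(rem)) {
      k <- k + 1L; i <- rem[1]
      mem <- i
      for (j in setdiff(rem, i))
        if (abs(pos[j] - pos[i]) <= 1e6 &&
            stats::cor(G[, i], G[, j])^2 > 0.1) mem <- c(mem, j)
      cid[mem] <- k; rem <- setdiff(rem, mem)
    }
    cid
  }
  expect_identical(cl3$clump, replay(p, G10, pos))
})

test_that("eGene discovery controls FDR and beta p is monotone in the minimum p", {
  coh <- small_cohort()
  ex <- small_expression()
  ce <- prepare_expression(ex, as.matrix(coh$covariates))
  cat <- map_cis_eqtls(coh, ce, samples = 1:200, max_permutations = 300,
                       seed = 31, masked_variants = ex$masked_variants)
  cal <- cat$calibration
  # signal genes called, null gene not
  expect_true(cal$egene[cal$gene_id == "gene0001"])
  expect_false(cal$egene[cal$gene_id == "gene0002"])
  # within a gene's calibration, a stronger observed signal gives a
  # smaller beta-approximated gene p
  set.seed(27)
  vars <- which(coh$panel$gene_of_variant == 1)
  G <- coh$dosage[, vars]
  y_strong <- G[, which(apply(G, 2, stats::sd) > 0.3)[1]] + stats::rnorm(200, 0, 2)
  y_weak <- stats::rnorm(200)
  pb_strong <- permute_calibrate(G, y_strong, max_permutations = 300, seed = 9)
  pb_weak <- permute_calibrate(G, y_weak, max_permutations = 300, seed = 9)
  expect_lt(pb_strong$p_beta, pb_weak$p_beta)
  # significant eQTLs lie inside their gene's window
  if (!is.null(cat$signif)) {
    gene_of <- coh$panel$gene_of_variant[match(cat$signif$variant,
                                               coh$panel$variant_id)]
    expect_identical(coh$panel$genes$gene_id[gene_of], cat$signif$gene_id)
  }
})

test_that("scan results are invariant to sample order", {
  coh <- small_cohort()
  ex <- small_expression()
  vars <- which(coh$panel$gene_of_variant == 1)
  G <- coh$dosage[, vars]
  y <- inverse_normal(ex$expr[1, ])
  perm <- sample(200)
  s1 <- cis_scan(G, y)
  s2 <- cis_scan(G[perm, ], y[perm])
  expect_equal(s1$beta, s2$beta, tolerance = 1e-12)
})
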