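#' Prepare expression for eQTL scanning
#'
#' Per gene: inverse-normal transform, then residualization on the
#' supplied covariates, then (optionally) on the top principal
#' components of the covariate-residualized expression matrix. The PCs
#' act as hidden-factor correction, absorbing batch-like structure
#' shared across genes.
#'
#' @param expression Genes x samples matrix (or `expression_dataset`).
#' @param covariates Data frame/matrix of per-sample covariates (may be
#'   NULL).
#' @param n_hidden_factors Number of expression PCs to remove
#'   (`< n_samples / 2`).
#' @return Corrected genes x samples matrix.
#' @export
prepare_expression <- function(expression, covariates = NULL,
                               n_hidden_factors = 0) {
  expr <- if (inherits(expression, "expression_dataset")) expression$expr
          else as.matrix(expression)
  n <- ncol(expr)
  if (n_hidden_factors >= n / 2)
    stop("n_hidden_factors must be < n_samples / 2")
  Y <- t(apply(expr, 1, inverse_normal))
  X <- cbind(rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  Y <- residualize_rows(Y, X)
  if (n_hidden_factors > 0) {
    if (n_hidden_factors >= qr(t(Y))$rank)
      stop("n_hidden_factors exceeds the rank of the expression matrix")
    pcs <- stats::prcomp(t(Y), center = TRUE, rank. = n_hidden_factors)$x
    Y <- residualize_rows(Y, cbind(1, pcs))
  }
  dimnames(Y) <- dimnames(expr)
  Y
}

#' Per-variant cis scan of one gene
#'
#' Simple linear regression of corrected expression on each variant's
#' dosage: slope, standard error, t statistic and two-sided p from the
#' t distribution with n - 2 degrees of freedom. Zero-variance dosage
#' columns are skipped.
#'
#' @param dosage n x m cis-window dosage matrix (column names = variant
#'   ids).
#' @param y Corrected expression vector.
#' @return data.frame of class `cis_scan`: `variant`, `beta`, `se`,
#'   `t`, `p` (one row per informative variant).
#' @export
cis_scan <- function(dosage, y) {
  dosage <- as.matrix(dosage)
  n <- length(y)
  stopifnot(nrow(dosage) == n)
  sds <- apply(dosage, 2, stats::sd)
  ok <- which(sds > 0)
  Gc <- sweep(dosage[, ok, drop = FALSE], 2, colMeans(dosage[, ok, drop = FALSE]))
  yc <- y - mean(y)
  ss <- colSums(Gc^2)
  beta <- as.numeric(crossprod(Gc, yc)) / ss
  rss <- sum(yc^2) - beta^2 * ss
  se <- sqrt(pmax(rss, 1e-300) / ((n - 2) * ss))
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- data.frame(variant = colnames(dosage)[ok] %||% ok,
                    beta = beta, se = se, t = tstat, p = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("cis_scan", "data.frame")
  out
}

# maximum-likelihood Beta(a, b) fit (method-of-moments start)
.fit_beta_ml <- function(x) {
  eps <- 1e-12
  x <- pmin(pmax(x, eps), 1 - eps)
  m <- mean(x); v <- stats::var(x)
  if (v < 1e-12) v <- 1e-12
  c0 <- max(m * (1 - m) / v - 1, 0.1)
  par0 <- log(c(max(m * c0, 1e-3), max((1 - m) * c0, 1e-3)))
  nll <- function(lp) -sum(stats::dbeta(x, exp(lp[1]), exp(lp[2]), log = TRUE))
  opt <- stats::optim(par0, nll, method = "Nelder-Mead",
                      control = list(maxit = 500))
  exp(opt$par)
}

#' Permutation calibration of a gene's minimum cis p-value
#'
#' Permutes expression across samples, records the minimum nominal
#' p-value per permutation, and fits a Beta(a, b) distribution to the
#' minima by maximum likelihood; the beta-approximated gene-level p is
#' the fitted CDF at the observed minimum. Permutation runs adaptively:
#' it stops once at least `min_exceed` permutation minima beat the
#' observed minimum (the gene is then clearly not significant) or after
#' `max_permutations`.
#'
#' @param dosage n x m cis dosage matrix.
#' @param y Corrected expression vector.
#' @param max_permutations Upper bound on permutations (>= 100).
#' @param min_exceed Early-stop exceedance count (default 30).
#' @param seed Integer seed.
#' @return List of class `permutation_calibration`: `p_min_obs`, `a`,
#'   `b`, `p_beta`, `p_empirical`, `n_permutations`, `degenerate`,
#'   `minima`.
#' @export
permute_calibrate <- function(dosage, y, max_permutations = 1000,
                              min_exceed = 30, seed = 1) {
  if (max_permutations < 100) stop("max_permutations must be >= 100")
  dosage <- as.matrix(dosage)
  n <- length(y)
  sds <- apply(dosage, 2, stats::sd)
  G <- scale(dosage[, sds > 0, drop = FALSE])

  r_to_p <- function(r) {
    r <- pmin(abs(r), 1 - 1e-15)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  }
  ys <- as.numeric(scale(y))
  r_obs <- abs(crossprod(G, ys) / (n - 1))
  p_min_obs <- r_to_p(max(r_obs))

  with_seed(substream_seed(seed, "permute"), {
    minima <- numeric(0)
    exceed <- 0L
    batch <- 100L
    while (length(minima) < max_permutations) {
      nb <- min(batch, max_permutations - length(minima))
      Yp <- matrix(ys[sample.int(n)], n, 1)
      if (nb > 1) {
        Yp <- vapply(seq_len(nb), function(i) ys[sample.int(n)],
                     numeric(n))
      }
      R <- abs(crossprod(G, Yp)) / (n - 1)
      rmax <- apply(R, 2, max)
      minima <- c(minima, r_to_p(rmax))
      exceed <- sum(minima <= p_min_obs)
      if (length(minima) >= 100 && exceed >= min_exceed) break
    }

    n_perm <- length(minima)
    p_emp <- (1 + sum(minima <= p_min_obs)) / (1 + n_perm)
    degenerate <- stats::sd(minima) < 1e-15
    if (degenerate) {
      a <- b <- NA_real_
      p_beta <- p_emp
    } else {
      x <- minima
      ties <- duplicated(x)
      if (any(ties)) x[ties] <- x[ties] * (1 + 1e-12 * seq_len(sum(ties)))
      ab <- .fit_beta_ml(x)
      a <- ab[1]; b <- ab[2]
      p_beta <- stats::pbeta(p_min_obs, a, b)
    }
    structure(list(p_min_obs = p_min_obs, a = a, b = b, p_beta = p_beta,
                   p_empirical = p_emp, n_permutations = n_perm,
                   degenerate = degenerate, minima = minima),
              class = "permutation_calibration")
  })
}

#' eGene discovery and gene-specific nominal thresholds
#'
#' Benjamini-Hochberg step-up across the beta-approximated gene-level
#' p-values; eGenes are genes significant at the given FDR. Each
#' significant gene receives a nominal p-value threshold by inverting
#' its fitted beta distribution at the gene-level significance boundary
#' (the midpoint between the largest significant and smallest
#' non-significant beta-approximated p).
#'
#' @param calibrations data.frame with columns `gene_id`, `a`, `b`,
#'   `p_beta` (one row per gene), e.g. from [map_cis_eqtls()].
#' @param fdr FDR level (default 0.05).
#' @return data.frame: `gene_id`, `p_beta`, `q`, `egene`,
#'   `nominal_threshold` (NA for non-eGenes).
#' @export
egene_fdr <- function(calibrations, fdr = 0.05) {
  if (!nrow(calibrations)) stop("empty calibration table")
  stopifnot(all(c("gene_id", "a", "b", "p_beta") %in% names(calibrations)))
  q <- stats::p.adjust(calibrations$p_beta, method = "BH")
  egene <- q < fdr
  thr <- rep(NA_real_, nrow(calibrations))
  if (any(egene)) {
    p_max_sig <- max(calibrations$p_beta[egene])
    p_min_ns <- if (any(!egene)) min(calibrations$p_beta[!egene]) else 1
    p_star <- (p_max_sig + p_min_ns) / 2
    thr[egene] <- stats::qbeta(p_star, calibrations$a[egene],
                               calibrations$b[egene])
  }
  data.frame(gene_id = calibrations$gene_id, p_beta = calibrations$p_beta,
             q = q, egene = egene, nominal_threshold = thr,
             stringsAsFactors = FALSE)
}

#' Greedy LD clumping of significant variants
#'
#' Takes the most significant remaining variant as an index, absorbs
#' every variant within the window whose dosage r-squared with the index
#' exceeds `r2_max`, and repeats; mirrors PLINK's
#' `--clump-kb 1000 --clump-r2 0.1`.
#'
#' @param p Nominal p-values of the candidate variants.
#' @param dosage n x m dosage matrix of the same variants (mean-imputed
#'   if it contains NAs).
#' @param pos Genomic positions of the variants.
#' @param r2_max Clumping r-squared threshold (default 0.1).
#' @param window_kb Clumping window (default 1000).
#' @return data.frame: `variant` (column index), `clump`, `is_index`.
#' @export
clump <- function(p, dosage, pos, r2_max = 0.1, window_kb = 1000) {
  dosage <- as.matrix(dosage)
  m <- length(p)
  stopifnot(ncol(dosage) == m, length(pos) == m)
  if (anyNA(dosage)) {
    mu <- colMeans(dosage, na.rm = TRUE)
    for (j in seq_len(m)) dosage[is.na(dosage[, j]), j] <- mu[j]
  }
  remaining <- order(p)
  clump_id <- integer(m)
  is_index <- logical(m)
  k <- 0L
  while (length(remaining)) {
    k <- k + 1L
    idx <- remaining[1]
    is_index[idx] <- TRUE
    near <- remaining[abs(pos[remaining] - pos[idx]) <= window_kb * 1000]
    r2 <- suppressWarnings(stats::cor(dosage[, idx], dosage[, near]))^2
    r2[is.na(r2)] <- 0
    members <- c(idx, near[r2 > r2_max])
    clump_id[unique(members)] <- k
    remaining <- setdiff(remaining, members)
  }
  data.frame(variant = seq_len(m), clump = clump_id, is_index = is_index)
}

#' Full cis-eQTL mapping pass over a set of genes
#'
#' For each gene: scans typed cis variants passing the MAF filter in the
#' selected samples, runs adaptive permutation calibration, and collects
#' per-gene summaries. Then applies BH across genes, derives
#' gene-specific nominal thresholds, and (for eGenes) clumps significant
#' variants into LD-independent signals.
#'
#' @param cohort An `admixed_cohort`.
#' @param corrected_expr Genes x samples matrix from
#'   [prepare_expression()] (full cohort width; `samples` selects
#'   columns).
#' @param samples Integer sample indices to analyze.
#' @param genes Gene indices (default all).
#' @param maf_min MAF filter within the analyzed samples.
#' @param max_permutations,fdr,seed Tuning knobs, see
#'   [permute_calibrate()] and [egene_fdr()].
#' @param masked_variants Variant ids to exclude (defaults to none).
#' @return List of class `eqtl_catalog`: `scans` (per-gene `cis_scan`
#'   with variant ids/positions), `calibration` (per-gene a, b, p_beta,
#'   q, egene, nominal_threshold), `signif` (per-variant significant
#'   eQTLs with clump assignment).
#' @export
map_cis_eqtls <- function(cohort, corrected_expr, samples,
                          genes = NULL, maf_min = 0.01,
                          max_permutations = 1000, fdr = 0.05, seed = 1,
                          masked_variants = character(0)) {
  panel <- cohort$panel
  genes <- genes %||% seq_len(nrow(panel$genes))
  scans <- list()
  calib <- list()
  for (g in genes) {
    vars <- which(panel$gene_of_variant == g &
                  !(panel$variant_id %in% masked_variants))
    G <- cohort$dosage[samples, vars, drop = FALSE]
    maf <- maf_from_dosage(G)
    keep <- maf >= maf_min
    if (!any(keep)) {
      calib[[length(calib) + 1]] <- data.frame(
        gene_id = panel$genes$gene_id[g], a = NA, b = NA, p_beta = NA,
        p_empirical = NA, n_permutations = 0, p_min_obs = NA)
      next
    }
    vars <- vars[keep]
    G <- G[, keep, drop = FALSE]
    colnames(G) <- panel$variant_id[vars]
    y <- corrected_expr[g, samples]
    sc <- cis_scan(G, y)
    sc$gene_id <- panel$genes$gene_id[g]
    sc$pos <- panel$pos[vars[match(sc$variant, panel$variant_id[vars])]]
    scans[[panel$genes$gene_id[g]]] <- sc
    pc <- permute_calibrate(G, y, max_permutations = max_permutations,
                            seed = substream_seed(seed, paste0("perm_g", g)))
    calib[[length(calib) + 1]] <- data.frame(
      gene_id = panel$genes$gene_id[g], a = pc$a, b = pc$b,
      p_beta = pc$p_beta, p_empirical = pc$p_empirical,
      n_permutations = pc$n_permutations, p_min_obs = pc$p_min_obs)
  }
  calib <- do.call(rbind, calib)
  fdr_tab <- egene_fdr(calib[!is.na(calib$p_beta), ], fdr = fdr)
  calib <- merge(calib, fdr_tab[, c("gene_id", "q", "egene", "nominal_threshold")],
                 by = "gene_id", all.x = TRUE, sort = FALSE)
  calib$egene[is.na(calib$egene)] <- FALSE

  signif <- list()
  for (gid in calib$gene_id[calib$egene]) {
    thr <- calib$nominal_threshold[calib$gene_id == gid]
    sc <- scans[[gid]]
    hits <- sc[sc$p < thr, , drop = FALSE]
    if (!nrow(hits)) next
    g_idx <- match(hits$variant, cohort$panel$variant_id)
    cl <- clump(hits$p, cohort$dosage[samples, g_idx, drop = FALSE],
                cohort$panel$pos[g_idx])
    hits$clump <- cl$clump
    hits$is_index <- cl$is_index
    signif[[gid]] <- hits
  }
  structure(list(scans = scans, calibration = calib,
                 signif = if (length(signif)) do.call(rbind, signif) else NULL,
                 samples = samples, fdr = fdr),
            class = "eqtl_catalog")
}
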