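#' Build a cis-region kinship matrix
#'
#' Standardized method: columns of the dosage matrix are standardized by
#' allele frequency, `(g - 2p)/sqrt(2p(1-p))`, and `K = X X' / m`.
#' LDAK-Thin method: variants are first greedily pruned so that no pair
#' within `window_kb` retains squared correlation above `r2_prune`
#' (duplicate-tag thinning), then the standardized kinship is computed
#' on the survivors. Variants with MAF below `maf_min` are excluded
#' before either method.
#'
#' @param dosage n x m dosage matrix for the cis-region (values in
#'   [0, 2]); column names are variant ids.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param method `"standardized"` or `"ldak_thin"`.
#' @param pos Variant positions (required for `ldak_thin`).
#' @param window_kb Pruning window for `ldak_thin` (default 100).
#' @param r2_prune Pruning r-squared threshold (default 0.98).
#' @return Object of class `cis_kinship`: `K`, `n_variants`, `method`,
#'   `maf_min`, `variants` (retained column indices).
#' @export
build_kinship <- function(dosage, maf_min = 0.01,
                          method = c("standardized", "ldak_thin"),
                          pos = NULL, window_kb = 100, r2_prune = 0.98) {
  method <- match.arg(method)
  dosage <- as.matrix(dosage)
  maf <- maf_from_dosage(dosage)
  v <- apply(dosage, 2, stats::var)
  keep <- which(maf >= maf_min & maf > 0 & v > 0)
  if (!length(keep)) stop("no informative variants after MAF filtering")

  if (method == "ldak_thin") {
    if (is.null(pos)) stop("ldak_thin requires variant positions")
    stopifnot(length(pos) == ncol(dosage))
    ord <- keep[order(pos[keep])]
    kept <- integer(0)
    for (j in ord) {
      near <- kept[abs(pos[kept] - pos[j]) <= window_kb * 1000]
      if (length(near)) {
        r2 <- suppressWarnings(stats::cor(dosage[, j], dosage[, near]))^2
        if (any(r2 > r2_prune, na.rm = TRUE)) next
      }
      kept <- c(kept, j)
    }
    keep <- kept
    if (!length(keep)) stop("no informative variants after LD thinning")
  }

  Z <- standardize_dosage(dosage[, keep, drop = FALSE])
  keep <- keep[attr(Z, "keep")]
  m <- ncol(Z)
  if (!m) stop("no informative variants after MAF filtering")
  K <- tcrossprod(Z) / m

  structure(list(K = K, n_variants = m, method = method,
                 maf_min = maf_min, variants = keep),
            class = "cis_kinship")
}

# restricted log-likelihood for V built from rotated single-kinship model;
# internal: lambda = sigma2_g / sigma2_e
.reml1_profile <- function(lambda, d, ystar, Xstar) {
  n <- length(ystar); p <- ncol(Xstar)
  v <- 1 + lambda * d
  if (any(v <= 0)) return(list(logL = -Inf))
  w <- 1 / v
  XtWX <- crossprod(Xstar, Xstar * w)
  XtWy <- crossprod(Xstar, ystar * w)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(logL = -Inf))
  b <- backsolve(ch, forwardsolve(t(ch), XtWy))
  quad <- sum(ystar^2 * w) - sum(XtWy * b)
  if (quad <= 0) return(list(logL = -Inf))
  s2e <- quad / (n - p)
  logL <- -0.5 * (sum(log(v)) + (n - p) * log(s2e) + 2 * sum(log(diag(ch))) +
                  (n - p) + (n - p) * log(2 * pi))
  list(logL = logL, s2e = s2e, beta = b)
}

#' Unconstrained REML fit of cis genetic variance components
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sigma2_g K)` (one term per
#' kinship) and `e ~ N(0, sigma2_e I)` by restricted maximum likelihood
#' without a positivity constraint on the genetic components, so
#' estimates (and the derived h2) may fall below zero, mirroring
#' unconstrained GREML. Single-kinship fits use an exact
#' eigendecomposition profile over the variance ratio; multi-kinship
#' fits (e.g. MAF-bin partitioning) use average-information updates with
#' step-halving when a step leaves the positive-definite region.
#' The likelihood-ratio test of `sigma2_g = 0` uses the boundary-mixture
#' reference 0.5*chi2_0 + 0.5*chi2_1.
#'
#' @param kinships A `cis_kinship` or list of them.
#' @param y Phenotype vector (typically inverse-normalized residualized
#'   expression).
#' @param covariates Optional matrix/data.frame of fixed-effect
#'   covariates (an intercept is always included).
#' @param constrain If TRUE, genetic components are floored at zero.
#' @param max_iter,tol AI-REML iteration controls (relative logL change).
#' @return Object of class `reml_fit`: `sigma2_g` (per component),
#'   `sigma2_e`, `h2`, `V_G`, `logL`, `logL0`, `lrt_p`, `converged`,
#'   `n_iter`.
#' @export
reml_fit <- function(kinships, y, covariates = NULL, constrain = FALSE,
                     max_iter = 100, tol = 1e-6) {
  if (inherits(kinships, "cis_kinship")) kinships <- list(kinships)
  Ks <- lapply(kinships, function(k) {
    if (inherits(k, "cis_kinship")) k$K else as.matrix(k)
  })
  n <- length(y)
  stopifnot(all(vapply(Ks, nrow, 1L) == n))
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
  }
  if (qr(X)$rank < ncol(X)) stop("singular covariate design")
  p <- ncol(X)

  # null model: iid residuals
  qrX <- qr(X)
  r0 <- qr.resid(qrX, y)
  s2_0 <- sum(r0^2) / (n - p)
  R <- qr.R(qrX)
  logL0 <- -0.5 * ((n - p) * log(s2_0) + 2 * sum(log(abs(diag(R)))) +
                   (n - p) + (n - p) * log(2 * pi))

  if (length(Ks) == 1L) {
    eg <- eigen(Ks[[1]], symmetric = TRUE)
    d <- eg$values
    if (max(d) - min(d) < 1e-10 * max(1, abs(max(d)))) {
      # kinship proportional to identity: genetic and residual variance
      # are not separable
      return(structure(list(sigma2_g = 0, sigma2_e = s2_0, h2 = 0, V_G = 0,
                            logL = logL0, logL0 = logL0, lrt = 0, lrt_p = 1,
                            converged = FALSE, n_iter = 0L, n = n,
                            n_components = 1L),
                       class = "reml_fit"))
    }
    ystar <- crossprod(eg$vectors, y)[, 1]
    Xstar <- crossprod(eg$vectors, X)
    dmax <- max(d)
    lo <- if (constrain) 0 else -1 / dmax + 1e-6
    grid <- unique(c(if (!constrain) seq(lo, 0, length.out = 8), 0,
                     exp(seq(log(1e-4), log(100), length.out = 30))))
    ll <- vapply(grid, function(l) .reml1_profile(l, d, ystar, Xstar)$logL, 1)
    i <- which.max(ll)
    bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
    opt <- stats::optimize(function(l) .reml1_profile(l, d, ystar, Xstar)$logL,
                           interval = bracket, maximum = TRUE, tol = 1e-9)
    lam <- opt$maximum
    prof <- .reml1_profile(lam, d, ystar, Xstar)
    s2e <- prof$s2e
    s2g <- lam * s2e
    logL <- prof$logL
    converged <- TRUE
    n_iter <- NA_integer_
  } else {
    comps <- c(Ks, list(diag(n)))
    nc <- length(comps)
    s <- rep(stats::var(y) / nc, nc)

    logL_at <- function(s) {
      V <- matrix(0, n, n)
      for (i in seq_len(nc)) V <- V + s[i] * comps[[i]]
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      Vinv <- chol2inv(ch)
      XtVX <- crossprod(X, Vinv %*% X)
      ch2 <- tryCatch(chol(XtVX), error = function(e) NULL)
      if (is.null(ch2)) return(NULL)
      P <- Vinv - Vinv %*% X %*% chol2inv(ch2) %*% crossprod(X, Vinv)
      Py <- P %*% y
      logL <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) +
                      sum(y * Py) + (n - p) * log(2 * pi))
      list(logL = logL, P = P, Py = Py)
    }

    st <- logL_at(s)
    if (is.null(st)) { s <- abs(s); st <- logL_at(s) }
    converged <- FALSE
    n_iter <- 0L
    for (it in seq_len(max_iter)) {
      n_iter <- it
      KPy <- lapply(comps, function(K) K %*% st$Py)
      score <- vapply(seq_len(nc), function(i) {
        -0.5 * (sum(st$P * comps[[i]]) - sum(st$Py * KPy[[i]]))
      }, 1)
      AI <- matrix(0, nc, nc)
      for (i in seq_len(nc)) for (j in i:nc) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * (st$P %*% KPy[[j]]))
      }
      delta <- tryCatch(solve(AI, score), error = function(e) score / diag(AI))
      step <- 1
      repeat {
        s_new <- s + step * delta
        if (constrain) s_new[seq_len(nc - 1)] <- pmax(s_new[seq_len(nc - 1)], 0)
        cand <- logL_at(s_new)
        if (!is.null(cand) && is.finite(cand$logL)) break
        step <- step / 2
        if (step < 1e-8) { cand <- st; s_new <- s; break }
      }
      dl <- abs(cand$logL - st$logL)
      s <- s_new; st <- cand
      if (dl < tol * (abs(st$logL) + 1)) { converged <- TRUE; break }
    }
    s2g <- s[seq_len(nc - 1)]
    s2e <- s[nc]
    logL <- st$logL
  }

  Vg <- sum(s2g)
  lrt <- max(0, 2 * (logL - logL0))
  lrt_p <- 0.5 * stats::pchisq(lrt, df = length(Ks), lower.tail = FALSE)
  structure(list(sigma2_g = s2g, sigma2_e = s2e,
                 h2 = Vg / (Vg + s2e), V_G = Vg,
                 logL = logL, logL0 = logL0, lrt = lrt, lrt_p = lrt_p,
                 converged = converged, n_iter = n_iter,
                 n = n, n_components = length(Ks)),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit: sigma2_g =", paste(signif(x$sigma2_g, 4), collapse = " + "),
      " sigma2_e =", signif(x$sigma2_e, 4),
      " h2 =", signif(x$h2, 4),
      " LRT p =", signif(x$lrt_p, 3),
      if (!x$converged) " (not converged)" else "", "\n")
  invisible(x)
}

#' Compare heritability or genetic-variance distributions between groups
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie and
#' continuity correction), reporting group medians.
#'
#' @param estimates_a,estimates_b Numeric vectors (e.g. per-gene h2 in
#'   two ancestry groups).
#' @return List with `statistic`, `p_value`, `median_a`, `median_b`,
#'   `n_a`, `n_b`.
#' @export
compare_groups <- function(estimates_a, estimates_b) {
  if (!length(estimates_a) || !length(estimates_b))
    stop("both groups must be non-empty")
  if (stats::sd(c(estimates_a, estimates_b)) == 0) {
    # complete tie: no evidence of a shift in either direction
    return(list(statistic = length(estimates_a) * length(estimates_b) / 2,
                p_value = 1,
                median_a = stats::median(estimates_a),
                median_b = stats::median(estimates_b),
                n_a = length(estimates_a), n_b = length(estimates_b)))
  }
  wt <- stats::wilcox.test(estimates_a, estimates_b, exact = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_a = stats::median(estimates_a),
       median_b = stats::median(estimates_b),
       n_a = length(estimates_a), n_b = length(estimates_b))
}

#' Per-gene cis-heritability across a cohort
#'
#' Convenience scan: for each gene, takes the cis-region dosages of the
#' selected samples (typed variants only), builds the kinship, and fits
#' unconstrained REML on the inverse-normalized expression phenotype
#' with age, sex, asthma and (optionally) global ancestry proportions as
#' fixed covariates.
#'
#' @param cohort An `admixed_cohort`.
#' @param expression An `expression_dataset` (or expression matrix).
#' @param samples Integer indices of individuals to use (default all).
#' @param genes Gene indices (default all).
#' @param method Kinship method, see [build_kinship()].
#' @param maf_min MAF filter.
#' @param maf_bins Optional numeric breaks (e.g. `c(0.01, 0.1, 0.5)`)
#'   for MAF-partitioned fits; overrides `method` with one standardized
#'   kinship per bin.
#' @param include_ancestry Include global ancestry proportions as
#'   covariates (analogous to genotype PCs).
#' @return data.frame with one row per gene: variance components, h2,
#'   V_G, LRT p, convergence flag.
#' @export
estimate_cis_h2 <- function(cohort, expression, samples = NULL, genes = NULL,
                            method = "standardized", maf_min = 0.01,
                            maf_bins = NULL, include_ancestry = TRUE) {
  expr <- if (inherits(expression, "expression_dataset")) expression$expr
          else as.matrix(expression)
  panel <- cohort$panel
  samples <- samples %||% seq_len(nrow(cohort$dosage))
  genes <- genes %||% seq_len(nrow(panel$genes))
  typed <- typed_variants(cohort,
                          if (inherits(expression, "expression_dataset")) expression)
  covs <- as.matrix(cohort$covariates[samples, c("age", "sex", "asthma")])
  if (include_ancestry) {
    th <- cohort$theta[samples, -ncol(cohort$theta), drop = FALSE]
    if (stats::sd(th[, 1]) > 0) covs <- cbind(covs, theta = th)
  }

  rows <- lapply(genes, function(g) {
    vars <- intersect(which(panel$gene_of_variant == g), typed)
    G <- cohort$dosage[samples, vars, drop = FALSE]
    y <- inverse_normal(expr[g, samples])
    fit <- tryCatch({
      if (!is.null(maf_bins)) {
        maf <- maf_from_dosage(G)
        ks <- list()
        for (b in seq_len(length(maf_bins) - 1)) {
          in_bin <- maf >= maf_bins[b] & maf < maf_bins[b + 1]
          if (sum(in_bin) > 0)
            ks <- c(ks, list(build_kinship(G[, in_bin, drop = FALSE],
                                           maf_min = maf_bins[1])))
        }
        if (!length(ks)) stop("no informative variants")
        reml_fit(ks, y, covs)
      } else {
        k <- build_kinship(G, maf_min = maf_min, method = method,
                           pos = panel$pos[vars])
        reml_fit(k, y, covs)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(gene_id = panel$genes$gene_id[g], n = length(samples),
                 sigma2_g = NA_real_, sigma2_e = NA_real_, h2 = NA_real_,
                 V_G = NA_real_, lrt_p = NA_real_, converged = FALSE)
    } else {
      data.frame(gene_id = panel$genes$gene_id[g], n = length(samples),
                 sigma2_g = sum(fit$sigma2_g), sigma2_e = fit$sigma2_e,
                 h2 = fit$h2, V_G = fit$V_G, lrt_p = fit$lrt_p,
                 converged = fit$converged)
    }
  })
  do.call(rbind, rows)
}
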