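#' Residualize inverse-normalized expression on basic covariates
#'
#' Step one of the stepwise ancestry-association procedure: per gene,
#' expression is inverse-normal transformed and regressed on age, sex
#' and asthma status; the residuals feed the global- and local-ancestry
#' regressions.
#'
#' @param expression Genes x samples matrix (or `expression_dataset`).
#' @param covariates Data frame with `age`, `sex`, `asthma` (no missing
#'   values).
#' @param int Apply the inverse-normal transform before residualizing
#'   (default TRUE; set FALSE when the input is already on a normalized
#'   scale).
#' @return List: `residuals` (genes x samples) and `flagged` (logical,
#'   genes with constant expression whose residuals are all zero).
#' @export
model0_residuals <- function(expression, covariates, int = TRUE) {
  expr <- if (inherits(expression, "expression_dataset")) expression$expr
          else as.matrix(expression)
  covariates <- as.data.frame(covariates)
  stopifnot(!anyNA(covariates), ncol(expr) == nrow(covariates))
  X <- cbind(1, as.matrix(covariates[, c("age", "sex", "asthma")]))
  flagged <- apply(expr, 1, function(x) stats::sd(x) == 0)
  Y <- expr
  if (int) for (g in which(!flagged)) Y[g, ] <- inverse_normal(expr[g, ])
  Y[flagged, ] <- 0
  res <- residualize_rows(Y, X)
  res[flagged, ] <- 0
  list(residuals = res, flagged = flagged)
}

# per-gene simple regression of each row of Y on x; returns beta, p
.row_simple_lm <- function(Y, x) {
  n <- length(x)
  sx <- stats::sd(x)
  if (is.na(sx) || sx == 0)
    return(data.frame(beta = rep(NA_real_, nrow(Y)), p = NA_real_))
  xc <- x - mean(x)
  ss <- sum(xc^2)
  Yc <- Y - rowMeans(Y)
  beta <- as.numeric(Yc %*% xc) / ss
  rss <- rowSums(Yc^2) - beta^2 * ss
  se <- sqrt(pmax(rss, 0) / ((n - 2) * ss))
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  data.frame(beta = beta, p = p)
}

#' Stepwise association of global and local ancestry with expression
#'
#' Implements the residual-on-residual cascade: model-0 residuals are
#' regressed on global ancestry (model 1), and the model-1 residuals on
#' the local ancestry allele count at the TSS (model 2), per gene.
#' Benjamini-Hochberg FDR is applied within each step separately.
#' Local ancestry uses additive allele-count coding (0/1/2).
#'
#' @param residuals Genes x samples matrix from [model0_residuals()].
#' @param theta Global ancestry proportion for the ancestry of interest
#'   (numeric vector over samples).
#' @param local_anc Genes x samples matrix (or samples vector, recycled)
#'   of local ancestry allele counts for the same ancestry.
#' @param fdr FDR level used for the significance flags (default 0.05).
#' @return data.frame per gene: `beta_global`, `p_global`, `q_global`,
#'   `sig_global`, `beta_local`, `p_local`, `q_local`, `sig_local`.
#'   Genes with zero-variance predictors get NA rows.
#' @export
stepwise_ancestry_assoc <- function(residuals, theta, local_anc, fdr = 0.05) {
  residuals <- as.matrix(residuals)
  n_genes <- nrow(residuals)
  stopifnot(length(theta) == ncol(residuals))
  if (is.null(dim(local_anc)))
    local_anc <- matrix(local_anc, n_genes, ncol(residuals), byrow = TRUE)
  stopifnot(dim(local_anc)[1] == n_genes)

  m1 <- .row_simple_lm(residuals, theta)
  # model-1 residuals
  xc <- theta - mean(theta)
  r1 <- residuals - rowMeans(residuals) - outer(m1$beta, xc)
  r1[is.na(m1$beta), ] <- residuals[is.na(m1$beta), ]

  beta_l <- p_l <- rep(NA_real_, n_genes)
  for (g in seq_len(n_genes)) {
    la <- local_anc[g, ]
    if (stats::sd(la) == 0) next
    f <- .row_simple_lm(r1[g, , drop = FALSE], la)
    beta_l[g] <- f$beta; p_l[g] <- f$p
  }

  q_g <- stats::p.adjust(m1$p, method = "BH")
  q_l <- stats::p.adjust(p_l, method = "BH")
  data.frame(beta_global = m1$beta, p_global = m1$p, q_global = q_g,
             sig_global = !is.na(q_g) & q_g < fdr,
             beta_local = beta_l, p_local = p_l, q_local = q_l,
             sig_local = !is.na(q_l) & q_l < fdr)
}

#' Joint variance in expression explained by global and local ancestry
#'
#' Per gene, model-0 residuals are regressed jointly on global and local
#' ancestry; the R-squared is attributed by sequential sums of squares in
#' both orders (global first, then local increment, and vice versa).
#' Fully collinear predictors are reported with a flag and a zero
#' increment for the second term.
#'
#' @param residuals Genes x samples matrix from [model0_residuals()].
#' @param theta Global ancestry vector.
#' @param local_anc Genes x samples matrix of local ancestry counts.
#' @return data.frame per gene: `r2_joint`, `r2_global_first`,
#'   `r2_local_increment`, `r2_local_first`, `r2_global_increment`,
#'   `collinear`.
#' @export
joint_variance_explained <- function(residuals, theta, local_anc) {
  residuals <- as.matrix(residuals)
  n_genes <- nrow(residuals)
  if (is.null(dim(local_anc)))
    local_anc <- matrix(local_anc, n_genes, ncol(residuals), byrow = TRUE)

  out <- data.frame(r2_joint = rep(NA_real_, n_genes),
                    r2_global_first = NA_real_, r2_local_increment = NA_real_,
                    r2_local_first = NA_real_, r2_global_increment = NA_real_,
                    collinear = FALSE)
  r2_of <- function(y, X) {
    fit <- stats::lm.fit(cbind(1, X), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  for (g in seq_len(n_genes)) {
    y <- residuals[g, ]
    if (stats::sd(y) == 0) next
    la <- local_anc[g, ]
    X <- cbind(theta, la)
    collinear <- qr(cbind(1, X))$rank < 3
    r2g <- if (stats::sd(theta) > 0) r2_of(y, theta) else 0
    r2l <- if (stats::sd(la) > 0) r2_of(y, la) else 0
    r2j <- if (collinear) max(r2g, r2l) else r2_of(y, X)
    out$r2_joint[g] <- r2j
    out$r2_global_first[g] <- r2g
    out$r2_local_increment[g] <- r2j - r2g
    out$r2_local_first[g] <- r2l
    out$r2_global_increment[g] <- r2j - r2l
    out$collinear[g] <- collinear
  }
  out
}
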