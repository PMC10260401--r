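#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomized operations in the package draw their RNG state from a
#' single user-supplied seed through named streams, so that each stage
#' (panel, genotypes, expression, permutations, ...) is reproducible on
#' its own and insensitive to the order in which other stages run.
#'
#' @param seed Integer master seed.
#' @param stream Character stream name.
#' @return An integer seed in [0, 2^31 - 1).
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # deterministic string hash (polynomial rolling, 31-bit)
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(stream)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Rank-based inverse-normal transform
#'
#' Maps a numeric vector to normal quantiles of its mid-ranks,
#' `qnorm((rank - 0.5)/n)`, the standard transform applied to expression
#' phenotypes before heritability and eQTL analysis.
#'
#' @param x Numeric vector (NAs not allowed).
#' @return Transformed vector with the same sample ranks as `x`.
#' @export
inverse_normal <- function(x) {
  stopifnot(!anyNA(x))
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
}

# least-squares residuals of each row of Y (genes x samples) on design X
residualize_rows <- function(Y, X) {
  X <- as.matrix(X)
  qrX <- qr(X)
  t(qr.resid(qrX, t(Y)))
}

# column-standardize a dosage matrix using allele frequency p:
# (g - 2p)/sqrt(2p(1-p)); columns with zero heterozygosity are dropped
standardize_dosage <- function(G) {
  p <- colMeans(G) / 2
  het <- 2 * p * (1 - p)
  keep <- het > 0
  Z <- sweep(G[, keep, drop = FALSE], 2, 2 * p[keep], "-")
  Z <- sweep(Z, 2, sqrt(het[keep]), "/")
  attr(Z, "keep") <- which(keep)
  Z
}

# minor allele frequency from dosages in [0,2]
maf_from_dosage <- function(G) {
  p <- colMeans(as.matrix(G)) / 2
  pmin(p, 1 - p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
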