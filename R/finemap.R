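#' Wakefield approximate Bayes factors from z-scores
#'
#' `ABF = sqrt(se^2/(se^2 + W)) * exp(z^2 W / (2 (se^2 + W)))` with
#' `W = prior_sd^2` the prior effect variance on the standardized scale
#' and `se^2 = 1/n` the approximate sampling variance of a standardized
#' marginal effect.
#'
#' @param z Per-variant z-scores.
#' @param n Sample size behind the z-scores.
#' @param prior_sd Prior effect-size standard deviation (default 0.15).
#' @return Vector of approximate Bayes factors (log scale avoided:
#'   returned on the natural scale relative to the strongest variant is
#'   handled by callers via normalization; values may be very large).
#' @keywords internal
wakefield_abf <- function(z, n, prior_sd = 0.15) {
  se2 <- 1 / n
  W <- prior_sd^2
  shrink <- se2 / (se2 + W)
  sqrt(shrink) * exp(z^2 * (1 - shrink) / 2)
}

# same quantity on the log scale, for safe normalization
.log_abf <- function(z, n, prior_sd) {
  se2 <- 1 / n
  W <- prior_sd^2
  shrink <- se2 / (se2 + W)
  0.5 * log(shrink) + z^2 * (1 - shrink) / 2
}

#' Single-causal-variant posterior inclusion probabilities
#'
#' Under the assumption of exactly one causal variant in the region with
#' a uniform prior over variants, the posterior probability of variant j
#' is its approximate Bayes factor divided by the sum over variants.
#'
#' @param z Per-variant z-scores across the cis window.
#' @param n Sample size.
#' @param prior_sd Prior effect-size sd (default 0.15).
#' @return Numeric vector of posterior probabilities summing to 1.
#' @export
single_causal_posterior <- function(z, n, prior_sd = 0.15) {
  la <- .log_abf(z, n, prior_sd)
  if (!any(is.finite(la))) stop("all Bayes factors are non-finite")
  la <- la - max(la, na.rm = TRUE)
  pp <- exp(la)
  pp[!is.finite(pp)] <- 0
  pp / sum(pp)
}

#' Build a credible set from posterior probabilities
#'
#' Variants are sorted by posterior probability (descending, ties broken
#' by ascending genomic position) and included until the cumulative
#' posterior reaches the level; the set is the minimal such prefix.
#'
#' @param pp Posterior probabilities (should sum to 1).
#' @param level Credible level in (0, 1), default 0.95.
#' @param pos Optional genomic positions for tie-breaking.
#' @param ids Optional variant ids (default indices).
#' @return Object of class `credible_set`: data.frame `members`
#'   (`variant`, `pp`, ordered), `level`, `cum_pp`.
#' @export
credible_set <- function(pp, level = 0.95, pos = seq_along(pp),
                         ids = seq_along(pp)) {
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  ord <- order(-pp, pos)
  cum <- cumsum(pp[ord])
  k <- which(cum >= level)[1]
  if (is.na(k)) k <- length(pp)
  sel <- ord[seq_len(k)]
  structure(list(members = data.frame(variant = ids[sel], pp = pp[sel],
                                      stringsAsFactors = FALSE),
                 level = level, cum_pp = cum[k]),
            class = "credible_set")
}

#' Do two credible sets share any variant?
#'
#' @param cs_a,cs_b `credible_set` objects for the same gene in two
#'   groups.
#' @return TRUE iff the member variant ids intersect.
#' @export
credible_sets_overlap <- function(cs_a, cs_b) {
  length(intersect(cs_a$members$variant, cs_b$members$variant)) > 0
}

#' Cross-population causal-configuration posterior
#'
#' A simplified two-population fine-mapping model assuming at most one
#' causal variant per group: configurations are all pairs (causal
#' variant in the high group or none, causal variant in the low group
#' or none), scored by the product of per-group approximate Bayes
#' factors under a uniform prior over the (M+1) x (M+1) configuration
#' grid. For each variant j the reported quantities are the posterior
#' marginals of j's own causal status: specific to the high group
#' (`pp_high`: causal in high, not in low), specific to the low group
#' (`pp_low`), or shared (`pp_shared`: causal in both). Together with
#' the per-variant null (causal in neither group at j) they sum to 1.
#' Under the uniform prior the posterior factorizes across groups, so
#' the marginals are products of per-group inclusion probabilities.
#'
#' @param z_high,z_low Aligned per-variant z-scores in the two groups.
#' @param n_high,n_low Group sample sizes.
#' @param prior_sd Prior effect sd (default 0.15).
#' @return data.frame: `pp_high`, `pp_low`, `pp_shared` per variant;
#'   per-group no-causal posteriors as attributes `pp_null_high`,
#'   `pp_null_low`.
#' @export
config_posterior <- function(z_high, z_low, n_high, n_low, prior_sd = 0.15) {
  M <- length(z_high)
  if (length(z_low) != M) stop("misaligned variant sets between groups")
  incl <- function(z, n) {
    la <- c(0, .log_abf(z, n, prior_sd))  # leading 0 = no causal in group
    la <- la - max(la)
    w <- exp(la)
    w / sum(w)
  }
  ph <- incl(z_high, n_high)
  pl <- incl(z_low, n_low)
  if (!all(is.finite(ph)) || !all(is.finite(pl)))
    stop("non-finite Bayes factors")
  out <- data.frame(pp_high = ph[-1] * (1 - pl[-1]),
                    pp_low = pl[-1] * (1 - ph[-1]),
                    pp_shared = ph[-1] * pl[-1])
  attr(out, "pp_null_high") <- ph[1]
  attr(out, "pp_null_low") <- pl[1]
  out
}

#' Cochran's Q test of eQTL effect-size heterogeneity between groups
#'
#' Inverse-variance fixed-effect meta-analysis of the two group
#' estimates; for two groups the statistic reduces to
#' `Q = (beta_high - beta_low)^2 / (se_high^2 + se_low^2)`, referred to
#' a chi-squared distribution with 1 degree of freedom.
#'
#' @param beta_high,se_high,beta_low,se_low Effect estimates and
#'   standard errors (vectorized).
#' @return data.frame of class `heterogeneity_test`: `Q`, `df`, `p`.
#' @export
cochran_q <- function(beta_high, se_high, beta_low, se_low) {
  if (any(se_high <= 0) || any(se_low <= 0)) stop("standard errors must be > 0")
  w1 <- 1 / se_high^2; w2 <- 1 / se_low^2
  b_fe <- (w1 * beta_high + w2 * beta_low) / (w1 + w2)
  Q <- w1 * (beta_high - b_fe)^2 + w2 * (beta_low - b_fe)^2
  p <- stats::pchisq(Q, df = 1, lower.tail = FALSE)
  out <- data.frame(Q = Q, df = 1, p = p)
  class(out) <- c("heterogeneity_test", "data.frame")
  out
}
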