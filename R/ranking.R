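# Sentinel used when both group variances are zero but the means differ:
# the site is maximally separable, so it must outrank every finite score.
.score_cap <- 1e12

#' Fisher ratio separability score
#'
#' `(mu1 - mu2)^2 / (var1 + var2)`; symmetric under group exchange.
#' With zero total variance the score is 0 for equal means and a large
#' sentinel (1e12) otherwise, so the ranking stays well defined.
#'
#' @param mu1,mu2 Group means.
#' @param var1,var2 Group-mean variances (model-based).
#' @export
fisher_ratio <- function(mu1, mu2, var1, var2) {
  v <- var1 + var2
  d2 <- (mu1 - mu2)^2
  ifelse(v > 0, d2 / v, ifelse(d2 == 0, 0, .score_cap))
}

#' Standardized mean-difference score
#'
#' `(mu1 - mu2) / sqrt(var1 + var2)`, the model-based analogue of a
#' both-class standardized difference; antisymmetric under group
#' exchange.
#'
#' @inheritParams fisher_ratio
#' @export
z_score <- function(mu1, mu2, var1, var2) {
  v <- var1 + var2
  d <- mu1 - mu2
  ifelse(v > 0, d / sqrt(v), ifelse(d == 0, 0, sign(d) * .score_cap))
}

#' Welch-type t statistic on model-based group means
#'
#' The variance estimates produced by the hierarchical model are already
#' variances of the pooled group means, so the statistic is
#' `(mu1 - mu2) / sqrt(var1 + var2)` with no further division by the
#' replicate count; the replicate counts enter only the
#' Welch–Satterthwaite degrees of freedom
#' `df = (var1 + var2)^2 / (var1^2/(n1-1) + var2^2/(n2-1))` (floored at
#' 1; a single-replicate group contributes infinite uncertainty, giving
#' the conservative df = 1). The p-value is the two-sided Student-t tail.
#'
#' @inheritParams fisher_ratio
#' @param n1,n2 Observed replicates per group.
#' @return List of vectors `t`, `df`, `p`.
#' @export
welch_t <- function(mu1, mu2, var1, var2, n1, n2) {
  v <- var1 + var2
  d <- mu1 - mu2
  t <- ifelse(v > 0, d / sqrt(v), ifelse(d == 0, 0, sign(d) * .score_cap))
  term1 <- ifelse(n1 > 1L, var1^2 / (n1 - 1L), Inf)
  term2 <- ifelse(n2 > 1L, var2^2 / (n2 - 1L), Inf)
  df <- ifelse(v > 0, v^2 / (term1 + term2), 1)
  df[!is.finite(df) | df < 1] <- 1
  p <- 2 * stats::pt(-abs(t), df)
  p <- pmax(p, .Machine$double.xmin)
  degen <- v == 0 & d != 0
  p[degen] <- .Machine$double.xmin
  p[v == 0 & d == 0] <- 1
  list(t = t, df = df, p = p)
}

#' Score every analyzable CpG with the three ranking statistics
#'
#' Computes the Fisher ratio, the standardized difference and the
#' Welch-type t (with its p-value) at every site where both groups were
#' estimated. Deterministic given the estimates.
#'
#' @param estimates A `group_estimates` frame from [fit_all()].
#' @return Data frame with columns `site_idx` (row index into the
#'   estimates/dataset), `chrom`, `pos`, `fisher_ratio`, `z_score`,
#'   `welch_t`, `welch_df`, `p_value`, `meth_diff` (case - control).
#' @export
score_all <- function(estimates) {
  keep <- which(estimates$analyzable)
  e <- estimates[keep, , drop = FALSE]
  w <- welch_t(e$mu_case, e$mu_control, e$var_case, e$var_control,
               e$n_case, e$n_control)
  data.frame(
    site_idx = keep,
    chrom = e$chrom,
    pos = e$pos,
    fisher_ratio = fisher_ratio(e$mu_case, e$mu_control,
                                e$var_case, e$var_control),
    z_score = z_score(e$mu_case, e$mu_control, e$var_case, e$var_control),
    welch_t = w$t,
    welch_df = w$df,
    p_value = w$p,
    meth_diff = e$mu_case - e$mu_control,
    row.names = NULL)
}
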