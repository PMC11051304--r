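#' Log-normal prior on the beta-binomial dispersion
#'
#' Genome-wide empirical-Bayes prior: `log(phi) ~ Normal(m0, r0^2)`.
#' The defaults (`m0 = -3.39`, `r0 = 1.08`) describe the dispersion field
#' of typical RRBS data and are treated as fixed constants, not
#' re-estimated per dataset.
#'
#' @param m0 Mean of `log(phi)`.
#' @param r0 Standard deviation of `log(phi)`; must be positive.
#' @return An object of class `dispersion_prior`.
#' @export
dispersion_prior <- function(m0 = -3.39, r0 = 1.08) {
  stopifnot(is.numeric(m0), is.numeric(r0), r0 > 0)
  structure(list(m0 = m0, r0 = r0), class = "dispersion_prior")
}

#' Mode of the dispersion prior density
#'
#' The log-normal density over `phi` peaks at `exp(m0 - r0^2)`; this is
#' the shrinkage target returned when the data carry no dispersion
#' information (a single replicate, or a degenerate group mean).
#'
#' @param prior A [dispersion_prior()].
#' @export
prior_mode <- function(prior) exp(prior$m0 - prior$r0^2)

#' Mean/dispersion parameterization of the beta distribution
#'
#' `mu = alpha/(alpha+beta)`, `phi = 1/(alpha+beta+1)`.
#'
#' @param alpha,beta Standard beta shape parameters, both positive.
#' @return Named numeric vector `c(mu, phi)`, both in (0, 1).
#' @export
beta_moments <- function(alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("alpha and beta must be positive")
  }
  c(mu = alpha / (alpha + beta), phi = 1 / (alpha + beta + 1))
}

#' Invert the mean/dispersion parameterization
#'
#' @param mu Mean in (0, 1), strictly interior.
#' @param phi Dispersion in (0, 1), strictly interior.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
beta_params_from_moments <- function(mu, phi) {
  if (any(mu <= 0) || any(mu >= 1) || any(phi <= 0) || any(phi >= 1)) {
    stop("mu and phi must lie strictly inside (0, 1)")
  }
  s <- 1 / phi - 1
  c(alpha = mu * s, beta = (1 - mu) * s)
}

#' Pooled-ratio group mean methylation
#'
#' `mu_hat = sum(meth) / sum(total)` over the observed replicates of one
#' group at one site.
#'
#' @param meth,total Integer vectors of equal length (missing replicates
#'   already excluded).
#' @export
estimate_group_mean <- function(meth, total) {
  stopifnot(length(meth) == length(total))
  st <- sum(total)
  if (st <= 0) stop("estimation error: zero total coverage")
  sum(meth) / st
}

# Beta-binomial log likelihood of one group's counts, mean fixed at mu,
# as a function of phi (vectorized over phi).
.bb_loglik <- function(phi, meth, total, mu) {
  s <- 1 / phi - 1
  vapply(s, function(si) {
    a <- mu * si
    b <- (1 - mu) * si
    sum(lchoose(total, meth) + lbeta(meth + a, total - meth + b) -
          lbeta(a, b))
  }, numeric(1))
}

# Penalized objective: beta-binomial log likelihood + log-normal
# log prior density over phi.
.disp_objective <- function(phi, meth, total, mu, prior) {
  .bb_loglik(phi, meth, total, mu) +
    stats::dlnorm(phi, meanlog = prior$m0, sdlog = prior$r0, log = TRUE)
}

#' Empirical-Bayes dispersion estimate for one site and group
#'
#' Maximizes the conditional posterior of `phi` given the plug-in group
#' mean: beta-binomial likelihood of the replicate counts times the
#' log-normal prior density. Optimization is over `log(phi)` on
#' `[1e-6, 1 - 1e-6]` by bounded scalar search (tolerance `1e-8` on the
#' log scale), falling back to a 1000-point log-spaced grid if the search
#' returns a non-finite objective.
#'
#' Between-replicate dispersion is unidentifiable from a single observed
#' replicate, and the likelihood is flat in `phi` when the plug-in mean
#' is 0 or 1; both cases return the prior mode [prior_mode()].
#'
#' @param meth,total Observed replicate counts (no missing entries).
#' @param mu_hat Plug-in group mean from [estimate_group_mean()].
#' @param prior A [dispersion_prior()].
#' @param bounds Search interval for `phi`.
#' @return The dispersion estimate `phi_hat` in (0, 1).
#' @export
estimate_dispersion <- function(meth, total, mu_hat,
                                prior = dispersion_prior(),
                                bounds = c(1e-6, 1 - 1e-6)) {
  stopifnot(length(meth) == length(total), sum(total) > 0)
  if (length(total) < 2L || mu_hat <= 0 || mu_hat >= 1) {
    return(prior_mode(prior))
  }
  obj <- function(t) .disp_objective(exp(t), meth, total, mu_hat, prior)
  opt <- stats::optimize(obj, interval = log(bounds), maximum = TRUE,
                         tol = 1e-8)
  if (!is.finite(opt$objective)) {
    warning("dispersion optimizer returned non-finite objective; ",
            "falling back to grid search")
    grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = 1000L))
    val <- .disp_objective(grid, meth, total, mu_hat, prior)
    return(grid[which.max(val)])
  }
  exp(opt$maximum)
}

#' Model-based variance of the pooled group mean
#'
#' `var_hat = sum(N_k * u(1-u) * (1 + (N_k - 1) phi)) / (sum N_k)^2`.
#' At `phi = 0` this is the binomial variance of the pooled proportion;
#' it grows monotonically with the dispersion. Note this is already the
#' variance of the group *mean*, not a per-replicate variance.
#'
#' @param total Observed replicate total counts.
#' @param mu_hat,phi_hat Group mean and dispersion estimates.
#' @export
estimate_group_variance <- function(total, mu_hat, phi_hat) {
  st <- sum(total)
  if (st <= 0) stop("estimation error: zero total coverage")
  u <- mu_hat * (1 - mu_hat)
  sum(total * u * (1 + (total - 1) * phi_hat)) / st^2
}

#' Fit the beta-binomial model at every site, per group
#'
#' For each CpG site and each group, estimates the pooled mean, the
#' empirical-Bayes dispersion and the variance of the group mean from
#' the observed replicates. Sites where either group has no observed
#' replicate are flagged `analyzable = FALSE` and skipped by the
#' ranking stage.
#'
#' @param ds A (validated, clustered) [meth_dataset()].
#' @param prior A [dispersion_prior()].
#' @return Data frame of class `group_estimates`: one row per site with
#'   columns `chrom`, `pos`, then `mu`, `phi`, `var`, `n_obs`, `reads`
#'   suffixed `_case`/`_control`, and `analyzable`.
#' @export
fit_all <- function(ds, prior = dispersion_prior()) {
  grp_idx <- list(case = which(ds$group == "case"),
                  control = which(ds$group == "control"))
  m <- n_sites(ds)
  out <- data.frame(chrom = ds$sites$chrom, pos = ds$sites$pos)
  for (g in names(grp_idx)) {
    meth_g <- ds$meth[, grp_idx[[g]], drop = FALSE]
    tot_g <- ds$total[, grp_idx[[g]], drop = FALSE]
    mu <- phi <- va <- rep(NA_real_, m)
    nobs <- reads <- rep(0L, m)
    for (i in seq_len(m)) {
      ok <- !is.na(tot_g[i, ])
      if (!any(ok)) next
      mk <- meth_g[i, ok]
      nk <- tot_g[i, ok]
      nobs[i] <- sum(ok)
      reads[i] <- sum(nk)
      mu[i] <- estimate_group_mean(mk, nk)
      phi[i] <- estimate_dispersion(mk, nk, mu[i], prior)
      va[i] <- estimate_group_variance(nk, mu[i], phi[i])
    }
    out[[paste0("mu_", g)]] <- mu
    out[[paste0("phi_", g)]] <- phi
    out[[paste0("var_", g)]] <- va
    out[[paste0("n_", g)]] <- nobs
    out[[paste0("reads_", g)]] <- reads
  }
  out$analyzable <- out$n_case >= 1L & out$n_control >= 1L
  class(out) <- c("group_estimates", "data.frame")
  out
}
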