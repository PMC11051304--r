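#' Pipeline configuration with the method's published defaults
#'
#' All thresholds default to the method's standard constants:
#' 75% sample presence, < 100 bp cluster gaps, 5-site minimum,
#' dispersion prior (-3.39, 1.08), per-CpG alpha 0.05, voting fraction
#' 0.7 and rank threshold 0.04. The three `min_*` post-filters (region
#' length, fold change, absolute difference) are off (0) by default;
#' they mirror the candidate filters sometimes applied to real-data
#' calls.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `dmr_config`.
#' @export
dmr_config <- function(...) {
  cfg <- list(
    presence_fraction = 0.75,
    min_coverage = 1L,
    max_gap = 100L,
    min_sites = 5L,
    m0 = -3.39,
    r0 = 1.08,
    alpha = 0.05,
    vote_fraction = 0.7,
    rank_threshold = 0.04,
    pseudocount = 1e-3,
    min_length_bp = 0,
    min_fold_change = 0,
    min_abs_diff = 0)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("dmr_config", "list"))
}

#' Significant differentially methylated CpGs
#'
#' A CpG is significant when it both survived the voting ensemble and
#' has a Welch p-value at or below `alpha`; the voting gate is
#' mandatory regardless of how small the p-value is.
#'
#' @param scores Score frame from [score_all()].
#' @param candidates Logical flags from [vote()], aligned to `scores`.
#' @param alpha Per-CpG significance level; default 0.05.
#' @export
significant_cpgs <- function(scores, candidates, alpha = 0.05) {
  stopifnot(length(candidates) == nrow(scores))
  candidates & scores$p_value <= alpha
}

#' Segment significant CpGs into direction-consistent regions
#'
#' Within each cluster, a region is a maximal run of consecutive member
#' CpGs that are all significant and share the sign of the methylation
#' difference; a sign flip, a zero difference or a non-significant site
#' ends the run. Runs shorter than `min_sites` are dropped.
#'
#' @param clusters Cluster frame from [build_clusters()].
#' @param significant Logical vector over all dataset sites.
#' @param meth_diff Numeric vector over all dataset sites
#'   (case - control; `NA` where not analyzable).
#' @param ds The [meth_dataset()] the indices refer to.
#' @param min_sites Minimum CpGs per region; default 5.
#' @return Data frame with columns `chrom`, `start`, `end`, `n_cpgs`,
#'   `direction` and list column `sites` (dataset row indices).
#' @export
segment_dmrs <- function(clusters, significant, meth_diff, ds,
                         min_sites = 5L) {
  out <- list()
  for (ci in seq_len(nrow(clusters))) {
    members <- clusters$sites[[ci]]
    sg <- sign(meth_diff[members])
    sg[is.na(sg)] <- 0
    ok <- significant[members] & sg != 0
    ok[is.na(ok)] <- FALSE
    # break runs at non-significant sites and at sign changes
    grp <- cumsum(c(TRUE, !ok[-1] | !ok[-length(ok)] |
                            sg[-1] != sg[-length(sg)]))
    for (run in split(seq_along(members), grp)) {
      if (!all(ok[run]) || length(run) < min_sites) next
      idx <- members[run]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ds$sites$chrom[idx[1]],
        start = ds$sites$pos[idx[1]],
        end = ds$sites$pos[idx[length(idx)]],
        n_cpgs = length(idx),
        direction = if (sg[run[1]] > 0) "hyper" else "hypo")
      out[[length(out)]]$sites <- list(idx)
    }
  }
  if (!length(out)) {
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      direction = character())
    res$sites <- list()
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Combine p-values by Fisher's method
#'
#' `X2 = -2 sum(log p)` referred to a chi-square distribution with `2k`
#' degrees of freedom. Zeros are clamped to `1e-300`. With a single
#' p-value the method is the identity. Member p-values of adjacent CpGs
#' are not independent, so the combined value is best read as a ranking
#' score rather than an exact tail probability.
#'
#' @param pvalues Numeric vector in (0, 1], length >= 1.
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0L) stop("no p-values to combine")
  p <- pmin(pmax(pvalues, 1e-300), 1)
  x2 <- -2 * sum(log(p))
  stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR control; thin wrapper over [stats::p.adjust()] so the
#' procedure is fixed in one place.
#'
#' @param pvalues Numeric vector, length >= 1.
#' @export
adjust_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) stop("no p-values to adjust")
  stats::p.adjust(pvalues, method = "BH")
}

#' Fill region-level statistics for segmented DMRs
#'
#' Group means are coverage-weighted averages of the member CpG means
#' (weights = total reads of the group at the site); the absolute
#' difference, a pseudocount-guarded case/control fold change, a
#' region Fisher ratio (region means over summed member variances) and
#' the Fisher-combined p of the member CpGs are derived from them.
#'
#' @param dmrs Skeleton frame from [segment_dmrs()].
#' @param estimates `group_estimates` from [fit_all()].
#' @param scores Score frame from [score_all()] (member p-values).
#' @param pseudocount Added to both means in the fold change; default
#'   1e-3.
#' @return The DMR frame with columns `mu_case`, `mu_control`,
#'   `abs_diff`, `fold_change`, `fisher_ratio`, `p` appended.
#' @export
dmr_statistics <- function(dmrs, estimates, scores, pseudocount = 1e-3) {
  p_by_site <- rep(NA_real_, nrow(estimates))
  p_by_site[scores$site_idx] <- scores$p_value
  fill <- function(idx) {
    e <- estimates[idx, , drop = FALSE]
    wc <- pmax(e$reads_case, 1)
    wn <- pmax(e$reads_control, 1)
    mu_case <- sum(wc * e$mu_case) / sum(wc)
    mu_control <- sum(wn * e$mu_control) / sum(wn)
    c(mu_case = mu_case,
      mu_control = mu_control,
      abs_diff = abs(mu_case - mu_control),
      fold_change = (mu_case + pseudocount) / (mu_control + pseudocount),
      fisher_ratio = fisher_ratio(mu_case, mu_control,
                                  sum(e$var_case), sum(e$var_control)),
      p = fisher_combine(p_by_site[idx][!is.na(p_by_site[idx])]))
  }
  stats_mat <- t(vapply(dmrs$sites, fill, numeric(6)))
  cbind(dmrs, as.data.frame(stats_mat))
}

#' Call DMRs end to end
#'
#' Runs the full pipeline: presence filtering, CpG clustering,
#' beta-binomial fitting, three-statistic scoring, normalized-rank
#' voting, significance gating, direction-consistent segmentation,
#' Fisher combination of member p-values and Benjamini-Hochberg FDR
#' over the called regions. Deterministic given the dataset and
#' configuration.
#'
#' @param ds A [meth_dataset()].
#' @param config A [dmr_config()].
#' @param verbose Emit stage-count messages; default `FALSE`.
#' @return List of class `dmr_result` with elements `dmrs` (the results
#'   table, sorted by chrom/start, with `q` values), `clusters`,
#'   `estimates`, `scores`, `candidates`, `significant`, `config` and
#'   `counts` (per-stage tallies).
#' @export
call_dmrs <- function(ds, config = dmr_config(), verbose = FALSE) {
  cfg <- config
  say <- function(...) if (verbose) message(...)
  say("sites read: ", n_sites(ds))
  valid <- filter_validated_cpgs(ds, cfg$presence_fraction,
                                 cfg$min_coverage)
  say("validated sites: ", n_sites(valid))
  clusters <- build_clusters(valid, cfg$max_gap, cfg$min_sites)
  say("clusters: ", nrow(clusters))
  in_cluster <- sort(unlist(clusters$sites))
  prior <- dispersion_prior(cfg$m0, cfg$r0)
  estimates <- fit_all(valid, prior)
  scores <- score_all(estimates)
  empty_dmrs <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    n_cpgs = integer(), direction = character(), mu_case = numeric(),
    mu_control = numeric(), abs_diff = numeric(), fold_change = numeric(),
    fisher_ratio = numeric(), p = numeric(), q = numeric())
  empty_dmrs$sites <- list()
  result <- list(clusters = clusters, estimates = estimates,
                 scores = scores, config = cfg)
  if (nrow(scores) < 2L || nrow(clusters) == 0L) {
    result$candidates <- logical(nrow(scores))
    result$significant <- logical(n_sites(valid))
    result$dmrs <- empty_dmrs
    result$dataset <- valid
    result$counts <- c(sites = n_sites(ds), validated = n_sites(valid),
                       clusters = nrow(clusters), candidates = 0L,
                       dmrs = 0L)
    class(result) <- "dmr_result"
    return(result)
  }
  rmat <- rank_matrix(scores)
  candidates <- vote(rmat, cfg$vote_fraction, cfg$rank_threshold)
  say("candidate CpGs: ", sum(candidates))
  sig_scored <- significant_cpgs(scores, candidates, cfg$alpha)
  significant <- logical(n_sites(valid))
  significant[scores$site_idx] <- sig_scored
  meth_diff <- rep(NA_real_, n_sites(valid))
  meth_diff[scores$site_idx] <- scores$meth_diff
  dmrs <- segment_dmrs(clusters, significant, meth_diff, valid,
                       cfg$min_sites)
  if (nrow(dmrs)) {
    dmrs <- dmr_statistics(dmrs, estimates, scores, cfg$pseudocount)
    dmrs$q <- adjust_fdr(dmrs$p)
    keep <- (dmrs$end - dmrs$start + 1L) >= cfg$min_length_bp &
      dmrs$fold_change >= cfg$min_fold_change &
      dmrs$abs_diff >= cfg$min_abs_diff
    dmrs <- dmrs[keep, , drop = FALSE]
    o <- order(dmrs$chrom, dmrs$start)
    dmrs <- dmrs[o, , drop = FALSE]
    rownames(dmrs) <- NULL
  } else {
    dmrs <- empty_dmrs
  }
  say("DMRs called: ", nrow(dmrs))
  result$candidates <- candidates
  result$significant <- significant
  result$dmrs <- dmrs
  result$dataset <- valid
  result$counts <- c(sites = n_sites(ds), validated = n_sites(valid),
                     clusters = nrow(clusters),
                     candidates = sum(candidates), dmrs = nrow(dmrs))
  class(result) <- "dmr_result"
  result
}

#' @export
print.dmr_result <- function(x, ...) {
  cat("<dmr_result>\n")
  cat("  sites: ", x$counts[["sites"]], " -> validated ",
      x$counts[["validated"]], "; clusters ", x$counts[["clusters"]],
      "\n", sep = "")
  cat("  candidate CpGs: ", x$counts[["candidates"]],
      "; DMRs: ", x$counts[["dmrs"]], "\n", sep = "")
  invisible(x)
}
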