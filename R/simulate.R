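#' Configuration for the RRBS-like two-group simulator
#'
#' Defaults describe a reduced-representation bisulfite experiment with
#' six case and six control replicates, clustered CpG positions,
#' ~20x per-sample coverage and beta-binomial counts whose per-site
#' dispersion is drawn from the same log-normal field the estimator
#' assumes. Baseline methylation is bimodal (mostly-unmethylated and
#' mostly-methylated clusters), as in real methylomes.
#'
#' @param seed Integer RNG seed.
#' @param n_case,n_control Replicates per group (default 6 and 6).
#' @param n_clusters Number of CpG clusters to simulate.
#' @param sites_per_cluster Integer range (min, max) of CpGs per cluster.
#' @param within_gap Range of gaps (bp) between cluster members; must
#'   stay below 100 so clusters survive segmentation.
#' @param between_gap Range of gaps (bp) between clusters (>= 200).
#' @param coverage_mean Mean per-site, per-sample read depth (default 20,
#'   i.e. the 19-24x regime of typical RRBS libraries).
#' @param coverage_model `"poisson"` or `"negative_binomial"`.
#' @param nb_size Negative-binomial size when that model is chosen.
#' @param mix_weight_low Probability a cluster is baseline-unmethylated.
#' @param beta_low,beta_high Beta shape pairs for the low/high baseline
#'   mixture components.
#' @param site_jitter_sd SD of the per-site jitter around the cluster
#'   baseline mean.
#' @param m0,r0 Dispersion field parameters (log-normal, truncated to
#'   (0, 1)); defaults -3.39 and 1.08.
#' @param dmr_fraction Fraction of clusters spiked as true DMRs.
#' @param effect_delta Group-mean shift of a spiked cluster.
#' @param effect_scale `"absolute_clamped"` (shift the proportion,
#'   clamped to [0.01, 0.99]) or `"logit"` (shift on the log-odds scale).
#' @param dropout Per-cell missingness probability (default 0).
#' @param chrom Chromosome name for the single simulated contig.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_case = 6L, n_control = 6L,
                       n_clusters = 200L,
                       sites_per_cluster = c(10L, 20L),
                       within_gap = c(5L, 60L),
                       between_gap = c(300L, 2000L),
                       coverage_mean = 20,
                       coverage_model = c("poisson", "negative_binomial"),
                       nb_size = 10,
                       mix_weight_low = 0.5,
                       beta_low = c(2, 8), beta_high = c(8, 2),
                       site_jitter_sd = 0.03,
                       m0 = -3.39, r0 = 1.08,
                       dmr_fraction = 0.1,
                       effect_delta = 0.25,
                       effect_scale = c("absolute_clamped", "logit"),
                       dropout = 0,
                       chrom = "chrSim") {
  coverage_model <- match.arg(coverage_model)
  effect_scale <- match.arg(effect_scale)
  stopifnot(n_case >= 1, n_control >= 1, n_clusters >= 1,
            all(sites_per_cluster >= 1),
            sites_per_cluster[1] <= sites_per_cluster[2],
            all(within_gap >= 1), within_gap[2] < 100,
            all(between_gap >= 200),
            coverage_mean > 0,
            dmr_fraction >= 0, dmr_fraction <= 1,
            effect_delta > 0, effect_delta < 1,
            dropout >= 0, dropout < 1)
  structure(as.list(environment()), class = c("sim_config", "list"))
}

# Log-normal draws truncated to (0, 1) by rejection; the untruncated
# mass above 1 is < 0.1% at the default field parameters.
.rln_trunc01 <- function(n, m0, r0) {
  out <- stats::rlnorm(n, m0, r0)
  bad <- which(out >= 1)
  while (length(bad)) {
    out[bad] <- stats::rlnorm(length(bad), m0, r0)
    bad <- bad[out[bad] >= 1]
  }
  out
}

#' Simulate a two-group methylation dataset with known truth
#'
#' Generative model per site i, group j, replicate k: dispersion
#' `phi_i ~ LogNormal(m0, r0^2)` truncated to (0, 1); replicate
#' proportion `p_ijk ~ Beta(mu_ij, phi_i)` in the mean/dispersion
#' parameterization; counts `X_ijk ~ Binomial(N_ijk, p_ijk)` with
#' `N_ijk` Poisson (or negative-binomial) coverage. A configured
#' fraction of whole clusters carries a case-group mean shift of
#' `effect_delta` with random sign; shifted means are clamped to
#' [0.01, 0.99] (with a warning when clamping bites).
#'
#' @param cfg A [sim_config()].
#' @return List with elements `dataset` (a [meth_dataset()]) and `truth`
#'   (list: `dmrs` frame with chrom/start/end/direction/delta/cluster_id,
#'   `clusters` frame for every simulated cluster with `is_dmr`,
#'   `site_truth` frame with per-site true `mu_control`, `mu_case`,
#'   `phi`, `cluster_id`).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  nsc <- sample(seq(cfg$sites_per_cluster[1], cfg$sites_per_cluster[2]),
                cfg$n_clusters, replace = TRUE)
  m <- sum(nsc)
  cluster_id <- rep(seq_len(cfg$n_clusters), nsc)
  # positions: clusters separated by large gaps, members by small ones
  gaps <- integer(m)
  first <- c(1L, cumsum(nsc)[-cfg$n_clusters] + 1L)
  gaps[first] <- sample(seq(cfg$between_gap[1], cfg$between_gap[2]),
                        cfg$n_clusters, replace = TRUE)
  inner <- setdiff(seq_len(m), first)
  gaps[inner] <- sample(seq(cfg$within_gap[1], cfg$within_gap[2]),
                        length(inner), replace = TRUE)
  pos <- cumsum(gaps)

  # cluster baselines from the bimodal mixture, jittered per site
  low <- stats::runif(cfg$n_clusters) < cfg$mix_weight_low
  base <- ifelse(low,
                 stats::rbeta(cfg$n_clusters, cfg$beta_low[1],
                              cfg$beta_low[2]),
                 stats::rbeta(cfg$n_clusters, cfg$beta_high[1],
                              cfg$beta_high[2]))
  mu_control <- pmin(pmax(base[cluster_id] +
                            stats::rnorm(m, 0, cfg$site_jitter_sd),
                          0.01), 0.99)
  phi <- .rln_trunc01(m, cfg$m0, cfg$r0)

  # spike whole clusters as DMRs, sign random per DMR
  n_dmr <- round(cfg$dmr_fraction * cfg$n_clusters)
  dmr_clusters <- if (n_dmr > 0) {
    sort(sample(cfg$n_clusters, n_dmr))
  } else integer()
  sgn <- stats::setNames(rep(0, cfg$n_clusters),
                         seq_len(cfg$n_clusters))
  if (n_dmr > 0) {
    sgn[dmr_clusters] <- sample(c(-1, 1), n_dmr, replace = TRUE)
  }
  shift <- sgn[cluster_id] * cfg$effect_delta
  if (cfg$effect_scale == "absolute_clamped") {
    raw <- mu_control + shift
    mu_case <- pmin(pmax(raw, 0.01), 0.99)
    if (any(shift != 0 & (raw < 0.01 | raw > 0.99))) {
      warning("some spiked means were clamped to [0.01, 0.99]")
    }
  } else {
    mu_case <- ifelse(shift != 0,
                      stats::plogis(stats::qlogis(mu_control) + shift),
                      mu_control)
  }

  n_samp <- cfg$n_case + cfg$n_control
  ids <- c(sprintf("case_%d", seq_len(cfg$n_case)),
           sprintf("control_%d", seq_len(cfg$n_control)))
  group <- stats::setNames(rep(c("case", "control"),
                               c(cfg$n_case, cfg$n_control)), ids)
  ncell <- m * n_samp
  N <- if (cfg$coverage_model == "poisson") {
    stats::rpois(ncell, cfg$coverage_mean)
  } else {
    stats::rnbinom(ncell, size = cfg$nb_size, mu = cfg$coverage_mean)
  }
  N <- matrix(N, m, n_samp, dimnames = list(NULL, ids))
  mu_mat <- cbind(matrix(mu_case, m, cfg$n_case),
                  matrix(mu_control, m, cfg$n_control))
  s <- 1 / phi - 1
  a <- mu_mat * s
  b <- (1 - mu_mat) * s
  p <- matrix(stats::rbeta(ncell, a, b), m, n_samp)
  X <- matrix(stats::rbinom(ncell, N, p), m, n_samp,
              dimnames = list(NULL, ids))
  miss <- N == 0L
  if (cfg$dropout > 0) {
    miss <- miss | matrix(stats::runif(ncell) < cfg$dropout, m, n_samp)
  }
  X[miss] <- NA_integer_
  N[miss] <- NA_integer_

  sites <- data.frame(chrom = cfg$chrom, pos = pos)
  ds <- meth_dataset(sites, X, N, group)

  cl_start <- tapply(pos, cluster_id, min)
  cl_end <- tapply(pos, cluster_id, max)
  clusters <- data.frame(chrom = cfg$chrom,
                         start = as.integer(cl_start),
                         end = as.integer(cl_end),
                         cluster_id = seq_len(cfg$n_clusters),
                         is_dmr = seq_len(cfg$n_clusters) %in%
                           dmr_clusters)
  dmrs <- clusters[clusters$is_dmr, c("chrom", "start", "end",
                                      "cluster_id")]
  dmrs$direction <- ifelse(sgn[dmrs$cluster_id] > 0, "hyper", "hypo")[
    seq_len(nrow(dmrs))]
  dmrs$delta <- rep(cfg$effect_delta, nrow(dmrs))
  rownames(dmrs) <- NULL
  truth <- list(
    dmrs = dmrs,
    clusters = clusters,
    site_truth = data.frame(chrom = cfg$chrom, pos = pos,
                            cluster_id = cluster_id,
                            mu_control = mu_control, mu_case = mu_case,
                            phi = phi))
  list(dataset = ds, truth = truth)
}

#' Randomly blank dataset cells
#'
#' Drops each (site, sample) cell independently with the given
#' probability, to exercise the sample-presence filter.
#'
#' @param ds A [meth_dataset()].
#' @param per_site_dropout Dropout probability in [0, 1).
#' @param seed RNG seed.
#' @export
punch_missingness <- function(ds, per_site_dropout, seed = 1L) {
  if (per_site_dropout >= 1 || per_site_dropout < 0) {
    stop("per_site_dropout must lie in [0, 1)")
  }
  if (per_site_dropout == 0) return(ds)
  set.seed(seed)
  drop <- matrix(stats::runif(length(ds$meth)) < per_site_dropout,
                 nrow(ds$meth), ncol(ds$meth))
  meth <- ds$meth
  total <- ds$total
  meth[drop] <- NA_integer_
  total[drop] <- NA_integer_
  meth_dataset(ds$sites, meth, total, ds$group)
}

#' Write a simulated dataset as per-sample files plus truth tracks
#'
#' Emits one `tsv_counts` file per sample (named `<sample_id>.tsv`), a
#' BED file of the true DMR intervals (`truth_dmrs.bed`) and a TSV of
#' all simulated cluster intervals (`truth_clusters.tsv`), so the
#' file-level pipeline can be exercised end to end.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of sample file paths.
#' @export
write_sim_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  paths <- character(0)
  for (id in ds$samples) {
    ok <- !is.na(ds$total[, id])
    sm <- sample_methylation(id, data.frame(
      chrom = ds$sites$chrom[ok], pos = ds$sites$pos[ok],
      meth = ds$meth[ok, id], total = ds$total[ok, id]))
    p <- file.path(dir, paste0(id, ".tsv"))
    write_counts_tsv(sm, p)
    paths <- c(paths, p)
  }
  td <- sim$truth$dmrs
  bed <- data.frame(chrom = td$chrom, start = td$start - 1L,
                    end = td$end, name = td$direction)
  utils::write.table(bed, file.path(dir, "truth_dmrs.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth$clusters,
                     file.path(dir, "truth_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(paths)
}
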