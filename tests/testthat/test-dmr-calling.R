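test_that("significance requires both the vote and the p-value gate", {
  scores <- data.frame(p_value = c(0.04, 0.06, 1e-9))
  cand <- c(TRUE, TRUE, FALSE)
  expect_equal(significant_cpgs(scores, cand),
               c(TRUE, FALSE, FALSE))
})

test_that("segmentation respects sign shifts and the 5-CpG minimum", {
  pos <- seq(100L, by = 10L, length.out = 8L)
  ds <- make_ds(pos, matrix(1L, 8, 2), matrix(2L, 8, 2))
  clusters <- data.frame(chrom = "chr1", start = 100L, end = 170L,
                         n_sites = 8L)
  clusters$sites <- list(1:8)
  # all significant, all positive -> one hyper DMR (first 6 sites only)
  d1 <- segment_dmrs(clusters, rep(TRUE, 8), rep(0.2, 8), ds)
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$direction, "hyper")
  expect_equal(d1$n_cpgs, 8L)
  # sign shift at site 4: hyper run of 3 dropped, hypo run of 5 kept
  d2 <- segment_dmrs(clusters, rep(TRUE, 8),
                     c(0.2, 0.2, 0.2, -0.2, -0.2, -0.2, -0.2, -0.2), ds)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$direction, "hypo")
  expect_equal(d2$start, 130L)
  expect_equal(d2$end, 170L)
  # only 4 significant -> nothing
  d3 <- segment_dmrs(clusters, c(rep(TRUE, 4), rep(FALSE, 4)),
                     rep(0.2, 8), ds)
  expect_equal(nrow(d3), 0L)
  # a zero methylation difference breaks a run
  d4 <- segment_dmrs(clusters, rep(TRUE, 8),
                     c(0.2, 0.2, 0.2, 0, 0.2, 0.2, 0.2, 0.2), ds)
  expect_equal(nrow(d4), 0L)
})

test_that("fisher combination matches the chi-square oracle", {
  expect_equal(fisher_combine(0.3), 0.3)  # identity at k = 1
  expect_equal(fisher_combine(c(0.05, 0.05)),
               pchisq(-2 * 2 * log(0.05), 4, lower.tail = FALSE))
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.01747866,
               tolerance = 1e-6)
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  expect_error(fisher_combine(numeric(0)), "no p-values")
  # monotone: lowering any member p lowers the combination
  set.seed(41)
  for (i in 1:20) {
    p <- runif(5)
    p2 <- p
    j <- sample(5, 1)
    p2[j] <- p[j] / 2
    expect_lt(fisher_combine(p2), fisher_combine(p))
  }
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(adjust_fdr(0.02), 0.02)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  step_up <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- numeric(n)
    q[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
    pmin(q, 1)
  }
  set.seed(43)
  for (i in 1:8) {
    p <- runif(sample(1:12, 1))
    q <- adjust_fdr(p)
    expect_equal(q, step_up(p))
    expect_true(all(q >= p & q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("region statistics aggregate member estimates as documented", {
  est <- data.frame(chrom = "chr1", pos = c(10L, 20L),
                    mu_case = c(0.5, 0.5), phi_case = 0.01,
                    var_case = c(0.001, 0.002), n_case = 6L,
                    reads_case = c(100L, 100L),
                    mu_control = c(0.5, 0.5), phi_control = 0.01,
                    var_control = c(0.001, 0.001), n_control = 6L,
                    reads_control = c(100L, 100L), analyzable = TRUE)
  scores <- data.frame(site_idx = 1:2, p_value = c(0.05, 0.05))
  dmrs <- data.frame(chrom = "chr1", start = 10L, end = 20L,
                     n_cpgs = 2L, direction = "hyper")
  dmrs$sites <- list(1:2)
  out <- dmr_statistics(dmrs, est, scores)
  expect_equal(out$mu_case, 0.5)
  expect_equal(out$abs_diff, 0)
  expect_equal(out$fold_change, 1)
  expect_equal(out$fisher_ratio, 0)
  expect_equal(out$p, fisher_combine(c(0.05, 0.05)))
  # pseudocount keeps the fold change finite at zero control methylation
  est2 <- est
  est2$mu_control <- 0
  est2$mu_case <- 0.2
  out2 <- dmr_statistics(dmrs, est2, scores)
  expect_equal(out2$fold_change, (0.2 + 1e-3) / 1e-3)
  expect_equal(out2$fold_change, 201)
  # coverage weighting of member means
  est3 <- est
  est3$mu_case <- c(0.2, 0.6)
  est3$reads_case <- c(300L, 100L)
  out3 <- dmr_statistics(dmrs, est3, scores)
  expect_equal(out3$mu_case, (300 * 0.2 + 100 * 0.6) / 400)
})

test_that("a strongly spiked cluster is called with the right direction", {
  sim <- suppressWarnings(simulate_dataset(sim_config(
    seed = 3, n_clusters = 40, sites_per_cluster = c(10L, 12L),
    dmr_fraction = 1 / 40, effect_delta = 0.4)))
  res <- call_dmrs(sim$dataset)
  truth <- sim$truth$dmrs
  expect_equal(nrow(truth), 1L)
  expect_gt(nrow(res$dmrs), 0L)
  hit <- overlaps_truth(res$dmrs[, c("chrom", "start", "end")], truth)
  expect_true(any(hit))
  expect_true(all(res$dmrs$direction[hit] == truth$direction))
})

test_that("few regions are called when nothing is spiked", {
  sim <- simulate_dataset(sim_config(seed = 5, n_clusters = 60,
                                     dmr_fraction = 0))
  res <- call_dmrs(sim$dataset)
  expect_lt(nrow(res$dmrs) / nrow(res$clusters), 0.1)
})

test_that("calls are deterministic and respect structural invariants", {
  sim <- suppressWarnings(simulate_dataset(sim_config(
    seed = 11, n_clusters = 60, dmr_fraction = 0.15)))
  res1 <- call_dmrs(sim$dataset)
  res2 <- call_dmrs(sim$dataset)
  expect_identical(res1$dmrs, res2$dmrs)
  dmrs <- res1$dmrs
  if (nrow(dmrs) > 1) {
    o <- order(dmrs$start)
    expect_true(all(dmrs$start[o][-1] > dmrs$end[o][-nrow(dmrs)]))
  }
  # every DMR sits inside a single cluster and never mixes signs
  diff_full <- rep(NA_real_, n_sites(res1$dataset))
  diff_full[res1$scores$site_idx] <- res1$scores$meth_diff
  for (i in seq_len(nrow(dmrs))) {
    idx <- dmrs$sites[[i]]
    inside <- vapply(res1$clusters$sites,
                     function(cl) all(idx %in% cl), logical(1))
    expect_equal(sum(inside), 1L)
    sg <- sign(diff_full[idx])
    expect_true(all(sg == sg[1]) && sg[1] != 0)
  }
})

test_that("permuting samples within groups leaves the calls unchanged", {
  sim <- suppressWarnings(simulate_dataset(sim_config(
    seed = 13, n_clusters = 30, dmr_fraction = 0.2)))
  ds <- sim$dataset
  perm <- c(sample(which(ds$group == "case")),
            sample(which(ds$group == "control")))
  ds2 <- meth_dataset(ds$sites, ds$meth[, perm], ds$total[, perm],
                      ds$group[perm])
  r1 <- call_dmrs(ds)
  r2 <- call_dmrs(ds2)
  expect_equal(r1$dmrs, r2$dmrs)
})
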