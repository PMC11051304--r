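#' Region-level confusion counts against ground truth
#'
#' Every tested region is classified by whether it was declared
#' significant and whether it overlaps a true DMR interval by at least
#' `min_overlap_bp`: significant and overlapping = TP, significant and
#' non-overlapping = FP, non-significant and overlapping = FN,
#' non-significant and non-overlapping = TN.
#'
#' @param regions Data frame of tested regions with columns `chrom`,
#'   `start`, `end` (1-based inclusive) and logical `significant`.
#' @param truth Data frame of true DMR intervals (`chrom`, `start`,
#'   `end`, same convention).
#' @param min_overlap_bp Minimum overlap to count as intersecting;
#'   default 1.
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
region_confusion <- function(regions, truth, min_overlap_bp = 1L) {
  stopifnot(all(c("chrom", "start", "end", "significant") %in%
                  names(regions)))
  if (nrow(regions) == 0L) {
    return(c(TP = 0L, FP = 0L, FN = 0L, TN = 0L))
  }
  hits <- overlaps_truth(regions, truth, min_overlap_bp)
  sig <- regions$significant
  c(TP = sum(sig & hits), FP = sum(sig & !hits),
    FN = sum(!sig & hits), TN = sum(!sig & !hits))
}

#' Flag regions that overlap any truth interval
#'
#' @inheritParams region_confusion
#' @return Logical vector along `regions`.
#' @export
overlaps_truth <- function(regions, truth, min_overlap_bp = 1L) {
  if (nrow(regions) == 0L) return(logical(0))
  if (nrow(truth) == 0L) return(rep(FALSE, nrow(regions)))
  gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end))
  gt <- GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(truth$start, truth$end))
  GenomicRanges::countOverlaps(gr, gt,
                               minoverlap = min_overlap_bp) > 0
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity, specificity, accuracy, PPV, NPV, Matthews correlation
#' and F1 from the four confusion counts; a zero denominator yields
#' `NaN` with a warning.
#'
#' @param confusion Named vector or list with elements `TP`, `FP`, `FN`,
#'   `TN`.
#' @return Named numeric vector of the seven metrics.
#' @export
confusion_metrics <- function(confusion) {
  tp <- as.numeric(confusion[["TP"]])
  fp <- as.numeric(confusion[["FP"]])
  fn <- as.numeric(confusion[["FN"]])
  tn <- as.numeric(confusion[["TN"]])
  if (tp + fp + fn + tn <= 0) stop("empty confusion matrix")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  ppv <- safe(tp, tp + fp, "PPV")
  npv <- safe(tn, tn + fn, "NPV")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator)")
    NaN
  } else (tp * tn - fp * fn) / mcc_den
  f1 <- safe(2 * tp, 2 * tp + fp + fn, "F1")
  c(sensitivity = sens, specificity = spec,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    ppv = ppv, npv = npv, mcc = mcc, f1 = f1)
}

#' ROC curve and AUC from region-wise p-values
#'
#' Sweeps the significance threshold across the sorted unique p-values
#' (smaller p = called positive), accumulating tied values together,
#' and integrates the curve by the trapezoid rule — equivalent to the
#' probabilistic (rank/Mann-Whitney) AUC with tie correction.
#'
#' @param pvalues Region-wise p-values.
#' @param labels Logical truth labels (region overlaps a true DMR).
#' @return List with `points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(pvalues, labels) {
  stopifnot(length(pvalues) == length(labels))
  labels <- as.logical(labels)
  npos <- sum(labels)
  nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L) {
    stop("need at least one positive and one negative label")
  }
  o <- order(pvalues)
  p <- pvalues[o]
  l <- labels[o]
  last <- !duplicated(p, fromLast = TRUE)  # end of each tie block
  tpr <- c(0, cumsum(l)[last] / npos)
  fpr <- c(0, cumsum(!l)[last] / nneg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a pipeline run against simulated truth
#'
#' The tested units are the pipeline's CpG clusters. A cluster is
#' declared significant when it contains a called DMR whose combined
#' p-value is at or below `alpha` (called regions also satisfy the
#' minimum-CpG rule by construction); its region-wise p-value for the
#' ROC sweep is the Fisher combination of all member CpG p-values.
#' Also reports the empirical false-discovery fraction among the
#' called DMRs themselves.
#'
#' @param result A `dmr_result` from [call_dmrs()].
#' @param truth_dmrs Data frame of true intervals (`chrom`, `start`,
#'   `end`), e.g. `sim$truth$dmrs`.
#' @param alpha Region significance level; default 0.05.
#' @param min_overlap_bp Overlap rule, default 1.
#' @return List with `regions` (per-cluster table), `confusion`,
#'   `metrics`, `auc`, `roc`, `fdr_called`, `n_dmrs`.
#' @export
evaluate_calls <- function(result, truth_dmrs, alpha = 0.05,
                           min_overlap_bp = 1L) {
  clusters <- result$clusters
  if (nrow(clusters) == 0L) stop("result contains no tested clusters")
  p_by_site <- rep(NA_real_, nrow(result$estimates))
  p_by_site[result$scores$site_idx] <- result$scores$p_value
  region_p <- vapply(clusters$sites, function(idx) {
    p <- p_by_site[idx]
    p <- p[!is.na(p)]
    if (!length(p)) return(1)
    fisher_combine(p)
  }, numeric(1))
  called <- result$dmrs[result$dmrs$p <= alpha, , drop = FALSE]
  sig <- if (nrow(called)) {
    overlaps_truth(clusters[, c("chrom", "start", "end")],
                   data.frame(chrom = called$chrom, start = called$start,
                              end = called$end), 1L)
  } else rep(FALSE, nrow(clusters))
  regions <- data.frame(chrom = clusters$chrom, start = clusters$start,
                        end = clusters$end, n_sites = clusters$n_sites,
                        p = region_p, significant = sig)
  conf <- region_confusion(regions, truth_dmrs, min_overlap_bp)
  metrics <- confusion_metrics(conf)
  roc <- roc_auc(regions$p, overlaps_truth(regions, truth_dmrs,
                                           min_overlap_bp))
  fdr_called <- if (nrow(called)) {
    mean(!overlaps_truth(called[, c("chrom", "start", "end")],
                         truth_dmrs, min_overlap_bp))
  } else NA_real_
  list(regions = regions, confusion = conf, metrics = metrics,
       auc = roc$auc, roc = roc$points, fdr_called = fdr_called,
       n_dmrs = nrow(called))
}
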