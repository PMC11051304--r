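#' Drop CpG sites observed in too few samples
#'
#' A site is *validated* when it is covered (total reads at or above
#' `min_coverage`) in at least `presence_fraction` of all samples; the
#' remainder are treated as noise and removed before clustering.
#'
#' @param ds A [meth_dataset()].
#' @param presence_fraction Minimum fraction of samples in which a site
#'   must be observed (inclusive); default 0.75.
#' @param min_coverage Read depth at which a site counts as observed in a
#'   sample; default 1.
#' @return The filtered [meth_dataset()] (possibly with zero sites).
#' @export
filter_validated_cpgs <- function(ds, presence_fraction = 0.75,
                                  min_coverage = 1L) {
  stopifnot(presence_fraction > 0, presence_fraction <= 1,
            min_coverage >= 1)
  present <- !is.na(ds$total) & ds$total >= min_coverage
  keep <- rowSums(present) >= presence_fraction * length(ds$samples)
  subset_sites(ds, keep)
}

#' Segment validated CpGs into clusters
#'
#' Per chromosome, a cluster is a maximal run of sites whose successive
#' position gaps are strictly below `max_gap`; runs shorter than
#' `min_sites` are discarded. Clusters are the unit within which DMRs are
#' later segmented.
#'
#' @param ds A validated-filtered [meth_dataset()].
#' @param max_gap Gap (bp) at which a run is broken; default 100,
#'   i.e. consecutive cluster members are < 100 bp apart.
#' @param min_sites Minimum sites per cluster; default 5.
#' @return Data frame with columns `chrom`, `start`, `end`, `n_sites` and
#'   a list column `sites` of row indices into `ds$sites`.
#' @export
build_clusters <- function(ds, max_gap = 100L, min_sites = 5L) {
  stopifnot(max_gap >= 1, min_sites >= 1)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer())
  empty$sites <- list()
  if (n_sites(ds) == 0L) return(empty)
  pos <- ds$sites$pos
  chrom <- ds$sites$chrom
  new_run <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                     diff(pos) >= max_gap)
  run_id <- cumsum(new_run)
  runs <- split(seq_along(run_id), run_id)
  runs <- runs[lengths(runs) >= min_sites]
  if (!length(runs)) return(empty)
  out <- data.frame(
    chrom = chrom[vapply(runs, `[`, integer(1), 1L)],
    start = pos[vapply(runs, `[`, integer(1), 1L)],
    end = pos[vapply(runs, function(r) r[length(r)], integer(1))],
    n_sites = lengths(runs))
  out$sites <- unname(runs)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
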