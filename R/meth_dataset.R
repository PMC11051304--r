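#' Per-sample methylation calls
#'
#' Bundles one replicate's CpG-level counts: for every covered cytosine the
#' number of reads supporting methylation and the total read count.
#'
#' @param sample_id Single string naming the replicate.
#' @param records Data frame with columns `chrom`, `pos` (1-based),
#'   `meth` and `total` (read counts). Zero-total rows are not allowed
#'   (an unobserved site is simply absent).
#' @return An object of class `sample_methylation`.
#' @export
sample_methylation <- function(sample_id, records) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  records <- as.data.frame(records)
  needed <- c("chrom", "pos", "meth", "total")
  if (!all(needed %in% names(records))) {
    stop("records must have columns chrom, pos, meth, total")
  }
  records <- records[, needed]
  if (nrow(records)) {
    if (any(records$meth < 0) || any(records$total < 1)) {
      stop("validation error: counts must satisfy meth >= 0 and total >= 1")
    }
    if (any(records$meth > records$total)) {
      stop("validation error: meth_count exceeds total_count")
    }
    o <- order(records$chrom, records$pos)
    records <- records[o, , drop = FALSE]
    if (anyDuplicated(records[, c("chrom", "pos")])) {
      stop("duplicate (chrom, pos) within sample '", sample_id, "'")
    }
    rownames(records) <- NULL
  }
  structure(list(sample_id = sample_id, records = records),
            class = "sample_methylation")
}

#' @export
print.sample_methylation <- function(x, ...) {
  cat("<sample_methylation> ", x$sample_id, ": ",
      nrow(x$records), " CpG records\n", sep = "")
  invisible(x)
}

#' Two-group methylation count dataset
#'
#' The central container: a site-by-sample pair of count matrices
#' (methylated reads and total reads) plus a case/control label per sample.
#' A site unobserved in a sample is `NA` in both matrices.
#'
#' @param sites Data frame with columns `chrom`, `pos`, sorted.
#' @param meth,total Integer matrices, `nrow(sites)` x `n samples`, sharing
#'   one missingness mask; `meth <= total` where present.
#' @param group Named character vector mapping sample id to
#'   `"case"` or `"control"`.
#' @return An object of class `meth_dataset`.
#' @export
meth_dataset <- function(sites, meth, total, group) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  sites <- sites[, c("chrom", "pos")]
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  if (!identical(dim(meth), dim(total))) {
    stop("meth and total matrices must have identical dimensions")
  }
  if (nrow(meth) != nrow(sites)) stop("matrix rows must match sites")
  if (is.null(colnames(meth))) stop("matrices need sample ids as colnames")
  if (!identical(colnames(meth), colnames(total))) {
    stop("meth/total column names disagree")
  }
  if (!identical(is.na(meth), is.na(total))) {
    stop("meth and total must share one missingness mask")
  }
  if (any(meth > total, na.rm = TRUE)) stop("meth exceeds total")
  if (any(meth < 0, na.rm = TRUE) || any(total < 0, na.rm = TRUE)) {
    stop("negative counts")
  }
  samples <- colnames(meth)
  group <- group[samples]
  if (any(is.na(group))) stop("every sample needs a group label")
  if (!all(group %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'")
  }
  for (g in c("case", "control")) {
    if (!any(group == g)) stop("group '", g, "' has zero samples")
  }
  if (is.unsorted(order(sites$chrom, sites$pos))) {
    o <- order(sites$chrom, sites$pos)
    sites <- sites[o, , drop = FALSE]
    meth <- meth[o, , drop = FALSE]
    total <- total[o, , drop = FALSE]
  }
  rownames(sites) <- NULL
  structure(list(sites = sites, meth = meth, total = total,
                 samples = samples, group = group),
            class = "meth_dataset")
}

#' @export
print.meth_dataset <- function(x, ...) {
  cat("<meth_dataset> ", nrow(x$sites), " CpG sites x ", length(x$samples),
      " samples (", sum(x$group == "case"), " case / ",
      sum(x$group == "control"), " control); ",
      sum(is.na(x$total)), " missing cells\n", sep = "")
  invisible(x)
}

#' Number of CpG sites in a dataset
#' @param ds A `meth_dataset`.
#' @export
n_sites <- function(ds) nrow(ds$sites)

#' Assemble per-sample call sets into one dataset
#'
#' The site universe is the union of all samples' positions; a
#' (site, sample) pair absent from that sample's records is missing.
#'
#' @param samples List of [sample_methylation()] objects (>= 2, unique ids).
#' @param group Named character vector, sample id -> `"case"`/`"control"`;
#'   both groups must be non-empty.
#' @return A [meth_dataset()].
#' @export
assemble_dataset <- function(samples, group) {
  if (length(samples) < 2L) stop("need at least 2 samples")
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_id: ",
                               ids[duplicated(ids)][1])
  all_sites <- unique(do.call(rbind, lapply(samples, function(s) {
    s$records[, c("chrom", "pos")]
  })))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), , drop = FALSE]
  rownames(all_sites) <- NULL
  key <- paste(all_sites$chrom, all_sites$pos)
  m <- matrix(NA_integer_, nrow(all_sites), length(ids),
              dimnames = list(NULL, ids))
  tot <- m
  for (s in samples) {
    idx <- match(paste(s$records$chrom, s$records$pos), key)
    m[idx, s$sample_id] <- as.integer(s$records$meth)
    tot[idx, s$sample_id] <- as.integer(s$records$total)
  }
  meth_dataset(all_sites, m, tot, group)
}

#' Subset a dataset to a set of site rows
#' @param ds A `meth_dataset`.
#' @param idx Integer or logical row index into `ds$sites`.
#' @export
subset_sites <- function(ds, idx) {
  meth_dataset(ds$sites[idx, , drop = FALSE],
               ds$meth[idx, , drop = FALSE],
               ds$total[idx, , drop = FALSE],
               ds$group)
}
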