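#' Read a per-sample methylation call file
#'
#' Two dialects are supported:
#' * `bismark_cov`: the Bismark coverage format
#'   (`chrom  start  end  meth_pct  count_meth  count_unmeth`, 1-based);
#'   the total count is reconstructed as `count_meth + count_unmeth`.
#' * `tsv_counts`: a generic 5-column table
#'   (`chrom  pos  strand  meth_count  total_count`). The strand column is
#'   carried but not used; opposite-strand calls are never merged here.
#'
#' Rows with zero total coverage are dropped at read time: a site
#' unobserved in a sample is treated as missing and handled later by the
#' sample-presence filter, not as a zero measurement.
#'
#' @param path Path to a plain or gzipped text file, no header.
#' @param dialect `"bismark_cov"` or `"tsv_counts"`.
#' @param sample_id Sample name; defaults to the file name without extension.
#' @return A [sample_methylation()] object.
#' @export
read_coverage_file <- function(path,
                               dialect = c("bismark_cov", "tsv_counts"),
                               sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(cov|tsv|txt)(\\.gz)?$", "", basename(path))
  }
  empty <- data.frame(chrom = character(), pos = integer(),
                      meth = integer(), total = integer())
  n_col <- if (dialect == "bismark_cov") 6L else 5L
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "",
                      colClasses = "character",
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        return(NULL)
      }
      stop("parse error in '", path, "': ", conditionMessage(e))
    })
  if (is.null(raw) || nrow(raw) == 0L) {
    return(sample_methylation(sample_id, empty))
  }
  if (ncol(raw) != n_col) {
    stop("parse error in '", path, "': expected ", n_col,
         " columns for dialect ", dialect, ", found ", ncol(raw))
  }
  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(x))
    if (length(bad)) {
      stop("parse error in '", path, "' line ", bad[1],
           ": non-numeric ", what)
    }
    x
  }
  if (dialect == "bismark_cov") {
    pos <- num(2L, "start")
    cm <- num(5L, "count_meth")
    cu <- num(6L, "count_unmeth")
    bad <- which(cm < 0 | cu < 0)
    if (length(bad)) {
      stop("validation error in '", path, "' line ", bad[1],
           ": negative count")
    }
    rec <- data.frame(chrom = raw[[1L]], pos = as.integer(pos),
                      meth = as.integer(cm), total = as.integer(cm + cu))
  } else {
    pos <- num(2L, "pos")
    cm <- num(4L, "meth_count")
    ct <- num(5L, "total_count")
    bad <- which(cm < 0 | ct < 0)
    if (length(bad)) {
      stop("validation error in '", path, "' line ", bad[1],
           ": negative count")
    }
    bad <- which(cm > ct)
    if (length(bad)) {
      stop("validation error in '", path, "' line ", bad[1],
           ": meth_count > total_count")
    }
    rec <- data.frame(chrom = raw[[1L]], pos = as.integer(pos),
                      meth = as.integer(cm), total = as.integer(ct))
  }
  rec <- rec[rec$total > 0L, , drop = FALSE]
  sample_methylation(sample_id, rec)
}

#' Write one sample's counts as a tsv_counts file
#'
#' Writes `chrom pos strand meth_count total_count` (strand is reported as
#' `"*"`); round-trips exactly through
#' `read_coverage_file(dialect = "tsv_counts")`.
#'
#' @param sm A [sample_methylation()] object.
#' @param path Output path.
#' @export
write_counts_tsv <- function(sm, path) {
  r <- sm$records
  out <- data.frame(chrom = r$chrom, pos = r$pos, strand = "*",
                    meth = r$meth, total = r$total)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

dmr_table_cols <- c("chrom", "start", "end", "n_cpgs", "mu_case",
                    "mu_control", "abs_diff", "fold_change",
                    "fisher_ratio", "p", "q", "direction")

#' Write a DMR results table
#'
#' Tab-separated with header; coordinates are 1-based inclusive.
#'
#' @param dmrs DMR data frame as returned by [call_dmrs()].
#' @param path Output path.
#' @export
write_dmr_table <- function(dmrs, path) {
  .check_dmr_overlap(dmrs)
  out <- as.data.frame(dmrs)[, dmr_table_cols, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write DMRs as a BED6 track
#'
#' Converts the internal 1-based inclusive intervals to BED's 0-based
#' half-open convention. The name field is the direction
#' (`hyper`/`hypo`), the score is `min(1000, round(-10 log10 q))`.
#'
#' @inheritParams write_dmr_table
#' @export
write_dmr_bed <- function(dmrs, path) {
  .check_dmr_overlap(dmrs)
  if (nrow(dmrs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  score <- pmin(1000, round(-10 * log10(pmax(dmrs$q, 1e-300))))
  out <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                    end = dmrs$end, name = dmrs$direction,
                    score = score, strand = ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.check_dmr_overlap <- function(dmrs) {
  if (nrow(dmrs) < 2L) return(invisible(TRUE))
  o <- order(dmrs$chrom, dmrs$start)
  d <- dmrs[o, ]
  same <- d$chrom[-1] == d$chrom[-nrow(d)]
  if (any(same & d$start[-1] <= d$end[-nrow(d)])) {
    stop("DMRs overlap within a chromosome; refusing to write")
  }
  invisible(TRUE)
}

#' Read a BED file of intervals into a 1-based data frame
#'
#' Minimal BED3+ reader used for ground-truth DMR intervals; converts
#' 0-based half-open to 1-based inclusive coordinates.
#'
#' @param path BED file path.
#' @return Data frame with columns `chrom`, `start`, `end` (and `name` if
#'   a fourth column is present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(raw[[1]]),
                    start = as.integer(raw[[2]]) + 1L,
                    end = as.integer(raw[[3]]))
  if (ncol(raw) >= 4L) out$name <- as.character(raw[[4]])
  out
}
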