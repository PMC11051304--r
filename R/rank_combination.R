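#' Normalize scores to ranks on [0, 1]
#'
#' The most differential CpG gets rank 0 and the least rank 1, scaled as
#' `(rank - 1) / (m - 1)` with ties receiving the mean of their
#' positional ranks before scaling.
#'
#' @param scores Numeric vector, length >= 2.
#' @param higher_is_more_differential If `TRUE` (default) large scores
#'   rank first; set `FALSE` for statistics where small means
#'   differential (e.g. p-values).
#' @export
normalize_ranks <- function(scores, higher_is_more_differential = TRUE) {
  m <- length(scores)
  if (m < 2L) stop("need at least 2 scores to rank")
  x <- if (higher_is_more_differential) -scores else scores
  (rank(x, ties.method = "average") - 1) / (m - 1)
}

#' Build the rank matrix for the three-voter ensemble
#'
#' One column of normalized ranks per ranking method. The signed
#' statistics are ranked by absolute value: a strongly hypomethylated
#' site is as differential as a strongly hypermethylated one.
#'
#' @param scores Data frame from [score_all()].
#' @return `m x 3` matrix with columns `fisher_ratio`, `z_score`,
#'   `welch_t`; entries in [0, 1], 0 = most differential.
#' @export
rank_matrix <- function(scores) {
  cbind(fisher_ratio = normalize_ranks(scores$fisher_ratio),
        z_score = normalize_ranks(abs(scores$z_score)),
        welch_t = normalize_ranks(abs(scores$welch_t)))
}

#' Voting rule over the ranked lists
#'
#' Voter `j` votes for CpG `i` when the site sits within the top
#' `rank_threshold` fraction of list `j` (normalized rank
#' `<= rank_threshold`, boundary inclusive). A site becomes a candidate
#' when strictly more than `vote_fraction` of the voters vote for it —
#' with three voters and the default 0.7 this requires unanimity, making
#' the ensemble the intersection of the three top lists.
#'
#' @param rmat Rank matrix from [rank_matrix()].
#' @param vote_fraction Fraction of voters that must be exceeded;
#'   default 0.7.
#' @param rank_threshold Top-fraction cutoff per list; default 0.04.
#' @return Logical vector of candidate flags, length `nrow(rmat)`.
#' @export
vote <- function(rmat, vote_fraction = 0.7, rank_threshold = 0.04) {
  stopifnot(is.matrix(rmat), ncol(rmat) >= 1)
  votes <- rowSums(rmat <= rank_threshold)
  votes / ncol(rmat) > vote_fraction
}

#' Candidate counts across a grid of rank thresholds
#'
#' Used to examine the sensitivity/specificity trade-off of the voting
#' cutoff; the count is monotone non-decreasing in the threshold.
#'
#' @param rmat Rank matrix from [rank_matrix()].
#' @param thresholds Numeric vector of cutoffs in [0, 1].
#' @param vote_fraction Passed to [vote()].
#' @return Data frame with columns `threshold`, `n_candidates`.
#' @export
sweep_threshold <- function(rmat, thresholds, vote_fraction = 0.7) {
  stopifnot(all(thresholds >= 0 & thresholds <= 1))
  n <- vapply(thresholds,
              function(th) sum(vote(rmat, vote_fraction, th)),
              numeric(1))
  data.frame(threshold = thresholds, n_candidates = n)
}
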