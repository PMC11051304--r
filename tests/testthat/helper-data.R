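# Small in-code fixtures shared across test files.

# A dataset built directly from matrices: `sites` positions on one
# chromosome, counts supplied per sample.
make_ds <- function(pos, meth, total, n_case = NULL, chrom = "chr1") {
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  n <- ncol(meth)
  if (is.null(n_case)) n_case <- n %/% 2
  ids <- c(sprintf("case_%d", seq_len(n_case)),
           sprintf("ctrl_%d", seq_len(n - n_case)))
  colnames(meth) <- colnames(total) <- ids
  group <- stats::setNames(rep(c("case", "control"),
                               c(n_case, n - n_case)), ids)
  meth_dataset(data.frame(chrom = chrom, pos = pos), meth, total, group)
}

# Beta-binomial replicate counts at given (mu, phi), fixed coverage.
rbetabinom <- function(k, size, mu, phi) {
  s <- 1 / phi - 1
  p <- stats::rbeta(k, mu * s, (1 - mu) * s)
  stats::rbinom(k, size, p)
}

# Independent grid-search oracle for the penalized dispersion objective.
grid_dispersion_oracle <- function(meth, total, mu, m0 = -3.39,
                                   r0 = 1.08, n_grid = 1e4) {
  grid <- exp(seq(log(1e-6), log(1 - 1e-6), length.out = n_grid))
  val <- vapply(grid, function(phi) {
    s <- 1 / phi - 1
    a <- mu * s
    b <- (1 - mu) * s
    sum(lchoose(total, meth) + lbeta(meth + a, total - meth + b) -
          lbeta(a, b)) +
      stats::dlnorm(phi, m0, r0, log = TRUE)
  }, numeric(1))
  grid[which.max(val)]
}

# Write a sample_methylation-style table to a temp file and return path.
write_tmp_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
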