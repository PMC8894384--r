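# shared fixture builders and independent oracles

# random valid correlation matrix
random_corr <- function(M, jitter = 0.5) {
  A <- matrix(rnorm(M * M), M)
  cov2cor(crossprod(A) + diag(M) * jitter)
}

# rows ~ MVN(0, R)
draw_mvn <- function(n, R) {
  matrix(rnorm(n * nrow(R)), n) %*% chol(R)
}

# Monte-Carlo oracle for P(sum lambda_i chisq_1 > q)
mc_quadform_sf <- function(q, lambdas, n = 2e5) {
  Q <- drop(matrix(rnorm(n * length(lambdas))^2, n) %*% lambdas)
  est <- mean(Q > q)
  list(p = est, se = sqrt(est * (1 - est) / n))
}

# classical Simes combination (independent-test oracle)
simes_pvalue <- function(p) {
  L <- length(p)
  min(1, min(L * sort(p) / seq_len(L)))
}

# brute-force grid oracle for the LD shrinkage parameter
grid_tuning_oracle <- function(Z, R, npts = 1001L) {
  grid <- seq(0, 1, length.out = npts)
  nll <- vapply(grid, function(a) neg_log_likelihood(Z, R, a), 0)
  list(a = grid[which.min(nll)], nll = min(nll), grid = grid, values = nll)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

extdata <- function(f) system.file("extdata", f, package = "overallgene")
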