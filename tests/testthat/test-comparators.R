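test_that("Cauchy combination matches its defining transform", {
  expect_equal(cauchy_combine(rep(0.5, 7)), 0.5)
  expect_equal(cauchy_combine(0.123), 0.123, tolerance = 1e-12)
  p <- c(0.01, 0.5, 0.5)
  Q <- mean(tan((0.5 - p) * pi))
  expect_equal(cauchy_combine(p), 0.5 - atan(Q) / pi)
  expect_error(cauchy_combine(numeric(0)), "empty")
})

test_that("Cauchy combination is permutation-invariant and monotone", {
  set.seed(6)
  p <- runif(8)
  expect_equal(cauchy_combine(p), cauchy_combine(sample(p)))
  for (i in 1:5) {
    p2 <- p
    j <- sample(8, 1)
    p2[j] <- p2[j] * runif(1)
    expect_lte(cauchy_combine(p2), cauchy_combine(p) + 1e-14)
  }
  # extreme inputs stay finite via clipping
  expect_gt(cauchy_combine(c(0, 1, 0.5)), 0)
})

test_that("S-TWAS matches hand calculations and is scale-stable", {
  expect_equal(s_twas(2, matrix(1), 1)$p, 2 * pnorm(-2))
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  r <- s_twas(c(2, 2), R, c(0.5, 0.5))
  expect_equal(r$z_stat, 2 / sqrt(0.75))
  # weight orthogonal to Z
  expect_equal(s_twas(c(1, -1), diag(2), c(1, 1))$z_stat, 0)
  expect_equal(s_twas(c(1, -1), diag(2), c(1, 1))$p, 1)
  set.seed(9)
  Z <- rnorm(4); R4 <- random_corr(4); w <- rnorm(4)
  expect_equal(s_twas(Z, R4, 3 * w)$z_stat, s_twas(Z, R4, w)$z_stat)
  expect_equal(s_twas(Z, R4, -w)$z_stat, -s_twas(Z, R4, w)$z_stat)
  expect_equal(s_twas(Z, R4, -w)$p, s_twas(Z, R4, w)$p)
  expect_error(s_twas(c(1, 1), diag(2), c(0, 0)), "degenerate")
})

test_that("S-TWAS p-values are uniform under the null", {
  set.seed(13)
  M <- 5
  R <- synth_ld(M, "ar1", 0.6)
  w <- standardize_weights(rnorm(M))
  Z <- draw_mvn(1e4, R)
  v <- drop(crossprod(w, R %*% w))
  p <- 2 * pnorm(-abs(drop(Z %*% w)) / sqrt(v))
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
})

test_that("S-PrediXcan defaults coincide with S-TWAS", {
  set.seed(14)
  M <- 5
  R <- synth_ld(M, "ar1", 0.4)
  Z <- rnorm(M); w <- rnorm(M)
  tw <- s_twas(Z, R, w)
  px <- s_predixcan(Z, w, R = R)
  expect_equal(px$z_stat, tw$z_stat)
  expect_equal(px$p, tw$p)
  # hand calculation with explicit SNP standard deviations
  r2 <- s_predixcan(c(1, 3), c(0.5, 0.5), R = diag(2), snp_sd = c(2, 1))
  expect_equal(r2$z_stat, (1 * 2 * 0.5 + 3 * 1 * 0.5) / sqrt(0.25 * 4 + 0.25))
  expect_equal(s_predixcan(2, 1, snp_sd = 1, expr_sd = 1)$z_stat, 2)
  expect_error(s_predixcan(2, 1, snp_sd = 1, expr_sd = -1), "positive")
})
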