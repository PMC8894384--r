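test_that("synthetic LD structures are valid correlation matrices", {
  expect_equal(synth_ld(4, "ar1", 0), diag(4))
  R <- synth_ld(3, "ar1", 0.5)
  expect_equal(R[1, 2:3], c(0.5, 0.25))
  expect_error(synth_ld(4, "exchangeable", -0.5), "semi-definite")
  for (st in c("ar1", "block", "exchangeable")) {
    R <- synth_ld(7, st, 0.4, block_size = 3)
    expect_equal(diag(R), rep(1, 7))
    expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("genotypes are sums of two sampled haplotypes", {
  # single-haplotype pool: every individual is 2h
  h <- c(1, 0, 1, 1)
  pool <- list(H = matrix(h, 1, byrow = TRUE), frequencies = 1)
  g <- generate_genotypes(pool, 50, maf_floor = 0, seed = 1)
  expect_equal(g$kept, 1:4)
  expect_true(all(g$X == matrix(2 * h, 50, 4, byrow = TRUE)))
  # two equiprobable haplotypes differing at one site: dosage ~ Bin(2, 1/2)
  pool2 <- list(H = rbind(c(1, 1), c(0, 1)), frequencies = c(0.5, 0.5))
  g2 <- generate_genotypes(pool2, 10000, maf_floor = 0, seed = 2)
  counts <- tabulate(g2$X[, 1] + 1, 3)
  gof <- chisq.test(counts, p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.001)
  # low-frequency variant removed by the MAF filter
  pool3 <- list(H = rbind(c(1, 1), c(0, 1), c(0, 0)),
                frequencies = c(0.01, 0.5, 0.49))
  g3 <- generate_genotypes(pool3, 5000, maf_floor = 0.05, seed = 3)
  expect_equal(g3$kept, 2L)
  expect_error(generate_genotypes(pool3, 5000, maf_floor = 0.9),
               "empty gene")
})

test_that("haplotype pools hit their target frequency mix", {
  pool <- synth_haplotype_pool(n_hap = 458, M = 23, seed = 42)
  expect_equal(dim(pool$H), c(458L, 23L))
  expect_true(all(pool$H %in% 0:1))
  maf <- pmin(pool$maf, 1 - pool$maf)
  expect_gte(sum(maf >= 0.05), 8)  # a usable common-variant core
})

test_that("expression generation hits the target heritability exactly", {
  set.seed(10)
  pool <- synth_haplotype_pool(n_hap = 100, M = 12, seed = 10)
  X <- generate_genotypes(pool, 500, maf_floor = 0.05)$X
  cfg <- sim_config(M = ncol(X), K = 3, p_causal = 0.4, h_e2 = 0.25,
                    h_p2 = 0.2, n = 500)
  gw <- generate_weights_and_expression(X, cfg)
  for (k in 1:3) {
    expect_equal(var(drop(X %*% gw$w_true[, k])), 0.25, tolerance = 1e-10)
    expect_equal(sum(gw$w_true[, k] != 0), cfg$M_causal)
  }
  # zero expression heritability: weights vanish, expression is unit noise
  cfg0 <- sim_config(M = ncol(X), K = 2, p_causal = 0.4, h_e2 = 0,
                     h_p2 = 0, n = 500)
  gw0 <- generate_weights_and_expression(X, cfg0)
  expect_true(all(gw0$w_true == 0))
  expect_equal(var(gw0$E[, 1]), 1, tolerance = 0.2)
})

test_that("phenotype effect vectors follow the scenarios", {
  E <- matrix(rnorm(400), 100, 4)
  cfg <- sim_config(M = 10, K = 4, h_p2 = 0.2, scenario = "uni", n = 100)
  expect_equal(generate_phenotype(E, cfg, seed = 1)$beta, rep(sqrt(0.05), 4))
  cfgb <- sim_config(M = 10, K = 4, h_p2 = 0.2, scenario = "bi", n = 100)
  b0 <- sqrt(0.05)
  expect_equal(generate_phenotype(E, cfgb, seed = 1)$beta,
               c(b0, b0, -b0, -b0))
  cfg0 <- sim_config(M = 10, K = 4, h_p2 = 0, scenario = "uni", n = 100)
  ph0 <- generate_phenotype(E, cfg0, seed = 1)
  expect_equal(ph0$beta, rep(0, 4))
  expect_error(sim_config(M = 10, K = 3, scenario = "uni_noise"),
               "K = 4")
  # noise scenarios perturb around +-beta0 with the stated signs
  cfgn <- sim_config(M = 10, K = 4, h_p2 = 0.2, scenario = "bi_noise",
                     n = 100)
  set.seed(77)
  bs <- replicate(50, generate_phenotype(E, cfgn)$beta)
  expect_lt(mean(bs[1, ]), 0)
  expect_gt(mean(bs[3, ]), 0)
  expect_gt(var(bs[2, ]), var(bs[1, ]))  # less relevant tissue is noisier
})

test_that("OLS Z-scores are computed per variant and guarded", {
  set.seed(20)
  n <- 3000
  X <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.45), rbinom(n, 2, 0.2))
  Y <- rnorm(n)
  Z <- compute_z_scores(X, Y)
  # against lm() on one variant
  fit <- summary(lm(Y ~ X[, 2]))$coefficients
  expect_equal(unname(Z[2]), unname(fit[2, 3]), tolerance = 1e-10)
  # null Z-scores approximately standard normal
  Znull <- as.numeric(replicate(40, compute_z_scores(X, rnorm(n))))
  expect_gt(suppressWarnings(ks.test(Znull, "pnorm"))$p.value, 0.001)
  # perfect fit capped, constant column dropped with a warning
  expect_equal(unname(compute_z_scores(cbind(X[, 1], X[, 1]), X[, 1])[1]),
               1e8)
  expect_warning(z2 <- compute_z_scores(cbind(X[, 1], rep(1, n)), Y),
                 "constant")
  expect_length(z2, 1)
  # duplicating individuals preserves the sign of every Z-score
  Ys <- drop(X %*% c(0.2, -0.1, 0)) + rnorm(n)
  z1 <- compute_z_scores(X, Ys)
  z2 <- compute_z_scores(rbind(X, X), c(Ys, Ys))
  expect_equal(sign(z1), sign(z2))
})

test_that("simulation is reproducible from the seed", {
  pool1 <- synth_haplotype_pool(seed = 5)
  pool2 <- synth_haplotype_pool(seed = 5)
  expect_identical(pool1$H, pool2$H)
  g1 <- generate_genotypes(pool1, 100, seed = 6)
  g2 <- generate_genotypes(pool2, 100, seed = 6)
  expect_identical(g1, g2)
})

test_that("signal flows end to end through the generative pipeline", {
  # with a large cohort and one study, the S-TWAS statistic built on the
  # true weights must clear the genome-wide threshold
  set.seed(30)
  pool <- synth_haplotype_pool(n_hap = 458, M = 23, seed = 30)
  nsig <- 0L
  for (r in 1:10) {
    X <- generate_genotypes(pool, 5e4, maf_floor = 0.05)$X
    cfg <- sim_config(M = ncol(X), K = 1, p_causal = 0.3, h_e2 = 0.2,
                      h_p2 = 0.3, n = 5e4)
    gw <- generate_weights_and_expression(X, cfg)
    Y <- generate_phenotype(gw$E, cfg)$Y
    Z <- as.numeric(compute_z_scores(X, Y))
    R <- cor(X)
    p <- s_twas(Z, R, standardize_weights(gw$w_true[, 1]))$p
    nsig <- nsig + (p < 1.75e-6)
  }
  expect_gte(nsig, 9L)
})
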