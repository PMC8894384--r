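test_that("effective number of tests matches the eigenvalue formula", {
  for (l in c(2, 5, 15))
    expect_equal(as.numeric(effective_number(diag(l))), l)
  for (l in c(2, 5, 15))
    expect_equal(as.numeric(effective_number(matrix(1, l, l))), 1)
  expect_equal(as.numeric(effective_number(matrix(c(1, .5, .5, 1), 2))), 1.5)
})

test_that("effective number lies in [1, l] for random correlation matrices", {
  set.seed(21)
  for (i in 1:20) {
    l <- sample(2:12, 1)
    me <- as.numeric(effective_number(random_corr(l, jitter = 0.1)))
    expect_gte(me, 1)
    expect_lte(me, l)
  }
})

test_that("extended Simes reduces to classical Simes under independence", {
  p <- c(a = 0.01, b = 0.02, c = 0.03)
  I3 <- diag(3); dimnames(I3) <- list(names(p), names(p))
  expect_equal(overall_pvalue(p, I3)$p_overall, 0.03)
  set.seed(31)
  for (i in 1:50) {
    L <- sample(2:15, 1)
    p <- setNames(runif(L)^2, paste0("t", seq_len(L)))
    I <- diag(L); dimnames(I) <- list(names(p), names(p))
    expect_equal(overall_pvalue(p, I)$p_overall, simes_pvalue(p),
                 tolerance = 1e-12)
  }
})

test_that("perfect dependence collapses to the smallest p-value", {
  p <- c(x = 0.4, y = 0.07, z = 0.9)
  J <- matrix(1, 3, 3); dimnames(J) <- list(names(p), names(p))
  res <- overall_pvalue(p, J)
  expect_equal(res$p_overall, 0.07)
  expect_equal(res$m_e, 1)
})

test_that("a two-test correlated case matches the hand calculation", {
  p <- c(u = 0.01, v = 0.5)
  Om <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(names(p), names(p)))
  res <- overall_pvalue(p, Om)
  # m_e(1) = 1, m_e = m_e(2) = 1.5: min(1.5*0.01/1, 1.5*0.5/1.5)
  expect_equal(res$p_overall, 0.015)
  expect_equal(res$m_e_l, c(1, 1.5))
})

test_that("the combined p-value is invariant to label permutations", {
  set.seed(17)
  L <- 9
  p <- setNames(runif(L), paste0("t", 1:L))
  Om <- random_corr(L, jitter = 0.2)
  dimnames(Om) <- list(names(p), names(p))
  r1 <- overall_pvalue(p, Om)$p_overall
  for (i in 1:3) {
    perm <- sample(L)
    expect_equal(overall_pvalue(p[perm], Om[perm, perm])$p_overall, r1)
  }
  expect_error(overall_pvalue(unname(p), Om), "labels")
})

test_that("replicated null correlation has exact structure", {
  R <- synth_ld(6, "ar1", 0.5)
  # duplicated eQTL study: the twin tests must be perfectly correlated
  set.seed(2)
  w <- rnorm(6)
  ws <- weight_set(cbind(s1 = w, s2 = w))
  Om <- estimate_null_correlation(R, ws, B = 80, seed = 7)
  expect_equal(diag(Om), rep(1, 9), ignore_attr = TRUE)
  expect_equal(Om["BT_s1", "BT_s2"], 1, tolerance = 1e-12)
  expect_equal(Om["SKAT_s1", "SKAT_s2"], 1, tolerance = 1e-12)
  expect_equal(Om["SKATO_s1", "SKATO_s2"], 1, tolerance = 1e-12)
  # deterministic given the seed
  Om2 <- estimate_null_correlation(R, ws, B = 80, seed = 7)
  expect_identical(Om, Om2)
  expect_true(all(Om >= -1 - 1e-12 & Om <= 1 + 1e-12))
})

test_that("replication estimate converges with the number of replicates", {
  R <- synth_ld(8, "ar1", 0.5)
  set.seed(3)
  ws <- weight_set(matrix(rnorm(16), 8, 2))
  tab <- omega_convergence(R, ws, B_grid = c(25, 100, 400), B_ref = 400,
                           seed = 5)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$max_abs_diff[3], 0)
  expect_equal(tab$frobenius[3], 0)
  expect_lt(tab$max_abs_diff[2], tab$max_abs_diff[1] + 0.05)
})
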