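test_that("weight standardization follows the absolute-sum rule", {
  expect_equal(standardize_weights(c(2, -2)), c(0.5, -0.5))
  expect_equal(standardize_weights(1), 1)
  expect_error(standardize_weights(c(0, 0)), "degenerate")
  expect_warning(weight_set(cbind(a = c(1, 2), b = c(0, 0))), "all-zero")
  ws <- suppressWarnings(weight_set(cbind(a = c(1, 2), b = c(0, 0))))
  expect_equal(ws$labels, c("0", "a"))
  expect_equal(colSums(abs(ws$W[, -1, drop = FALSE])), 1,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("test count is 3(K+1) with fixed label order", {
  labs <- function(K) {
    ws <- if (K > 0) weight_set(matrix(1, 4, K)) else weight_set(M = 4)
    overallgene:::.test_labels(ws$labels)
  }
  expect_length(labs(4), 15)
  expect_length(labs(20), 63)
  expect_length(labs(0), 3)
  expect_equal(labs(1)[1:3], c("BT_0", "SKAT_0", "SKATO_0"))
})

test_that("burden test matches hand calculations", {
  # M = 1: p is the two-sided normal tail
  expect_equal(bt_test(2, matrix(1), 1), 2 * pnorm(-2))
  # M = 2 with w = (0.5, 0.5) and off-diagonal 0.5: v = 0.75
  U <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(bt_test(c(2, 2), U, c(0.5, 0.5)),
               pchisq(16 / 3, 1, lower.tail = FALSE))
  expect_equal(bt_test(c(0, 0), U, c(0.5, 0.5)), 1)
  expect_error(bt_test(c(1, -1), U, c(1, -1) * 1e-9), "degenerate")
})

test_that("SKAT matches eigen decompositions and Monte-Carlo oracles", {
  # M = 1 reduces to the burden test
  expect_equal(skat_test(2, matrix(1), 1), bt_test(2, matrix(1), 1))
  # M = 2, identity weights: eigenvalues 1 +- r
  U <- matrix(c(1, 0.5, 0.5, 1), 2)
  p <- skat_test(c(1, 1), U, c(1, 1))
  expect_equal(p, quad_form_pvalue(2, c(1.5, 0.5)))
  expect_equal(skat_test(c(0, 0), U, c(1, 1)), 1)
  set.seed(8)
  for (i in 1:5) {
    M <- sample(2:6, 1)
    R <- random_corr(M)
    w <- standardize_weights(rnorm(M))
    Z <- drop(crossprod(chol(R), rnorm(M))) * runif(1, 0.8, 2)
    Q <- sum((w * Z)^2)
    ev <- eigen(outer(w, w) * R, symmetric = TRUE, only.values = TRUE)$values
    mc <- mc_quadform_sf(Q, ev[ev > 1e-10 * max(ev)])
    expect_lt(abs(skat_test(Z, R, w) - mc$p), 3 * mc$se + 1e-9)
  }
})

test_that("SKAT-O reduces to its endpoints and respects min-p bounds", {
  set.seed(4)
  R <- synth_ld(5, "ar1", 0.4)
  w <- standardize_weights(rnorm(5))
  Z <- drop(crossprod(chol(R), rnorm(5)))
  expect_equal(skato_test(Z, R, w, rho_grid = 0), skat_test(Z, R, w),
               tolerance = 1e-6)
  expect_equal(skato_test(Z, R, w, rho_grid = 1), bt_test(Z, R, w),
               tolerance = 1e-6)
  expect_equal(skato_test(2, matrix(1), 1), bt_test(2, matrix(1), 1))
  grid <- skato_rho_grid()
  for (i in 1:5) {
    M <- sample(3:8, 1)
    R <- random_corr(M)
    w <- standardize_weights(rnorm(M))
    Z <- drop(crossprod(chol(R), rnorm(M))) * runif(1, 0.5, 2.5)
    res <- overallgene:::.skato_cpp(outer(w, w) * R, sum((w * Z)^2),
                                    sum(w * Z)^2, grid, 1e-8, FALSE)
    expect_gte(res$p, res$pmin - 1e-12)
    expect_lte(res$p, min(1, length(grid) * res$pmin) + 1e-12)
    expect_equal(res$pmin, min(res$p_rho))
  }
})

test_that("p-values are invariant to the scale of raw weights", {
  set.seed(12)
  R <- synth_ld(6, "ar1", 0.5)
  raw <- rnorm(6)
  Z <- drop(crossprod(chol(R), rnorm(6)))
  for (cc in c(3, -2, 0.01)) {
    w1 <- standardize_weights(raw)
    w2 <- standardize_weights(raw * cc)
    expect_equal(bt_test(Z, R, w1), bt_test(Z, R, w2))
    expect_equal(skat_test(Z, R, w1), skat_test(Z, R, w2))
    expect_equal(skato_test(Z, R, w1), skato_test(Z, R, w2),
                 tolerance = 1e-8)
  }
})

test_that("burden p-values are uniform under the multivariate-normal null", {
  set.seed(99)
  M <- 6
  R <- synth_ld(M, "ar1", 0.5)
  w <- rep(1, M)
  v <- drop(crossprod(w, R %*% w))
  Z <- draw_mvn(1e4, R)
  p <- pchisq(rowSums(Z)^2 / v, 1, lower.tail = FALSE)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
})

test_that("all_tests returns the full labeled battery", {
  set.seed(5)
  M <- 6
  R <- synth_ld(M, "ar1", 0.3)
  W <- matrix(rnorm(M * 2), M, 2, dimnames = list(NULL, c("x", "y")))
  ws <- weight_set(W)
  Z <- drop(crossprod(chol(R), rnorm(M)))
  p <- all_tests(Z, R, ws)
  expect_length(p, 9)
  expect_named(p, c("BT_0", "SKAT_0", "SKATO_0", "BT_x", "SKAT_x",
                    "SKATO_x", "BT_y", "SKAT_y", "SKATO_y"))
  expect_true(all(p > 0 & p <= 1))
  expect_equal(unname(p["BT_x"]), bt_test(Z, R, ws$W[, 2]))
})
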