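test_that("the fitting function returns a coherent result object", {
  set.seed(2)
  M <- 8
  R <- synth_ld(M, "ar1", 0.5)
  z <- drop(crossprod(chol(R), rnorm(M)))
  W <- matrix(rnorm(M * 2), M, 2, dimnames = list(NULL, c("tA", "tB")))
  fit <- overall_test(z, R, W, B = 150, seed = 11, gene_id = "demo")
  expect_s3_class(fit, "overall_fit")
  expect_equal(fit$M, M)
  expect_equal(fit$K, 2L)
  expect_length(fit$p_tests, 9)
  expect_true(all(fit$p_tests > 0 & fit$p_tests <= 1))
  expect_gte(fit$p_overall, 0)
  expect_lte(fit$p_overall, 1)
  expect_gte(fit$a_hat, 0)
  expect_lte(fit$a_hat, 1)
  expect_equal(dim(fit$omega), c(9L, 9L))
  expect_equal(nrow(fit$comparators), 2L)
  # the per-rank effective numbers are bounded by the rank
  expect_true(all(fit$m_e_l >= 1 & fit$m_e_l <= seq_along(fit$m_e_l)))
  # same seed gives identical results
  fit2 <- overall_test(z, R, W, B = 150, seed = 11, gene_id = "demo")
  expect_equal(fit$p_overall, fit2$p_overall)
  expect_equal(fit$omega, fit2$omega)
  # a supplied omega is used as-is
  fit3 <- overall_test(z, R, W, omega = fit$omega)
  expect_equal(fit3$p_overall, fit$p_overall)
})

test_that("print, summary and plot methods run cleanly", {
  set.seed(4)
  R <- synth_ld(5, "ar1", 0.4)
  z <- drop(crossprod(chol(R), rnorm(5)))
  fit <- overall_test(z, R, B = 60, seed = 2)
  expect_output(print(fit), "p_overall")
  expect_output(print(summary(fit)), "Component test p-values")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("file-based inputs reproduce an in-memory analysis", {
  R <- read_ld_matrix(extdata("gene1_ld.tsv"))
  ss <- read_summary_stats(extdata("gene1_sumstats.tsv"))
  wt <- read_weights(extdata("gene1_weights.tsv"))
  ids <- rownames(R)
  expect_true(all(ids %in% ss$id))
  z <- setNames(ss$z[match(ids, ss$id)], ids)
  W <- wt$W[match(ids, wt$ids), ]
  fit <- overall_test(z, R, W, B = 100, seed = 5, gene_id = "gene1")
  expect_true(fit$p_overall > 0 && fit$p_overall <= 1)
  expect_equal(names(fit$p_tests)[1:3], c("BT_0", "SKAT_0", "SKATO_0"))
})

test_that("the command-line interface drives the same pipeline", {
  script <- system.file("cli", "overallgene", package = "overallgene")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- tempfile(fileext = ".tsv")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  res <- system2(rscript,
                 c(script, "test",
                   "--sumstats", shQuote(extdata("gene1_sumstats.tsv")),
                   "--ld", shQuote(extdata("gene1_ld.tsv")),
                   "--weights", shQuote(extdata("gene1_weights.tsv")),
                   "--estimate-omega", "100", "--seed", "3",
                   "--gene-id", "gene1", "--out", shQuote(out)),
                 env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  d <- read.delim(out, check.names = FALSE)
  expect_equal(d$gene_id, "gene1")
  expect_true(d$p_overall > 0 && d$p_overall <= 1)
  expect_true(all(c("BT_0", "SKATO_tissueB") %in% names(d)))
})
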