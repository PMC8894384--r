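#' Empirical type-I-error experiment
#'
#' Draws `n_rep` null Z-score vectors from `MVN(0, R)`, applies the LD
#' regularization and the full battery of weighted gene-based tests plus the
#' extended-Simes (`Overall`) and Cauchy (`OT`) combinations, and tabulates
#' the proportion of p-values below each significance level.  The null
#' p-value correlation matrix is estimated once (with `omega_B`
#' replications) before the rate loop.
#'
#' @param R LD correlation matrix.
#' @param weights A [weight_set()].
#' @param n_rep Number of null replicates.
#' @param alphas Significance levels.
#' @param seed Integer seed.
#' @param omega_B Replications for the null-correlation estimate.
#' @param rho_grid SKAT-O rho grid.
#' @param acc Quadratic-form accuracy.
#' @param refit_a Whether to re-estimate the LD shrinkage parameter from
#'   each simulated Z-vector.  Default `FALSE`: in this experiment the
#'   Z-scores are drawn from the very matrix used as the null covariance, so
#'   the generative truth is `a = 1` and a single-draw ML refit only injects
#'   noise (with real reference-panel LD matrices, which are close to
#'   singular, the likelihood pins `a` at 1 and the refit is innocuous).
#' @return Data frame with columns `method`, `alpha`, `rate`, `se`
#'   (binomial standard error); the matrix of simulated p-values is attached
#'   as attribute `"pvalues"`.
#' @export
type1_experiment <- function(R, weights, n_rep = 10000L,
                             alphas = c(0.05, 0.01), seed = 1L,
                             omega_B = 1000L, rho_grid = skato_rho_grid(),
                             acc = 1e-5, refit_a = FALSE) {
  stopifnot(inherits(weights, "weight_set"))
  .check_corr_matrix(R)
  Omega <- estimate_null_correlation(R, weights, B = omega_B, seed = seed,
                                     rho_grid = rho_grid, acc = acc,
                                     refit_a = refit_a)
  labels <- .test_labels(weights$labels)
  P <- .null_pvalue_replicates(R, weights$W, n_rep, seed + 1L, rho_grid,
                               refit_a = refit_a, a_fixed = 1, acc = acc,
                               fast = TRUE)
  colnames(P) <- labels
  cache <- new.env(hash = TRUE, parent = emptyenv())
  extra <- t(apply(P, 1L, function(p) {
    c(Overall = .overall_pvalue_core(p, Omega, cache)$p_overall,
      OT = cauchy_combine(p))
  }))
  P <- cbind(P, extra)
  out <- do.call(rbind, lapply(colnames(P), function(m) {
    rate <- vapply(alphas, function(a) mean(P[, m] < a), 0)
    data.frame(method = m, alpha = alphas, rate = rate,
               se = sqrt(rate * (1 - rate) / n_rep))
  }))
  rownames(out) <- NULL
  attr(out, "pvalues") <- P
  out
}

#' Power experiment over a grid of generative settings
#'
#' For each cell of the settings grid, `n_rep` cohorts are generated from
#' the haplotype pool; each replicate draws a fresh gene architecture
#' (causal variants, raw eQTL weights, expression and phenotype), computes
#' per-variant OLS Z-scores and a cohort-estimated LD matrix, and applies
#' all methods.  Power is the proportion of replicates with p-value below
#' `alpha`.  The null p-value correlation matrix is estimated once per cell
#' (from the pool LD and a representative weight draw), mirroring the
#' estimate-once-per-gene usage.  `BEST` is the per-cell maximum power over
#' the individual weighted/unweighted tests, and `S-TWAS.B` /
#' `S-PrediXcan.B` the maxima over the per-study comparators.
#'
#' @param pool A [synth_haplotype_pool()].
#' @param cells Data frame of settings with columns `scenario`, `p_causal`,
#'   `h_e2`, `h_p2`.
#' @param n_rep Replicates per cell.
#' @param alpha Significance level (genome-wide: `1.75e-6`).
#' @param seed Integer seed.
#' @param K Number of eQTL studies.
#' @param n Cohort size.
#' @param maf_floor MAF analysis floor, applied once per cell at the pool
#'   level so the variant set (and hence the null-correlation matrix) is
#'   fixed across replicates.
#' @param omega_B Replications for the per-cell null-correlation estimate.
#' @param rho_grid SKAT-O rho grid.
#' @param acc Quadratic-form accuracy.
#' @return Data frame with one row per (cell, method): the cell settings,
#'   `method`, `power`, and binomial `se`.
#' @export
power_experiment <- function(pool, cells, n_rep = 200L, alpha = 1.75e-6,
                             seed = 1L, K = 4L, n = 2000L, maf_floor = 0.05,
                             omega_B = 1000L, rho_grid = skato_rho_grid(),
                             acc = 1e-7) {
  stopifnot(all(c("scenario", "p_causal", "h_e2", "h_p2") %in% names(cells)))
  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    cell_seed <- seed + 101L * ci
    set.seed(cell_seed)
    # pool-level MAF filter fixes the analysis variant set for the cell
    pool_maf <- pmin(pool$maf, 1 - pool$maf)
    kept <- which(pool_maf >= maf_floor)
    if (length(kept) == 0L) stop("all pool variants below the MAF floor")
    H <- pool$H[, kept, drop = FALSE]
    subpool <- list(H = H, frequencies = pool$frequencies)
    M <- length(kept)
    cfg <- sim_config(M = M, K = K, p_causal = cell$p_causal,
                      h_e2 = cell$h_e2, h_p2 = cell$h_p2, n = n,
                      scenario = as.character(cell$scenario),
                      maf_floor = maf_floor)
    # representative weight draw for the once-per-cell null correlation
    w_raw <- matrix(0, M, K)
    for (k in seq_len(K)) {
      causal <- sample.int(M, min(cfg$M_causal, M))
      w_raw[causal, k] <- rnorm(length(causal))
    }
    ws <- weight_set(w_raw)
    R_pool <- stats::cor(H)
    Omega <- estimate_null_correlation(R_pool, ws, B = omega_B,
                                       seed = cell_seed + 1L,
                                       rho_grid = rho_grid, acc = acc)
    labels <- .test_labels(ws$labels)
    meth_names <- c(labels, "Overall", "OT",
                    paste0("S-TWAS_", ws$labels[-1L]),
                    paste0("S-PrediXcan_", ws$labels[-1L]))
    Pm <- matrix(NA_real_, n_rep, length(meth_names),
                 dimnames = list(NULL, meth_names))
    cache <- new.env(hash = TRUE, parent = emptyenv())
    set.seed(cell_seed + 2L)
    for (r in seq_len(n_rep)) {
      gg <- generate_genotypes(subpool, n, maf_floor = 0)
      if (length(gg$kept) < M) next  # cohort lost a variant; skip replicate
      X <- gg$X
      gw <- generate_weights_and_expression(X, cfg)
      ph <- generate_phenotype(gw$E, cfg)
      Z <- as.numeric(compute_z_scores(X, ph$Y))
      Rhat <- suppressWarnings(stats::cor(X))
      if (anyNA(Rhat)) next
      ctx <- .gene_context(Rhat)
      y2 <- drop(crossprod(ctx$vectors, Z))^2
      a <- .estimate_tuning_spec(y2, ctx$values)
      U <- a * Rhat + (1 - a) * ctx$I
      wstd <- apply(gw$w_true, 2L, standardize_weights)
      p <- .all_tests_core(Z, U, cbind(1, wstd), rho_grid, acc,
                           fast = TRUE)
      names(p) <- labels
      if (anyNA(p)) next
      ov <- .overall_pvalue_core(p, Omega, cache)$p_overall
      ot <- cauchy_combine(p)
      ptw <- vapply(seq_len(K),
                    function(k) s_twas(Z, Rhat, wstd[, k])$p, 0)
      ppx <- vapply(seq_len(K),
                    function(k) s_predixcan(Z, wstd[, k], R = Rhat)$p, 0)
      Pm[r, ] <- c(p, ov, ot, ptw, ppx)
    }
    ok <- !is.na(Pm[, 1L])
    nr <- sum(ok)
    pow <- colMeans(Pm[ok, , drop = FALSE] < alpha)
    # reporting conventions: per-cell maxima
    pow <- c(pow,
             BEST = max(pow[labels]),
             `S-TWAS.B` = max(pow[paste0("S-TWAS_", ws$labels[-1L])]),
             `S-PrediXcan.B` = max(pow[paste0("S-PrediXcan_",
                                              ws$labels[-1L])]))
    res[[ci]] <- data.frame(scenario = as.character(cell$scenario),
                            p_causal = cell$p_causal, h_e2 = cell$h_e2,
                            h_p2 = cell$h_p2, method = names(pow),
                            power = as.numeric(pow),
                            se = sqrt(pow * (1 - pow) / nr),
                            n_rep = nr)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
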