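#' Effective number of correlated tests
#'
#' For an `l x l` correlation matrix with eigenvalues `lambda_i`, the
#' effective number of tests is
#' `m_e(l) = l - sum((lambda_i - 1) * I(lambda_i > 1))`.
#' Independent tests give `m_e = l`; perfectly dependent tests give
#' `m_e = 1`.  Sampling noise can make estimated correlation matrices
#' slightly non-PSD, so eigenvalues are clipped at zero first (the clipped
#' mass is returned as an attribute).
#'
#' @param sub_corr Correlation matrix (symmetric, unit diagonal).
#' @return The effective number, a scalar in `[1, l]`.
#' @export
effective_number <- function(sub_corr) {
  sub_corr <- as.matrix(sub_corr)
  l <- nrow(sub_corr)
  if (l == 1L) return(structure(1, clipped = 0))
  ev <- eigen(sub_corr, symmetric = TRUE, only.values = TRUE)$values
  clipped <- -sum(ev[ev < 0])
  ev[ev < 0] <- 0
  me <- l - sum((ev - 1)[ev > 1])
  structure(me, clipped = clipped)
}

#' Combine correlated p-values with the extended Simes procedure
#'
#' Sorts the `L` p-values ascending and returns
#' `p_overall = min_l { m_e * p_(l) / m_e(l) }`, where `m_e(l)` is the
#' effective number of tests among the `l` smallest p-values (computed from
#' the corresponding submatrix of the null p-value correlation matrix
#' `Omega`) and `m_e = m_e(L)`.  With `Omega = I` this reduces to the
#' classical Simes p-value.
#'
#' @param p Named vector of p-values.
#' @param Omega Null correlation matrix of the p-values, with dimnames
#'   matching `names(p)` as a set (e.g. from
#'   [estimate_null_correlation()]).
#' @return An object of class `overall_pvalue`: a list with `p_overall`,
#'   `m_e`, the per-rank `m_e_l`, and the label `ordering` by ascending p.
#' @export
overall_pvalue <- function(p, Omega) {
  stopifnot(is.numeric(p), length(p) >= 1L)
  if (is.null(names(p)) || is.null(rownames(Omega)))
    stop("p and Omega must carry matching labels")
  if (!setequal(names(p), rownames(Omega)) || length(p) != nrow(Omega))
    stop("labels of p and Omega do not match")
  Omega <- Omega[names(p), names(p), drop = FALSE]
  res <- .overall_pvalue_core(p, Omega)
  structure(list(p_overall = res$p_overall, m_e = res$m_e,
                 m_e_l = res$m_e_l,
                 ordering = names(p)[res$ord]),
            class = "overall_pvalue")
}

#' @export
print.overall_pvalue <- function(x, ...) {
  cat("Extended-Simes combination of ", length(x$m_e_l), " tests\n",
      "  p_overall = ", format(x$p_overall, digits = 6),
      "  (m_e = ", format(x$m_e, digits = 4), ")\n", sep = "")
  invisible(x)
}

# cache: environment keyed by the index set of the top-l tests
.overall_pvalue_core <- function(p, Omega, cache = NULL) {
  L <- length(p)
  ord <- order(p, seq_len(L))
  me_l <- numeric(L)
  for (l in seq_len(L)) {
    idx <- sort(ord[seq_len(l)])
    if (!is.null(cache)) {
      key <- paste(idx, collapse = ",")
      v <- cache[[key]]
      if (is.null(v)) {
        v <- as.numeric(effective_number(Omega[idx, idx, drop = FALSE]))
        cache[[key]] <- v
      }
      me_l[l] <- v
    } else {
      me_l[l] <- as.numeric(effective_number(Omega[idx, idx, drop = FALSE]))
    }
  }
  me <- me_l[L]
  list(p_overall = min(1, min(me * p[ord] / me_l)), m_e = me, m_e_l = me_l,
       ord = ord)
}

#' Estimate the null correlation of the combined tests by replication
#'
#' Draws `B` Z-score vectors from `MVN(0, R)`, applies the LD regularization
#' and the full battery of gene-based tests to each, and returns the Pearson
#' sample correlation matrix of the resulting p-value columns.  The
#' procedure only needs to be run once per gene; 1000 replications are
#' enough for a stable estimate.
#'
#' @param R LD correlation matrix used to draw null Z-scores.
#' @param weights A [weight_set()].
#' @param B Number of replications (at least 2).
#' @param seed Integer seed for the replication draws.
#' @param rho_grid SKAT-O rho grid.
#' @param refit_a If `TRUE` (default) the shrinkage parameter is re-estimated
#'   from each simulated Z-vector; if `FALSE` it is fixed at `a_fixed`.
#' @param a_fixed Shrinkage parameter used when `refit_a = FALSE`.
#' @param acc Quadratic-form accuracy used inside the replications.
#' @return Labeled `L x L` correlation matrix (class `matrix`), with unit
#'   diagonal; degenerate (constant) p-value columns get zero correlations
#'   with a warning.
#' @export
estimate_null_correlation <- function(R, weights, B = 1000L, seed = 1L,
                                      rho_grid = skato_rho_grid(),
                                      refit_a = TRUE, a_fixed = 1,
                                      acc = 1e-7) {
  stopifnot(B >= 2L, inherits(weights, "weight_set"))
  .check_corr_matrix(R)
  labels <- .test_labels(weights$labels)
  P <- .null_pvalue_replicates(R, weights$W, B, seed, rho_grid,
                               refit_a, a_fixed, acc, fast = TRUE)
  colnames(P) <- labels
  const <- apply(P, 2L, function(x) all(!is.finite(x)) ||
                   isTRUE(sd(x, na.rm = TRUE) == 0))
  Omega <- suppressWarnings(cor(P, use = "pairwise.complete.obs"))
  if (any(const) || anyNA(Omega)) {
    warning("degenerate test column(s) in the replication; ",
            "their correlations are set to 0")
    Omega[!is.finite(Omega)] <- 0
  }
  diag(Omega) <- 1
  Omega
}

# B x L matrix of null p-values (shared by the omega estimator and the
# type-I experiment)
.null_pvalue_replicates <- function(R, W, B, seed, rho_grid, refit_a,
                                    a_fixed, acc, fast = TRUE) {
  M <- nrow(R)
  set.seed(seed)
  ctx <- .gene_context(R)
  Zmat <- matrix(rnorm(B * M), B, M) %*% ctx$chol
  L <- 3L * ncol(W)
  P <- matrix(NA_real_, B, L)
  for (b in seq_len(B)) {
    Z <- Zmat[b, ]
    a <- if (refit_a) {
      y2 <- drop(crossprod(ctx$vectors, Z))^2
      .estimate_tuning_spec(y2, ctx$values)
    } else a_fixed
    U <- a * R + (1 - a) * ctx$I
    P[b, ] <- .all_tests_core(Z, U, W, rho_grid, acc, fast)
  }
  P
}

.gene_context <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  evc <- pmax(e$values, 0)
  # pivoted-free draw root: R = Vsqrt' Vsqrt
  ch <- diag(sqrt(evc)) %*% t(e$vectors)
  list(values = e$values, vectors = e$vectors, chol = ch, I = diag(nrow(R)))
}

#' Convergence of the replication estimate of the p-value correlation
#'
#' Re-estimates the null p-value correlation matrix at each replication
#' count in `B_grid` and reports its distance from a reference estimate at
#' `B_ref`, as a convergence diagnostic for choosing `B`.
#'
#' @inheritParams estimate_null_correlation
#' @param B_grid Integer vector of replication counts to evaluate.
#' @param B_ref Reference replication count (at least `max(B_grid)`).
#' @return A data frame with one row per `B`: the maximum absolute
#'   entrywise difference and the Frobenius distance from the reference.
#' @export
omega_convergence <- function(R, weights, B_grid, B_ref, seed = 1L,
                              rho_grid = skato_rho_grid(), acc = 1e-7) {
  stopifnot(B_ref >= max(B_grid))
  ref <- estimate_null_correlation(R, weights, B = B_ref, seed = seed,
                                   rho_grid = rho_grid, acc = acc)
  out <- lapply(B_grid, function(B) {
    Om <- estimate_null_correlation(R, weights, B = B, seed = seed,
                                    rho_grid = rho_grid, acc = acc)
    d <- Om - ref
    data.frame(B = B, max_abs_diff = max(abs(d)),
               frobenius = sqrt(sum(d^2)))
  })
  do.call(rbind, out)
}
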