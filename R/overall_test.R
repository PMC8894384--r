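#' Gene-based association test combining weighted tests with extended Simes
#'
#' The main fitting function.  Given the per-variant Z-scores of a gene, an
#' LD correlation matrix, and (optionally) `K` eQTL-derived weight vectors,
#' it
#' \enumerate{
#'   \item shrinks the LD matrix toward the identity with the tuning
#'     parameter estimated by maximum likelihood of `Z`,
#'   \item computes the `L = 3 (K + 1)` weighted burden / SKAT / SKAT-O
#'     p-values,
#'   \item estimates (or takes) the null correlation matrix of those
#'     p-values, and
#'   \item combines them into a single gene-level p-value with the extended
#'     Simes procedure, alongside the Cauchy-combination (`OT`) and the
#'     per-weight S-TWAS / S-PrediXcan comparators.
#' }
#'
#' @param z Named (or plain) numeric vector of variant Z-scores.
#' @param ld LD correlation matrix, variants in the same order as `z`.
#' @param weights Optional `M x K` matrix of raw eQTL-derived weights (one
#'   column per study); rows must follow the variant order of `z`.
#' @param omega Optional pre-estimated null p-value correlation matrix (as
#'   from [estimate_null_correlation()]); if `NULL` it is estimated with
#'   `B` replications.
#' @param B Replications for the null-correlation estimate.
#' @param seed Integer seed for the replication draws.
#' @param rho_grid SKAT-O rho grid.
#' @param refit_a Whether to re-estimate the shrinkage parameter per
#'   replication when estimating `omega`.
#' @param comparator_ld Use the raw LD (`"raw"`, as in the printed
#'   comparator formulas) or the corrected LD (`"corrected"`) in the
#'   comparators.
#' @param gene_id Optional gene identifier carried into the result.
#' @param acc Quadratic-form accuracy.
#' @return An object of class `overall_fit`; see [print.overall_fit()] and
#'   [summary.overall_fit()].
#' @examples
#' R <- synth_ld(8, "ar1", rho = 0.5)
#' set.seed(7)
#' z <- drop(crossprod(chol(R), rnorm(8)))
#' w <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("tisA", "tisB")))
#' fit <- overall_test(z, R, w, B = 200, seed = 42)
#' fit
#' @export
overall_test <- function(z, ld, weights = NULL, omega = NULL, B = 1000L,
                         seed = 1L, rho_grid = skato_rho_grid(),
                         refit_a = TRUE,
                         comparator_ld = c("raw", "corrected"),
                         gene_id = NULL, acc = 1e-9) {
  comparator_ld <- match.arg(comparator_ld)
  z <- drop(as.numeric(z))
  M <- length(z)
  .check_corr_matrix(ld)
  if (nrow(ld) != M) stop("dim(ld) does not match length(z)")
  ws <- if (is.null(weights)) weight_set(M = M) else weight_set(weights)
  if (nrow(ws$W) != M) stop("weights rows do not match length(z)")
  K <- length(ws$labels) - 1L

  a_hat <- estimate_tuning(z, ld)
  U <- corrected_ld(ld, a_hat)$U
  p_tests <- all_tests(z, U, ws, rho_grid = rho_grid, acc = acc)
  if (is.null(omega)) {
    omega <- estimate_null_correlation(ld, ws, B = B, seed = seed,
                                       rho_grid = rho_grid,
                                       refit_a = refit_a)
  }
  ov <- overall_pvalue(p_tests, omega[names(p_tests), names(p_tests),
                                      drop = FALSE])
  p_ot <- cauchy_combine(p_tests)

  comp <- NULL
  if (K > 0L) {
    Rcomp <- if (comparator_ld == "raw") ld else U
    comp <- do.call(rbind, lapply(seq_len(K), function(k) {
      w <- ws$W[, k + 1L]
      tw <- s_twas(z, Rcomp, w)
      px <- s_predixcan(z, w, R = Rcomp)
      data.frame(label = ws$labels[k + 1L], z_twas = tw$z_stat,
                 p_twas = tw$p, z_predixcan = px$z_stat,
                 p_predixcan = px$p, stringsAsFactors = FALSE)
    }))
  }
  structure(list(gene_id = if (is.null(gene_id)) "gene" else gene_id,
                 M = M, K = K, a_hat = a_hat,
                 p_tests = p_tests, p_overall = ov$p_overall,
                 m_e = ov$m_e, m_e_l = ov$m_e_l, ordering = ov$ordering,
                 p_ot = p_ot, comparators = comp, omega = omega,
                 rho_grid = rho_grid, call = match.call()),
            class = "overall_fit")
}

#' @rdname overall_test
#' @param x,object An `overall_fit` object.
#' @param ... Unused.
#' @export
print.overall_fit <- function(x, ...) {
  cat("Gene-based association test (extended Simes over ",
      length(x$p_tests), " weighted tests)\n", sep = "")
  cat("  gene: ", x$gene_id, "   variants: ", x$M, "   eQTL weights: ",
      x$K, "\n", sep = "")
  cat("  LD shrinkage a_hat = ", format(x$a_hat, digits = 4), "\n", sep = "")
  cat("  p_overall = ", format(x$p_overall, digits = 6),
      "   (effective tests m_e = ", format(x$m_e, digits = 4), ")\n",
      sep = "")
  cat("  p_OT      = ", format(x$p_ot, digits = 6),
      "   (Cauchy combination)\n", sep = "")
  top <- sort(x$p_tests)[seq_len(min(3L, length(x$p_tests)))]
  cat("  smallest component tests: ",
      paste(names(top), format(top, digits = 4), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname overall_test
#' @export
summary.overall_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.overall_fit")
}

#' @export
print.summary.overall_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nComponent test p-values:\n")
  print(data.frame(test = names(f$p_tests), p = unname(f$p_tests)),
        row.names = FALSE)
  if (!is.null(f$comparators)) {
    cat("\nComparators (per eQTL weight):\n")
    print(f$comparators, row.names = FALSE)
  }
  invisible(x)
}

#' @rdname overall_test
#' @export
plot.overall_fit <- function(x, ...) {
  p <- c(x$p_tests, Overall = x$p_overall, OT = x$p_ot)
  old <- par(mar = c(8, 4, 2, 1))
  on.exit(par(old))
  barplot(-log10(p), las = 2, ylab = expression(-log[10](p)),
          main = paste("Gene", x$gene_id), ...)
  abline(h = -log10(0.05), lty = 2)
  invisible(x)
}
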