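#' Standardize an eQTL-derived weight vector
#'
#' Weights are rescaled to `w_m = raw_m / sum(|raw|)` so that the absolute
#' weights sum to one; signs are preserved.  This removes the influence of
#' the scale of the raw per-variant effect estimates.
#'
#' @param raw Numeric weight vector with at least one nonzero entry.
#' @return The standardized weight vector.
#' @export
standardize_weights <- function(raw) {
  stopifnot(is.numeric(raw), length(raw) >= 1L)
  s <- sum(abs(raw))
  if (s == 0) stop("degenerate weight vector: all entries are zero")
  raw / s
}

#' Construct a weight set for the gene-based tests
#'
#' Bundles `K` raw eQTL-derived weight vectors together with the identity
#' "unweighted" vector (label `"0"`).  Each supplied column is standardized
#' with [standardize_weights()]; all-zero columns are dropped with a warning.
#'
#' @param raw_weights `M x K` numeric matrix of raw weights (one column per
#'   eQTL study), or `NULL` for the unweighted test only.
#' @param M Number of variants; required when `raw_weights` is `NULL`.
#' @param labels Optional study labels (defaults to column names or `1:K`).
#' @return An object of class `weight_set`: a list with `labels`
#'   (length `K + 1`, first element `"0"`) and `W`, the `M x (K+1)` matrix of
#'   standardized weights whose first column is all ones.
#' @export
weight_set <- function(raw_weights = NULL, M = NULL, labels = NULL) {
  if (is.null(raw_weights)) {
    stopifnot(!is.null(M))
    W <- matrix(1, M, 1L)
    return(structure(list(labels = "0", W = W), class = "weight_set"))
  }
  raw_weights <- as.matrix(raw_weights)
  M <- nrow(raw_weights)
  K <- ncol(raw_weights)
  if (is.null(labels))
    labels <- if (!is.null(colnames(raw_weights))) colnames(raw_weights)
              else as.character(seq_len(K))
  keep <- colSums(abs(raw_weights)) > 0
  if (!all(keep)) {
    warning("dropping all-zero weight column(s): ",
            paste(labels[!keep], collapse = ", "))
    raw_weights <- raw_weights[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  Wstd <- apply(raw_weights, 2L, standardize_weights)
  Wstd <- matrix(Wstd, nrow = M)
  W <- cbind(1, Wstd)
  structure(list(labels = c("0", labels), W = W), class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("Weight set: ", nrow(x$W), " variants, ", length(x$labels) - 1L,
      " eQTL studies (labels: ", paste(x$labels, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Default rho grid for SKAT-O
#'
#' Eleven points `0, 0.1^2, ..., 0.9^2, 1`, mirroring the canonical SKAT-O
#' implementation.
#' @return Numeric vector of length 11.
#' @export
skato_rho_grid <- function() c(0, (1:9 / 10)^2, 1)

.check_rho_grid <- function(grid) {
  stopifnot(is.numeric(grid), length(grid) >= 1L,
            all(grid >= 0), all(grid <= 1), !is.unsorted(grid, strictly = TRUE))
  grid
}

#' Weighted burden test from summary statistics
#'
#' `Q = (Z' W 1)^2` with null variance `v = w' U w`; `Q / v` is chi-square
#' with 1 df under the null.
#'
#' @param Z Variant Z-score vector.
#' @param U Corrected LD matrix (or raw LD).
#' @param w Standardized weight vector (all ones for the unweighted test).
#' @return The burden-test p-value.
#' @export
bt_test <- function(Z, U, w) {
  stopifnot(length(Z) == nrow(U), length(w) == length(Z))
  v <- drop(crossprod(w, U %*% w))
  if (v <= 1e-12)
    stop("degenerate burden test: weights are null under the LD metric")
  Q <- sum(w * Z)^2
  max(pchisq(Q / v, df = 1, lower.tail = FALSE), 1e-300)
}

#' Weighted SKAT test from summary statistics
#'
#' `Q = (W Z)' (W Z)`; under the null `Q` is a weighted sum of 1-df
#' chi-squares with weights the eigenvalues of `Sigma = W U W` (eigenvalues
#' below `1e-10` of the largest are dropped).
#'
#' @inheritParams bt_test
#' @param acc Accuracy passed to [quad_form_pvalue()].
#' @return The SKAT p-value.
#' @export
skat_test <- function(Z, U, w, acc = 1e-9) {
  stopifnot(length(Z) == nrow(U), length(w) == length(Z))
  Sigma <- outer(w, w) * U
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-10 * max(ev, 0)]
  if (length(ev) == 0L) stop("degenerate SKAT test: null weighted covariance")
  Q <- sum((w * Z)^2)
  quad_form_pvalue(Q, ev, acc = acc)
}

#' SKAT-O test from summary statistics
#'
#' Minimizes `(1 - rho) Q_SKAT + rho Q_BT` over a grid of `rho`, then turns
#' the minimum per-`rho` p-value into an overall p-value by one-dimensional
#' integration conditional on the common burden component.  Conditionally on
#' the burden score, the SKAT component is an exact noncentral weighted
#' chi-square, so the integration involves no moment-matching approximation.
#' The result is bracketed by `[min_p, |grid| * min_p]`.
#'
#' @inheritParams skat_test
#' @param rho_grid Strictly increasing grid in `[0, 1]`; see
#'   [skato_rho_grid()].
#' @param fast If `TRUE`, use the moment-matched (variance-adjusted)
#'   variant of the conditional construction instead of the exact noncentral
#'   integration; this is much faster and is the route used inside large
#'   replication loops.
#' @return The SKAT-O p-value.
#' @export
skato_test <- function(Z, U, w, rho_grid = skato_rho_grid(), acc = 1e-9,
                       fast = FALSE) {
  stopifnot(length(Z) == nrow(U), length(w) == length(Z))
  .check_rho_grid(rho_grid)
  if (length(Z) == 1L) return(bt_test(Z, U, w))
  Sigma <- outer(w, w) * U
  Qs <- sum((w * Z)^2)
  Qb <- sum(w * Z)^2
  res <- .skato_cpp(Sigma, Qs, Qb, rho_grid, acc, fast)
  min(max(res$p, 1e-300), 1)
}

#' All gene-based tests for one Z-score vector
#'
#' Computes the `L = 3 (K + 1)` p-values of the burden, SKAT and SKAT-O
#' tests under each weight (including the unweighted `k = 0`), in the fixed
#' label order `BT_k, SKAT_k, SKATO_k` for `k = 0..K`.  Degenerate
#' individual tests are recorded as `NA` with a warning and dropped from the
#' returned vector.
#'
#' @inheritParams bt_test
#' @inheritParams skato_test
#' @param weights A [weight_set()].
#' @param rho_grid SKAT-O rho grid.
#' @param acc Quadratic-form accuracy.
#' @return Named numeric vector of p-values.
#' @export
all_tests <- function(Z, U, weights, rho_grid = skato_rho_grid(),
                      acc = 1e-9, fast = FALSE) {
  stopifnot(inherits(weights, "weight_set"), nrow(weights$W) == length(Z))
  p <- .all_tests_core(Z, U, weights$W, rho_grid, acc, fast)
  names(p) <- .test_labels(weights$labels)
  if (anyNA(p)) {
    warning("degenerate test(s) dropped: ",
            paste(names(p)[is.na(p)], collapse = ", "))
    p <- p[!is.na(p)]
  }
  p
}

.test_labels <- function(wlabels) {
  as.vector(vapply(wlabels,
                   function(l) paste(c("BT", "SKAT", "SKATO"), l, sep = "_"),
                   character(3L)))
}

# core loop shared by all_tests and the replication machinery; returns NA for
# degenerate tests instead of erroring
.all_tests_core <- function(Z, U, W, rho_grid, acc, fast = FALSE) {
  nk <- ncol(W)
  p <- rep(NA_real_, 3L * nk)
  for (k in seq_len(nk)) {
    w <- W[, k]
    wz <- w * Z
    v <- drop(crossprod(w, U %*% w))
    i <- 3L * (k - 1L)
    if (v > 1e-12)
      p[i + 1L] <- max(pchisq(sum(wz)^2 / v, df = 1, lower.tail = FALSE),
                       1e-300)
    Sigma <- outer(w, w) * U
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    evk <- ev[ev > 1e-10 * max(ev, 0)]
    Qs <- sum(wz^2)
    if (length(evk) > 0L) {
      r <- .qf_sf_cpp(Qs, evk, numeric(0), acc)
      p[i + 2L] <- min(max(r$p, 1e-300), 1)
      if (length(Z) == 1L) {
        p[i + 3L] <- p[i + 1L]
      } else {
        so <- .skato_cpp(Sigma, Qs, sum(wz)^2, rho_grid, acc, fast)
        p[i + 3L] <- min(max(so$p, 1e-300), 1)
      }
    }
  }
  p
}
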