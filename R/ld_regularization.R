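#' LD-matrix shrinkage regularization
#'
#' A reference-panel LD (correlation) matrix `R` is noisy when the panel is
#' small.  The corrected matrix is the convex combination
#' `U = a R + (1 - a) I`, with the tuning parameter `a` chosen by maximizing
#' the likelihood of the observed Z-score vector under `Z ~ MVN(0, U)`.
#'
#' @name ld_regularization
NULL

.check_corr_matrix <- function(R, tol_sym = 1e-6, tol_diag = 1e-8) {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    stop("R must be a square matrix")
  if (max(abs(R - t(R))) > tol_sym)
    stop("R is not symmetric (tolerance ", tol_sym, ")")
  if (max(abs(diag(R) - 1)) > tol_diag)
    stop("R must have unit diagonal")
  if (max(abs(R)) > 1 + 1e-8)
    stop("R has entries outside [-1, 1]")
  invisible(R)
}

# negative log-likelihood profile in a, given the spectral decomposition of R:
# y2 = (V'Z)^2, ev = eigenvalues of R
.nll_profile <- function(y2, ev, a) {
  d <- a * ev + (1 - a)
  d[d < 1e-10] <- d[d < 1e-10] + 1e-10
  0.5 * (sum(log(d)) + sum(y2 / d))
}

#' Negative log-likelihood of Z under the shrunken LD matrix
#'
#' Evaluates `0.5 * (log det U + Z' U^{-1} Z)` for `U = a R + (1 - a) I`
#' (the additive constant of the MVN log-density is dropped).  When `a = 1`
#' and `R` is singular, a ridge of `1e-10` is applied for the evaluation
#' only.
#'
#' @param Z Numeric vector of variant Z-scores.
#' @param R LD correlation matrix (symmetric, unit diagonal).
#' @param a Shrinkage tuning parameter in `[0, 1]`.
#' @return The negative log-likelihood (a scalar).
#' @export
neg_log_likelihood <- function(Z, R, a) {
  if (!all(is.finite(Z))) stop("Z contains non-finite entries")
  stopifnot(length(a) == 1L, a >= 0, a <= 1)
  .check_corr_matrix(R)
  if (length(Z) != nrow(R)) stop("length(Z) must equal nrow(R)")
  e <- eigen(R, symmetric = TRUE)
  y2 <- drop(crossprod(e$vectors, Z))^2
  .nll_profile(y2, e$values, a)
}

#' Estimate the LD shrinkage parameter by maximum likelihood
#'
#' Maximizes the MVN log-likelihood of `Z` over `a` in `[0, 1]` using a
#' 21-point grid scan followed by golden-section refinement.  Ties (a flat
#' likelihood, e.g. when `R` is the identity) are broken toward the larger
#' `a`, so a perfectly estimated LD matrix is not shrunk.
#'
#' @inheritParams neg_log_likelihood
#' @param tol Convergence tolerance on `a`.
#' @return The estimated tuning parameter `a_hat` in `[0, 1]`.
#' @export
estimate_tuning <- function(Z, R, tol = 1e-4) {
  if (!all(is.finite(Z))) stop("Z contains non-finite entries")
  .check_corr_matrix(R)
  e <- eigen(R, symmetric = TRUE)
  y2 <- drop(crossprod(e$vectors, Z))^2
  .estimate_tuning_spec(y2, e$values, tol)
}

# spectral-form worker shared with the replication loops
.estimate_tuning_spec <- function(y2, ev, tol = 1e-4) {
  f <- function(a) .nll_profile(y2, ev, a)
  grid <- seq(0, 1, length.out = 21L)
  fg <- vapply(grid, f, 0)
  fmin <- min(fg)
  ftol <- 1e-10 * (1 + abs(fmin))
  # rightmost grid minimizer (tie-break toward larger a)
  i <- max(which(fg <= fmin + ftol))
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, 21L)]
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 > f2 + ftol) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    }
  }
  a_hat <- (lo + hi) / 2
  # flat-likelihood tie-break: prefer the largest a attaining the minimum
  cand <- c(a_hat, grid[i], 1)
  fc <- vapply(cand, f, 0)
  best <- min(fc)
  max(cand[fc <= best + ftol])
}

#' Build the corrected (shrunken) LD matrix
#'
#' @inheritParams neg_log_likelihood
#' @param a_hat Shrinkage parameter, typically from [estimate_tuning()].
#' @return An object of class `corrected_ld`: a list with the original `R`,
#'   the tuning parameter `a_hat`, and the corrected matrix `U`.
#' @export
corrected_ld <- function(R, a_hat) {
  stopifnot(length(a_hat) == 1L, a_hat >= 0, a_hat <= 1)
  .check_corr_matrix(R)
  U <- a_hat * R + (1 - a_hat) * diag(nrow(R))
  dimnames(U) <- dimnames(R)
  structure(list(R = R, a_hat = a_hat, U = U), class = "corrected_ld")
}

#' @export
print.corrected_ld <- function(x, ...) {
  cat("Corrected LD matrix: ", nrow(x$U), " variants, a_hat = ",
      format(x$a_hat, digits = 4), "\n", sep = "")
  invisible(x)
}
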