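#' Cauchy combination (omnibus test, OT) of p-values
#'
#' Transforms each p-value by `tan((0.5 - p) * pi)`, averages, and maps the
#' mean back through the standard Cauchy tail:
#' `p_OT = 1/2 - arctan(Q) / pi`.  Inputs are clipped into
#' `[1e-15, 1 - 1e-15]` to avoid infinite tangents.
#'
#' @param p Non-empty vector of p-values.
#' @return The combined p-value in `(0, 1)`.
#' @export
cauchy_combine <- function(p) {
  if (length(p) == 0L) stop("empty p-value list")
  stopifnot(is.numeric(p), all(is.finite(p)))
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  Q <- mean(tan((0.5 - p) * pi))
  0.5 - atan(Q) / pi
}

#' S-TWAS test statistic from summary statistics
#'
#' `z = w' Z / sqrt(w' R w)` with a standard-normal reference.
#'
#' @param Z Variant Z-score vector.
#' @param R LD correlation matrix.
#' @param w eQTL-derived weight vector.
#' @return List with `z_stat` and two-sided `p`.
#' @export
s_twas <- function(Z, R, w) {
  stopifnot(length(Z) == length(w), nrow(R) == length(w))
  v <- drop(crossprod(w, R %*% w))
  if (v <= 1e-12) stop("degenerate S-TWAS test: w' R w is null")
  z <- sum(w * Z) / sqrt(v)
  list(z_stat = z, p = 2 * pnorm(-abs(z)))
}

#' S-PrediXcan test statistic from summary statistics
#'
#' `z = sum_m w_m sigma_m Z_m / sigma`, where `sigma_m` is the SNP dosage
#' standard deviation and `sigma` the standard deviation of the predicted
#' expression.  With `snp_sd = NULL` (standardized genotypes) and `expr_sd`
#' auto-computed from `R`, the statistic coincides with [s_twas()].
#'
#' @inheritParams s_twas
#' @param snp_sd Per-variant dosage standard deviations (default all 1).
#' @param expr_sd Standard deviation of the predicted expression; if `NULL`
#'   it is computed as `sqrt(w' D R D w)` with `D = diag(snp_sd)`.
#' @return List with `z_stat` and two-sided `p`.
#' @export
s_predixcan <- function(Z, w, R = NULL, snp_sd = NULL, expr_sd = NULL) {
  M <- length(Z)
  stopifnot(length(w) == M)
  if (is.null(snp_sd)) snp_sd <- rep(1, M)
  stopifnot(length(snp_sd) == M, all(snp_sd > 0))
  if (is.null(expr_sd)) {
    if (is.null(R)) stop("supply expr_sd or R to compute it")
    sw <- snp_sd * w
    expr_sd <- sqrt(drop(crossprod(sw, R %*% sw)))
  }
  if (!is.finite(expr_sd) || expr_sd <= 0)
    stop("expr_sd must be positive")
  z <- sum(w * snp_sd * Z) / expr_sd
  list(z_stat = z, p = 2 * pnorm(-abs(z)))
}
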