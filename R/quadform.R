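#' Tail probability of a weighted sum of 1-df chi-squares
#'
#' Computes `P(sum_i lambda_i * chisq_1 > q)`, the null survival probability
#' of quadratic-form statistics such as SKAT.  The probability is obtained by
#' numerical inversion of the characteristic function (a Davies/Imhof-type
#' algorithm) to the requested absolute accuracy; closed forms are used when
#' all weights are equal, a saddlepoint approximation takes over in the deep
#' tail, and a Liu-type moment-matching approximation is the fallback if the
#' exact routine fails (the fallback is signalled with a message).
#'
#' @param q Non-negative quadratic-form value.
#' @param lambdas Numeric vector of weights (eigenvalues); non-positive
#'   entries are dropped.
#' @param acc Absolute accuracy of the inversion integral.
#' @return A p-value in `(0, 1]`, floored at `1e-300`.
#' @examples
#' quad_form_pvalue(2, c(1, 1))   # chi^2_2 tail: exp(-1)
#' quad_form_pvalue(2, c(2))      # P(chi^2_1 > 1)
#' @export
quad_form_pvalue <- function(q, lambdas, acc = 1e-9) {
  stopifnot(is.numeric(q), length(q) == 1L, is.finite(q), q >= 0,
            is.numeric(lambdas), length(lambdas) >= 1L)
  lambdas <- lambdas[lambdas > 0]
  if (length(lambdas) == 0L)
    stop("all lambdas are non-positive")
  res <- .qf_sf_cpp(q, lambdas, numeric(0), acc)
  if (res$method == 3L)
    message("quad_form_pvalue: exact inversion failed, ",
            "Liu-type approximation used")
  min(max(res$p, 1e-300), 1)
}
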