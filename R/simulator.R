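#' Synthetic LD correlation matrices
#'
#' Convenience generator of valid correlation structures used throughout the
#' simulation study: `ar1` (`rho^|i-j|`), `block` (constant `rho` within
#' consecutive blocks), and `exchangeable` (constant `rho` everywhere).
#'
#' @param M Number of variants.
#' @param structure One of `"ar1"`, `"block"`, `"exchangeable"`.
#' @param rho Correlation parameter, `|rho| < 1`.
#' @param block_size Block size for the block structure.
#' @return An `M x M` correlation matrix.
#' @export
synth_ld <- function(M, structure = c("ar1", "block", "exchangeable"),
                     rho = 0.5, block_size = 5L) {
  structure <- match.arg(structure)
  stopifnot(M >= 1L, abs(rho) < 1)
  idx <- seq_len(M)
  R <- switch(structure,
    ar1 = rho^abs(outer(idx, idx, "-")),
    block = {
      blk <- (idx - 1L) %/% block_size
      if (rho < -1 / max(1, min(block_size, M) - 1))
        stop("block structure with rho = ", rho, " is not positive ",
             "semi-definite")
      R <- (outer(blk, blk, "==")) * rho
      diag(R) <- 1
      R
    },
    exchangeable = {
      if (M > 1L && rho < -1 / (M - 1))
        stop("exchangeable structure with rho = ", rho,
             " is not positive semi-definite (needs rho >= -1/(M-1))")
      R <- matrix(rho, M, M)
      diag(R) <- 1
      R
    })
  unname(R)
}

#' Synthetic haplotype pool
#'
#' Generates a pool of binary haplotypes from a latent Gaussian threshold
#' model: each haplotype is a draw from `MVN(0, ar1(rho))`, thresholded at
#' the quantile of its variant's target allele frequency.  The default pool
#' emulates a small gene with a mix of common and low-frequency variants
#' (roughly half the variants above the usual 5% MAF analysis floor), akin
#' to reference-panel haplotypes of a 23-variant gene.
#'
#' @param n_hap Number of haplotypes in the pool.
#' @param M Number of variants.
#' @param rho Latent AR(1) correlation controlling LD strength.
#' @param maf Optional vector of target allele frequencies; by default half
#'   the variants are common (`U(0.05, 0.45)`) and half low-frequency
#'   (`U(0.005, 0.05)`), in random positions.
#' @param seed Integer seed.
#' @return An object of class `haplotype_pool`: a list with the binary
#'   `n_hap x M` matrix `H`, the per-haplotype sampling `frequencies`
#'   (uniform), and the realized pool allele frequencies `maf`.
#' @export
synth_haplotype_pool <- function(n_hap = 458L, M = 23L, rho = 0.7,
                                 maf = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) {
    n_common <- ceiling(M / 2)
    maf <- sample(c(runif(n_common, 0.05, 0.45),
                    runif(M - n_common, 0.005, 0.05)))
  }
  stopifnot(length(maf) == M, all(maf > 0), all(maf < 1))
  R <- synth_ld(M, "ar1", rho = rho)
  G <- matrix(rnorm(n_hap * M), n_hap, M) %*% chol(R)
  H <- t(t(G) < qnorm(maf)) + 0L
  structure(list(H = H, frequencies = rep(1 / n_hap, n_hap),
                 maf = colMeans(H)),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("Haplotype pool: ", nrow(x$H), " haplotypes x ", ncol(x$H),
      " variants; pool MAF in [",
      format(min(pmin(x$maf, 1 - x$maf)), digits = 3), ", ",
      format(max(pmin(x$maf, 1 - x$maf)), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles the generative parameters of the power study: each individual's
#' genotype is the sum of two pool haplotypes, `K` expression traits are
#' built from sparse variant weights with expression heritability `h_e2`,
#' and the phenotype from the expressions with phenotypic heritability
#' `h_p2` under one of four effect-direction scenarios.
#'
#' @param M Number of variants (after any MAF filtering).
#' @param K Number of eQTL studies (expression traits).
#' @param p_causal Proportion of causal variants per study.
#' @param h_e2 Expression heritability in `[0, 1)`.
#' @param h_p2 Phenotypic heritability in `[0, 1)`.
#' @param n Cohort sample size.
#' @param scenario `"uni"` (all effects `+beta0`), `"bi"` (half `+`, half
#'   `-`), or the four-study noise variants `"uni_noise"` / `"bi_noise"`.
#' @param maf_floor Minor-allele-frequency analysis floor.
#' @param seed Integer seed.
#' @return An object of class `sim_config` (a list), with `beta0 =
#'   sqrt(h_p2 / K)` and `M_causal = max(1, round(M * p_causal))` filled in.
#' @export
sim_config <- function(M, K = 4L, p_causal = 0.3, h_e2 = 0.2, h_p2 = 0.2,
                       n = 2000L,
                       scenario = c("uni", "bi", "uni_noise", "bi_noise"),
                       maf_floor = 0.05, seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(p_causal > 0, p_causal <= 1, h_e2 >= 0, h_e2 < 1,
            h_p2 >= 0, h_p2 < 1, n >= 2L, K >= 1L)
  if (scenario %in% c("uni_noise", "bi_noise") && K != 4L)
    stop("noise scenarios are defined for K = 4 studies only")
  structure(list(M = M, K = K, p_causal = p_causal, h_e2 = h_e2,
                 h_p2 = h_p2, n = n, scenario = scenario,
                 beta0 = sqrt(h_p2 / K),
                 M_causal = max(1L, round(M * p_causal)),
                 maf_floor = maf_floor, seed = seed),
            class = "sim_config")
}

#' Sample a genotype cohort from a haplotype pool
#'
#' Each individual's dosage vector is the sum of two haplotypes sampled
#' independently (with replacement, by pool frequency).  Variants whose
#' sample MAF falls below `maf_floor` are removed; the kept indices are
#' returned so LD and weights can be subset consistently.
#'
#' @param pool A [synth_haplotype_pool()] (or any list with `H` and
#'   `frequencies`).
#' @param n Number of individuals.
#' @param maf_floor MAF filter threshold (set 0 to keep everything
#'   polymorphic).
#' @param seed Integer seed.
#' @return List with the `n x M_kept` dosage matrix `X` and the `kept`
#'   variant indices.
#' @export
generate_genotypes <- function(pool, n, maf_floor = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- pool$H
  stopifnot(nrow(H) >= 1L)
  i1 <- sample.int(nrow(H), n, replace = TRUE, prob = pool$frequencies)
  i2 <- sample.int(nrow(H), n, replace = TRUE, prob = pool$frequencies)
  X <- H[i1, , drop = FALSE] + H[i2, , drop = FALSE]
  f <- colMeans(X) / 2
  maf <- pmin(f, 1 - f)
  kept <- which(maf >= maf_floor)
  if (length(kept) == 0L)
    stop("empty gene: all variants removed by the MAF filter")
  list(X = X[, kept, drop = FALSE], kept = kept)
}

#' Generate eQTL weights and expression traits
#'
#' For each study `k`, a causal subset of `M_causal` variants is drawn,
#' nonzero raw weights are standard normal, and the weight vector is
#' rescaled so the sample variance of the genetic score `X w_k` equals the
#' target expression heritability `h_e2`; the expression trait is then
#' `E_k = X w_k + eps` with `eps ~ N(0, 1 - h_e2)`.
#'
#' @param X Dosage matrix (`n x M`).
#' @param config A [sim_config()].
#' @param w_raw Optional `M x K` matrix of pre-drawn raw weights (nonzero on
#'   the causal variants); when supplied only the rescaling and the noise
#'   draw are performed, so a fixed gene architecture can be reused across
#'   cohorts.
#' @param seed Integer seed.
#' @return List with the rescaled true weights `w_true` (`M x K`) and the
#'   expression matrix `E` (`n x K`).
#' @export
generate_weights_and_expression <- function(X, config, w_raw = NULL,
                                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X); M <- ncol(X); K <- config$K
  stopifnot(M >= 1L)
  w_true <- matrix(0, M, K)
  E <- matrix(0, n, K)
  for (k in seq_len(K)) {
    for (attempt in seq_len(100L)) {
      w <- if (!is.null(w_raw)) {
        w_raw[, k]
      } else {
        wk <- numeric(M)
        causal <- sample.int(M, min(config$M_causal, M))
        wk[causal] <- rnorm(length(causal))
        wk
      }
      g <- drop(X %*% w)
      v <- var(g)
      if (config$h_e2 == 0) { w <- w * 0; g <- g * 0; v <- 1 }
      if (v > 1e-12) {
        scl <- if (config$h_e2 == 0) 0 else sqrt(config$h_e2 / v)
        w_true[, k] <- w * scl
        E[, k] <- g * scl + rnorm(n, 0, sqrt(1 - config$h_e2))
        break
      }
      if (!is.null(w_raw) || attempt == 100L)
        stop("could not draw a non-degenerate causal set for study ", k)
    }
  }
  list(w_true = w_true, E = E)
}

#' Generate a phenotype from expression traits
#'
#' `Y = E beta + eps` with `eps ~ N(0, 1 - h_p2)`.  The effect vector
#' follows the configured scenario: `uni` sets all `beta_k = beta0`; `bi`
#' sets the first half `+beta0` and the second half `-beta0`; the four-study
#' noise scenarios perturb the most relevant study by `N(0, 0.1 h_p2)` and
#' the others by `N(0, 0.5 h_p2)`.
#'
#' @param E Expression matrix (`n x K`).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with the phenotype vector `Y` and the effect vector `beta`.
#' @export
generate_phenotype <- function(E, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- ncol(E); n <- nrow(E)
  stopifnot(K == config$K)
  b0 <- config$beta0
  h2 <- config$h_p2
  beta <- switch(config$scenario,
    uni = rep(b0, K),
    bi = c(rep(b0, floor(K / 2)), rep(-b0, K - floor(K / 2))),
    uni_noise = c(b0 + rnorm(1, 0, sqrt(0.1 * h2)),
                  b0 + rnorm(3, 0, sqrt(0.5 * h2))),
    bi_noise = c(-b0 + rnorm(1, 0, sqrt(0.1 * h2)),
                 -b0 + rnorm(1, 0, sqrt(0.5 * h2)),
                 b0 + rnorm(1, 0, sqrt(0.1 * h2)),
                 b0 + rnorm(1, 0, sqrt(0.5 * h2))))
  if (h2 == 0) beta <- beta * 0
  Y <- drop(E %*% beta) + rnorm(n, 0, sqrt(1 - h2))
  list(Y = Y, beta = beta)
}

#' Per-variant Z-scores by ordinary least squares
#'
#' Regresses the phenotype on each variant dosage separately (with
#' intercept) and returns `Z_m = beta_hat_m / se(beta_hat_m)`.  Constant
#' dosage columns are dropped with a warning; an exactly perfect fit
#' (`se = 0`) is capped at `|Z| = 1e8`.
#'
#' @param X Dosage matrix (`n x M`).
#' @param Y Phenotype vector.
#' @return Numeric vector of Z-scores with attribute `kept` (indices of the
#'   non-constant columns).
#' @export
compute_z_scores <- function(X, Y) {
  n <- nrow(X)
  stopifnot(length(Y) == n, n > 2L)
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- Y - mean(Y)
  Sxx <- colSums(Xc^2)
  keep <- Sxx > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant variant column(s) dropped")
    Xc <- Xc[, keep, drop = FALSE]
    Sxx <- Sxx[keep]
  }
  Sxy <- drop(crossprod(Xc, Yc))
  slope <- Sxy / Sxx
  Syy <- sum(Yc^2)
  rss <- Syy - slope^2 * Sxx
  rss[rss < 1e-12 * Syy] <- 0
  se <- sqrt(rss / (n - 2) / Sxx)
  Z <- ifelse(se > 0, slope / se, sign(slope) * 1e8)
  Z[!is.finite(Z)] <- 0
  Z <- pmin(pmax(Z, -1e8), 1e8)
  structure(Z, kept = which(keep))
}
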