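#' Read per-variant GWAS summary statistics
#'
#' Reads a tab-separated file with a header containing at least `ID`, `A1`
#' (effect allele), `A2` (other allele) and either a `Z` column or both
#' `BETA` and `SE`.  When `Z` is absent it is filled in as `BETA / SE`;
#' when both are present the `Z` column wins (with a message), since the
#' model consumes Z-scores directly.
#'
#' @param path Path to the file.
#' @param variant_subset Optional character vector of variant IDs to keep.
#' @return Data frame with columns `id`, `effect_allele`, `other_allele`,
#'   `z` (and `beta`, `se` when present), in file order.
#' @export
read_summary_stats <- function(path, variant_subset = NULL) {
  # read as character so the allele "T" is not coerced to logical TRUE
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = "character")
  names(d) <- toupper(names(d))
  need <- c("ID", "A1", "A2")
  if (!all(need %in% names(d)))
    stop("summary-statistics format error: missing column(s) ",
         paste(setdiff(need, names(d)), collapse = ", "))
  has_z <- "Z" %in% names(d)
  has_bse <- all(c("BETA", "SE") %in% names(d))
  if (!has_z && !has_bse)
    stop("summary-statistics format error: need a Z column or BETA and SE")
  if (has_z && has_bse)
    message("both Z and BETA/SE present; using the Z column")
  out <- data.frame(id = as.character(d$ID),
                    effect_allele = toupper(as.character(d$A1)),
                    other_allele = toupper(as.character(d$A2)),
                    stringsAsFactors = FALSE)
  if (!all(grepl("^[ACGT]$", out$effect_allele)) ||
      !all(grepl("^[ACGT]$", out$other_allele)))
    stop("alleles must be single characters A/C/G/T")
  if (has_z) {
    out$z <- as.numeric(d$Z)
  } else {
    se <- as.numeric(d$SE)
    bad <- which(!is.na(se) & se <= 0)
    if (length(bad) > 0L)
      stop("SE must be positive; offending row(s): ",
           paste(bad, collapse = ", "))
    out$z <- as.numeric(d$BETA) / se
  }
  if (has_bse) { out$beta <- as.numeric(d$BETA); out$se <- as.numeric(d$SE) }
  if (!is.null(variant_subset))
    out <- out[out$id %in% variant_subset, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize GWAS records against a reference variant list
#'
#' Matches variants by ID and aligns the Z-scores to the reference allele
#' coding: when effect/other alleles are swapped relative to the reference
#' the sign of `z` is flipped; strand-ambiguous variants (A/T, C/G),
#' unmatched IDs, and allele mismatches are dropped and counted.  Duplicated
#' IDs are dropped beyond the first occurrence, with a warning.
#'
#' @param gwas Data frame with `id`, `effect_allele`, `other_allele`, `z`
#'   (as from [read_summary_stats()]).
#' @param reference Data frame with `id`, `effect_allele`, `other_allele`
#'   defining the target coding and order.
#' @return List with the aligned named vector `z`, `kept` (indices into
#'   `reference`), and the drop counts `n_unmatched`, `n_ambiguous`,
#'   `n_mismatched`.
#' @export
harmonize <- function(gwas, reference) {
  stopifnot(all(c("id", "effect_allele", "other_allele", "z") %in%
                  names(gwas)),
            all(c("id", "effect_allele", "other_allele") %in%
                  names(reference)))
  for (nm in c("gwas", "reference")) {
    d <- get(nm)
    if (anyDuplicated(d$id)) {
      warning("duplicated variant IDs in ", nm,
              "; keeping the first occurrence")
      assign(nm, d[!duplicated(d$id), , drop = FALSE])
    }
  }
  m <- match(reference$id, gwas$id)
  n_unmatched <- sum(is.na(m))
  kept <- integer(0)
  z <- numeric(0)
  n_amb <- 0L; n_mis <- 0L
  for (i in which(!is.na(m))) {
    g <- gwas[m[i], ]
    r <- reference[i, ]
    if (.ambiguous_pair(g$effect_allele, g$other_allele) ||
        .ambiguous_pair(r$effect_allele, r$other_allele)) {
      n_amb <- n_amb + 1L
      next
    }
    if (g$effect_allele == r$effect_allele &&
        g$other_allele == r$other_allele) {
      kept <- c(kept, i); z <- c(z, g$z)
    } else if (g$effect_allele == r$other_allele &&
               g$other_allele == r$effect_allele) {
      kept <- c(kept, i); z <- c(z, -g$z)
    } else {
      n_mis <- n_mis + 1L
    }
  }
  if (length(kept) == 0L)
    stop("empty gene: no variants survive harmonization")
  names(z) <- reference$id[kept]
  list(z = z, kept = kept, n_unmatched = n_unmatched,
       n_ambiguous = n_amb, n_mismatched = n_mis)
}

#' Read an LD matrix, or compute one from a genotype matrix
#'
#' In `type = "ld"` mode the file is a square whitespace/tab-delimited
#' numeric matrix with a variant-ID header row; it must be symmetric within
#' `1e-6`, have unit diagonal within `1e-8`, and entries within
#' `[-1 - 1e-8, 1 + 1e-8]`.  In `type = "genotype"` mode the file holds
#' dosages (rows = samples, columns = variants, header row of IDs) and the
#' Pearson correlation matrix of the dosage columns is returned; monomorphic
#' columns are dropped with a warning.
#'
#' @param path Path to the file.
#' @param type `"ld"` (default) or `"genotype"`.
#' @return Correlation matrix with variant IDs as dimnames.
#' @export
read_ld_matrix <- function(path, type = c("ld", "genotype")) {
  type <- match.arg(type)
  d <- read.table(path, header = TRUE, check.names = FALSE)
  X <- as.matrix(d)
  ids <- colnames(X)
  if (type == "genotype") {
    mono <- apply(X, 2L, function(x) var(x) == 0)
    if (any(mono)) {
      warning("dropping monomorphic column(s): ",
              paste(ids[mono], collapse = ", "))
      X <- X[, !mono, drop = FALSE]
      ids <- ids[!mono]
    }
    R <- cor(X)
    dimnames(R) <- list(ids, ids)
    return(R)
  }
  if (nrow(X) != ncol(X))
    stop("LD format error: matrix is not square")
  storage.mode(X) <- "double"
  if (max(abs(X - t(X))) > 1e-6)
    stop("LD format error: matrix is asymmetric beyond 1e-6")
  if (max(abs(diag(X) - 1)) > 1e-8)
    stop("LD format error: diagonal is not 1")
  if (max(abs(X)) > 1 + 1e-8)
    stop("LD format error: entries outside [-1, 1]")
  dimnames(X) <- list(ids, ids)
  X
}

#' Read eQTL-derived weights
#'
#' Tab-separated file with a header: `ID`, then one numeric column per eQTL
#' study.  Variants with a missing weight in any study are dropped (with a
#' message), so all studies are compared on the same variant set.
#'
#' @param path Path to the file.
#' @return List with `ids`, the `M x K` matrix `W` of raw weights, and the
#'   study `labels`.
#' @export
read_weights <- function(path) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE)
  idcol <- which(toupper(names(d)) == "ID")
  if (length(idcol) != 1L)
    stop("weights format error: need an ID column")
  ids <- as.character(d[[idcol]])
  W <- as.matrix(d[, -idcol, drop = FALSE])
  storage.mode(W) <- "double"
  miss <- rowSums(!is.finite(W)) > 0
  if (any(miss)) {
    message(sum(miss), " variant(s) dropped for missing weights")
    W <- W[!miss, , drop = FALSE]
    ids <- ids[!miss]
  }
  list(ids = ids, W = W, labels = colnames(W))
}

#' Write gene-level results to a TSV file
#'
#' One row per gene, fixed column order (`gene_id`, `M`, `a_hat`,
#' `p_overall`, `p_OT`, the per-test p-values, then per-weight comparator
#' p-values), p-values in scientific notation with 7 significant digits.
#' Output is byte-identical across re-runs on the same input.
#'
#' @param results A single [overall_test()] fit or a list of them.
#' @param path Output path.
#' @return The output path, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "overall_fit")) results <- list(results)
  fmt <- function(x) formatC(x, format = "e", digits = 6)
  if (length(results) == 0L) {
    writeLines(paste(c("gene_id", "M", "a_hat", "p_overall", "p_OT"),
                     collapse = "\t"), con = path)
    return(invisible(path))
  }
  labels <- names(results[[1L]]$p_tests)
  comp_labels <- results[[1L]]$comparators$label
  header <- c("gene_id", "M", "a_hat", "p_overall", "p_OT", labels,
              if (length(comp_labels))
                c(paste0("S-TWAS_", comp_labels),
                  paste0("S-PrediXcan_", comp_labels)))
  rows <- vapply(results, function(r) {
    stopifnot(inherits(r, "overall_fit"))
    vals <- c(fmt(r$a_hat), fmt(r$p_overall), fmt(r$p_ot),
              fmt(r$p_tests[labels]),
              if (length(comp_labels))
                c(fmt(r$comparators$p_twas), fmt(r$comparators$p_predixcan)))
    paste(c(r$gene_id, r$M, vals), collapse = "\t")
  }, character(1L))
  writeLines(c(paste(header, collapse = "\t"), rows), con = path)
  invisible(path)
}

#' Write / read a labeled p-value correlation matrix
#'
#' The null correlation matrix of the combined tests (from
#' [estimate_null_correlation()]) is serialized as a square tab-separated
#' matrix with test labels on both axes, so it can be estimated once per
#' gene and reused.
#'
#' @param Omega Labeled square correlation matrix.
#' @param path File path.
#' @return `write_omega` returns the path invisibly; `read_omega` returns
#'   the labeled matrix.
#' @export
write_omega <- function(Omega, path) {
  stopifnot(is.matrix(Omega), !is.null(rownames(Omega)))
  df <- data.frame(label = rownames(Omega),
                   formatC(Omega, format = "e", digits = 8),
                   check.names = FALSE)
  colnames(df) <- c("label", colnames(Omega))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_omega
#' @export
read_omega <- function(path) {
  d <- read.delim(path, header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  labels <- as.character(d[[1L]])
  Om <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(Om) <- "double"
  dimnames(Om) <- list(labels, colnames(d)[-1L])
  if (!identical(rownames(Om), colnames(Om)))
    stop("correlation-matrix file is not a labeled square matrix")
  Om
}
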