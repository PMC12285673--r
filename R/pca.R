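#' Genetic principal components
#'
#' Principal components of the standardized dosage matrix (per-variant
#' mean 0, variance 1), for use as ancestry covariates. Missing dosages
#' are mean-imputed for this computation only; zero-variance variants are
#' excluded with a warning. The decomposition runs on the smaller of the
#' two Gram matrices, so it is cheap even for wide genotype matrices, and
#' a deterministic sign convention (the largest-magnitude loading of each
#' component is positive) makes runs comparable.
#'
#' @param data A [cohort_dataset()].
#' @param k Number of components; must satisfy `k < min(n, m)`.
#' @param max_variants If the dataset has more variants, a deterministic
#'   random subset of this size is used (standard practice for ancestry
#'   PCs; set to `Inf` to use all variants).
#' @return An object of class `pc_result` with `scores` (n x k, named
#'   PC1..PCk), `loadings` (m_used x k, unit-norm columns), `eigenvalues`
#'   (variances of the scores, non-increasing), and `variants_used`.
#' @export
compute_pcs <- function(data, k = 5L, max_variants = 5000L) {
  stopifnot(inherits(data, "cohort_dataset"))
  n <- n_samples(data)
  X <- data$dosages
  if (is.finite(max_variants) && ncol(X) > max_variants) {
    keep <- with_seed(2641L, sort(sample.int(ncol(X), max_variants)))
    X <- X[, keep, drop = FALSE]
  }
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X))
    X[nas] <- mu[(nas - 1L) %/% n + 1L]
  }
  sds <- apply(X, 2, stats::sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero)) {
    warning(sum(zero), " zero-variance variant(s) excluded from PC ",
            "computation")
    X <- X[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  m <- ncol(X)
  if (k >= min(n, m))
    stop("k must be smaller than min(n_samples, n_variants) = ", min(n, m))
  Xs <- scale(X, center = TRUE, scale = sds)
  if (n <= m) {
    eg <- eigen(tcrossprod(Xs), symmetric = TRUE)
    d2 <- pmax(eg$values[seq_len(k)], 0)
    U <- eg$vectors[, seq_len(k), drop = FALSE]
    scores <- U * rep(sqrt(d2), each = n)
    loadings <- crossprod(Xs, U) /
      rep(pmax(sqrt(d2), .Machine$double.eps), each = m)
  } else {
    eg <- eigen(crossprod(Xs), symmetric = TRUE)
    d2 <- pmax(eg$values[seq_len(k)], 0)
    loadings <- eg$vectors[, seq_len(k), drop = FALSE]
    scores <- Xs %*% loadings
  }
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(data$dosages), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = d2 / (n - 1),
                 variants_used = colnames(X)),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("<pc_result> %d samples x %d components (on %d variants)\n",
              nrow(x$scores), ncol(x$scores), length(x$variants_used)))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Covariate design for association testing
#'
#' Builds the standard covariate matrix — age, sex, and the first `k_pcs`
#' genetic principal components — used throughout the pipeline.
#'
#' @param data A [cohort_dataset()].
#' @param pcs Optional [compute_pcs()] result; computed here (with
#'   `k = k_pcs`) when `NULL` and `k_pcs > 0`.
#' @param k_pcs Number of principal components to include.
#' @return Numeric matrix (n x (2 + k_pcs)), without an intercept column.
#' @export
make_covariates <- function(data, pcs = NULL, k_pcs = 5L) {
  covs <- cbind(age = data$samples$age, sex = data$samples$sex)
  if (k_pcs > 0L) {
    if (is.null(pcs)) pcs <- compute_pcs(data, k = k_pcs)
    covs <- cbind(covs, pcs$scores[, seq_len(k_pcs), drop = FALSE])
  }
  rownames(covs) <- data$samples$sample_id
  covs
}
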