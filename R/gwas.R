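#' Per-variant linear GWAS (additive model)
#'
#' For every variant, ordinary least squares of the quantitative
#' phenotype on effect-allele dosage plus covariates and an intercept;
#' reports the dosage term's beta, SE and two-sided t-test p-value.
#' Variants with complete dosages are processed in one vectorized pass
#' (phenotype and dosages residualized against the covariate design —
#' algebraically identical to the full OLS fit); variants with missing
#' dosages fall back to per-variant complete-case regression, so
#' missingness in one variant never affects another (PLINK behaviour).
#'
#' @param data A [cohort_dataset()] with a quantitative phenotype.
#' @param covariates Numeric matrix (n x p) of covariates without
#'   intercept, e.g. from [make_covariates()]; `NULL` for none.
#' @param outcome Name of the outcome column in `data$samples`.
#' @return Data frame of per-variant summary statistics with columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `p`, `n`. Zero-variance variants are skipped
#'   with a warning.
#' @export
gwas_linear <- function(data, covariates = NULL, outcome = "phenotype") {
  stopifnot(inherits(data, "cohort_dataset"))
  y <- data$samples[[outcome]]
  if (is.null(y) || !is.numeric(y))
    stop("outcome column '", outcome, "' missing or not numeric")
  if (anyNA(y)) stop("outcome contains missing values; drop those samples")
  n <- n_samples(data)
  W <- .design_matrix(covariates, n)
  p_cov <- ncol(W)
  if (n < p_cov + 2L)
    stop("need at least ", p_cov + 2L, " samples for ", p_cov - 1L,
         " covariates")

  G <- data$dosages
  m <- ncol(G)
  eaf_all <- colMeans(G, na.rm = TRUE) / 2
  nn_all <- colSums(!is.na(G))
  beta <- se <- pv <- rep(NA_real_, m)
  nv <- integer(m)

  qrW <- qr(W)
  has_na <- colAnyNA(G)
  cc <- which(!has_na)
  if (length(cc)) {
    yr <- qr.resid(qrW, y)
    Gr <- G[, cc, drop = FALSE]
    Gr <- Gr - W %*% qr.coef(qrW, Gr)
    den <- colSums(Gr^2)
    ok <- den > n * 1e-12
    num <- crossprod(Gr, yr)[, 1]
    b <- num / den
    rss <- sum(yr^2) - b * num
    df <- n - p_cov - 1L
    s <- sqrt(pmax(rss, 0) / df / den)
    tt <- b / s
    beta[cc[ok]] <- b[ok]
    se[cc[ok]] <- s[ok]
    pv[cc[ok]] <- 2 * stats::pt(-abs(tt[ok]), df)
    nv[cc] <- n
  }
  for (j in which(has_na)) {
    use <- !is.na(G[, j])
    nj <- sum(use)
    if (nj < p_cov + 2L) next
    X <- cbind(W[use, , drop = FALSE], dose = G[use, j])
    XtX <- crossprod(X)
    d <- try(solve(XtX), silent = TRUE)
    if (inherits(d, "try-error")) next
    bj <- d %*% crossprod(X, y[use])
    res <- y[use] - X %*% bj
    df <- nj - ncol(X)
    sig2 <- sum(res^2) / df
    beta[j] <- bj[ncol(X)]
    se[j] <- sqrt(sig2 * d[ncol(X), ncol(X)])
    pv[j] <- 2 * stats::pt(-abs(beta[j] / se[j]), df)
    nv[j] <- nj
  }
  skipped <- is.na(beta)
  if (any(skipped))
    warning(sum(skipped), " variant(s) skipped ",
            "(zero dosage variance or too few complete cases)")
  out <- cbind(data$variant_meta[!skipped,
                 c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele")],
               data.frame(eaf = eaf_all[!skipped], beta = beta[!skipped],
                          se = se[!skipped], p = pv[!skipped],
                          n = nv[!skipped]))
  rownames(out) <- NULL
  out
}

# intercept + covariates, with a collinearity check that names offenders
.design_matrix <- function(covariates, n) {
  if (is.null(covariates)) {
    W <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
    return(W)
  }
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n)
    stop("covariate rows (", nrow(covariates), ") != samples (", n, ")")
  if (anyNA(covariates)) stop("covariates contain missing values")
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("covar", seq_len(ncol(covariates)))
  W <- cbind(`(Intercept)` = 1, covariates)
  qw <- qr(W)
  if (qw$rank < ncol(W)) {
    bad <- colnames(W)[qw$pivot[(qw$rank + 1L):ncol(W)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  W
}

#' Per-variant logistic GWAS
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of a
#' binary outcome on effect-allele dosage plus covariates; Wald SE and
#' two-sided p for the dosage term, with betas on the log-odds scale.
#' Non-convergence and (quasi-)separation are flagged per variant: such
#' variants keep `converged = FALSE` and carry no estimate.
#'
#' @inheritParams gwas_linear
#' @param outcome Name of the 0/1 outcome column in `data$samples`.
#' @return As [gwas_linear()], plus a logical `converged` column.
#' @export
gwas_logistic <- function(data, covariates = NULL, outcome = "phenotype") {
  stopifnot(inherits(data, "cohort_dataset"))
  y <- data$samples[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' missing")
  if (anyNA(y)) stop("outcome contains missing values")
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; logistic regression undefined")
  n <- n_samples(data)
  W <- .design_matrix(covariates, n)
  G <- data$dosages
  m <- ncol(G)
  eaf_all <- colMeans(G, na.rm = TRUE) / 2
  beta <- se <- pv <- rep(NA_real_, m)
  nv <- integer(m)
  conv <- logical(m)
  for (j in seq_len(m)) {
    use <- !is.na(G[, j])
    nj <- sum(use)
    if (nj < ncol(W) + 2L || stats::var(G[use, j]) == 0) next
    X <- cbind(W[use, -1L, drop = FALSE], dose = G[use, j])
    fit <- withCallingHandlers(
      stats::glm.fit(cbind(1, X), y[use], family = stats::binomial()),
      warning = function(w) invokeRestart("muffleWarning"))
    k <- ncol(X) + 1L
    mu <- fit$fitted.values
    separated <- any(mu < 1e-10 | mu > 1 - 1e-10)
    nv[j] <- nj
    if (!fit$converged || separated) next
    # Wald SE from the weighted information matrix
    Xf <- cbind(1, X)
    wts <- mu * (1 - mu)
    info <- crossprod(Xf * sqrt(wts))
    vc <- try(solve(info), silent = TRUE)
    if (inherits(vc, "try-error")) next
    conv[j] <- TRUE
    beta[j] <- fit$coefficients[k]
    se[j] <- sqrt(vc[k, k])
    pv[j] <- 2 * stats::pnorm(-abs(beta[j] / se[j]))
  }
  out <- cbind(data$variant_meta[, c("variant_id", "chrom", "pos",
                                     "effect_allele", "other_allele")],
               data.frame(eaf = eaf_all, beta = beta, se = se, p = pv,
                          n = nv, converged = conv))
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor
#'
#' Lambda is the median of the chi-square(1 df) quantiles of the observed
#' two-sided p-values divided by the null median 0.4549364; values near 1
#' indicate calibrated association tests.
#'
#' @param stats Summary-statistics data frame with a `p` column (or a
#'   bare numeric vector of p-values).
#' @return Scalar lambda.
#' @export
genomic_lambda <- function(stats) {
  p <- if (is.data.frame(stats)) stats$p else stats
  p <- p[!is.na(p)]
  if (length(p) < 100L)
    stop("need at least 100 p-values for a stable lambda (got ",
         length(p), ")")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}
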