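#' Squared genotype correlation between two variants
#'
#' Sample squared Pearson correlation of the two dosage vectors over
#' samples where both are non-missing — the LD measure used for
#' clumping.
#'
#' @param data A [cohort_dataset()] (the LD panel).
#' @param a,b Variant ids.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(data, a, b) {
  ia <- match(a, colnames(data$dosages))
  ib <- match(b, colnames(data$dosages))
  if (is.na(ia) || is.na(ib))
    stop("variant(s) not present in the LD panel: ",
         paste(c(a, b)[c(is.na(ia), is.na(ib))], collapse = ", "))
  x <- data$dosages[, ia]
  y <- data$dosages[, ib]
  use <- !is.na(x) & !is.na(y)
  if (sum(use) < 50L)
    stop("fewer than 50 samples with both variants non-missing")
  if (stats::var(x[use]) == 0 || stats::var(y[use]) == 0)
    stop("zero dosage variance for one of the variants")
  stats::cor(x[use], y[use])^2
}

#' Greedy LD clumping of candidate variants
#'
#' PLINK/PRSice-style clumping on summary statistics: repeatedly take
#' the remaining candidate with the smallest p-value (ties broken toward
#' the smaller genomic position, then by id) and discard every remaining
#' candidate on the same chromosome within `window_kb` whose genotype
#' r-squared with it is at or above `r2_max`. Candidates absent from the
#' LD panel (or monomorphic there) are excluded with a warning.
#'
#' @param candidates Data frame of candidate variants (columns
#'   `variant_id`, `chrom`, `pos` and a p-value column `p_meta` or `p`).
#' @param ld_panel [cohort_dataset()] providing genotypes for r-squared.
#' @param r2_max LD ceiling; pairs at or above it are clumped
#'   (default 0.1).
#' @param window_kb Window, in kilobases, within which LD is checked
#'   (default 250).
#' @return The retained subset of `candidates`, sorted by ascending p.
#' @export
clump <- function(candidates, ld_panel, r2_max = 0.1, window_kb = 250) {
  pcol <- if ("p_meta" %in% names(candidates)) "p_meta" else "p"
  if (!pcol %in% names(candidates)) stop("candidates need a p-value column")
  cand <- candidates
  present <- cand$variant_id %in% colnames(ld_panel$dosages)
  if (any(present)) {
    v <- apply(ld_panel$dosages[, cand$variant_id[present], drop = FALSE],
               2, stats::var, na.rm = TRUE)
    poly <- v > 0 & !is.na(v)
    present[present] <- poly
  }
  if (any(!present)) {
    warning(sum(!present), " candidate(s) excluded: absent from or ",
            "monomorphic in the LD panel")
    cand <- cand[present, , drop = FALSE]
  }
  if (!nrow(cand)) return(cand)
  ord <- order(cand[[pcol]], cand$pos, cand$variant_id)
  cand <- cand[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(cand))
  retained <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    retained[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive &
                    cand$chrom == cand$chrom[i] &
                    abs(cand$pos - cand$pos[i]) <= window_kb * 1000)
    for (j in near) {
      if (ld_r2(ld_panel, cand$variant_id[i], cand$variant_id[j]) >= r2_max)
        alive[j] <- FALSE
    }
  }
  out <- cand[retained, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a weighted genetic risk score model
#'
#' Thresholded entry over an LD-clumped candidate list: variants with
#' pooled p strictly below `p_threshold` enter the model with the pooled
#' meta-analysis beta as their weight (per effect-allele dose).
#'
#' @param retained Clumped candidate data frame (needs `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `beta_meta` or `beta`, and
#'   `p_meta` or `p`).
#' @param p_threshold Entry threshold (default 5e-5).
#' @param clump_r2,clump_window_kb,weight_source Provenance fields
#'   recorded in the model.
#' @return An object of class `grs_model` with `entries` (data frame:
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `weight`) and
#'   `provenance`.
#' @export
build_grs <- function(retained, p_threshold = 5e-5, clump_r2 = 0.1,
                      clump_window_kb = 250,
                      weight_source = "discovery meta-analysis beta") {
  pcol <- if ("p_meta" %in% names(retained)) "p_meta" else "p"
  bcol <- if ("beta_meta" %in% names(retained)) "beta_meta" else "beta"
  keep <- !is.na(retained[[pcol]]) & retained[[pcol]] < p_threshold
  oa <- if ("other_allele" %in% names(retained)) retained$other_allele
        else rep(NA_character_, nrow(retained))
  entries <- data.frame(variant_id = retained$variant_id[keep],
                        chrom = retained$chrom[keep],
                        pos = retained$pos[keep],
                        effect_allele = retained$effect_allele[keep],
                        other_allele = oa[keep],
                        weight = retained[[bcol]][keep],
                        stringsAsFactors = FALSE)
  if (!nrow(entries))
    stop("empty score model: no clumped candidate passed p < ",
         format(p_threshold), " (", nrow(retained),
         " candidates entered thresholding)")
  if (any(!is.finite(entries$weight) | entries$weight == 0))
    stop("model weights must be finite and nonzero")
  if (anyDuplicated(entries$variant_id)) stop("duplicate model variants")
  structure(list(entries = entries,
                 provenance = list(clump_r2 = clump_r2,
                                   clump_window_kb = clump_window_kb,
                                   p_threshold = p_threshold,
                                   weight_source = weight_source)),
            class = "grs_model")
}

#' @export
print.grs_model <- function(x, ...) {
  cat(sprintf("<grs_model> %d variants (clump r2 < %g, window %g kb, p < %g)\n",
              nrow(x$entries), x$provenance$clump_r2,
              x$provenance$clump_window_kb, x$provenance$p_threshold))
  print(utils::head(x$entries, 10))
  invisible(x)
}

#' Compute per-sample risk scores
#'
#' Weighted allele-dosage sum over the model variants present in the
#' target cohort, after harmonizing the model's effect alleles to the
#' cohort's (flipped alleles contribute `2 - dosage`). Missing dosages
#' are imputed as twice the scoring cohort's effect-allele frequency.
#' The sum is divided by the number of model variants used
#' (average-per-variant convention; set `normalize = FALSE` for the raw
#' sum).
#'
#' @param model A [build_grs()] model (or one read by
#'   [read_grs_model()]).
#' @param data Target [cohort_dataset()].
#' @param normalize Divide by the number of model variants used
#'   (default `TRUE`).
#' @return Numeric vector of scores, one per sample, named by sample id,
#'   with `attr(, "n_variants_used")`.
#' @export
score_samples <- function(model, data, normalize = TRUE) {
  entries <- model$entries
  i <- match(entries$variant_id, colnames(data$dosages))
  present <- !is.na(i)
  if (!any(present))
    stop("none of the ", nrow(entries),
         " model variants are present in cohort '", data$cohort_name, "'")
  if (any(!present))
    warning(sum(!present), " model variant(s) absent from the scoring ",
            "cohort and skipped")
  ent <- entries[present, , drop = FALSE]
  G <- data$dosages[, i[present], drop = FALSE]
  vm <- data$variant_meta[i[present], ]
  same <- ent$effect_allele == vm$effect_allele
  flip <- ent$effect_allele == vm$other_allele
  if (any(!same & !flip)) {
    warning(sum(!same & !flip), " model variant(s) dropped: allele pair ",
            "incompatible with the scoring cohort")
    keep <- same | flip
    ent <- ent[keep, , drop = FALSE]
    G <- G[, keep, drop = FALSE]
    flip <- flip[keep]
    if (!ncol(G)) stop("no allele-compatible model variants remain")
  }
  if (any(flip)) G[, flip] <- 2 - G[, flip]
  if (anyNA(G)) {
    f <- colMeans(G, na.rm = TRUE) / 2
    for (j in seq_len(ncol(G))) {
      nas <- is.na(G[, j])
      if (any(nas)) G[nas, j] <- 2 * f[j]
    }
  }
  sc <- drop(G %*% ent$weight)
  if (normalize) sc <- sc / ncol(G)
  names(sc) <- rownames(data$dosages)
  attr(sc, "n_variants_used") <- ncol(G)
  sc
}

#' Test a risk score against an outcome
#'
#' Regression of the outcome on the score plus covariates (with
#' intercept). Quantitative outcomes use OLS and additionally report the
#' incremental variance explained, `delta R^2 = R^2(covariates + score)
#' - R^2(covariates)`; binary outcomes use logistic regression and
#' report the odds ratio per score unit with a Wald 95% CI (no
#' pseudo-R-squared is computed).
#'
#' @param score Numeric vector from [score_samples()] (same sample
#'   order as `data`).
#' @param data Target [cohort_dataset()].
#' @param covariates Covariate matrix as in [gwas_linear()].
#' @param outcome Outcome column in `data$samples`.
#' @param binary Force outcome type; by default outcomes with only 0/1
#'   values are treated as binary.
#' @return An `association_report` list: `outcome`, `type`, `effect`,
#'   `se`, `p`, `ci` (binary: OR scale), `or` (binary), `incremental_r2`
#'   (quantitative), `n`.
#' @export
evaluate_grs <- function(score, data, covariates = NULL,
                         outcome = "phenotype", binary = NULL) {
  y <- data$samples[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' missing")
  if (length(score) != length(y))
    stop("score length != sample count")
  if (anyNA(y) || anyNA(score)) stop("missing values in outcome or score")
  if (is.null(binary)) binary <- all(y %in% c(0, 1))
  n <- length(y)
  W <- .design_matrix(covariates, n)
  if (!binary) {
    X <- cbind(W, score = score)
    fit <- stats::lm.fit(X, y)
    df <- n - ncol(X)
    sig2 <- sum(fit$residuals^2) / df
    xtxi <- chol2inv(chol(crossprod(X)))[ncol(X), ncol(X)]
    beta <- fit$coefficients["score"]
    se <- sqrt(sig2 * xtxi)
    p <- 2 * stats::pt(-abs(beta / se), df)
    r2_full <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    fit0 <- stats::lm.fit(W, y)
    r2_cov <- 1 - sum(fit0$residuals^2) / sum((y - mean(y))^2)
    rep <- list(outcome = outcome, type = "quantitative",
                effect = unname(beta), se = se, p = unname(p),
                ci = unname(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                incremental_r2 = r2_full - r2_cov, n = n)
  } else {
    if (length(unique(y)) < 2L) stop("binary outcome has a single class")
    X <- cbind(W[, -1L, drop = FALSE], score = score)
    fit <- stats::glm(y ~ X, family = stats::binomial())
    cf <- summary(fit)$coefficients
    k <- nrow(cf)
    beta <- cf[k, 1]; se <- cf[k, 2]
    p <- 2 * stats::pnorm(-abs(beta / se))
    ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
    rep <- list(outcome = outcome, type = "binary",
                effect = unname(beta), se = unname(se), p = unname(p),
                or = exp(unname(beta)), ci = ci,
                incremental_r2 = NA_real_, n = n)
  }
  structure(rep, class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  if (x$type == "quantitative")
    cat(sprintf(
      "<association_report> %s (linear, n=%d): beta = %.4g (se %.3g), p = %.3g, delta-R2 = %.4g\n",
      x$outcome, x$n, x$effect, x$se, x$p, x$incremental_r2))
  else
    cat(sprintf(
      "<association_report> %s (logistic, n=%d): OR = %.3g [%.3g-%.3g], p = %.3g\n",
      x$outcome, x$n, x$or, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' Benchmark two score models on the same cohort
#'
#' Scores the cohort with both models and evaluates each against the
#' same outcome and covariates; for quantitative outcomes the
#' incremental-R-squared difference (a - b) is reported.
#'
#' @param model_a,model_b [build_grs()] models.
#' @inheritParams evaluate_grs
#' @return List with `report_a`, `report_b`, and `delta_incremental_r2`.
#' @export
compare_scores <- function(model_a, model_b, data, covariates = NULL,
                           outcome = "phenotype") {
  sa <- score_samples(model_a, data)
  sb <- score_samples(model_b, data)
  ra <- evaluate_grs(sa, data, covariates, outcome)
  rb <- evaluate_grs(sb, data, covariates, outcome)
  list(report_a = ra, report_b = rb,
       delta_incremental_r2 = ra$incremental_r2 - rb$incremental_r2)
}
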