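#' Harmonize effect alleles between two summary-statistics sets
#'
#' Aligns `other` to the allele orientation of `reference` by variant id:
#' where `other`'s effect allele equals the reference's other allele (and
#' vice versa) the row is flipped (`beta -> -beta`, `eaf -> 1 - eaf`);
#' rows whose allele pair does not match the reference's are dropped with
#' a warning. Variants absent from the reference pass through unchanged.
#'
#' @param reference,other Summary-statistics data frames as produced by
#'   [gwas_linear()] (columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `eaf`, ...).
#' @return `other`, aligned; the number of dropped rows is reported via
#'   `attr(, "n_dropped")`.
#' @export
harmonize_alleles <- function(reference, other) {
  i <- match(other$variant_id, reference$variant_id)
  shared <- !is.na(i)
  ref_ea <- reference$effect_allele[i]
  ref_oa <- reference$other_allele[i]
  same <- shared & other$effect_allele == ref_ea &
    other$other_allele == ref_oa
  flip <- shared & other$effect_allele == ref_oa &
    other$other_allele == ref_ea
  bad <- shared & !same & !flip
  if (any(flip)) {
    other$beta[flip] <- -other$beta[flip]
    if (!is.null(other$eaf)) other$eaf[flip] <- 1 - other$eaf[flip]
    tmp <- other$effect_allele[flip]
    other$effect_allele[flip] <- other$other_allele[flip]
    other$other_allele[flip] <- tmp
  }
  if (any(bad))
    warning(sum(bad), " variant(s) dropped: allele pair incompatible ",
            "with the reference")
  out <- other[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Random-effects inverse-variance meta-analysis (DerSimonian-Laird)
#'
#' Pools per-study association statistics per variant. With fixed-effect
#' weights \eqn{w_i = 1/se_i^2}, the heterogeneity statistic is
#' \eqn{Q = \sum w_i (\beta_i - \beta_{fixed})^2} and the
#' between-study variance \eqn{\tau^2 = \max(0, (Q - (k-1)) /
#' (\sum w_i - \sum w_i^2 / \sum w_i))}; random-effects weights are
#' \eqn{1/(se_i^2 + \tau^2)}, giving the pooled beta, its SE
#' \eqn{1/\sqrt{\sum w_i^*}} and a two-sided normal p-value. Variants
#' present in a single study carry that study's statistics with `k = 1`
#' and `tau2 = 0`. Studies must already be allele-harmonized (see
#' [harmonize_alleles()]).
#'
#' @param per_study List of per-study summary-statistics data frames
#'   ([gwas_linear()] format).
#' @param method `"DL"` (random effects, default) or `"FE"`
#'   (fixed-effect pooling, for comparison).
#' @return Data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf` (inverse-variance weighted),
#'   `beta_meta`, `se_meta`, `p_meta`, `q_stat`, `tau2`, `k`,
#'   `directions` (per-study sign pattern, `?` where absent), sorted by
#'   ascending `p_meta`.
#' @export
meta_analyze <- function(per_study, method = c("DL", "FE")) {
  method <- match.arg(method)
  if (!length(per_study)) stop("need at least one study")
  if (!is.data.frame(per_study[[1]])) stop("per_study must hold data frames")
  for (s in per_study)
    if (any(!is.finite(s$se) | s$se <= 0))
      stop("all standard errors must be positive and finite")
  ids <- unique(unlist(lapply(per_study, `[[`, "variant_id")))
  K <- length(per_study)
  m <- length(ids)
  B <- SE <- EAF <- matrix(NA_real_, m, K)
  for (j in seq_len(K)) {
    i <- match(per_study[[j]]$variant_id, ids)
    B[i, j] <- per_study[[j]]$beta
    SE[i, j] <- per_study[[j]]$se
    EAF[i, j] <- per_study[[j]]$eaf
  }
  W <- 1 / SE^2
  sw <- rowSums(W, na.rm = TRUE)
  k <- rowSums(!is.na(B))
  bf <- rowSums(W * B, na.rm = TRUE) / sw
  Q <- rowSums(W * (B - bf)^2, na.rm = TRUE)
  if (method == "DL") {
    denom <- sw - rowSums(W^2, na.rm = TRUE) / sw
    tau2 <- ifelse(k > 1, pmax(0, (Q - (k - 1)) / denom), 0)
  } else {
    tau2 <- rep(0, m)
  }
  Wr <- 1 / (SE^2 + tau2)
  swr <- rowSums(Wr, na.rm = TRUE)
  beta_meta <- rowSums(Wr * B, na.rm = TRUE) / swr
  se_meta <- 1 / sqrt(swr)
  p_meta <- 2 * stats::pnorm(-abs(beta_meta / se_meta))
  eaf <- rowSums(W * EAF, na.rm = TRUE) / sw
  dir_chr <- matrix("?", m, K)
  dir_chr[!is.na(B) & B > 0] <- "+"
  dir_chr[!is.na(B) & B < 0] <- "-"
  dir_chr[!is.na(B) & B == 0] <- "0"
  directions <- apply(dir_chr, 1, paste, collapse = "")

  # variant annotation taken from the first study carrying the variant
  first_study <- apply(!is.na(B), 1, which.max)
  meta_cols <- c("variant_id", "chrom", "pos", "effect_allele",
                 "other_allele")
  vm <- data.frame(variant_id = ids, chrom = NA_integer_,
                   pos = NA_integer_, effect_allele = NA_character_,
                   other_allele = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(K)) {
    take <- which(first_study == j)
    if (!length(take)) next
    s <- per_study[[j]]
    vm[take, meta_cols] <- s[match(ids[take], s$variant_id), meta_cols]
  }
  out <- cbind(vm,
               data.frame(eaf = eaf, beta_meta = beta_meta,
                          se_meta = se_meta, p_meta = p_meta, q_stat = Q,
                          tau2 = tau2, k = k, directions = directions,
                          stringsAsFactors = FALSE))
  out <- out[order(out$p_meta, out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Select suggestive candidates from a meta-analysis
#'
#' Keeps variants with pooled p strictly below the threshold, sorted by
#' ascending p (the entry list for score construction).
#'
#' @param meta [meta_analyze()] output.
#' @param p_threshold Suggestive-association threshold (default 5e-5).
#' @return Subset of `meta`; empty (zero-row) results are allowed.
#' @export
select_candidates <- function(meta, p_threshold = 5e-5) {
  if (!nrow(meta)) stop("meta-analysis result is empty")
  out <- meta[!is.na(meta$p_meta) & meta$p_meta < p_threshold, ,
              drop = FALSE]
  out <- out[order(out$p_meta), ]
  rownames(out) <- NULL
  out
}

#' Refine candidates against an independent replication cohort
#'
#' Applies the two-clause replication filter: a candidate is retained iff
#' it is present in the replication statistics, its replication p-value
#' is strictly below `p_max`, and its replication effect has the same
#' sign as the pooled discovery effect. Alleles must be harmonized
#' beforehand. Every candidate receives a decision record; the first
#' failing clause (missing, then p, then sign) is recorded as the
#' reason.
#'
#' @param candidates [select_candidates()] output (needs `variant_id`,
#'   `beta_meta`).
#' @param replication Replication-cohort summary statistics
#'   ([gwas_linear()] format), harmonized to the candidates.
#' @param p_max Replication p-value ceiling (default 0.2; `p >= p_max`
#'   fails).
#' @return Data frame with columns `variant_id`, `replication_p`,
#'   `replication_sign`, `concordant`, `retained`, `reason`.
#' @export
refine_candidates <- function(candidates, replication, p_max = 0.2) {
  i <- match(candidates$variant_id, replication$variant_id)
  rep_p <- replication$p[i]
  rep_b <- replication$beta[i]
  missing <- is.na(i) | is.na(rep_p) | is.na(rep_b)
  concordant <- !missing & sign(rep_b) == sign(candidates$beta_meta) &
    sign(rep_b) != 0
  p_ok <- !missing & rep_p < p_max
  reason <- ifelse(missing, "missing_in_replication",
                   ifelse(!p_ok, "p_fail",
                          ifelse(!concordant, "sign_fail", "pass")))
  data.frame(variant_id = candidates$variant_id,
             replication_p = rep_p,
             replication_sign = ifelse(missing, NA, sign(rep_b)),
             concordant = ifelse(missing, NA, concordant),
             retained = reason == "pass",
             reason = reason,
             stringsAsFactors = FALSE)
}
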