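#' Quality-control thresholds
#'
#' Container for the variant- and sample-level QC cutoffs applied by
#' [apply_variant_qc()] and [apply_sample_qc()]. Defaults follow common
#' array-GWAS practice: variants are dropped at call rate < 95%,
#' Hardy-Weinberg exact p < 1e-5, or minor allele frequency below the
#' analysis floor (5% for imputed common-variant analyses; the 1% array
#' floor is kept as a separate field for raw-array QC); samples are
#' dropped at call rate < 98% or when a pair shows relatedness
#' PI_HAT >= 0.25.
#'
#' @param variant_call_rate_min Minimum per-variant call rate.
#' @param hwe_p_min Minimum Hardy-Weinberg exact-test p-value.
#' @param maf_min_array Array-stage MAF floor (informational unless used
#'   as the analysis floor).
#' @param maf_min_analysis MAF floor applied by [apply_variant_qc()].
#' @param sample_call_rate_min Minimum per-sample call rate.
#' @param pi_hat_max Relatedness ceiling; one member of each pair at or
#'   above it is removed.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(variant_call_rate_min = 0.95,
                          hwe_p_min = 1e-5,
                          maf_min_array = 0.01,
                          maf_min_analysis = 0.05,
                          sample_call_rate_min = 0.98,
                          pi_hat_max = 0.25) {
  th <- list(variant_call_rate_min = variant_call_rate_min,
             hwe_p_min = hwe_p_min,
             maf_min_array = maf_min_array,
             maf_min_analysis = maf_min_analysis,
             sample_call_rate_min = sample_call_rate_min,
             pi_hat_max = pi_hat_max)
  bad <- names(th)[!vapply(th, function(v)
    is.numeric(v) && length(v) == 1L && v >= 0 && v <= 1, logical(1))]
  if (length(bad))
    stop("qc_thresholds fields must be single values in [0, 1]: ",
         paste(bad, collapse = ", "))
  structure(th, class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact conditional test: given the observed allele counts,
#' the returned p-value is the total probability of heterozygote counts
#' whose conditional probability does not exceed that of the observed
#' count. Probabilities follow the standard levene-haldane distribution,
#' evaluated with the heterozygote-count recurrence; tables sharing the
#' same (total, allele-count) key are computed once, so the function is
#' efficient when called on whole-array genotype-count vectors.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectors of equal length are
#'   accepted and tested element-wise).
#' @return p-value(s) in \[0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  k <- length(n_AA)
  if (length(n_Aa) != k || length(n_aa) != k)
    stop("genotype count vectors must have equal length")
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0, na.rm = TRUE))
    stop("genotype counts must be non-negative")
  N <- n_AA + n_Aa + n_aa
  if (any(!is.finite(N)) || any(N == 0))
    stop("each table needs a positive total genotype count")
  nA <- 2 * n_AA + n_Aa
  # rare-allele count caps the heterozygote count; parity of nA fixes its
  # lattice
  nr_all <- pmin(nA, 2 * N - nA)
  key <- paste(N, nr_all)
  out <- numeric(k)
  for (sel in split(seq_len(k), key)) {
    Ni <- N[sel[1]]
    nr <- nr_all[sel[1]]
    h0 <- nr %% 2L
    hs <- seq.int(h0, nr, by = 2L)
    if (length(hs) == 1L) {
      out[sel] <- 1
      next
    }
    # P(h+2)/P(h) = 4 nAA(h) naa(h) / ((h+1)(h+2)), counts expressed via
    # the rarer allele (the distribution is symmetric in allele
    # labelling); accumulated in log space to avoid overflow
    hmid <- hs[-length(hs)]
    n_rr <- (nr - hmid) / 2
    n_cc <- Ni - n_rr - hmid
    logp <- c(0, cumsum(log(4 * n_rr * n_cc) -
                          log((hmid + 1) * (hmid + 2))))
    p <- exp(logp - max(logp))
    p <- p / sum(p)
    # two-sided exact p: total mass of outcomes no more probable than
    # the observed one (sorted cumulative sums, O(K log K))
    ord <- order(p)
    cs <- cumsum(p[ord])
    idx <- findInterval(p * (1 + 1e-12), p[ord])
    pv <- cs[idx]
    obs_h <- n_Aa[sel]
    out[sel] <- pmin(1, pv[match(obs_h, hs)])
  }
  if (anyNA(out))
    stop("observed heterozygote count incompatible with allele totals")
  out
}

#' QC report
#'
#' Records what a QC pass removed and why. Units failing several filters
#' are attributed to the first failing filter in the documented order
#' (variants: call rate, then HWE, then MAF; samples: call rate, then
#' relatedness), so per-filter counts sum to the total removed.
#' @param scope `"variant"` or `"sample"`.
#' @param n_in,n_out Unit counts before/after.
#' @param removed Named list of removed-id character vectors, one per
#'   filter.
#' @param thresholds The `qc_thresholds` applied.
#' @return An object of class `qc_report`.
#' @keywords internal
qc_report <- function(scope, n_in, n_out, removed, thresholds) {
  stopifnot(n_in - n_out == sum(lengths(removed)))
  structure(list(scope = scope, n_in = n_in, n_out = n_out,
                 removed = removed, thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report: %s> %d in -> %d out (%d removed)\n",
              x$scope, x$n_in, x$n_out, x$n_in - x$n_out))
  for (f in names(x$removed))
    cat(sprintf("  %-22s %d\n", f, length(x$removed[[f]])))
  invisible(x)
}

#' Tabular form of a QC report
#' @param report A `qc_report`.
#' @return Data frame with columns `filter`, `n_removed`.
#' @export
qc_report_table <- function(report) {
  data.frame(filter = names(report$removed),
             n_removed = lengths(report$removed),
             row.names = NULL, stringsAsFactors = FALSE)
}

# genotype counts from (possibly fractional) dosages; fractional values
# are rounded to the nearest hard call for HWE/IBS purposes only
.geno_counts <- function(dosages) {
  g <- round(dosages)
  n2 <- colSums(g == 2, na.rm = TRUE)
  n1 <- colSums(g == 1, na.rm = TRUE)
  n0 <- colSums(g == 0, na.rm = TRUE)
  cbind(n_AA = n2, n_Aa = n1, n_aa = n0)
}

#' Variant-level quality control
#'
#' Removes variants failing, in order: call rate below
#' `variant_call_rate_min`; Hardy-Weinberg exact p below `hwe_p_min`;
#' minor allele frequency below `maf_min_analysis`. Each variant is
#' attributed to the first filter it fails.
#'
#' @param data A [cohort_dataset()].
#' @param th A [qc_thresholds()].
#' @return List with elements `data` (filtered dataset) and `report`
#'   (a `qc_report`).
#' @export
apply_variant_qc <- function(data, th = qc_thresholds()) {
  stopifnot(inherits(data, "cohort_dataset"), inherits(th, "qc_thresholds"))
  m <- n_variants(data)
  if (m == 0) stop("dataset has no variants")
  n <- n_samples(data)
  ids <- data$variant_meta$variant_id

  call_rate <- 1 - colSums(is.na(data$dosages)) / n
  fail_cr <- call_rate < th$variant_call_rate_min

  counts <- .geno_counts(data$dosages)
  hwe_p <- rep(1, m)
  nz <- rowSums(counts) > 0
  hwe_p[nz] <- hwe_exact_test(counts[nz, 1], counts[nz, 2], counts[nz, 3])
  fail_hwe <- !fail_cr & hwe_p < th$hwe_p_min

  eaf <- colMeans(data$dosages, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  maf[is.nan(maf)] <- 0
  fail_maf <- !fail_cr & !fail_hwe & maf < th$maf_min_analysis

  keep <- !(fail_cr | fail_hwe | fail_maf)
  if (!any(keep))
    stop("variant QC removed every variant; review thresholds ",
         "(call rate >= ", th$variant_call_rate_min,
         ", HWE p >= ", th$hwe_p_min,
         ", MAF >= ", th$maf_min_analysis, ")")
  removed <- list(call_rate = ids[fail_cr],
                  hwe = ids[fail_hwe],
                  maf = ids[fail_maf])
  out <- subset_cohort(data, variants = which(keep))
  list(data = out,
       report = qc_report("variant", m, sum(keep), removed, th))
}

# Per-variant sums of the IBS-state probabilities conditional on IBD
# state, given effect-allele frequencies p (method-of-moments pieces).
.ibs_expectations <- function(p) {
  q <- 1 - p
  list(e0_z0 = sum(2 * p^2 * q^2),
       e1_z0 = sum(4 * p^3 * q + 4 * p * q^3),
       e2_z0 = sum(p^4 + q^4 + 4 * p^2 * q^2),
       e1_z1 = sum(2 * p * q),
       e2_z1 = sum(p^2 + q^2))
}

.pi_hat_from_ibs <- function(N0, N1, N2, e, m) {
  z0 <- N0 / e$e0_z0
  z1 <- (N1 - z0 * e$e1_z0) / e$e1_z1
  z2 <- (N2 - z0 * e$e2_z0 - z1 * e$e2_z1) / m
  z0 <- pmin(pmax(z0, 0), 1)
  z1 <- pmin(pmax(z1, 0), 1)
  z2 <- pmin(pmax(z2, 0), 1)
  tot <- z0 + z1 + z2
  ok <- tot > 0
  z1[ok] <- z1[ok] / tot[ok]
  z2[ok] <- z2[ok] / tot[ok]
  pmin(pmax(z1 / 2 + z2, 0), 1)
}

#' Pairwise relatedness (PI_HAT) for one sample pair
#'
#' Method-of-moments identity-by-descent estimate from identity-by-state
#' counts, with allele frequencies estimated from the full sample:
#' PI_HAT = P(IBD=1)/2 + P(IBD=2), clamped to \[0, 1\]. Fractional
#' dosages are rounded to hard calls. Requires at least 500 variants
#' non-missing in both samples.
#'
#' @param data A [cohort_dataset()].
#' @param pair Length-2 vector of sample ids (or row indices).
#' @return PI_HAT estimate in \[0, 1\].
#' @export
estimate_pi_hat <- function(data, pair) {
  if (length(pair) != 2L) stop("'pair' must name exactly two samples")
  i <- if (is.character(pair)) match(pair, rownames(data$dosages)) else pair
  if (anyNA(i)) stop("unknown sample id in 'pair'")
  gi <- round(data$dosages[i[1], ])
  gj <- round(data$dosages[i[2], ])
  shared <- !is.na(gi) & !is.na(gj)
  if (sum(shared) < 500L)
    stop("only ", sum(shared), " shared non-missing variants; ",
         "need >= 500 for a stable PI_HAT estimate")
  p <- colMeans(data$dosages[, shared, drop = FALSE], na.rm = TRUE) / 2
  ok <- p > 0 & p < 1
  gi <- gi[shared][ok]; gj <- gj[shared][ok]; p <- p[ok]
  d <- abs(gi - gj)
  e <- .ibs_expectations(p)
  .pi_hat_from_ibs(sum(d == 2), sum(d == 1), sum(d == 0), e, length(p))
}

# All-pairs PI_HAT on a random subset of polymorphic variants (hard-call
# IBS via indicator cross-products). Missing entries contribute to no
# IBS state; under missingness-completely-at-random the observed counts
# are rescaled by the per-pair shared-call fraction.
pairwise_pi_hat <- function(data, max_variants = 2000L, seed = 1L) {
  g <- round(data$dosages)
  p_all <- colMeans(g, na.rm = TRUE) / 2
  use <- which(!is.na(p_all) & p_all > 0 & p_all < 1)
  if (length(use) < 100L)
    stop("fewer than 100 polymorphic variants; cannot screen relatedness")
  if (length(use) < 1000L)
    warning("relatedness screen running on only ", length(use),
            " polymorphic variants; PI_HAT estimates will be noisy")
  if (length(use) > max_variants)
    use <- with_seed(seed, sort(sample(use, max_variants)))
  g <- g[, use, drop = FALSE]
  p <- p_all[use]
  m <- length(use)
  obs <- !is.na(g)
  H0 <- (g == 0) & obs; H1 <- (g == 1) & obs; H2 <- (g == 2) & obs
  H0[!obs] <- FALSE; H1[!obs] <- FALSE; H2[!obs] <- FALSE
  H0 <- H0 * 1; H1 <- H1 * 1; H2 <- H2 * 1
  M <- tcrossprod(obs * 1)                  # shared non-missing calls
  N2 <- tcrossprod(H0) + tcrossprod(H1) + tcrossprod(H2)
  N0 <- tcrossprod(H0, H2)
  N0 <- N0 + t(N0)
  N1 <- M - N0 - N2
  scale <- m / pmax(M, 1)
  e <- .ibs_expectations(p)
  ph <- .pi_hat_from_ibs(N0 * scale, N1 * scale, N2 * scale, e, m)
  ph[M < 100L] <- 0   # too few shared calls for any statement
  diag(ph) <- 1
  dimnames(ph) <- list(rownames(data$dosages), rownames(data$dosages))
  ph
}

colAnyNA <- function(x) colSums(is.na(x)) > 0L

#' Sample-level quality control
#'
#' Removes samples below the call-rate floor, then screens remaining
#' pairs for relatedness: for each pair with PI_HAT at or above
#' `pi_hat_max`, the member with the lower call rate is removed (tie:
#' the later sample in table order). The relatedness screen uses a
#' random subset of at most `ibd_variants` complete polymorphic variants.
#'
#' @param data A [cohort_dataset()].
#' @param th A [qc_thresholds()].
#' @param relatedness Logical; run the PI_HAT screen (default `TRUE`).
#' @param ibd_variants Maximum variants used for the pairwise screen.
#' @return List with elements `data` and `report`, as
#'   [apply_variant_qc()].
#' @export
apply_sample_qc <- function(data, th = qc_thresholds(), relatedness = TRUE,
                            ibd_variants = 2000L) {
  stopifnot(inherits(data, "cohort_dataset"), inherits(th, "qc_thresholds"))
  n <- n_samples(data)
  if (n < 2L) stop("sample QC needs at least 2 samples")
  ids <- data$samples$sample_id
  call_rate <- 1 - rowSums(is.na(data$dosages)) / n_variants(data)
  fail_cr <- call_rate < th$sample_call_rate_min

  rel_removed <- character(0)
  if (relatedness && sum(!fail_cr) >= 2L) {
    keep_idx <- which(!fail_cr)
    sub <- subset_cohort(data, samples = keep_idx)
    ph <- pairwise_pi_hat(sub, max_variants = ibd_variants)
    ph[lower.tri(ph, diag = TRUE)] <- 0
    pr <- which(ph >= th$pi_hat_max, arr.ind = TRUE)
    if (nrow(pr)) {
      ord <- order(ph[pr], decreasing = TRUE)
      pr <- pr[ord, , drop = FALSE]
      cr_sub <- call_rate[keep_idx]
      alive <- rep(TRUE, length(keep_idx))
      for (r in seq_len(nrow(pr))) {
        a <- pr[r, 1]; b <- pr[r, 2]
        if (!alive[a] || !alive[b]) next
        drop_one <- if (cr_sub[a] < cr_sub[b]) a
                    else if (cr_sub[b] < cr_sub[a]) b
                    else max(a, b)   # tie: later sample order
        alive[drop_one] <- FALSE
      }
      rel_removed <- sub$samples$sample_id[!alive]
    }
  }
  keep <- !fail_cr & !(ids %in% rel_removed)
  if (!any(keep))
    stop("sample QC removed every sample; review thresholds")
  removed <- list(call_rate = ids[fail_cr], relatedness = rel_removed)
  out <- subset_cohort(data, samples = which(keep))
  list(data = out,
       report = qc_report("sample", n, sum(keep), removed, th))
}
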