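#' Simulation configuration for synthetic multi-cohort genotype data
#'
#' Defines a shared genetic architecture (variant frequencies, LD blocks,
#' planted causal effects, ancestry strata) from which any number of
#' cohorts are drawn. All cohorts simulated from one config share variant
#' metadata, allele frequencies and causal effects, so downstream cohorts
#' genuinely replicate upstream signal (with modality-specific
#' attenuation), mirroring discovery / neuropathology / plasma designs.
#'
#' @param seed Integer master seed; with an identical config the generator
#'   is bit-reproducible.
#' @param n_per_cohort Named integer vector, cohort name -> sample count.
#' @param m_variants Total number of variants.
#' @param ld_block_size Variants per LD block (blocks are mutually
#'   independent; `m_variants` need not be a multiple, the last block is
#'   shorter).
#' @param ld_rho Latent adjacent-variant correlation within a block, in
#'   \[0, 1). The realised genotype correlation is smaller (thresholding
#'   attenuates it); see [expected_adjacent_r2()].
#' @param maf_range Length-2 numeric `(low, high)` in (0, 0.5]; base
#'   effect-allele frequencies are drawn uniformly on this interval.
#' @param n_causal Number of planted causal variants. Each is placed in a
#'   distinct LD block (at a uniform position within the block) and
#'   restricted to base frequency >= 0.08 — comfortably above the 5%
#'   analysis MAF floor — so planted signal survives variant QC by
#'   construction.
#' @param h2_target Fraction of phenotype variance explained by the causal
#'   variants in an unattenuated cohort, in \[0, 1). Causal effects are
#'   sized for equal per-variant contributions (`h2_target / n_causal`
#'   each) with random signs.
#' @param effect_attenuation Named numeric vector, cohort name ->
#'   multiplier applied to all causal effects in that cohort (models
#'   attenuation of a shared genetic basis across measurement modalities).
#'   Cohorts absent from the vector get 1.
#' @param covariate_effects Named numeric vector with elements `age_beta`
#'   (per year) and `sex_beta`, on the standardized latent phenotype
#'   scale (unit total variance before modality scaling).
#' @param n_ancestry_strata Number of ancestry strata; stratum allele
#'   frequencies are Balding-Nichols draws around the base frequency.
#' @param fst Balding-Nichols differentiation parameter controlling the
#'   magnitude of per-stratum allele-frequency shifts (ignored when
#'   `n_ancestry_strata == 1`).
#' @param stratum_pheno_sd SD of per-stratum phenotype offsets (latent
#'   scale); nonzero values create stratification confounding that the
#'   principal-component covariates must absorb.
#' @param missing_rate Per-genotype probability of a missing call
#'   (completely at random).
#' @param braak_threshold Quantile of the latent tangle-burden trait above
#'   which the binary high-Braak outcome is 1.
#' @param tangle_attenuation Multiplier (relative to the neuropathology
#'   cohort's own attenuation) applied to causal effects on the tangle
#'   trait.
#'
#' @return A validated object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_per_cohort = c(discovery_a = 500,
                                               discovery_b = 500),
                              m_variants = 2000L,
                              ld_block_size = 10L,
                              ld_rho = 0.7,
                              maf_range = c(0.05, 0.5),
                              n_causal = 0L,
                              h2_target = 0,
                              effect_attenuation = NULL,
                              covariate_effects = c(age_beta = 0.02,
                                                    sex_beta = 0.2),
                              n_ancestry_strata = 1L,
                              fst = 0.01,
                              stratum_pheno_sd = 0,
                              missing_rate = 0,
                              braak_threshold = 0.7,
                              tangle_attenuation = 0.7) {
  fail <- function(field, ...) stop("invalid '", field, "': ", ...,
                                    call. = FALSE)
  if (length(seed) != 1L || !is.finite(seed)) fail("seed", "single integer")
  if (is.null(names(n_per_cohort)) || any(!nzchar(names(n_per_cohort))))
    fail("n_per_cohort", "must be a named vector of cohort sizes")
  if (any(n_per_cohort < 1)) fail("n_per_cohort", "counts must be >= 1")
  if (m_variants < 1) fail("m_variants", "must be >= 1")
  if (ld_block_size < 1) fail("ld_block_size", "must be >= 1")
  if (ld_rho < 0 || ld_rho >= 1) fail("ld_rho", "must be in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1] <= 0 ||
      maf_range[1] > maf_range[2] || maf_range[2] > 0.5)
    fail("maf_range", "need 0 < low <= high <= 0.5")
  if (n_causal < 0 || n_causal > m_variants)
    fail("n_causal", "must be in [0, m_variants]")
  n_blocks <- ceiling(m_variants / ld_block_size)
  if (n_causal > n_blocks)
    fail("n_causal", "at most one causal variant per LD block (n_blocks = ",
         n_blocks, ")")
  if (h2_target < 0 || h2_target >= 1) fail("h2_target", "must be in [0, 1)")
  if (!all(c("age_beta", "sex_beta") %in% names(covariate_effects)))
    fail("covariate_effects", "needs named elements age_beta, sex_beta")
  if (n_ancestry_strata < 1) fail("n_ancestry_strata", "must be >= 1")
  if (fst <= 0 || fst >= 1) fail("fst", "must be in (0, 1)")
  if (stratum_pheno_sd < 0) fail("stratum_pheno_sd", "must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    fail("missing_rate", "must be in [0, 1)")
  if (braak_threshold <= 0 || braak_threshold >= 1)
    fail("braak_threshold", "must be in (0, 1)")
  if (tangle_attenuation < 0) fail("tangle_attenuation", "must be >= 0")
  att <- setNames(rep(1, length(n_per_cohort)), names(n_per_cohort))
  if (!is.null(effect_attenuation)) {
    unknown <- setdiff(names(effect_attenuation), names(n_per_cohort))
    if (length(unknown))
      fail("effect_attenuation", "unknown cohort(s): ",
           paste(unknown, collapse = ", "))
    att[names(effect_attenuation)] <- effect_attenuation
  }
  structure(
    list(seed = as.integer(seed),
         n_per_cohort = n_per_cohort,
         m_variants = as.integer(m_variants),
         ld_block_size = as.integer(ld_block_size),
         ld_rho = ld_rho,
         maf_range = maf_range,
         n_causal = as.integer(n_causal),
         h2_target = h2_target,
         effect_attenuation = att,
         covariate_effects = covariate_effects,
         n_ancestry_strata = as.integer(n_ancestry_strata),
         fst = fst,
         stratum_pheno_sd = stratum_pheno_sd,
         missing_rate = missing_rate,
         braak_threshold = braak_threshold,
         tangle_attenuation = tangle_attenuation),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$m_variants, "variants in blocks of",
      x$ld_block_size, "(rho =", x$ld_rho, ")\n")
  cat("  cohorts:", paste(sprintf("%s(n=%d, att=%.2g)", names(x$n_per_cohort),
                                  x$n_per_cohort,
                                  x$effect_attenuation[names(x$n_per_cohort)]),
                          collapse = ", "), "\n")
  cat(sprintf("  causal: %d variants, h2 = %.3g; strata: %d (Fst %.3g)\n",
              x$n_causal, x$h2_target, x$n_ancestry_strata, x$fst))
  invisible(x)
}

# Deterministic genetic architecture shared by every cohort drawn from a
# config: variant metadata (ids, positions, alleles), base and per-stratum
# allele frequencies, and planted causal effects on the standardized
# latent phenotype scale.
sim_architecture <- function(config) {
  with_seed(config$seed, {
    m <- config$m_variants
    bs <- config$ld_block_size
    block <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
    n_blocks <- max(block)
    # one LD block per megabase, blocks cycled over 22 autosomes, 5 kb
    # spacing within a block: same-block pairs sit inside any clumping
    # window >= block span, different blocks never do
    chrom <- ((block - 1L) %% 22L) + 1L
    block_on_chrom <- ((block - 1L) %/% 22L)
    within <- stats::ave(seq_len(m), block, FUN = seq_along)
    pos <- block_on_chrom * 1e6 + (within - 1L) * 5000L + 1L
    alle <- matrix(c("A", "G", "C", "T"), ncol = 2, byrow = TRUE)
    pick <- sample(1:2, m, replace = TRUE)
    meta <- data.frame(
      variant_id = sprintf("snp%06d", seq_len(m)),
      chrom = chrom, pos = pos,
      effect_allele = alle[pick, 1], other_allele = alle[pick, 2],
      block = block,
      stringsAsFactors = FALSE)
    base_freq <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    S <- config$n_ancestry_strata
    if (S > 1L) {
      F <- config$fst
      a <- base_freq * (1 - F) / F
      b <- (1 - base_freq) * (1 - F) / F
      freq <- matrix(stats::rbeta(m * S, rep(a, S), rep(b, S)), nrow = m)
      # keep stratum frequencies away from fixation so variants stay
      # polymorphic everywhere
      freq <- pmin(pmax(freq, 0.01), 0.99)
    } else {
      freq <- matrix(base_freq, nrow = m, ncol = 1L)
    }
    stratum_offsets <- if (S > 1L && config$stratum_pheno_sd > 0)
      stats::rnorm(S, 0, config$stratum_pheno_sd) else rep(0, S)
    causal_idx <- integer(0)
    beta <- numeric(0)
    if (config$n_causal > 0L) {
      # placement floor sits above the 5% analysis MAF floor so planted
      # variants cannot be lost to variant QC through sampling noise
      eligible_blocks <- unique(block[base_freq >= 0.08])
      if (length(eligible_blocks) < config$n_causal)
        stop("not enough LD blocks with a common (base frequency >= 8%) ",
             "variant to place ", config$n_causal, " causal variants")
      pick_blocks <- sample(eligible_blocks, config$n_causal)
      causal_idx <- vapply(pick_blocks, function(b) {
        cand <- which(block == b & base_freq >= 0.08)
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      causal_idx <- sort(causal_idx)
      # equal per-variant variance contributions h2/n_causal, random signs
      v_per <- config$h2_target / config$n_causal
      het <- 2 * base_freq[causal_idx] * (1 - base_freq[causal_idx])
      beta <- sample(c(-1, 1), config$n_causal, replace = TRUE) *
        sqrt(v_per / het)
    }
    list(meta = meta, base_freq = base_freq, freq = freq,
         stratum_offsets = stratum_offsets,
         causal_idx = causal_idx, causal_beta = beta)
  })
}

#' Theoretical adjacent-variant genotype r-squared of the LD model
#'
#' Computes, by one-dimensional numerical integration of the bivariate
#' normal threshold model, the expected squared correlation between
#' adjacent variant dosages for a latent correlation `rho` and allele
#' frequencies `f1`, `f2`. Haplotype alleles at adjacent sites are
#' indicators of correlated Gaussians falling below their frequency
#' quantiles; the genotype correlation of HWE diploids equals the
#' haplotype allele correlation.
#'
#' @param rho Latent adjacent correlation in \[0, 1).
#' @param f1,f2 Effect-allele frequencies.
#' @return Expected genotype r-squared (scalar).
#' @export
expected_adjacent_r2 <- function(rho, f1, f2) {
  t1 <- stats::qnorm(f1); t2 <- stats::qnorm(f2)
  # P(Z1 < t1, Z2 < t2) for correlation rho
  p11 <- stats::integrate(function(z)
    stats::dnorm(z) * stats::pnorm((t2 - rho * z) / sqrt(1 - rho^2)),
    -Inf, t1, rel.tol = 1e-10)$value
  r <- (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
  r^2
}
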