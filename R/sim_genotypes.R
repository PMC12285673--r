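#' Simulate genotypes for one cohort
#'
#' Draws a dosage matrix under a latent-Gaussian threshold model: within
#' each LD block the two haplotype latents follow an AR(1) process with
#' adjacent correlation `ld_rho`; an allele is carried when its latent
#' falls below the frequency quantile of the sample's ancestry stratum.
#' Blocks are independent, haplotypes are independent (so genotypes are
#' in Hardy-Weinberg equilibrium within each stratum), and missing calls
#' are injected completely at random at `missing_rate`.
#'
#' All cohorts drawn from the same config share variant metadata, allele
#' frequencies and planted causal effects; only the sample draws differ.
#'
#' @param config A [simulation_config()].
#' @param cohort Cohort name; must be a name of `config$n_per_cohort`.
#' @return A [cohort_dataset()] with genotypes, covariates (age, sex,
#'   stratum) and an all-`NA` phenotype; `truth` holds the planted causal
#'   effects on the standardized latent scale (see
#'   [simulate_phenotypes()]).
#' @export
simulate_genotypes <- function(config, cohort) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be created by simulation_config()")
  idx <- match(cohort, names(config$n_per_cohort))
  if (is.na(idx))
    stop("unknown cohort '", cohort, "'; config defines: ",
         paste(names(config$n_per_cohort), collapse = ", "))
  arch <- sim_architecture(config)
  n <- as.integer(config$n_per_cohort[[idx]])
  m <- config$m_variants
  seed_cohort <- (config$seed * 131L + idx * 7919L) %% 2147483629L

  with_seed(seed_cohort, {
    S <- config$n_ancestry_strata
    stratum <- sample.int(S, n, replace = TRUE)
    age <- pmin(pmax(stats::rnorm(n, 75, 8), 55), 95)
    sex <- stats::rbinom(n, 1L, 0.5)

    rho <- config$ld_rho
    sig <- sqrt(1 - rho^2)
    block <- arch$meta$block
    new_block <- c(TRUE, block[-1] != block[-m])
    dos <- matrix(0, n, m)
    chunk_size <- 2000L
    starts <- seq(1L, m, by = chunk_size)
    # align chunk boundaries to block starts so the AR(1) recursion never
    # crosses a chunk edge mid-block
    starts <- vapply(starts, function(s) {
      while (s > 1L && !new_block[s]) s <- s - 1L
      s
    }, integer(1))
    starts <- unique(starts)
    ends <- c(starts[-1] - 1L, m)
    for (ci in seq_along(starts)) {
      cols <- starts[ci]:ends[ci]
      mb <- length(cols)
      thr <- stats::qnorm(arch$freq[cols, , drop = FALSE])  # mb x S
      thrN <- t(thr)[stratum, , drop = FALSE]               # n x mb
      g <- matrix(0, n, mb)
      for (h in 1:2) {
        Z <- matrix(stats::rnorm(n * mb), n, mb)
        if (rho > 0) {
          nb <- new_block[cols]
          for (j in 2:mb) if (!nb[j])
            Z[, j] <- rho * Z[, j - 1L] + sig * Z[, j]
        }
        g <- g + (Z <= thrN)
      }
      dos[, cols] <- g
    }
    if (config$missing_rate > 0) {
      nmiss <- stats::rbinom(1L, n * m, config$missing_rate)
      if (nmiss > 0)
        dos[sample.int(n * m, nmiss)] <- NA_real_
    }
    samples <- data.frame(
      sample_id = sprintf("%s_s%05d", cohort, seq_len(n)),
      phenotype = NA_real_, age = age, sex = sex, stratum = stratum,
      stringsAsFactors = FALSE)
    truth <- NULL
    if (length(arch$causal_idx))
      truth <- data.frame(
        variant_id = arch$meta$variant_id[arch$causal_idx],
        beta = arch$causal_beta,
        stringsAsFactors = FALSE)
    cohort_dataset(cohort, dos, arch$meta, samples, truth = truth)
  })
}

#' Simulate a phenotype on top of simulated genotypes
#'
#' Fills the phenotype column of a simulated cohort:
#' \deqn{y = a \sum_j \beta_j g_j + \beta_{age}(age - 75) + \beta_{sex} sex
#'       + stratum\ offset + \epsilon}
#' on a standardized latent scale (unit total variance for an
#' unattenuated cohort), then maps the latent value to the modality's
#' units by a fixed affine transform. The noise variance is set so that
#' the causal variants explain exactly `h2_target` of the latent variance
#' in an unattenuated cohort; a cohort with attenuation `a` therefore has
#' causal fraction close to `h2_target * a^2`.
#'
#' Modalities:
#' \describe{
#'   \item{`centiloid`}{amyloid-PET burden, Centiloid-like scale
#'     (mean 35, SD ~30).}
#'   \item{`neuropath`}{postmortem amyloid percent-area (mean 4, SD ~3);
#'     also fills `tangle_density` (a second trait sharing the causal
#'     basis, further attenuated by `tangle_attenuation`) and the binary
#'     `braak_high` indicator (latent tangle burden above the
#'     `braak_threshold` quantile).}
#'   \item{`plasma`}{plasma p-tau-like concentration (mean 2.3, SD ~1.6).}
#' }
#'
#' @param genotypes A [cohort_dataset()] from [simulate_genotypes()].
#' @param config The same [simulation_config()] used for the genotypes.
#' @param modality One of `"centiloid"`, `"neuropath"`, `"plasma"`.
#' @return The dataset with phenotype (and, for `neuropath`, tangle and
#'   Braak outcomes) filled; `truth$beta` is rescaled to effects on the
#'   final phenotype scale.
#' @export
simulate_phenotypes <- function(genotypes, config, modality = "centiloid") {
  valid <- c("centiloid", "neuropath", "plasma")
  if (!modality %in% valid)
    stop("unknown modality '", modality, "'; valid modalities: ",
         paste(valid, collapse = ", "))
  cohort <- genotypes$cohort_name
  idx <- match(cohort, names(config$n_per_cohort))
  if (is.na(idx)) stop("cohort '", cohort, "' not defined in config")
  att <- config$effect_attenuation[[cohort]]
  ab <- config$covariate_effects[["age_beta"]]
  sb <- config$covariate_effects[["sex_beta"]]
  h2 <- config$h2_target
  sigma_c2 <- ab^2 * 64 + sb^2 * 0.25
  sigma_e2 <- 1 - h2 - sigma_c2
  if (sigma_e2 <= 0)
    stop("covariate_effects too large for h2_target: ",
         "latent noise variance would be non-positive")

  n <- n_samples(genotypes)
  gval <- rep(0, n)
  gval_t <- rep(0, n)
  if (!is.null(genotypes$truth) && h2 > 0) {
    gmat <- genotypes$dosages[, genotypes$truth$variant_id, drop = FALSE]
    if (anyNA(gmat)) {  # impute to the column mean for the latent value
      mu <- colMeans(gmat, na.rm = TRUE)
      for (j in seq_len(ncol(gmat))) {
        nas <- is.na(gmat[, j])
        if (any(nas)) gmat[nas, j] <- mu[j]
      }
    }
    gmat <- scale(gmat, center = TRUE, scale = FALSE)  # centred effects
    gval <- drop(gmat %*% genotypes$truth$beta) * att
    gval_t <- gval * config$tangle_attenuation
  }
  arch_off <- sim_architecture(config)$stratum_offsets
  off <- arch_off[genotypes$samples$stratum]
  # covariates enter centred so the latent trait is mean-zero and the
  # Braak threshold quantile refers to the population latent scale
  fixed <- ab * (genotypes$samples$age - 75) +
    sb * (genotypes$samples$sex - 0.5) + off

  seed_pheno <- (config$seed * 131L + idx * 7919L + 104729L +
                   match(modality, valid) * 17L) %% 2147483629L
  out <- genotypes
  with_seed(seed_pheno, {
    y0 <- gval + fixed + stats::rnorm(n, 0, sqrt(sigma_e2))
    scale_for <- list(centiloid = c(35, 30), neuropath = c(4, 3),
                      plasma = c(2.3, 1.6))[[modality]]
    out$samples$phenotype <- scale_for[1] + scale_for[2] * y0
    if (modality == "neuropath") {
      yt0 <- gval_t + fixed + stats::rnorm(n, 0, sqrt(sigma_e2))
      sd_t <- sqrt((att * config$tangle_attenuation)^2 * h2 +
                     sigma_c2 + sigma_e2)
      out$samples$tangle_density <- 1.5 + 1.2 * yt0
      out$samples$braak_high <-
        as.integer(yt0 > stats::qnorm(config$braak_threshold, 0, sd_t))
    }
    if (!is.null(out$truth))
      out$truth$beta <- out$truth$beta * att * scale_for[2]
    out$modality <- modality
    out
  })
}

#' Convenience: genotypes + phenotype in one call
#' @inheritParams simulate_phenotypes
#' @inheritParams simulate_genotypes
#' @return A phenotype-complete [cohort_dataset()].
#' @export
simulate_cohort <- function(config, cohort, modality = "centiloid") {
  simulate_phenotypes(simulate_genotypes(config, cohort), config, modality)
}

#' Fraction of phenotype variance explained by the planted causal variants
#'
#' Direct variance bookkeeping on the generator's own draws: the realised
#' genetic value of the planted effects (`truth`) is regressed out of
#' nothing — its sample variance is simply divided by the sample
#' phenotype variance. Used to verify `h2_target` calibration and as the
#' ground truth against which recovered score R-squared is compared.
#'
#' @param data A simulated [cohort_dataset()] with `truth` and phenotype.
#' @return Scalar fraction in \[0, 1\].
#' @export
planted_variance_fraction <- function(data) {
  if (is.null(data$truth) || nrow(data$truth) == 0) return(0)
  if (all(is.na(data$samples$phenotype)))
    stop("phenotype not simulated yet")
  gmat <- data$dosages[, data$truth$variant_id, drop = FALSE]
  if (anyNA(gmat)) {
    mu <- colMeans(gmat, na.rm = TRUE)
    for (j in seq_len(ncol(gmat))) {
      nas <- is.na(gmat[, j])
      if (any(nas)) gmat[nas, j] <- mu[j]
    }
  }
  gv <- drop(gmat %*% data$truth$beta)
  stats::var(gv) / stats::var(data$samples$phenotype)
}
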