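test_that("config validation rejects bad fields by name", {
  expect_error(simulation_config(ld_rho = 1), "ld_rho")
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(maf_range = c(0.3, 0.6)), "maf_range")
  expect_error(simulation_config(h2_target = 1), "h2_target")
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
  expect_error(simulation_config(n_per_cohort = c(100, 100)),
               "n_per_cohort")
  expect_error(
    simulation_config(n_causal = 300, m_variants = 2000,
                      ld_block_size = 10),
    "n_causal")
  expect_error(
    simulation_config(effect_attenuation = c(nope = 0.5)),
    "effect_attenuation")
  expect_error(simulate_genotypes(simulation_config(), "nope"),
               "unknown cohort")
  expect_error(
    simulate_phenotypes(
      simulate_genotypes(simulation_config(
        n_per_cohort = c(a = 50), m_variants = 50), "a"),
      simulation_config(n_per_cohort = c(a = 50), m_variants = 50),
      modality = "nope"),
    "centiloid.*neuropath.*plasma")
})

test_that("identical config and seed reproduce datasets exactly", {
  cfg <- simulation_config(seed = 42, n_per_cohort = c(a = 80, b = 60),
                           m_variants = 300, n_causal = 5,
                           h2_target = 0.2, missing_rate = 0.01,
                           n_ancestry_strata = 2)
  d1 <- simulate_cohort(cfg, "a")
  d2 <- simulate_cohort(cfg, "a")
  expect_identical(d1$dosages, d2$dosages)
  expect_identical(d1$samples, d2$samples)
  expect_identical(d1$truth, d2$truth)
  # different cohorts from the same config share architecture, not draws
  db <- simulate_genotypes(cfg, "b")
  expect_identical(db$variant_meta, d1$variant_meta)
  expect_false(identical(db$dosages[1:10, 1:10], d1$dosages[1:10, 1:10]))
})

test_that("dosages are valid and missingness matches the configured rate", {
  cfg <- simulation_config(seed = 7, n_per_cohort = c(a = 400),
                           m_variants = 500, missing_rate = 0.05)
  d <- simulate_genotypes(cfg, "a")
  expect_true(all(d$dosages %in% c(0, 1, 2) | is.na(d$dosages)))
  rate <- mean(is.na(d$dosages))
  expect_lt(abs(rate - 0.05), 0.005)
})

test_that("independence case: near-zero correlation when ld_rho = 0", {
  cfg <- simulation_config(seed = 1, n_per_cohort = c(a = 5000),
                           m_variants = 200, ld_rho = 0,
                           maf_range = c(0.1, 0.5))
  d <- simulate_genotypes(cfg, "a")
  cm <- cor(d$dosages)
  off <- cm[upper.tri(cm)]
  expect_lt(abs(mean(off)), 0.02)
})

test_that("symmetric case: maf_range (0.5, 0.5) gives frequencies near 0.5", {
  n <- 3000
  cfg <- simulation_config(seed = 2, n_per_cohort = c(a = n),
                           m_variants = 100, maf_range = c(0.5, 0.5))
  d <- simulate_genotypes(cfg, "a")
  f <- colMeans(d$dosages) / 2
  se <- sqrt(0.5 * 0.5 / (2 * n))
  expect_true(all(abs(f - 0.5) < 3.5 * se))
  # block LD correlates per-variant estimates; bound the grand mean
  # loosely rather than at the independent-variant rate
  expect_lt(abs(mean(f) - 0.5), 0.006)
})

test_that("adjacent-pair r2 matches the bivariate-threshold integrator", {
  cfg <- simulation_config(seed = 5, n_per_cohort = c(a = 5000),
                           m_variants = 400, ld_block_size = 10,
                           ld_rho = 0.8, maf_range = c(0.1, 0.5))
  d <- simulate_genotypes(cfg, "a")
  blocks <- d$variant_meta$block
  f <- colMeans(d$dosages) / 2
  adj <- which(diff(blocks) == 0)
  emp <- vapply(adj, function(j)
    cor(d$dosages[, j], d$dosages[, j + 1])^2, numeric(1))
  theo <- vapply(adj, function(j)
    expected_adjacent_r2(0.8, f[j], f[j + 1]), numeric(1))
  expect_lt(abs(mean(emp) - mean(theo)), 0.05)
})

test_that("variance bookkeeping recovers h2_target", {
  cfg <- simulation_config(seed = 9, n_per_cohort = c(a = 10000),
                           m_variants = 500, n_causal = 10,
                           h2_target = 0.3, ld_block_size = 10)
  d <- simulate_cohort(cfg, "a")
  expect_lt(abs(planted_variance_fraction(d) - 0.30), 0.03)
})

test_that("null heritability gives calibrated slopes on causal dosages", {
  cfg <- simulation_config(seed = 12, n_per_cohort = c(a = 2000),
                           m_variants = 400, n_causal = 20, h2_target = 0)
  d <- simulate_cohort(cfg, "a")
  expect_true(all(d$truth$beta == 0))
  st <- gwas_linear(subset_cohort(d, variants = d$truth$variant_id))
  # nominal type-I behaviour at the planted (null) variants
  expect_lt(mean(st$p < 0.05), 0.25)
  expect_gt(min(st$p), 1e-4)
})

test_that("attenuated cohorts scale per-variant effects proportionally", {
  cfg <- simulation_config(
    seed = 3, n_per_cohort = c(base = 10000, att = 10000),
    m_variants = 200, n_causal = 10, h2_target = 0.3,
    effect_attenuation = c(att = 0.5))
  base <- simulate_cohort(cfg, "base")
  att <- simulate_cohort(cfg, "att")
  bb <- vapply(base$truth$variant_id, function(v)
    coef(lm(base$samples$phenotype ~ base$dosages[, v]))[2], numeric(1))
  ba <- vapply(att$truth$variant_id, function(v)
    coef(lm(att$samples$phenotype ~ att$dosages[, v]))[2], numeric(1))
  slope <- coef(lm(ba ~ 0 + bb))[1]
  expect_lt(abs(slope - 0.5), 0.05)
})

test_that("genotypes satisfy HWE within ancestry strata", {
  cfg <- simulation_config(seed = 21, n_per_cohort = c(a = 4000),
                           m_variants = 800, n_ancestry_strata = 2,
                           fst = 0.05, maf_range = c(0.1, 0.5))
  d <- simulate_genotypes(cfg, "a")
  for (s in 1:2) {
    g <- d$dosages[d$samples$stratum == s, ]
    cnt <- cbind(colSums(g == 2), colSums(g == 1), colSums(g == 0))
    p <- hwe_exact_test(cnt[, 1], cnt[, 2], cnt[, 3])
    # exact test is conservative: rejection rate at or below nominal
    expect_lt(mean(p < 0.05), 0.065)
  }
  # pooling differentiated strata induces heterozygote deficit
  cntp <- cbind(colSums(d$dosages == 2), colSums(d$dosages == 1),
                colSums(d$dosages == 0))
  pp <- hwe_exact_test(cntp[, 1], cntp[, 2], cntp[, 3])
  expect_gt(mean(pp < 0.05), mean(p < 0.05))
})

test_that("neuropath modality fills tangle and Braak outcomes", {
  cfg <- simulation_config(seed = 8, n_per_cohort = c(np = 3000),
                           m_variants = 200, n_causal = 5,
                           h2_target = 0.2, braak_threshold = 0.7)
  d <- simulate_cohort(cfg, "np", modality = "neuropath")
  expect_true(all(c("tangle_density", "braak_high") %in% names(d$samples)))
  expect_true(all(d$samples$braak_high %in% 0:1))
  expect_lt(abs(mean(d$samples$braak_high) - 0.3), 0.04)
})
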