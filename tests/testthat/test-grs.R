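test_that("ld_r2 equals the direct correlation oracle", {
  set.seed(91)
  dos <- binom_dosages(200, runif(6, 0.2, 0.5), seed = 91) * 1.0
  dos[, 2] <- dos[, 1]                     # identical pair
  dos[5:10, 3] <- NA                       # partial missingness
  d <- toy_cohort(dos)
  expect_equal(ld_r2(d, "v001", "v002"), 1.0)
  use <- complete.cases(dos[, 3], dos[, 4])
  expect_equal(ld_r2(d, "v003", "v004"),
               cor(dos[use, 3], dos[use, 4])^2, tolerance = 1e-12)
  for (pair in list(c(5, 6), c(1, 5), c(4, 6))) {
    a <- sprintf("v%03d", pair[1]); b <- sprintf("v%03d", pair[2])
    expect_equal(ld_r2(d, a, b),
                 cor(dos[, pair[1]], dos[, pair[2]],
                     use = "complete.obs")^2, tolerance = 1e-12)
  }
  dz <- toy_cohort(cbind(v1 = rep(1, 60), v2 = rbinom(60, 2, 0.3)) * 1.0)
  expect_error(ld_r2(dz, "v1", "v2"), "variance")
  expect_error(ld_r2(d, "v001", "nope"), "not present")
})

test_that("independent variants rarely exceed r2 = 0.01 at n = 5000", {
  set.seed(92)
  d <- toy_cohort(binom_dosages(5000, runif(40, 0.1, 0.5), seed = 92))
  r2 <- combn(paste0("v", sprintf("%03d", 1:40)), 2,
              function(p) ld_r2(d, p[1], p[2]))
  expect_gte(mean(r2 < 0.01), 0.95)
})

make_cand <- function(ids, p, pos, chrom = 1L, beta = 1) {
  data.frame(variant_id = ids, chrom = chrom, pos = pos,
             effect_allele = "A", other_allele = "G",
             eaf = 0.3, beta_meta = beta, se_meta = 0.1, p_meta = p,
             stringsAsFactors = FALSE)
}

test_that("clumping keeps the top variant of a correlated pair", {
  set.seed(93)
  g <- rbinom(300, 2, 0.4)
  dos <- cbind(a = g, b = g, c = rbinom(300, 2, 0.4)) * 1.0
  panel <- toy_cohort(dos, pos = c(1000L, 2000L, 3000L))
  cand <- make_cand(c("a", "b", "c"), c(1e-8, 1e-6, 1e-7),
                    c(1000L, 2000L, 3000L))
  out <- clump(cand, panel)
  expect_setequal(out$variant_id, c("a", "c"))
})

test_that("hand-traced three-variant chain clumps to {1, 3}", {
  set.seed(94)
  n <- 4000
  thr <- qnorm(0.4)
  # AR(1) haplotype latents on both chromosomes: adjacent pairs are in
  # LD, the 1-3 pair decays below the clumping ceiling
  h <- function(rho_prev, prev) rho_prev * prev +
    sqrt(1 - rho_prev^2) * rnorm(n)
  a1 <- rnorm(n); b1 <- rnorm(n)
  a2 <- h(0.62, a1); b2 <- h(0.62, b1)
  a3 <- h(0.62, a2); b3 <- h(0.62, b2)
  dos <- cbind(v1 = (a1 < thr) + (b1 < thr),
               v2 = (a2 < thr) + (b2 < thr),
               v3 = (a3 < thr) + (b3 < thr)) * 1.0
  panel <- toy_cohort(dos, pos = c(1000L, 2000L, 3000L))
  r12 <- ld_r2(panel, "v1", "v2"); r13 <- ld_r2(panel, "v1", "v3")
  r23 <- ld_r2(panel, "v2", "v3")
  expect_gt(r12, 0.1); expect_gt(r23, 0.1); expect_lt(r13, 0.1)
  cand <- make_cand(c("v1", "v2", "v3"), c(1e-9, 1e-8, 1e-7),
                    c(1000L, 2000L, 3000L))
  out <- clump(cand, panel)
  expect_equal(out$variant_id, c("v1", "v3"))
  expect_equal(out$variant_id,
               clump_reference(cand, panel$dosages, panel$variant_meta$pos,
                               panel$variant_meta$chrom))
})

test_that("r2_max = 1 removes only perfect duplicates in window", {
  set.seed(95)
  g <- rbinom(500, 2, 0.3)
  dos <- cbind(a = g, b = g, c = rbinom(500, 2, 0.3)) * 1.0
  panel <- toy_cohort(dos, pos = c(1L, 100L, 200L))
  cand <- make_cand(c("a", "b", "c"), c(1e-8, 1e-7, 1e-6),
                    c(1L, 100L, 200L))
  out <- clump(cand, panel, r2_max = 1)
  expect_setequal(out$variant_id, c("a", "c"))
})

test_that("greedy clump matches the independent reference on random instances", {
  set.seed(96)
  for (inst in 1:60) {
    k <- sample(4:12, 1)
    n <- 150
    base <- matrix(rnorm(n * k), n, k)
    # random correlation structure: mix in a few shared factors
    fac <- matrix(rnorm(n * 2), n, 2)
    lam <- matrix(runif(k * 2, -1, 1), 2, k)
    z <- base + fac %*% lam
    dos <- (z < 0) + (matrix(rnorm(n * k), n, k) < 0)
    colnames(dos) <- sprintf("w%02d", seq_len(k))
    pos <- sort(sample.int(600000, k))
    chrom <- sample(1:2, k, replace = TRUE)
    panel <- toy_cohort(dos * 1.0, pos = pos, chrom = chrom)
    cand <- make_cand(colnames(dos), runif(k), pos, chrom = chrom)
    got <- clump(cand, panel, r2_max = 0.1, window_kb = 250)$variant_id
    want <- clump_reference(cand, panel$dosages, pos, chrom,
                            r2_max = 0.1, window_kb = 250)
    expect_identical(got, want)
    # retained pairs within the window stay below the LD ceiling
    if (length(got) > 1) {
      cm <- combn(got, 2)
      for (q in seq_len(ncol(cm))) {
        i1 <- match(cm[1, q], colnames(dos))
        i2 <- match(cm[2, q], colnames(dos))
        if (chrom[i1] == chrom[i2] && abs(pos[i1] - pos[i2]) <= 250000)
          expect_lt(ld_r2(panel, cm[1, q], cm[2, q]), 0.1)
      }
    }
  }
})

test_that("score model construction enforces threshold and nonemptiness", {
  cand <- make_cand(c("a", "b", "c"), c(1e-6, 4e-5, 2e-4),
                    c(1000L, 2000L, 3000L), beta = c(5, -2, 1))
  model <- build_grs(cand, p_threshold = 5e-5)
  expect_equal(model$entries$variant_id, c("a", "b"))
  expect_equal(model$entries$weight, c(5, -2))
  expect_equal(model$provenance$p_threshold, 5e-5)
  cand$p_meta <- rep(0.5, 3)
  expect_error(build_grs(cand), "empty score model")
  one <- make_cand("a", 1e-6, 1000L, beta = 5)
  m1 <- build_grs(one)
  expect_equal(nrow(m1$entries), 1)
  expect_equal(m1$entries$weight, 5)
})

test_that("scores reproduce hand arithmetic and the PRSice convention", {
  dos <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
                dimnames = list(c("s1", "s2", "s3"), c("va", "vb")))
  d <- toy_cohort(dos)
  model <- build_grs(make_cand(c("va", "vb"), c(1e-8, 1e-8),
                               c(1000L, 2000L), beta = c(2, -1)))
  raw <- score_samples(model, d, normalize = FALSE)
  expect_equal(as.vector(raw), c(-2, 1, 4))
  norm <- score_samples(model, d)
  expect_equal(as.vector(norm), c(-1, 0.5, 2))
  expect_equal(attr(norm, "n_variants_used"), 2)
})

test_that("scoring is invariant to allele flips in the target cohort", {
  set.seed(97)
  dos <- binom_dosages(100, c(0.3, 0.4), seed = 97) * 1.0
  d <- toy_cohort(dos)
  model <- build_grs(make_cand(c("v001", "v002"), c(1e-8, 1e-8),
                               c(1000L, 2000L), beta = c(1.5, -0.5)))
  s1 <- score_samples(model, d)
  flipped <- d
  flipped$dosages[, 1] <- 2 - flipped$dosages[, 1]
  flipped$variant_meta$effect_allele[1] <- "G"
  flipped$variant_meta$other_allele[1] <- "A"
  s2 <- score_samples(model, flipped)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("scoring is linear in the weights and imputes by frequency", {
  set.seed(98)
  dos <- binom_dosages(80, c(0.3, 0.4, 0.2), seed = 98) * 1.0
  d <- toy_cohort(dos)
  ids <- colnames(d$dosages); pos <- c(1000L, 2000L, 3000L)
  w1 <- c(1, 2, -1); w2 <- c(0.5, -1, 2)
  mk <- function(w) build_grs(make_cand(ids, rep(1e-8, 3), pos, beta = w))
  s1 <- score_samples(mk(w1), d, normalize = FALSE)
  s2 <- score_samples(mk(w2), d, normalize = FALSE)
  s12 <- score_samples(mk(w1 + w2), d, normalize = FALSE)
  expect_equal(as.vector(s12), as.vector(s1 + s2), tolerance = 1e-12)

  dmiss <- d
  dmiss$dosages[3, 1] <- NA
  f <- mean(dmiss$dosages[, 1], na.rm = TRUE) / 2
  sm <- score_samples(mk(c(1, 0.0001, 0.0001)), dmiss, normalize = FALSE)
  expect_equal(unname(sm[3]),
               2 * f * 1 + dmiss$dosages[3, 2] * 1e-4 +
                 dmiss$dosages[3, 3] * 1e-4,
               tolerance = 1e-10)
  # model variants absent from the cohort are skipped with a warning
  m4 <- build_grs(make_cand(c("v001", "ghost"), c(1e-8, 1e-8),
                            c(1000L, 9000L), beta = c(1, 1)))
  expect_warning(s4 <- score_samples(m4, d), "absent")
  expect_equal(attr(s4, "n_variants_used"), 1)
  mg <- build_grs(make_cand("ghost", 1e-8, 9000L, beta = 1))
  expect_error(score_samples(mg, d), "none of the")
})

test_that("evaluation reports incremental variance explained", {
  set.seed(99)
  n <- 600
  covs <- cbind(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5))
  y <- 0.1 * covs[, 1] + rnorm(n)
  d <- toy_cohort(binom_dosages(n, 0.3, seed = 990) * 1.0, phenotype = y,
                  age = covs[, 1], sex = covs[, 2])
  # degenerate case: the score IS the phenotype
  rep1 <- evaluate_grs(y, d, covs)
  r2cov <- summary(lm(y ~ covs))$r.squared
  expect_equal(rep1$incremental_r2, 1 - r2cov, tolerance = 1e-10)
  # independent score explains ~nothing
  inc <- replicate(20, evaluate_grs(rnorm(n), d, covs)$incremental_r2)
  expect_lt(mean(inc), 0.002)
  expect_true(all(inc >= 0))
})

test_that("binary evaluation matches glm and reports OR with CI", {
  set.seed(100)
  n <- 400
  score <- rnorm(n)
  covs <- cbind(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * score))
  d <- toy_cohort(binom_dosages(n, 0.3, seed = 100) * 1.0, phenotype = y,
                  age = covs[, 1], sex = covs[, 2])
  rep <- evaluate_grs(score, d, covs, binary = TRUE)
  ref <- glm(y ~ covs + score, family = binomial())
  cf <- summary(ref)$coefficients["score", ]
  expect_equal(rep$effect, unname(cf[1]), tolerance = 1e-8)
  expect_equal(rep$or, exp(unname(cf[1])), tolerance = 1e-8)
  expect_true(rep$ci[1] < rep$or && rep$or < rep$ci[2])
  expect_true(is.na(rep$incremental_r2))
})

test_that("score comparison is zero for identical models and favours the
           on-target score", {
  set.seed(101)
  cfg <- simulation_config(seed = 101, n_per_cohort = c(a = 800),
                           m_variants = 300, n_causal = 6,
                           h2_target = 0.25)
  d <- simulate_cohort(cfg, "a")
  ids <- d$truth$variant_id
  vm <- d$variant_meta[match(ids, d$variant_meta$variant_id), ]
  mk <- function(w) build_grs(data.frame(
    variant_id = ids, chrom = vm$chrom, pos = vm$pos,
    effect_allele = vm$effect_allele, other_allele = vm$other_allele,
    beta_meta = w, p_meta = 1e-8, stringsAsFactors = FALSE))
  covs <- make_covariates(d, k_pcs = 0)
  true_model <- mk(d$truth$beta)
  same <- compare_scores(true_model, true_model, d, covs)
  expect_equal(same$delta_incremental_r2, 0)
  # off-target: same variants, permuted weights
  off_model <- mk(sample(d$truth$beta))
  cmpr <- compare_scores(true_model, off_model, d, covs)
  expect_gt(cmpr$delta_incremental_r2, 0)
})
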