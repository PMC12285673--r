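make_stats <- function(ids, beta, se, ea = "A", oa = "G", eaf = 0.3,
                       p = NULL, n = 500) {
  m <- length(ids)
  data.frame(variant_id = ids, chrom = 1L, pos = seq_len(m) * 1000L,
             effect_allele = rep(ea, length.out = m),
             other_allele = rep(oa, length.out = m),
             eaf = rep(eaf, length.out = m), beta = beta, se = se,
             p = p %||% (2 * pnorm(-abs(beta / se))), n = n,
             stringsAsFactors = FALSE)
}

test_that("single-study meta is the identity with tau2 = 0", {
  s <- make_stats(c("a", "b"), c(0.5, -0.2), c(0.1, 0.2))
  m <- meta_analyze(list(s))
  m <- m[match(c("a", "b"), m$variant_id), ]
  expect_equal(m$beta_meta, s$beta)
  expect_equal(m$se_meta, s$se)
  expect_equal(m$tau2, c(0, 0))
  expect_equal(m$k, c(2, 2) * 0 + 1L)
  expect_equal(m$directions, c("+", "-"))
})

test_that("homogeneous two-study case pools to se/sqrt(2)", {
  s <- make_stats("a", 0.4, 0.1)
  m <- meta_analyze(list(s, s))
  expect_equal(m$beta_meta, 0.4)
  expect_equal(m$q_stat, 0)
  expect_equal(m$tau2, 0)
  expect_equal(m$se_meta, 0.1 / sqrt(2))
  expect_equal(m$directions, "++")
})

test_that("three-study toy reproduces the DerSimonian-Laird closed form", {
  studies <- lapply(c(1, 2, 3), function(b) make_stats("a", b, 0.5))
  m <- meta_analyze(studies)
  expect_equal(m$q_stat, 8.0, tolerance = 1e-12)
  expect_equal(m$tau2, 0.75, tolerance = 1e-12)
  expect_equal(m$beta_meta, 2.0, tolerance = 1e-12)
  expect_equal(m$se_meta, sqrt((0.25 + 0.75) / 3), tolerance = 1e-12)
  expect_equal(m$se_meta, 0.5774, tolerance = 1e-4)
})

test_that("meta-analysis agrees with an independent reference (metafor)", {
  skip_if_not_installed("metafor")
  set.seed(81)
  ids <- sprintf("v%02d", 1:40)
  studies <- lapply(1:3, function(j)
    make_stats(ids, rnorm(40, 0.2, 0.3), runif(40, 0.05, 0.4)))
  m <- meta_analyze(studies)
  for (v in sample(ids, 10)) {
    bi <- vapply(studies, function(s) s$beta[s$variant_id == v],
                 numeric(1))
    sei <- vapply(studies, function(s) s$se[s$variant_id == v],
                  numeric(1))
    ref <- metafor::rma(yi = bi, sei = sei, method = "DL")
    row <- m[m$variant_id == v, ]
    expect_equal(row$beta_meta, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(row$se_meta, ref$se, tolerance = 1e-8)
    expect_equal(row$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(row$q_stat, ref$QE, tolerance = 1e-8)
    expect_equal(row$p_meta, ref$pval, tolerance = 1e-8)
  }
})

test_that("pooled beta lies within the study range, invariant to order", {
  set.seed(82)
  ids <- sprintf("v%02d", 1:30)
  studies <- lapply(1:4, function(j)
    make_stats(ids, rnorm(30), runif(30, 0.1, 0.5)))
  m1 <- meta_analyze(studies)
  m2 <- meta_analyze(rev(studies))
  m2 <- m2[match(m1$variant_id, m2$variant_id), ]
  expect_equal(m1$beta_meta, m2$beta_meta, tolerance = 1e-12)
  expect_equal(m1$tau2, m2$tau2, tolerance = 1e-12)
  B <- sapply(studies, `[[`, "beta")
  i <- match(ids, m1$variant_id)
  expect_true(all(m1$beta_meta[i] >= apply(B, 1, min) - 1e-12))
  expect_true(all(m1$beta_meta[i] <= apply(B, 1, max) + 1e-12))
})

test_that("identical studies pool to the common beta for any k", {
  s <- make_stats("a", 0.7, 0.2)
  for (k in c(2, 3, 5)) {
    m <- meta_analyze(rep(list(s), k))
    expect_equal(m$beta_meta, 0.7)
    expect_equal(m$tau2, 0)
    expect_equal(m$k, k)
  }
})

test_that("meta rejects non-positive standard errors", {
  s <- make_stats("a", 0.5, 0)
  expect_error(meta_analyze(list(s)), "positive")
})

test_that("allele harmonization flips, passes, and drops correctly", {
  ref <- make_stats(c("a", "b", "c"), c(0.1, 0.2, 0.3), 0.1)
  oth <- make_stats(c("a", "b", "c"), c(0.4, 0.5, 0.6), 0.1)
  # a: aligned; b: swapped alleles; c: incompatible pair
  oth$effect_allele[2] <- "G"; oth$other_allele[2] <- "A"
  oth$effect_allele[3] <- "C"; oth$other_allele[3] <- "T"
  expect_warning(h <- harmonize_alleles(ref, oth), "dropped")
  expect_equal(nrow(h), 2)
  expect_equal(h$beta[h$variant_id == "a"], 0.4)
  expect_equal(h$beta[h$variant_id == "b"], -0.5)
  expect_equal(h$eaf[h$variant_id == "b"], 0.7)
  expect_equal(attr(h, "n_dropped"), 1)
  # already-aligned input passes through untouched
  h2 <- harmonize_alleles(ref, make_stats("a", 0.4, 0.1))
  expect_equal(h2$beta, 0.4)
})

test_that("candidate selection applies a strict threshold", {
  s <- make_stats(c("a", "b", "c"), c(1, 1, 1), c(0.1, 0.1, 0.1))
  m <- meta_analyze(list(s))
  m$p_meta <- c(0.5, 5e-5, 4.9e-5)
  cand <- select_candidates(m, 5e-5)
  expect_equal(cand$variant_id, m$variant_id[m$p_meta < 5e-5])
  m$p_meta <- rep(0.5, 3)
  expect_equal(nrow(select_candidates(m, 5e-5)), 0)
})

test_that("refinement applies the two-clause replication rule", {
  cand <- data.frame(variant_id = c("a", "b", "c", "d"),
                     beta_meta = c(1, 1, -1, 1))
  rep_stats <- make_stats(c("a", "b", "c"), c(0.3, 0.3, 0.5), 0.2,
                          p = c(0.05, 0.2, 0.01))
  dec <- refine_candidates(cand, rep_stats, p_max = 0.2)
  expect_equal(dec$reason,
               c("pass", "p_fail", "sign_fail", "missing_in_replication"))
  expect_equal(dec$retained, c(TRUE, FALSE, FALSE, FALSE))
  # decisions partition the candidates
  expect_equal(nrow(dec), nrow(cand))
  expect_equal(sum(table(dec$reason)), nrow(cand))
})

test_that("null replication retains candidates at the analytic 10% rate", {
  set.seed(83)
  n_var <- 12000
  ids <- sprintf("v%05d", seq_len(n_var))
  cand <- data.frame(variant_id = ids,
                     beta_meta = sample(c(-1, 1), n_var, TRUE))
  b <- rnorm(n_var)                    # null replication effects
  rep_stats <- make_stats(ids, b, 1)   # p two-sided from the same draw
  dec <- refine_candidates(cand, rep_stats, p_max = 0.2)
  # P(retained) = P(p < 0.2) * P(sign agrees) = 0.2 * 0.5
  expect_lt(abs(mean(dec$retained) - 0.10), 0.01)
})

test_that("refinement enriches true positives in a mixed candidate pool", {
  set.seed(84)
  n_true <- 40; n_false <- 160
  ids <- sprintf("v%03d", seq_len(n_true + n_false))
  truth <- c(rep(TRUE, n_true), rep(FALSE, n_false))
  beta_true <- rnorm(n_true, 1.2, 0.1) * sample(c(-1, 1), n_true, TRUE)
  cand <- data.frame(variant_id = ids,
                     beta_meta = c(beta_true, sample(c(-1, 1), n_false,
                                                     TRUE)))
  gain <- replicate(20, {
    rep_b <- rnorm(n_true + n_false,
                   mean = ifelse(truth, cand$beta_meta * 0.4, 0), sd = 0.3)
    rep_stats <- make_stats(ids, rep_b, 0.3)
    dec <- refine_candidates(cand, rep_stats)
    mean(truth[dec$retained]) - mean(truth)
  })
  expect_gt(mean(gain), 0)
})
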