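# Independent reference implementations used as test oracles. Each is a
# deliberately different computational route from the package code it
# checks (closed forms, enumeration, generic optimizers).

# Hardy-Weinberg exact p by full enumeration over all heterozygote counts
# compatible with the observed allele totals, using log-factorial
# multinomial probabilities (the package uses a ratio recurrence).
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  N <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nr <- min(nA, 2 * N - nA)
  hs <- seq.int(nr %% 2L, nr, by = 2L)
  logu <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- N - aa - h
    if (aa < 0 || bb < 0) return(-Inf)
    -lfactorial(aa) - lfactorial(h) - lfactorial(bb) + h * log(2)
  }, numeric(1))
  p <- exp(logu - max(logu))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hs)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Per-variant OLS via explicit pseudoinverse normal equations.
ols_pinv_oracle <- function(y, g, covs = NULL) {
  X <- cbind(1, covs, g)
  XtXi <- solve(crossprod(X))
  b <- XtXi %*% crossprod(X, y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  sig2 <- sum(res^2) / df
  k <- ncol(X)
  se <- sqrt(sig2 * XtXi[k, k])
  tval <- b[k] / se
  list(beta = b[k], se = se, p = 2 * pt(-abs(tval), df))
}

# Logistic ML by generic quasi-Newton optimization of the binomial
# log-likelihood with analytic gradient.
logistic_optim_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  nll <- function(b) {
    eta <- drop(X1 %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  grad <- function(b) {
    mu <- 1 / (1 + exp(-drop(X1 %*% b)))
    drop(crossprod(X1, mu - y))
  }
  fit <- optim(rep(0, ncol(X1)), nll, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  fit$par
}

# Greedy clumping reference: plain data-frame loop, r2 via stats::cor on
# complete observations, recomputed from scratch for every pair.
clump_reference <- function(candidates, dosages, positions, chroms,
                            r2_max = 0.1, window_kb = 250) {
  pcol <- if ("p_meta" %in% names(candidates)) "p_meta" else "p"
  df <- candidates[order(candidates[[pcol]], candidates$pos,
                         candidates$variant_id), ]
  kept <- character(0)
  removed <- character(0)
  for (i in seq_len(nrow(df))) {
    vid <- df$variant_id[i]
    if (vid %in% removed) next
    kept <- c(kept, vid)
    for (j in seq_len(nrow(df))) {
      wid <- df$variant_id[j]
      if (wid == vid || wid %in% removed || wid %in% kept) next
      if (df$chrom[j] != df$chrom[i]) next
      if (abs(df$pos[j] - df$pos[i]) > window_kb * 1000) next
      x <- dosages[, vid]; z <- dosages[, wid]
      use <- complete.cases(x, z)
      if (cor(x[use], z[use])^2 >= r2_max) removed <- c(removed, wid)
    }
  }
  kept
}

# Minimal cohort constructor for hand fixtures.
toy_cohort <- function(dosages, phenotype = NULL, age = NULL, sex = NULL,
                       chrom = NULL, pos = NULL, effect = NULL,
                       other = NULL, name = "toy") {
  n <- nrow(dosages); m <- ncol(dosages)
  vm <- data.frame(
    variant_id = colnames(dosages) %||% sprintf("v%03d", seq_len(m)),
    chrom = chrom %||% rep(1L, m),
    pos = pos %||% (seq_len(m) * 1000L),
    effect_allele = effect %||% rep("A", m),
    other_allele = other %||% rep("G", m),
    stringsAsFactors = FALSE)
  sm <- data.frame(
    sample_id = rownames(dosages) %||% sprintf("s%03d", seq_len(n)),
    phenotype = phenotype %||% rep(NA_real_, n),
    age = age %||% rep(70, n),
    sex = sex %||% rep(0L, n),
    stringsAsFactors = FALSE)
  colnames(dosages) <- vm$variant_id
  rownames(dosages) <- sm$sample_id
  cohort_dataset(name, dosages, vm, sm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simple independent binomial genotype draw (no LD), for fixtures where
# the package generator itself is under test elsewhere.
binom_dosages <- function(n, freqs, seed = 1) {
  set.seed(seed)
  m <- length(freqs)
  matrix(rbinom(n * m, 2, rep(freqs, each = n)), n, m)
}
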