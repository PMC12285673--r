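---
title: "Methods: building and validating a non-APOE amyloid genetic risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating a non-APOE amyloid genetic risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Brain β-amyloid accumulation is a quantitative endophenotype of
Alzheimer's disease that can be measured in vivo (amyloid PET, on the
Centiloid scale), postmortem (immunohistochemical percent-area burden),
and indirectly through blood biomarkers (plasma p-tau181). In *APOE*
ε3/ε3 individuals — who carry neither the main risk nor the main
protective *APOE* allele — amyloid burden still varies substantially,
and a score aggregating many small non-*APOE* genetic effects may
stratify that risk. `amygrs` implements a four-phase procedure for
constructing and validating such a score from multi-cohort data:

1. **Discovery.** Per-cohort GWAS of the quantitative amyloid phenotype
   (additive model, covariate-adjusted), pooled by random-effects
   inverse-variance meta-analysis; variants with pooled `p < 5e-5` form
   the candidate set.
2. **Refinement.** Candidates are re-tested in an independent cohort
   with postmortem amyloid measurements; candidates with replication
   `p >= 0.2` or a discordant direction of effect are excluded.
3. **Score construction.** Clumping and thresholding (C+T): greedy LD
   clumping collapses each group of correlated candidates
   (`r^2 >= 0.1` within 250 kb) to its top variant, and surviving
   variants enter the score weighted by their meta-analysis beta.
4. **Validation.** The score is tested against held-out outcomes:
   amyloid PET (incremental variance explained beyond covariates),
   postmortem amyloid and tangle burden, the binary high-Braak-stage
   outcome (logistic regression, odds ratio), and a plasma biomarker in
   a cohort disjoint from discovery.

Because the cohorts this design targets are access-restricted, the
package ships a synthetic-cohort generator that reproduces the
*statistical structure* the pipeline relies on; every stage is tested
against that generator and against independent numerical oracles.

## Models and estimators

### Per-variant association

For variant $j$ with effect-allele dosage $g_{ij} \in [0,2]$ the
discovery model is ordinary least squares

$$y_i = \alpha + \beta_j g_{ij} + \gamma^T c_i + \varepsilon_i,$$

with covariates $c_i$ = age, sex, and the first 5 genetic principal
components. Two-sided p-values use the $t$ distribution with residual
degrees of freedom. Computationally, variants with complete dosages are
processed in one vectorized pass: phenotype and dosages are residualized
against the covariate design, which is algebraically identical to the
full multiple regression (asserted against a per-variant pseudoinverse
oracle to 1e-8 in the tests). Variants with missing calls fall back to
per-variant complete-case fits, so one variant's missingness never
affects another (the behaviour of standard GWAS tools). Binary outcomes
use maximum-likelihood logistic regression (IRLS via `stats::glm.fit`)
with Wald standard errors; separation and non-convergence are flagged
per variant and such variants carry no estimate.

Principal components are computed from the standardized dosage matrix
(mean-imputed for this computation only), by eigendecomposition of the
smaller Gram matrix, on a deterministic random subset of at most 5,000
variants (the standard practice of computing ancestry PCs on a pruned
subset; exposed as `pc_max_variants`). A fixed sign convention (largest
loading positive) keeps runs comparable.

### Meta-analysis

DerSimonian–Laird random effects. With fixed-effect weights
$w_i = 1/se_i^2$:

$$Q = \sum_i w_i(\beta_i - \bar\beta_{FE})^2, \qquad
\tau^2 = \max\!\left(0, \frac{Q - (k-1)}
{\sum w_i - \sum w_i^2 / \sum w_i}\right),$$

then $w_i^* = 1/(se_i^2 + \tau^2)$, pooled
$\beta = \sum w_i^* \beta_i / \sum w_i^*$,
$se = 1/\sqrt{\sum w_i^*}$, and a two-sided normal p-value. The
three-study toy case $(\beta, se) = (1, 0.5), (2, 0.5), (3, 0.5)$ gives
$Q = 8$, $\tau^2 = 0.75$, $\beta = 2$, $se \approx 0.5774$ exactly, and
the implementation is cross-checked against `metafor::rma(method =
"DL")`. DL was chosen because it is the default in the standard GWAS
meta-analysis tools; a fixed-effect mode is exposed for comparison. One
property worth knowing: with only $k = 2$ discovery cohorts the
$\tau^2$ estimate is very noisy, and chance heterogeneity between the
two cohort betas inflates the pooled standard error — random-effects
pooling at $k = 2$ therefore has visibly less power than fixed-effect
pooling. This cost is inherent to the prescribed design and shows up in
the end-to-end recovery experiments as occasional loss of a truly
causal block.

Variants present in a single cohort are retained with $k = 1$ (their
cohort statistics pass through; $\tau^2 = 0$) rather than silently
dropped, since dropping would shrink the candidate pool invisibly.
Effect alleles are harmonized before pooling: rows whose allele pair is
swapped relative to the reference are flipped
($\beta \to -\beta$, $f \to 1-f$), incompatible pairs are dropped with
a warning. Both suggestive-candidate selection (`p < 5e-5`) and the
refinement rule (`p < 0.2` with concordant sign) use strict
inequalities: the refinement rule is an exclusion at `p >= 0.2`, so the
retention side is strict.

### Quality control

Variant filters, applied in a fixed documented order (call rate →
Hardy–Weinberg → MAF) with each failure attributed to the first filter:
call rate < 95%; HWE exact p < 1e-5; minor allele frequency below the
5% analysis floor (the separate 1% raw-array floor is kept as a
configuration field). The HWE test is the exact conditional
(Levene–Haldane) test: the two-sided p-value is the total probability
of heterozygote counts no more probable than the observed one, given
the allele totals. Probabilities come from the heterozygote-count ratio
recurrence accumulated in log space (overflow-safe for any sample
size), with tail sums via sorted cumulative sums; tables sharing an
(N, allele count) key are computed once, so whole-array vectors are
cheap. A relative tie tolerance of 1e-12 decides "no more probable
than", and the tests require agreement with a full log-factorial
enumeration oracle to 1e-12 for every table with N ≤ 200.

Sample filters: call rate < 98%, then a relatedness screen. Pairwise
PI_HAT = P(IBD=1)/2 + P(IBD=2) is estimated by the method of moments
from identity-by-state counts with allele frequencies taken from the
full sample, clamped to [0,1]. For each pair at or above PI_HAT 0.25
the member with the lower call rate is dropped (ties: the later sample
in table order; which member of a related pair to drop is a convention,
and this is ours). The all-pairs screen runs on a
deterministic subset of at most `ibd_variants` polymorphic variants via
indicator cross-products; missing entries contribute to no IBS state
and counts are rescaled by the per-pair shared-call fraction, which is
unbiased under missingness completely at random. With fewer than about
1,000 variants the estimator is noisy enough that unrelated pairs can
cross 0.25 by chance, so the screen warns below that count. No LD
pruning is applied before relatedness estimation; at the simulated
scales this simplification is adequate.

Fractional dosages are rounded to hard calls for HWE and IBS only;
association testing keeps fractional values.

### Score construction and evaluation

Clumping is greedy: take the remaining candidate with the smallest
p-value (ties broken toward the smaller genomic position, then
lexicographic id), remove every remaining candidate on the same
chromosome within 250 kb with $r^2 \ge 0.1$ against it, repeat. $r^2$
is the squared Pearson correlation of dosages over complete pairs in
the pooled discovery genotypes (which sample a C+T workflow should use
for LD is a genuine design choice; pooling discovery is ours and is
config-exposed). The 250 kb window is the common C+T default; only the
$r^2$ cutoff is prescribed. Greedy output is verified against an
independent reference implementation on hundreds of random instances.

The score is $s_i = \sum_j w_j g_{ij}$ over model variants present in
the target cohort, after allele harmonization, divided by the number of
variants used (the average-per-variant convention of common scoring
tools; `normalize = FALSE` gives the raw sum — the choice affects scale
only, not p-values). Missing dosages are imputed as twice the *scoring*
cohort's allele frequency, deliberately not the discovery frequency, to
avoid leaking discovery information into validation.

Evaluation regresses the outcome on covariates plus the score:
quantitative outcomes report the score beta and the incremental
variance explained $\Delta R^2 = R^2(\text{covariates + score}) -
R^2(\text{covariates})$ (we define it explicitly as this difference;
"variance explained" is ambiguous across scoring tools); binary
outcomes report the odds ratio with a Wald 95% CI and deliberately no
pseudo-$R^2$ (the choice of pseudo-$R^2$ is not standardized). An
external weight file can be scored through the same machinery for
comparator benchmarking.

## The synthetic-cohort generator

`simulation_config()` defines a genetic architecture shared by all
cohorts drawn from it; `simulate_genotypes()` and
`simulate_phenotypes()` draw cohorts from that architecture.

**Genotypes.** Haplotype alleles are threshold indicators of latent
Gaussians: within an LD block the latents follow an AR(1) process with
adjacent correlation `ld_rho`; two independent haplotypes per person
are summed to a dosage. This preserves Hardy–Weinberg equilibrium
within strata by construction, gives a controllable LD decay
($\rho^d$ on the latent scale, attenuated by thresholding on the
genotype scale — the package provides the bivariate-normal integrator
`expected_adjacent_r2()` as the closed-form check), and keeps blocks
exactly independent. Blocks are laid out one per megabase (5 kb spacing
within a block, cycled over 22 autosomes) so that same-block pairs
always fall inside a 250 kb clumping window and different blocks never
do. Population structure is Balding–Nichols: per-stratum allele
frequencies are Beta draws around the base frequency with
differentiation `fst`, and optional per-stratum phenotype offsets
(`stratum_pheno_sd`) create genuine confounding that the PC covariates
must absorb. Missingness is injected completely at random — the source
procedure says nothing about informative missingness, so we model
none.

**Phenotypes.** On a standardized latent scale,

$$y = a \sum_j \beta_j (g_j - 2f_j) + \beta_{age}(age - 75) +
\beta_{sex}(sex - 0.5) + \text{stratum offset} + \varepsilon,$$

where $a$ is the cohort's modality attenuation. Causal variants are
placed one per LD block (at most), with equal per-variant variance
contributions `h2_target / n_causal` and random signs; placement
requires base frequency ≥ 0.08, comfortably above the 5% analysis
floor, so planted signal survives variant QC by construction rather
than by luck in the realized allele counts. The noise variance is set
so the causal fraction of latent variance equals `h2_target` exactly in
an unattenuated cohort; genetic and covariate contributions enter
centred so the latent trait is mean-zero and threshold quantiles are
meaningful. The latent value is mapped to modality units by fixed
affine transforms (Centiloid-like mean 35/SD 30; percent-area-like mean
4/SD 3; pg/mL-like mean 2.3/SD 1.6 — chosen to resemble published
cohort descriptive statistics; affine maps change no $R^2$ or p-value).
The neuropathology modality adds a tangle trait sharing the causal
basis (further attenuated by `tangle_attenuation`) and the binary
high-Braak indicator, a threshold at the `braak_threshold` quantile of
the tangle latent. `planted_variance_fraction()` performs the variance
bookkeeping on the generator's own draws and is the ground truth for
recovery experiments.

**What the generator does not emulate.** Imputation uncertainty and
imputation-quality filtering (data are generated as already-imputed
hard calls), strand flips and multi-allelic sites, X-chromosome dosage,
rare variants, linkage between blocks, informative missingness,
realistic minor-allele-frequency spectra, and *APOE* itself (all
analyses model the ε3/ε3 stratum only). Passing tests therefore
demonstrate correctness of the estimators and of the pipeline's
plumbing under the stated statistical structure — not robustness to
everything real array data can contain.

## Default parameters

| Parameter | Default | Meaning |
|---|---|---|
| `variant_call_rate_min` | 0.95 | variant call-rate floor |
| `hwe_p_min` | 1e-5 | HWE exact-test floor |
| `maf_min_analysis` | 0.05 | analysis MAF floor |
| `sample_call_rate_min` | 0.98 | sample call-rate floor |
| `pi_hat_max` | 0.25 | relatedness ceiling |
| `k_pcs` | 5 | genetic PCs as covariates |
| `candidate_p` | 5e-5 | suggestive entry threshold |
| `refine_p` | 0.2 | replication p ceiling |
| `clump_r2` | 0.1 | LD ceiling for clumping |
| `clump_window_kb` | 250 | clumping window |
| `ld_rho` | 0.7 | latent adjacent-variant correlation |
| `ld_block_size` | 10 | variants per LD block |
| `fst` | 0.01 | Balding–Nichols differentiation |
| `braak_threshold` | 0.7 | latent quantile for high Braak |

The bundled `paper_scale` study (in `demo_sim_config()`) uses cohort
sizes 983 + 513 discovery, 710 neuropathology, 641 plasma validation
and m = 20,000 variants, with 8 causal blocks at 2.5% of discovery
variance each (h2 = 0.20), attenuation 0.8 (neuropathology) and 0.6
(plasma), and three ancestry strata at fst = 0.005. The per-block 2.5%
was fixed by an a-priori power computation: at meta-analysis n = 1,496
the per-block non-centrality gives ≈ 98% power at `p < 5e-5`, and at
n = 710 with attenuation 0.8 the refinement clause passes with ≈ 99%
probability, so the pipeline is expected to capture most (not all)
planted blocks — k = 2 random-effects pooling, realized-frequency
variation, and clumping ties account for the remainder.

## Numerical and experimental choices

* **Degenerate inputs.** Monomorphic variants are skipped in GWAS with
  a warning and excluded from PCs; all-zero genotype tables are an
  error in the HWE test; empty score models abort construction with a
  diagnostic of where candidates were lost; one-class binary outcomes
  are an error.
* **Determinism.** All randomness in the generator derives from the
  config seed (cohort-specific streams are derived deterministically);
  internal subsampling (PC and IBD variant subsets) uses fixed derived
  seeds; clumping tie-breaks are total-ordered. Identical configs give
  bit-identical datasets and reports.
* **Calibration experiments.** The null-calibration checks (type-I
  error 0.05 ± 0.01, genomic λ 1.00 ± 0.02) are run on LD-free null
  variants, pooling three replicate 20,000-variant GWAS for λ: the
  median-based λ estimator has Monte-Carlo SE ≈ 0.03 on 20,000
  LD-correlated tests, which no correct implementation could reliably
  bring inside ±0.02, whereas 60,000 independent tests give SE ≈ 0.01.
  The stratified-confounding check keeps LD.
* **Null leakage experiment.** Under a strictly null architecture at
  the production thresholds the expected candidate count is ≈ 1 per
  20,000 variants and the final model is almost always empty, leaving
  nothing to validate. The leakage test therefore relaxes the
  config-exposed thresholds (`candidate_p = 0.01`, `refine_p = 0.5`) so
  null models exist; validation p-values are uniform exactly when no
  information flows between phases, which is the property under test.
* **Problem sizes in the test-suite.** Oracle-equivalence tests run at
  n = 120–200 with hundreds of replicates; calibration at n = 800,
  m = 20,000; end-to-end recovery at the paper-scale sizes above over
  10 seeds; the leakage experiment at n = 250–300, m = 1,200 over 40
  seeds. These sizes were chosen so each experiment's Monte-Carlo error
  is small relative to the tolerance it asserts.

## Known limitations

* PI_HAT uses no small-sample bias correction and no LD pruning; with
  few variants it is noisy (the package warns). It is a screening
  statistic here, not a pedigree estimator.
* Random-effects pooling with two cohorts is inefficient (see above);
  with k = 2 a fixed-effect sensitivity analysis (`method = "FE"`) is
  advisable.
* The binary high-Braak analysis reports odds ratios only; no
  variance-explained analogue is attempted.
* The generator's equal-contribution causal architecture is a
  convenience, not an estimate of any real trait's architecture;
  recovery rates under realistic effect-size distributions will differ.
* Clumping recomputes pairwise r² on demand; for candidate sets orders
  of magnitude larger than the suggestive sets this produces, a
  windowed precomputation would be preferable.
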