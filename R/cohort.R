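#' Cohort dataset container
#'
#' Bundles a genotype dosage matrix with per-variant metadata and a
#' per-sample phenotype/covariate table for one cohort and measurement
#' modality. This is the unit of data every pipeline stage consumes and
#' returns.
#'
#' @param cohort_name Single string naming the cohort.
#' @param dosages Numeric matrix, samples x variants; entries are
#'   effect-allele dosages in \[0, 2\] or `NA` for missing. Row names are
#'   sample ids, column names variant ids.
#' @param variant_meta Data frame with one row per variant and columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`.
#' @param samples Data frame with one row per sample: `sample_id`,
#'   `phenotype` (quantitative outcome; may be `NA` for genotype-only
#'   datasets), `age` (years), `sex` (0/1), and optionally further
#'   outcome columns (e.g. `braak_high`, `tangle_density`) or the
#'   simulation column `stratum`.
#' @param truth Optional data frame (`variant_id`, `beta`) of true causal
#'   effects on this cohort's phenotype scale; simulation bookkeeping only.
#' @param modality Single string describing what the phenotype measures
#'   (e.g. `"centiloid"`, `"neuropath"`, `"plasma"`), or `NA`.
#'
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(cohort_name, dosages, variant_meta, samples,
                           truth = NULL, modality = NA_character_) {
  stopifnot(is.character(cohort_name), length(cohort_name) == 1L)
  if (!is.matrix(dosages) || !is.numeric(dosages))
    stop("'dosages' must be a numeric matrix (samples x variants)")
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosage entries must lie in [0, 2] or be NA")
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele")
  miss <- setdiff(req, names(variant_meta))
  if (length(miss))
    stop("variant_meta lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(variant_meta) != ncol(dosages))
    stop("variant_meta rows (", nrow(variant_meta),
         ") != dosage columns (", ncol(dosages), ")")
  if (anyDuplicated(variant_meta$variant_id))
    stop("duplicate variant ids in variant_meta")
  if (any(variant_meta$effect_allele == variant_meta$other_allele))
    stop("effect_allele must differ from other_allele for every variant")
  reqs <- c("sample_id", "phenotype", "age", "sex")
  miss <- setdiff(reqs, names(samples))
  if (length(miss))
    stop("samples table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(samples) != nrow(dosages))
    stop("samples rows (", nrow(samples),
         ") != dosage rows (", nrow(dosages), ")")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids")
  dimnames(dosages) <- list(samples$sample_id, variant_meta$variant_id)
  structure(
    list(cohort_name = cohort_name,
         dosages = dosages,
         variant_meta = as.data.frame(variant_meta),
         samples = as.data.frame(samples),
         truth = if (is.null(truth)) NULL else as.data.frame(truth),
         modality = modality),
    class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "<cohort_dataset '%s'> %d samples x %d variants (modality: %s)\n",
    x$cohort_name, nrow(x$dosages), ncol(x$dosages), x$modality))
  nmiss <- sum(is.na(x$dosages))
  cat(sprintf("  missing dosages: %d (%.3f%%)\n",
              nmiss, 100 * nmiss / length(x$dosages)))
  if (!is.null(x$truth))
    cat(sprintf("  planted causal variants: %d\n", nrow(x$truth)))
  invisible(x)
}

#' Number of samples / variants in a cohort dataset
#' @param data A `cohort_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(data) nrow(data$dosages)

#' @rdname n_samples
#' @export
n_variants <- function(data) ncol(data$dosages)

#' Subset a cohort dataset
#'
#' @param data A `cohort_dataset`.
#' @param samples Optional sample ids or logical/integer index over rows.
#' @param variants Optional variant ids or logical/integer index over columns.
#' @return A `cohort_dataset` restricted to the requested rows/columns.
#' @export
subset_cohort <- function(data, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(data$dosages)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(data$dosages)) else variants
  if (is.character(si)) si <- match(si, rownames(data$dosages))
  if (is.character(vi)) vi <- match(vi, colnames(data$dosages))
  if (anyNA(si)) stop("unknown sample id in subset")
  if (anyNA(vi)) stop("unknown variant id in subset")
  dos <- data$dosages[si, vi, drop = FALSE]
  vm <- data$variant_meta[vi, , drop = FALSE]
  sm <- data$samples[si, , drop = FALSE]
  tr <- data$truth
  if (!is.null(tr)) tr <- tr[tr$variant_id %in% vm$variant_id, , drop = FALSE]
  cohort_dataset(data$cohort_name, dos, vm, sm, truth = tr,
                 modality = data$modality)
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# global RNG stream is untouched.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
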