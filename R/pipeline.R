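#' Pipeline configuration
#'
#' Single structured configuration driving the four analysis phases:
#' cohort roles, QC thresholds, covariate specification, and the
#' selection / refinement / clumping thresholds. Cohorts are referred to
#' by name; genotype/phenotype file locations are optional (datasets may
#' equally be passed to [run_pipeline()] in memory).
#'
#' @param discovery Character vector (>= 1) of discovery cohort names
#'   (quantitative amyloid-PET-like phenotype; these are GWASed and
#'   meta-analyzed).
#' @param refinement Single cohort name with independent neuropathology
#'   phenotype used to refine the candidate list (`NULL` to skip
#'   refinement).
#' @param validation Character vector (possibly empty) of held-out
#'   validation cohort names.
#' @param qc A [qc_thresholds()].
#' @param k_pcs Number of genetic principal components used as
#'   covariates (default 5).
#' @param candidate_p Suggestive threshold for candidate entry
#'   (default 5e-5).
#' @param refine_p Replication p ceiling in the refinement cohort
#'   (default 0.2).
#' @param clump_r2 LD ceiling for clumping (default 0.1).
#' @param clump_window_kb Clumping window (default 250 kb).
#' @param score_normalize Average-per-variant score convention
#'   (default `TRUE`).
#' @param relatedness Run the PI_HAT sample screen (default `TRUE`).
#' @param ibd_variants Variant subset size for the relatedness screen.
#' @param pc_max_variants Variant subset size for PC computation.
#' @param comparator_weights Optional path to an external score weight
#'   file benchmarked against the fitted score.
#' @param files Optional named list: cohort name -> list(`genotypes`,
#'   `phenotypes`, `format`).
#' @param seed Integer seed echoed into the run report.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(discovery,
                            refinement = NULL,
                            validation = character(0),
                            qc = qc_thresholds(),
                            k_pcs = 5L,
                            candidate_p = 5e-5,
                            refine_p = 0.2,
                            clump_r2 = 0.1,
                            clump_window_kb = 250,
                            score_normalize = TRUE,
                            relatedness = TRUE,
                            ibd_variants = 2000L,
                            pc_max_variants = 5000L,
                            comparator_weights = NULL,
                            files = NULL,
                            seed = 1L) {
  if (length(discovery) < 1L) stop("need at least one discovery cohort")
  if (!is.null(refinement) && length(refinement) != 1L)
    stop("'refinement' must be a single cohort name or NULL")
  roles <- c(discovery, refinement, validation)
  if (anyDuplicated(roles))
    stop("a cohort may hold only one role; duplicated: ",
         paste(unique(roles[duplicated(roles)]), collapse = ", "))
  structure(list(discovery = discovery, refinement = refinement,
                 validation = validation, qc = qc, k_pcs = as.integer(k_pcs),
                 candidate_p = candidate_p, refine_p = refine_p,
                 clump_r2 = clump_r2, clump_window_kb = clump_window_kb,
                 score_normalize = score_normalize,
                 relatedness = relatedness,
                 ibd_variants = as.integer(ibd_variants),
                 pc_max_variants = pc_max_variants,
                 comparator_weights = comparator_weights,
                 files = files, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` the path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$qc <- unclass(x$qc)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- yaml::read_yaml(path)
  qc <- do.call(qc_thresholds, x$qc)
  x$qc <- NULL
  x$validation <- as.character(x$validation %||% character(0))
  do.call(pipeline_config, c(x, list(qc = qc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the four-phase score construction and validation pipeline
#'
#' Executes, in order: per-cohort variant and sample QC; per-discovery-
#' cohort GWAS (age, sex and `k_pcs` genetic PCs as covariates) with
#' genomic-inflation lambda; random-effects meta-analysis and suggestive
#' candidate selection; refinement of candidates in the independent
#' neuropathology cohort (replication p and direction filter); greedy LD
#' clumping on the pooled discovery panel; thresholded score
#' construction weighted by the meta-analysis betas; scoring and
#' association testing in every cohort (quantitative outcomes: beta and
#' incremental R-squared; binary outcomes: odds ratio with 95% CI), plus
#' optional benchmarking against an external comparator score.
#'
#' Any phase-level error aborts the run with the phase name; the
#' condition carries the phases completed so far in
#' `attr(, "partial_report")`.
#'
#' @param config A [pipeline_config()].
#' @param datasets Named list of [cohort_dataset()] objects covering
#'   every configured cohort; if `NULL`, cohorts are read from
#'   `config$files`.
#' @return An object of class `run_report`.
#' @export
run_pipeline <- function(config, datasets = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = config, seed = config$seed,
                 version = as.character(utils::packageVersion("amygrs")),
                 counts = list(), lambda = list(), qc_reports = list(),
                 associations = list())
  phase <- "load"
  run_phase <- function(name, code) {
    phase <<- name
    tryCatch(code, error = function(e) {
      cond <- simpleError(sprintf("pipeline aborted in phase '%s': %s",
                                  name, conditionMessage(e)))
      attr(cond, "partial_report") <- report
      stop(cond)
    })
  }

  datasets <- run_phase("load", {
    if (is.null(datasets)) {
      if (is.null(config$files))
        stop("no datasets given and config carries no file locations")
      lapply(config$files, function(f)
        read_cohort(f$genotypes, f$phenotypes,
                    format = f$format %||% "traw"))
    } else datasets
  })
  run_phase("load", {
    need <- c(config$discovery, config$refinement, config$validation)
    miss <- setdiff(need, names(datasets))
    if (length(miss))
      stop("missing dataset(s): ", paste(miss, collapse = ", "))
    disc_ids <- unlist(lapply(datasets[config$discovery],
                              function(d) d$samples$sample_id))
    for (cn in c(config$refinement, config$validation)) {
      overlap <- intersect(disc_ids, datasets[[cn]]$samples$sample_id)
      if (length(overlap))
        stop("cohort '", cn, "' shares ", length(overlap),
             " sample id(s) with the discovery set; refusing to run")
    }
    invisible(NULL)
  })

  used <- c(config$discovery, config$refinement, config$validation)
  datasets <- datasets[used]
  datasets <- run_phase("qc", {
    out <- list()
    for (cn in used) {
      v <- apply_variant_qc(datasets[[cn]], config$qc)
      s <- apply_sample_qc(v$data, config$qc,
                           relatedness = config$relatedness,
                           ibd_variants = config$ibd_variants)
      report$qc_reports[[cn]] <- list(variant = v$report,
                                       sample = s$report)
      report$counts$variants_after_qc[[cn]] <- n_variants(s$data)
      report$counts$samples_after_qc[[cn]] <- n_samples(s$data)
      out[[cn]] <- s$data
    }
    out
  })

  covs <- run_phase("pcs", {
    lapply(datasets, function(d)
      make_covariates(d, pcs = compute_pcs(
        d, k = config$k_pcs, max_variants = config$pc_max_variants),
        k_pcs = config$k_pcs))
  })

  disc_stats <- run_phase("gwas", {
    out <- list()
    for (cn in config$discovery) {
      st <- gwas_linear(datasets[[cn]], covs[[cn]])
      report$lambda[[cn]] <- genomic_lambda(st)
      out[[cn]] <- st
    }
    out
  })

  meta <- run_phase("meta", {
    if (length(disc_stats) > 1L)
      for (j in 2:length(disc_stats))
        disc_stats[[j]] <- harmonize_alleles(disc_stats[[1]],
                                             disc_stats[[j]])
    meta_analyze(disc_stats)
  })
  report$meta <- meta

  candidates <- run_phase("candidates", {
    cand <- select_candidates(meta, config$candidate_p)
    report$counts$candidates <- nrow(cand)
    cand
  })

  kept <- candidates
  if (!is.null(config$refinement) && nrow(candidates)) {
    kept <- run_phase("refinement", {
      rcoh <- datasets[[config$refinement]]
      have <- intersect(candidates$variant_id,
                        rcoh$variant_meta$variant_id)
      rep_stats <- if (length(have)) {
        sub <- subset_cohort(rcoh, variants = have)
        gwas_linear(sub, covs[[config$refinement]])
      } else candidates[0, ]
      if (nrow(rep_stats))
        rep_stats <- harmonize_alleles(candidates, rep_stats)
      decisions <- refine_candidates(candidates, rep_stats,
                                     p_max = config$refine_p)
      report$refinement_decisions <- decisions
      out <- candidates[candidates$variant_id %in%
                          decisions$variant_id[decisions$retained], ,
                        drop = FALSE]
      report$counts$post_refinement <- nrow(out)
      out
    })
  } else {
    report$counts$post_refinement <- nrow(kept)
  }

  clumped <- run_phase("clump", {
    if (!nrow(kept)) {
      report$counts$post_clump <- 0L
      kept
    } else {
      panel <- .pooled_panel(datasets[config$discovery],
                             kept$variant_id)
      out <- clump(kept, panel, r2_max = config$clump_r2,
                   window_kb = config$clump_window_kb)
      report$counts$post_clump <- nrow(out)
      out
    }
  })

  model <- run_phase("build", {
    m <- build_grs(clumped, p_threshold = config$candidate_p,
                   clump_r2 = config$clump_r2,
                   clump_window_kb = config$clump_window_kb)
    report$counts$model_size <- nrow(m$entries)
    m
  })
  report$model <- model

  run_phase("evaluate", {
    for (cn in used) {
      d <- datasets[[cn]]
      sc <- score_samples(model, d, normalize = config$score_normalize)
      report$scores[[cn]] <- data.frame(
        sample_id = d$samples$sample_id, score = unname(sc),
        n_variants_used = attr(sc, "n_variants_used"))
      if (!all(is.na(d$samples$phenotype)))
        report$associations[[cn]] <-
          evaluate_grs(sc, d, covs[[cn]], "phenotype")
      if ("tangle_density" %in% names(d$samples))
        report$associations[[paste0(cn, ":tangles")]] <-
          evaluate_grs(sc, d, covs[[cn]], "tangle_density")
      if ("braak_high" %in% names(d$samples) &&
          length(unique(d$samples$braak_high)) > 1L)
        report$associations[[paste0(cn, ":braak")]] <-
          evaluate_grs(sc, d, covs[[cn]], "braak_high", binary = TRUE)
    }
    invisible(NULL)
  })

  if (!is.null(config$comparator_weights)) run_phase("comparator", {
    cmp <- read_grs_model(config$comparator_weights)
    for (cn in config$discovery)
      report$comparison[[cn]] <-
        compare_scores(model, cmp, datasets[[cn]], covs[[cn]])
    invisible(NULL)
  })

  structure(report, class = "run_report")
}

# Stack discovery cohorts' dosages over the given variants into one LD
# panel (variants absent from a cohort contribute missing entries; LD is
# computed on complete pairs).
.pooled_panel <- function(cohorts, variant_ids) {
  blocks <- lapply(cohorts, function(d) {
    i <- match(variant_ids, colnames(d$dosages))
    g <- matrix(NA_real_, n_samples(d), length(variant_ids),
                dimnames = list(rownames(d$dosages), variant_ids))
    g[, !is.na(i)] <- d$dosages[, i[!is.na(i)], drop = FALSE]
    g
  })
  dos <- do.call(rbind, blocks)
  vm <- do.call(rbind, lapply(cohorts, function(d)
    d$variant_meta[match(variant_ids, d$variant_meta$variant_id), ]))
  vm <- vm[!is.na(vm$variant_id) & !duplicated(vm$variant_id), ,
           drop = FALSE]
  vm <- vm[match(variant_ids, vm$variant_id), , drop = FALSE]
  if (anyNA(vm$variant_id))
    stop("variant(s) requested for the LD panel are absent from every ",
         "discovery cohort")
  samples <- data.frame(sample_id = rownames(dos),
                        phenotype = NA_real_, age = NA_real_,
                        sex = NA_integer_, stringsAsFactors = FALSE)
  cohort_dataset("pooled_ld_panel", dos, vm, samples)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> amygrs", x$version, "| seed", x$seed, "\n")
  cat("  funnel: candidates", x$counts$candidates,
      "-> refined", x$counts$post_refinement,
      "-> clumped", x$counts$post_clump,
      "-> model", x$counts$model_size, "\n")
  for (cn in names(x$lambda))
    cat(sprintf("  lambda[%s] = %.3f\n", cn, x$lambda[[cn]]))
  for (nm in names(x$associations)) {
    cat("  ", nm, ": ", sep = "")
    print(x$associations[[nm]])
  }
  invisible(x)
}

#' Write every pipeline artifact to a directory
#'
#' Emits the interchange tables (per-cohort QC summaries, meta-analysis
#' statistics, refinement decisions, model weights, per-sample scores)
#' plus a machine-readable JSON summary of the run.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(report$meta, file.path(dir, "meta_analysis.tsv"))
  if (!is.null(report$refinement_decisions))
    data.table::fwrite(report$refinement_decisions,
                       file.path(dir, "refinement_decisions.tsv"),
                       sep = "\t", na = "NA")
  write_grs_model(report$model, file.path(dir, "grs_weights.tsv"))
  for (cn in names(report$scores))
    data.table::fwrite(report$scores[[cn]],
                       file.path(dir, paste0("scores_", cn, ".tsv")),
                       sep = "\t", na = "NA")
  qc_tab <- do.call(rbind, lapply(names(report$qc_reports), function(cn) {
    v <- qc_report_table(report$qc_reports[[cn]]$variant)
    s <- qc_report_table(report$qc_reports[[cn]]$sample)
    v$scope <- "variant"; s$scope <- "sample"
    out <- rbind(v, s); out$cohort <- cn; out
  }))
  data.table::fwrite(qc_tab, file.path(dir, "qc_summary.tsv"), sep = "\t")
  summ <- list(version = report$version, seed = report$seed,
               counts = report$counts, lambda = report$lambda,
               associations = lapply(report$associations, unclass))
  jsonlite::write_json(summ, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Generate a bundled synthetic demonstration dataset
#'
#' Writes a four-cohort synthetic dataset (two amyloid-PET discovery
#' cohorts, one neuropathology refinement cohort, one plasma validation
#' cohort) in `.traw` + phenotype-table form, together with a matching
#' pipeline configuration. `"tiny"` is sized to run the full pipeline in
#' well under a minute; `"paper_scale"` mirrors the sample sizes of the
#' cohorts the method was designed around (983/513 discovery, 710
#' neuropathology, 641 plasma validation).
#'
#' @param out_dir Writable output directory (created if needed).
#' @param scale `"tiny"` or `"paper_scale"`.
#' @param seed Master simulation seed.
#' @return List with the simulation config (`sim`), pipeline config
#'   (`config`), config path, and per-cohort file paths.
#' @export
make_demo_data <- function(out_dir, scale = c("tiny", "paper_scale"),
                           seed = 1L) {
  scale <- match.arg(scale)
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, mode = 2) != 0)
    stop("output directory not writable: ", out_dir)
  sim <- demo_sim_config(scale, seed)
  modality <- c(discovery_a = "centiloid", discovery_b = "centiloid",
                neuropath = "neuropath", plasma = "plasma")
  files <- list()
  for (cn in names(sim$n_per_cohort)) {
    d <- simulate_cohort(sim, cn, modality[[cn]])
    gp <- file.path(out_dir, paste0(cn, ".traw"))
    pp <- file.path(out_dir, paste0(cn, "_phenotypes.tsv"))
    write_cohort(d, gp, pp, format = "traw")
    files[[cn]] <- list(genotypes = gp, phenotypes = pp, format = "traw")
  }
  config <- pipeline_config(
    discovery = c("discovery_a", "discovery_b"),
    refinement = "neuropath",
    validation = "plasma",
    ibd_variants = if (scale == "tiny") 1000L else 2000L,
    files = files, seed = seed)
  cfg_path <- file.path(out_dir, "pipeline_config.yaml")
  write_pipeline_config(config, cfg_path)
  list(sim = sim, config = config, config_path = cfg_path, files = files)
}

#' Simulation settings used by the bundled demonstrations
#'
#' `"tiny"` plants strong effects in a small sample so the full funnel
#' stays populated in seconds; `"paper_scale"` plants 8 causal LD blocks
#' each explaining 2.5% of discovery phenotype variance across 20,000
#' variants (per-block discovery power ~98% at the suggestive threshold,
#' by non-central-t calculation), with modality attenuation 0.8
#' (neuropathology) and 0.6 (plasma) and mild three-stratum population
#' structure.
#'
#' @param scale `"tiny"` or `"paper_scale"`.
#' @param seed Master seed.
#' @return A [simulation_config()].
#' @export
demo_sim_config <- function(scale = c("tiny", "paper_scale"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "tiny")
    simulation_config(
      seed = seed,
      n_per_cohort = c(discovery_a = 200, discovery_b = 200,
                       neuropath = 150, plasma = 150),
      m_variants = 2000L, ld_block_size = 10L, ld_rho = 0.7,
      maf_range = c(0.05, 0.5), n_causal = 8L, h2_target = 0.4,
      effect_attenuation = c(neuropath = 0.8, plasma = 0.7),
      n_ancestry_strata = 2L, fst = 0.01)
  else
    simulation_config(
      seed = seed,
      n_per_cohort = c(discovery_a = 983, discovery_b = 513,
                       neuropath = 710, plasma = 641),
      m_variants = 20000L, ld_block_size = 10L, ld_rho = 0.7,
      maf_range = c(0.05, 0.5), n_causal = 8L, h2_target = 0.20,
      effect_attenuation = c(neuropath = 0.8, plasma = 0.6),
      n_ancestry_strata = 3L, fst = 0.005)
}
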