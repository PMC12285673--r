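# Shared setup for the numbered analysis drivers: one synthetic
# four-cohort study at the scale of the cohorts the method was designed
# around (983 + 513 amyloid-PET discovery, 710 neuropathology, 641
# plasma validation; 20,000 common variants in LD blocks, 8 planted
# causal blocks). Simulated datasets are cached under scratch/ so the
# drivers can be run in sequence without re-simulating.

library(amygrs)

ANALYSIS_SEED <- 1L
RESULTS_DIR <- "results"
CACHE_DIR <- "scratch/analysis_cache"

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(CACHE_DIR, showWarnings = FALSE, recursive = TRUE)

cohort_modalities <- c(discovery_a = "centiloid", discovery_b = "centiloid",
                       neuropath = "neuropath", plasma = "plasma")

get_datasets <- function(seed = ANALYSIS_SEED) {
  cache <- file.path(CACHE_DIR, sprintf("datasets_seed%d.rds", seed))
  if (file.exists(cache)) return(readRDS(cache))
  cfg <- demo_sim_config("paper_scale", seed = seed)
  d <- lapply(setNames(nm = names(cfg$n_per_cohort)), function(cn)
    simulate_cohort(cfg, cn, cohort_modalities[[cn]]))
  saveRDS(d, cache)
  d
}

get_pipeline_config <- function(seed = ANALYSIS_SEED)
  pipeline_config(discovery = c("discovery_a", "discovery_b"),
                  refinement = "neuropath", validation = "plasma",
                  seed = seed)

get_run_report <- function(seed = ANALYSIS_SEED) {
  cache <- file.path(CACHE_DIR, sprintf("run_report_seed%d.rds", seed))
  if (file.exists(cache)) return(readRDS(cache))
  r <- run_pipeline(get_pipeline_config(seed), get_datasets(seed))
  saveRDS(r, cache)
  r
}

write_result <- function(tab, name) {
  path <- file.path(RESULTS_DIR, name)
  data.table::fwrite(tab, path, sep = "\t", na = "NA")
  cat("  wrote", path, "\n")
  invisible(path)
}
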