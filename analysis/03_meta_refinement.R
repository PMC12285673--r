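#!/usr/bin/env Rscript
# Phases 1b-2: random-effects (DerSimonian-Laird) meta-analysis across
# the discovery cohorts, suggestive candidate selection at p < 5e-5, and
# refinement against the independent neuropathology cohort (drop
# candidates with replication p >= 0.2 or a discordant effect
# direction).

source("analysis/common.R")

d <- get_datasets()
sa <- data.table::fread(file.path(CACHE_DIR, "sumstats_discovery_a.tsv"),
                        data.table = FALSE)
sb <- data.table::fread(file.path(CACHE_DIR, "sumstats_discovery_b.tsv"),
                        data.table = FALSE)
sb <- harmonize_alleles(sa, sb)
meta <- meta_analyze(list(sa, sb))
data.table::fwrite(meta, file.path(CACHE_DIR, "meta.tsv"), sep = "\t")

cand <- select_candidates(meta, 5e-5)
cat(sprintf("%d variants reach suggestive association (p < 5e-5)\n",
            nrow(cand)))

np <- d$neuropath
v <- apply_variant_qc(np); s <- apply_sample_qc(v$data)
np_qc <- s$data
covs <- make_covariates(np_qc, k_pcs = 5)
have <- intersect(cand$variant_id, np_qc$variant_meta$variant_id)
rep_stats <- gwas_linear(subset_cohort(np_qc, variants = have), covs)
rep_stats <- harmonize_alleles(cand, rep_stats)
dec <- refine_candidates(cand, rep_stats, p_max = 0.2)

cat("\nRefinement decisions:\n")
print(table(dec$reason))
funnel <- data.frame(
  stage = c("meta_tested", "candidates_p5e-5", "available_in_neuropath",
            "retained_after_refinement"),
  n = c(nrow(meta), nrow(cand), length(have), sum(dec$retained)))
print(funnel, row.names = FALSE)

write_result(funnel, "03_funnel.tsv")
dec$replication_p <- signif(dec$replication_p, 4)
write_result(dec, "03_refinement_decisions.tsv")
kept <- cand[cand$variant_id %in% dec$variant_id[dec$retained], ]
data.table::fwrite(kept, file.path(CACHE_DIR, "kept_candidates.tsv"),
                   sep = "\t")

truth_ids <- d$discovery_a$truth$variant_id
vm <- d$discovery_a$variant_meta
cb <- vm$block[match(truth_ids, vm$variant_id)]
cand_blocks <- vm$block[match(cand$variant_id, vm$variant_id)]
kept_blocks <- vm$block[match(kept$variant_id, vm$variant_id)]
cat(sprintf("\ncausal blocks among candidates: %d/8; after refinement: %d/8\n",
            length(intersect(cand_blocks, cb)),
            length(intersect(kept_blocks, cb))))
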