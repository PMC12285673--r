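#' Write a cohort's genotypes and phenotypes to disk
#'
#' Genotypes go to VCF v4.2 (GT hard calls plus a DS dosage field) or to
#' the PLINK variant-major text dialect (`.traw`: header line, one row
#' per variant, one column per sample, values are counted-allele
#' dosages). Phenotypes and covariates go to a tab-delimited table with
#' columns `sample_id`, `phenotype`, `age`, `sex` plus any extra outcome
#' columns present.
#'
#' @param data A [cohort_dataset()].
#' @param genotype_path,phenotype_path Output file paths.
#' @param format `"vcf"` or `"traw"`.
#' @return Invisibly, the genotype path.
#' @export
write_cohort <- function(data, genotype_path, phenotype_path,
                         format = c("traw", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") .write_vcf(data, genotype_path)
  else .write_traw(data, genotype_path)
  extra <- setdiff(names(data$samples),
                   c("sample_id", "phenotype", "age", "sex"))
  tab <- data$samples[, c("sample_id", "phenotype", "age", "sex", extra)]
  data.table::fwrite(tab, phenotype_path, sep = "\t", na = "NA")
  invisible(genotype_path)
}

.write_vcf <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=amygrs",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste0('##FORMAT=<ID=DS,Number=1,Type=Float,',
                      'Description="Effect allele dosage">'),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       data$samples$sample_id), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  m <- n_variants(data)
  vm <- data$variant_meta
  for (start in seq(1L, m, by = 2000L)) {
    cols <- start:min(start + 1999L, m)
    D <- t(data$dosages[, cols, drop = FALSE])  # variants x samples
    hard <- round(D)
    gt <- matrix(gt_codes[hard + 1L], nrow(D), ncol(D))
    gt[is.na(hard)] <- "./."
    ds <- matrix(formatC(D, format = "g", digits = 6), nrow(D), ncol(D))
    ds[is.na(D)] <- "."
    cells <- matrix(paste(gt, ds, sep = ":"), nrow(D), ncol(D))
    body <- apply(cells, 1, paste, collapse = "\t")
    lines <- paste(vm$chrom[cols], vm$pos[cols], vm$variant_id[cols],
                   # effect allele written as ALT so DS counts it
                   vm$other_allele[cols], vm$effect_allele[cols],
                   ".", "PASS", ".", "GT:DS", body, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

.write_traw <- function(data, path) {
  vm <- data$variant_meta
  tab <- data.table::data.table(
    CHR = vm$chrom, SNP = vm$variant_id, `(C)M` = 0, POS = vm$pos,
    COUNTED = vm$effect_allele, ALT = vm$other_allele)
  dos <- data.table::as.data.table(t(data$dosages))
  data.table::setnames(dos, data$samples$sample_id)
  data.table::fwrite(cbind(tab, dos), path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read a cohort from genotype + phenotype files
#'
#' Reads genotypes from VCF (using the DS dosage field where present,
#' otherwise counting ALT alleles in GT) or from the `.traw` text
#' dialect, joins them with the phenotype/covariate table, and returns a
#' [cohort_dataset()]. Samples are the intersection of the two files, in
#' the phenotype table's order; samples present in only one file are
#' dropped with a warning. Duplicate variant ids are rejected.
#'
#' @param genotype_path,phenotype_path Input files.
#' @param format `"vcf"` or `"traw"`.
#' @param cohort_name Name for the dataset (default: genotype file
#'   basename).
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(genotype_path, phenotype_path,
                        format = c("traw", "vcf"),
                        cohort_name = NULL) {
  format <- match.arg(format)
  if (!file.exists(genotype_path)) stop("no such file: ", genotype_path)
  if (!file.exists(phenotype_path)) stop("no such file: ", phenotype_path)
  g <- if (format == "vcf") .read_vcf(genotype_path)
       else .read_traw(genotype_path)
  if (anyDuplicated(g$meta$variant_id))
    stop("duplicate variant id(s) in ", genotype_path, ": ",
         paste(unique(g$meta$variant_id[duplicated(g$meta$variant_id)]),
               collapse = ", "))
  ph <- data.table::fread(phenotype_path, sep = "\t",
                          data.table = FALSE)
  req <- c("sample_id", "phenotype", "age", "sex")
  miss <- setdiff(req, names(ph))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  ph$sample_id <- as.character(ph$sample_id)
  common <- intersect(ph$sample_id, rownames(g$dosages))
  if (!length(common))
    stop("no overlapping sample ids between genotype and phenotype files")
  n_drop <- (nrow(ph) - length(common)) +
    (nrow(g$dosages) - length(common))
  if (n_drop > 0)
    warning(n_drop, " sample(s) present in only one file were dropped")
  ph <- ph[ph$sample_id %in% common, , drop = FALSE]
  dos <- g$dosages[ph$sample_id, , drop = FALSE]
  if (is.null(cohort_name))
    cohort_name <- sub("\\.(vcf|traw)(\\.gz)?$", "",
                       basename(genotype_path))
  cohort_dataset(cohort_name, dos, g$meta, ph)
}

.read_traw <- function(path) {
  tab <- tryCatch(
    suppressWarnings(data.table::fread(path, sep = "\t",
                                       data.table = FALSE)),
    error = function(e) stop("malformed .traw file ", path, ": ",
                             conditionMessage(e)))
  fixed <- c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT")
  miss <- setdiff(fixed, names(tab))
  if (length(miss))
    stop("malformed .traw file ", path, " (line 1): missing column(s) ",
         paste(miss, collapse = ", "))
  samp <- setdiff(names(tab), fixed)
  dos <- t(as.matrix(tab[, samp, drop = FALSE]))
  if (!is.numeric(dos))
    stop("malformed .traw file ", path, ": non-numeric dosage values")
  storage.mode(dos) <- "double"
  bad <- which(!is.na(dos) & (dos < 0 | dos > 2))
  if (length(bad)) {
    line <- (bad[1] - 1L) %/% length(samp) + 2L
    stop("malformed .traw file ", path, " (line ", line,
         "): dosage outside [0, 2]")
  }
  rownames(dos) <- samp
  colnames(dos) <- tab$SNP
  meta <- data.frame(variant_id = tab$SNP, chrom = tab$CHR, pos = tab$POS,
                     effect_allele = tab$COUNTED, other_allele = tab$ALT,
                     stringsAsFactors = FALSE)
  list(dosages = dos, meta = meta)
}

.read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  meta <- data.frame(variant_id = fix[, "ID"],
                     chrom = suppressWarnings(as.integer(fix[, "CHROM"])),
                     pos = as.integer(fix[, "POS"]),
                     # ALT carries the counted (effect) allele
                     effect_allele = fix[, "ALT"],
                     other_allele = fix[, "REF"],
                     stringsAsFactors = FALSE)
  fmt <- vcf@gt[1, "FORMAT"]
  if (grepl("DS", fmt)) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gtc <- vcfR::extract.gt(vcf, element = "GT")
    ds <- matrix(NA_real_, nrow(gtc), ncol(gtc), dimnames = dimnames(gtc))
    ok <- !is.na(gtc) & gtc != "./." & gtc != ".|."
    ds[ok] <- vapply(strsplit(gtc[ok], "[/|]"),
                     function(a) sum(a == "1"), numeric(1))
  }
  dos <- t(ds)
  colnames(dos) <- meta$variant_id
  list(dosages = dos, meta = meta)
}

#' Write / read a summary-statistics table
#'
#' The tab-delimited interchange format produced by the GWAS engine and
#' consumed by the meta-analysis and scoring stages: columns
#' `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `p`, `n` (meta-analysis tables carry their own columns
#' and round-trip the same way).
#'
#' @param stats Summary-statistics data frame.
#' @param path File path.
#' @return `read_sumstats()` returns the data frame; `write_sumstats()`
#'   the path, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  data.table::fwrite(stats, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  data.table::fread(path, sep = "\t", data.table = FALSE)
}

#' Write / read a score weight file
#'
#' Delimited text with columns `variant_id`, `chrom`, `pos`,
#' `effect_allele`, `weight` (an `other_allele` column is kept when
#' present) — also the import format for externally published comparator
#' scores.
#'
#' @param model A [build_grs()] model.
#' @param path File path.
#' @param weight_source Provenance string recorded when reading.
#' @return `read_grs_model()` returns a `grs_model`;
#'   `write_grs_model()` the path, invisibly.
#' @export
write_grs_model <- function(model, path) {
  data.table::fwrite(model$entries, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_grs_model
#' @export
read_grs_model <- function(path, weight_source = paste("file:", path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- data.table::fread(path, sep = "\t", data.table = FALSE)
  req <- c("variant_id", "chrom", "pos", "effect_allele", "weight")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("weight file lacks columns: ", paste(miss, collapse = ", "))
  if (!"other_allele" %in% names(tab))
    tab$other_allele <- NA_character_
  entries <- tab[, c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "weight")]
  if (any(!is.finite(entries$weight) | entries$weight == 0))
    stop("model weights must be finite and nonzero")
  if (anyDuplicated(entries$variant_id)) stop("duplicate model variants")
  structure(list(entries = entries,
                 provenance = list(clump_r2 = NA_real_,
                                   clump_window_kb = NA_real_,
                                   p_threshold = NA_real_,
                                   weight_source = weight_source)),
            class = "grs_model")
}
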