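## End-to-end orchestration: simulate -> EBV -> QC -> expression -> weights
## -> GWAS -> TWAS -> annotation, over plain-text intermediate files, with a
## JSON manifest recording seeds, per-stage counts and file checksums. Each
## stage is independently runnable from the previous stage's files; the
## manifest is the only cross-stage contract.

#' Pipeline run configuration
#'
#' @param sim [sim_config()] for the synthetic cohort.
#' @param qc [qc_thresholds()].
#' @param hp [dpr_hyperparams()].
#' @param alpha family-wise significance level (default 0.05).
#' @param nominal_p nominal GWAS reporting threshold (default 1e-4).
#' @param n_pcs GWAS covariate PCs (default 3).
#' @param cv_r2_min stage-I model retention threshold (default 0.005).
#' @param n_effective optional explicit effective test count for the TWAS
#'   threshold (default: genes with non-missing statistics).
#' @param annotate_window annotation half-width in bp (default 25 kb).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), qc = qc_thresholds(),
                       hp = dpr_hyperparams(), alpha = 0.05,
                       nominal_p = 1e-4, n_pcs = 3L, cv_r2_min = 0.005,
                       n_effective = NULL, annotate_window = 25000) {
  structure(list(sim = sim, qc = qc, hp = hp, alpha = alpha,
                 nominal_p = nominal_p, n_pcs = as.integer(n_pcs),
                 cv_r2_min = cv_r2_min, n_effective = n_effective,
                 annotate_window = annotate_window),
            class = "run_config")
}

stage_path <- function(dir, name) file.path(dir, name)

#' Stage 1: simulate the synthetic cohort to disk
#'
#' Writes pedigree TSV, genotype VCF + .raw TSV, gene-model GTF, count and
#' expression TSVs, phenotype TSV, and the ground-truth breeding values.
#'
#' @param cfg [run_config()].
#' @param dir output directory (created if needed).
#' @return named list of per-stage counts (invisibly, for the manifest).
#' @export
stage_simulate <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- cfg$sim
  ped_total <- ceiling(2.15 * sim$n_animals / 5) * 5
  ped <- simulate_pedigree(ped_total / 5, 4L, seed = sim$seed)
  pheno_ids <- ped$id[(nrow(ped) - sim$n_animals + 1L):nrow(ped)]
  gen <- simulate_genotypes(sim, sample_ids = pheno_ids)
  genes <- sim_gene_annotation(sim)
  expr <- simulate_expression(gen$G, sim, genes = genes)
  counts <- simulate_counts(expr$E, genes, sim)
  td <- simulate_testday(ped, sim)

  write_tsv_table(ped, stage_path(dir, "pedigree.tsv"))
  write_genotypes_vcf(gen$G, stage_path(dir, "genotypes.vcf"))
  write_genotypes_raw(gen$G, stage_path(dir, "genotypes.raw.tsv"))
  write_gtf(genes, stage_path(dir, "genes.gtf"))
  cnt_df <- data.frame(gene_id = rownames(counts), length = attr(counts, "length"),
                       counts, check.names = FALSE)
  write_tsv_table(cnt_df, stage_path(dir, "counts.tsv"))
  write_tsv_table(td$records, stage_path(dir, "phenotypes.tsv"))
  truth_df <- data.frame(animal_id = names(td$truth$true_breeding_values),
                         tbv = unname(td$truth$true_breeding_values))
  write_tsv_table(truth_df, stage_path(dir, "true_breeding_values.tsv"))
  invisible(list(n_animals = sim$n_animals, n_ped = nrow(ped),
                 n_snps = ncol(gen$G$dosage), n_genes = nrow(genes),
                 n_records = nrow(td$records)))
}

#' Stage 2: screen fixed factors and estimate EBVs
#' @param cfg [run_config()].
#' @param dir run directory holding stage-1 outputs.
#' @return stage counts, invisibly.
#' @export
stage_ebv <- function(cfg, dir) {
  records <- read_tsv_table(stage_path(dir, "phenotypes.tsv"),
                            c("animal_id", "parity", "dim", "htd", "ys", "mc", "value"))
  ped <- read_tsv_table(stage_path(dir, "pedigree.tsv"), c("id", "sire", "dam"))
  retained <- screen_fixed_factors(records, c("htd", "ys", "mc"))
  sol <- fit_rr_testday_model(records, ped, cfg$sim$varcomps, retained)
  ebv_df <- data.frame(animal_id = names(sol$ebv), ebv = unname(sol$ebv))
  write_tsv_table(ebv_df, stage_path(dir, "ebv.tsv"))
  writeLines(retained, stage_path(dir, "retained_factors.txt"))
  invisible(list(n_retained_factors = length(retained),
                 n_ebv = nrow(ebv_df)))
}

#' Stage 3: genotype QC, kinship, principal components
#' @param cfg [run_config()].
#' @param dir run directory.
#' @return stage counts, invisibly.
#' @export
stage_qc <- function(cfg, dir) {
  G <- read_genotypes(stage_path(dir, "genotypes.raw.tsv"), "raw")
  res <- apply_qc(G, cfg$qc)
  write_genotypes_raw(res$G, stage_path(dir, "genotypes_qc.raw.tsv"))
  write_tsv_table(res$report, stage_path(dir, "qc_report.tsv"))
  K <- compute_kinship(res$G)
  pcs <- compute_pcs(res$G, cfg$n_pcs)
  write_tsv_table(data.frame(animal_id = rownames(K), K, check.names = FALSE),
                  stage_path(dir, "kinship.tsv"))
  write_tsv_table(data.frame(animal_id = rownames(pcs), pcs, check.names = FALSE),
                  stage_path(dir, "pcs.tsv"))
  invisible(list(n_snps_qc = ncol(res$G$dosage),
                 n_samples_qc = nrow(res$G$dosage)))
}

#' Stage 4: TPM normalisation and expression filtering
#' @param cfg [run_config()].
#' @param dir run directory.
#' @return stage counts, invisibly.
#' @export
stage_expr <- function(cfg, dir) {
  cnt <- read_tsv_table(stage_path(dir, "counts.tsv"), c("gene_id", "length"))
  counts <- as.matrix(cnt[, setdiff(names(cnt), c("gene_id", "length")), drop = FALSE])
  rownames(counts) <- cnt$gene_id
  tpm <- compute_tpm(counts, cnt$length)
  fl <- filter_expressed(tpm)
  write_tsv_table(data.frame(gene_id = rownames(fl$tpm), fl$tpm, check.names = FALSE),
                  stage_path(dir, "tpm_filtered.tsv"))
  invisible(list(n_genes_expressed = fl$n_kept, n_genes_total = nrow(counts)))
}

#' Stage 5: train DPR cis-eQTL weights with CV retention
#' @param cfg [run_config()].
#' @param dir run directory.
#' @return stage counts, invisibly.
#' @export
stage_weights <- function(cfg, dir) {
  G <- read_genotypes(stage_path(dir, "genotypes_qc.raw.tsv"), "raw")
  genes <- read_gtf(stage_path(dir, "genes.gtf"))
  tp <- read_tsv_table(stage_path(dir, "tpm_filtered.tsv"), "gene_id")
  expr <- as.matrix(tp[, setdiff(names(tp), "gene_id"), drop = FALSE])
  rownames(expr) <- tp$gene_id
  expr <- expr[, rownames(G$dosage), drop = FALSE]
  fits <- train_weights_all(expr, G, genes, cfg$hp)
  kept <- retain_models(fits, cfg$cv_r2_min)
  tabs <- weights_table(kept, G$map)
  write_tsv_table(tabs$weights, stage_path(dir, "weights.tsv"))
  write_tsv_table(tabs$models, stage_path(dir, "weight_models.tsv"))
  invisible(list(n_models_trained = length(fits), n_models_retained = length(kept)))
}

#' Stage 6: GWAS scan of the EBV phenotype
#' @param cfg [run_config()].
#' @param dir run directory.
#' @return stage counts, invisibly.
#' @export
stage_gwas <- function(cfg, dir) {
  G <- read_genotypes(stage_path(dir, "genotypes_qc.raw.tsv"), "raw")
  ebv <- read_tsv_table(stage_path(dir, "ebv.tsv"), c("animal_id", "ebv"))
  pcs <- read_tsv_table(stage_path(dir, "pcs.tsv"), "animal_id")
  ids <- rownames(G$dosage)
  y <- ebv$ebv[match(ids, ebv$animal_id)]
  check_that(!anyNA(y), "EBV missing for genotyped animal(s)")
  cov <- as.matrix(pcs[match(ids, pcs$animal_id),
                       setdiff(names(pcs), "animal_id"), drop = FALSE])
  ss <- single_snp_scan(y, G, covariates = cov)
  write_tsv_table(ss, stage_path(dir, "sumstats.tsv"))
  thr <- bonferroni_threshold(cfg$alpha, sum(!is.na(ss$p)))
  invisible(list(n_snps_tested = sum(!is.na(ss$p)),
                 n_nominal = sum(ss$p < cfg$nominal_p, na.rm = TRUE),
                 n_significant = sum(ss$p < thr, na.rm = TRUE),
                 gwas_threshold = thr))
}

#' Stage 7: TWAS burden tests and significance calls
#' @param cfg [run_config()].
#' @param dir run directory.
#' @return stage counts, invisibly.
#' @export
stage_twas <- function(cfg, dir) {
  G <- read_genotypes(stage_path(dir, "genotypes_qc.raw.tsv"), "raw")
  ss <- read_tsv_table(stage_path(dir, "sumstats.tsv"), c("snp_id", "z"))
  wt <- read_tsv_table(stage_path(dir, "weights.tsv"), c("gene_id", "snp_id", "weight"))
  md <- read_tsv_table(stage_path(dir, "weight_models.tsv"), "gene_id")
  weights <- lapply(split(wt, wt$gene_id), function(d) {
    list(gene_id = d$gene_id[1], snp_ids = d$snp_id,
         w = stats::setNames(d$weight, d$snp_id))
  })
  weights <- weights[md$gene_id[md$gene_id %in% names(weights)]]
  ld <- build_ld_reference(G, weights)
  res <- twas_burden(ss, weights, ld)
  called <- call_significant(res, cfg$alpha, cfg$n_effective)
  write_tsv_table(called$results, stage_path(dir, "twas.tsv"))
  common <- overlap_genes(called$sig_fusion, called$sig_spredixcan)
  writeLines(common, stage_path(dir, "twas_common_genes.txt"))
  invisible(list(n_genes_tested = nrow(res),
                 n_sig_fusion = length(called$sig_fusion),
                 n_sig_spredixcan = length(called$sig_spredixcan),
                 n_sig_common = length(common)))
}

#' Stage 8: annotate significant TWAS genes with neighbours
#' @param cfg [run_config()].
#' @param dir run directory.
#' @return stage counts, invisibly.
#' @export
stage_annotate <- function(cfg, dir) {
  genes <- read_gtf(stage_path(dir, "genes.gtf"))
  common <- readLines(stage_path(dir, "twas_common_genes.txt"))
  common <- common[nzchar(common)]
  if (length(common) == 0L) {
    write_tsv_table(data.frame(signal_id = character(0), gene_id = character(0),
                               distance = numeric(0)),
                    stage_path(dir, "annotation.tsv"))
    return(invisible(list(n_signals_annotated = 0L)))
  }
  i <- match(common, genes$gene_id)
  signals <- data.frame(signal_id = common, chr = genes$chr[i],
                        start = genes$start[i], end = genes$end[i])
  ann <- annotate_signals(signals, genes, cfg$annotate_window)
  write_tsv_table(ann, stage_path(dir, "annotation.tsv"))
  invisible(list(n_signals_annotated = length(common)))
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order under `dir` and writes
#' `manifest.json` recording the seed, per-stage counts and MD5 checksums
#' of every stage output. A failing stage halts with the stage name in the
#' error message.
#'
#' @param cfg [run_config()].
#' @param dir run directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list(simulate = stage_simulate, ebv = stage_ebv, qc = stage_qc,
                 expr = stage_expr, weights = stage_weights, gwas = stage_gwas,
                 twas = stage_twas, annotate = stage_annotate)
  counts <- list()
  for (nm in names(stages)) {
    counts[[nm]] <- tryCatch(stages[[nm]](cfg, dir), error = function(e)
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest <- list(seed = cfg$sim$seed, counts = counts,
                   files = stats::setNames(
                     lapply(files, function(f) file_md5(file.path(dir, f))),
                     files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
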