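#!/usr/bin/env Rscript
## Stage I of the TWAS: per-gene Dirichlet-process-regression cis-eQTL
## weights (variational fit, +/- 1 Mb cis window) with 5-fold CV, retaining
## models with CV R2 > 0.005.

source(file.path("analysis", "config.R"))

counts <- stage_weights(cfg, run_dir)
md <- read_tsv_table(file.path(run_dir, "weight_models.tsv"))
cat(sprintf("Trained %d models; %d retained at CV R2 > %.3f.\n",
            counts$n_models_trained, counts$n_models_retained, cfg$cv_r2_min))
cat(sprintf("Median CV R2 = %.4f; median training R2 = %.4f; median cis SNPs per model = %d.\n",
            median(md$cv_r2), median(md$train_r2), median(md$n_snps)))
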