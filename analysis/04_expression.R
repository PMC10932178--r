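#!/usr/bin/env Rscript
## Length-normalised TPM from the simulated count matrix, then the
## expression filter (TPM >= 0.1 in at least 20% of samples).

source(file.path("analysis", "config.R"))

counts <- stage_expr(cfg, run_dir)
cat(sprintf("%d of %d genes pass the expression filter (%.1f%%).\n",
            counts$n_genes_expressed, counts$n_genes_total,
            100 * counts$n_genes_expressed / counts$n_genes_total))
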