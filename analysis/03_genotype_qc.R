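#!/usr/bin/env Rscript
## Genotype quality control (call rates, MAF > 0.05, exact HWE p > 1e-6),
## then VanRaden kinship and the top principal components used as GWAS
## covariates.

source(file.path("analysis", "config.R"))

counts <- stage_qc(cfg, run_dir)
rep_ <- read_tsv_table(file.path(run_dir, "qc_report.tsv"))
print(rep_)
cat(sprintf("%d of %d animals and %d SNPs remain after QC.\n",
            counts$n_samples_qc, cfg$sim$n_animals, counts$n_snps_qc))
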