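#!/usr/bin/env Rscript
## Covariate-adjusted single-SNP scan of the EBV phenotype with 3 PCs,
## reporting nominal (p < 1e-4) and Bonferroni-significant SNPs.

source(file.path("analysis", "config.R"))

counts <- stage_gwas(cfg, run_dir)
cat(sprintf("Scanned %d SNPs; %d nominal (p < %.0e), %d significant (p < %.3g).\n",
            counts$n_snps_tested, counts$n_nominal, cfg$nominal_p,
            counts$n_significant, counts$gwas_threshold))
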