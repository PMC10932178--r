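#!/usr/bin/env Rscript
## Simulate the synthetic cohort: pedigree, LD-structured genotypes,
## cis-regulated blood expression with derived counts, and multi-parity
## test-day records with known breeding values.

source(file.path("analysis", "config.R"))

counts <- stage_simulate(cfg, run_dir)
cat(sprintf(
  "Simulated %d phenotyped animals (pedigree of %d), %d SNPs, %d genes, %d test-day records.\n",
  counts$n_animals, counts$n_ped, counts$n_snps, counts$n_genes,
  counts$n_records))
cat("Outputs: pedigree.tsv, genotypes.vcf, genotypes.raw.tsv, genes.gtf,",
    "counts.tsv, phenotypes.tsv, true_breeding_values.tsv in", run_dir, "\n")
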