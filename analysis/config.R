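## Shared configuration for the analysis scripts: one synthetic cohort of
## 100 phenotyped buffalo (215-animal pedigree), 5000 SNPs on 5 chromosomes,
## 300 genes, recorded over three lactations. All scripts read and write
## under results/run/.

library(bubalusTwas)

run_dir <- file.path("results", "run")
cfg <- run_config(sim = sim_config(seed = 20240916))
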