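#!/usr/bin/env Rscript
## Screen the candidate fixed factors (herd-test-date, calving year-season,
## month of calving), fit the random-regression test-day model, and collapse
## the breeding-value curves to one EBV per animal.

source(file.path("analysis", "config.R"))

counts <- stage_ebv(cfg, run_dir)
ret <- readLines(file.path(run_dir, "retained_factors.txt"))
ebv <- read_tsv_table(file.path(run_dir, "ebv.tsv"))
tbv <- read_tsv_table(file.path(run_dir, "true_breeding_values.tsv"))
r <- cor(ebv$ebv, tbv$tbv[match(ebv$animal_id, tbv$animal_id)])
cat(sprintf("Retained fixed factors: %s.\n", paste(ret, collapse = ", ")))
cat(sprintf("EBVs estimated for %d pedigree animals; corr(EBV, true BV) = %.3f.\n",
            counts$n_ebv, r))
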