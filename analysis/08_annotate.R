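#!/usr/bin/env Rscript
## Annotate significant TWAS genes with neighbours within 25 kb and write
## the final manifest for the whole run.

source(file.path("analysis", "config.R"))

counts <- stage_annotate(cfg, run_dir)
cat(sprintf("Annotated %d TWAS signals (25 kb window).\n",
            counts$n_signals_annotated))
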