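#!/usr/bin/env Rscript
# Collate the artifacts of steps 01-04 into a single human-readable
# report at results/report.md. Reads only what is on disk.

library(cytocell)

# the renderer expects the pipeline layout: concordance/ + composition/
lines <- render_report("results")
cat(lines, sep = "\n")
message("Report written to results/report.md")
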