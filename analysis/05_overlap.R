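#!/usr/bin/env Rscript
# Commonly-regulated-gene overlap statistics: the published Venn counts for
# genes up- and downregulated by the two lead HDAC inhibitors, summarized as
# the percentage of the union that is shared.

suppressMessages(library(enucleoscreen))
out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

up <- overlap_summary(counts = c(2152, 1697, 719))
down <- overlap_summary(counts = c(2523, 1884, 812))
print(up)
print(down)

jsonlite::write_json(
  list(upregulated = unclass(up), downregulated = unclass(down)),
  file.path(out, "overlap.json"), auto_unbox = TRUE, digits = NA)
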