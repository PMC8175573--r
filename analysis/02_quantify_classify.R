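#!/usr/bin/env Rscript
# Run the imaging pipeline over the simulated plate from 01_simulate.R:
# per well, render the fields and detect objects (images are processed in
# memory well-by-well and discarded, so the plate never has to sit on disk);
# calibrate per-channel positivity cutoffs from the plate's own DMSO wells;
# classify every object by the three-signal truth table and write per-well
# state counts.
#
# Also quantifies the demo well's on-disk TIFFs to show the file-based route.

suppressMessages(library(enucleoscreen))
out <- "results/screen"
seed <- 20260924

lib <- read_table_csv(file.path(out, "library.csv"))
lay <- read_plate_map(file.path(out, "plate_map.csv"))

res <- screen_plate(lay, lib, preset_well_truth("dmso", 3000),
                    n_fields = 6, seed = seed)
write_thresholds(res$thresholds, file.path(out, "thresholds.json"))
write_table_csv(res$counts, file.path(out, "counts.csv"))
write_well_truth(res$truth, file.path(out, "well_truth.json"))
message(sprintf("Calibrated cutoffs (counts): %s",
                paste(sprintf("%s=%.0f", names(res$thresholds$cutoff),
                              res$thresholds$cutoff), collapse = ", ")))
message(sprintf("Counted %d wells; total objects %d",
                nrow(res$counts), sum(res$counts$n_objects_total)))
write_table_csv(res$folds, file.path(out, "well_folds.csv"))

# file-based route: quantify the demo well from its TIFFs
demo <- read_field_images(file.path(out, "images"), "P001", "DEMO")
obj <- detect_well(demo)
write_table_csv(obj, file.path(out, "demo_well_objects_detected.csv"))
message(sprintf("Demo well: detected %d objects from TIFFs", nrow(obj)))
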