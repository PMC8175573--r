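#!/usr/bin/env Rscript
# Score the simulated screen: plate-normalized fold changes against the
# in-plate DMSO means, the dual hit criterion (enucleation fold > 9.0 and
# cell-number fold >= 0.25), and the ranked hit report. Compares the
# estimated folds with the generator's true effects.

suppressMessages(library(enucleoscreen))
out <- "results/screen"

folds <- read_table_csv(file.path(out, "well_folds.csv"))
lib <- read_table_csv(file.path(out, "library.csv"))

test <- folds[folds$role == "test", ]
hits <- call_hits(test)
report <- rank_report(hits)
write_table_csv(report, file.path(out, "hits.csv"))

message("Ranked report (estimated folds, 2 dp):")
print(report)

truth <- merge(test, lib[, c("compound_id", "true_enuc_fold", "true_cellnum_fold")])
message("\nEstimated vs true enucleation folds:")
print(data.frame(name = truth$name, conc_uM = truth$concentration_uM,
                 est = round(truth$enuc_fold, 2), true = truth$true_enuc_fold))
n_hit <- sum(report$is_hit)
message(sprintf("\n%d of %d compound x concentration rows called hits.",
                n_hit, nrow(report)))
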