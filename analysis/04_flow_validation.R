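#!/usr/bin/env Rscript
# Flow-cytometry-style validation of the imaging presets: gate the simulated
# event tables from 01_simulate.R on FSC and the SYTO 16 / 7AAD quadrants and
# compare the flow enucleation percentage with each preset's ground truth.

suppressMessages(library(enucleoscreen))
out <- "results/screen"

ref <- read_flow_events(file.path(out, "flow_events_dmso.csv"))
cut <- calibrate_flow_cutoffs(ref)
message(sprintf("Dye cutoffs from the vehicle reference: SYTO16=%.0f, 7AAD=%.0f",
                cut[["syto16"]], cut[["aad7"]]))

rows <- lapply(c("dmso", "treated"), function(cond) {
  ev <- read_flow_events(file.path(out, sprintf("flow_events_%s.csv", cond)))
  sp <- split_fsc(ev)
  g <- gate_enucleation(sp, cut[["syto16"]], cut[["aad7"]])
  tr <- preset_well_truth(cond)
  data.frame(condition = cond,
             n_events = g$n_events,
             fsc_cutoff = round(sp$cutoff, 2),
             enucleation_pct = round(g$enucleation_pct, 2),
             true_enucleated_fraction_pct = 100 * tr$state_fractions[["enucleated"]])
})
tab <- do.call(rbind, rows)
write_table_csv(tab, file.path(out, "flow_gates.csv"))
print(tab)
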