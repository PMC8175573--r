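#!/usr/bin/env Rscript
# Build a small demonstration screen: a compound library with two known
# enucleation inducers spiked into null compounds, a 96-well plate layout with
# in-plate DMSO controls of both volume classes, example rendered field images
# for one well, and flow-cytometry event tables for the two condition presets.
#
# Outputs under results/screen/.

suppressMessages(library(enucleoscreen))
out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260924

# Two spiked true effects taken from the published hit table (enucleation
# fold, cell-number fold), plus null compounds as the screen background.
lib <- make_library(
  4,
  hit_spec = data.frame(
    name = c("Trichostatin A", "Vorinostat (SAHA)"),
    true_enuc_fold = c(11.60, 11.52),
    true_cellnum_fold = c(0.46, 0.99)),
  seed = seed)
lay <- make_plate_layouts(lib, controls_per_plate = 8, seed = seed)
write_table_csv(lib, file.path(out, "library.csv"))
write_plate_map(lay, file.path(out, "plate_map.csv"))
message(sprintf("Plate map: %d wells (%d test, %d DMSO)",
                nrow(lay), sum(lay$role == "test"), sum(lay$role == "dmso")))

# Example rendered images for one treated well, written as 16-bit TIFFs.
tsa <- lib[lib$name == "Trichostatin A", ]
truth <- sample_well_population(tsa, preset_well_truth("dmso", 500),
                                seed = seed, well_address = "DEMO")
rnd <- render_field_images(truth, n_fields = 2, image_shape = c(512, 512),
                           seed = seed, well_address = "DEMO")
write_field_images(rnd$fields, file.path(out, "images"))
write_well_truth(truth, file.path(out, "demo_well_truth.json"))
write_table_csv(rnd$objects, file.path(out, "demo_well_objects_truth.csv"))
message(sprintf("Rendered %d cells across 2 demo fields (see %s/images)",
                truth$total_cells, out))

# Flow event tables for the vehicle and treated presets.
for (cond in c("dmso", "treated")) {
  tr <- preset_well_truth(cond, 10000)
  tr$well_address <- toupper(cond)
  ev <- simulate_flow_events(tr, 10000, seed = derive_seed(seed, cond))
  write_flow_events(ev, file.path(out, sprintf("flow_events_%s.csv", cond)))
}
message("Wrote flow event tables for the DMSO and treated presets.")
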