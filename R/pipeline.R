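#' Detect objects in every field of a rendered well
#'
#' @param fields List of field images (see [render_field_images()]).
#' @param ... Passed to [detect_objects()].
#' @return Combined object table for the well.
#' @export
detect_well <- function(fields, ...) {
  do.call(rbind, lapply(fields, detect_objects, ...))
}

#' Simulate, image and quantify one plate of a screen
#'
#' Runs the screen stages end to end for a single plate: draw each well's
#' ground-truth population from the plate map and compound library, render its
#' fields, detect objects, calibrate per-channel cutoffs from the plate's own
#' DMSO wells, classify, count, and compute plate-normalized fold changes.
#' Images are rendered and quantified well by well and discarded, so memory
#' stays flat regardless of plate size.
#'
#' @param plate_map Rows of a [make_plate_layouts()] table for one plate.
#' @param library Compound library from [make_library()].
#' @param baseline Baseline `"well_truth"` template (vehicle composition and
#'   seeded cell number), e.g. `preset_well_truth("dmso", 10000)`.
#' @param n_fields Fields imaged per well.
#' @param image_shape Field dimensions in pixels.
#' @param intensity_model From [default_intensity_model()].
#' @param seed Master seed; all wells derive sub-seeds from it.
#' @param min_area,min_separation,thr_k Passed to [detect_objects()].
#' @param denominator_mode Passed to [enucleation_frequency()].
#' @return A list: `truth` (per-well ground-truth records), `counts` (per-well
#'   state counts), `thresholds`, `scores`, `folds` (from [fold_changes()]).
#' @export
screen_plate <- function(plate_map, library, baseline, n_fields = 10,
                         image_shape = c(1024, 1024),
                         intensity_model = default_intensity_model(),
                         seed = 1, min_area = 20, min_separation = 5,
                         thr_k = 6, denominator_mode = "methods") {
  stop_if_not(length(unique(plate_map$plate_id)) == 1,
              "screen_plate expects a single plate")
  plate_id <- plate_map$plate_id[1]
  active <- plate_map[plate_map$role %in% c("test", "dmso"), , drop = FALSE]

  truths <- list()
  objects <- list()
  for (i in seq_len(nrow(active))) {
    w <- active[i, ]
    compound <- if (w$role == "dmso") "DMSO" else
      library[library$compound_id == w$compound_id, , drop = FALSE]
    truth <- sample_well_population(compound, baseline,
                                    seed = derive_seed(seed, plate_id),
                                    well_address = w$well)
    rnd <- render_field_images(truth, n_fields = n_fields,
                               image_shape = image_shape,
                               intensity_model = intensity_model,
                               seed = seed, plate_id = plate_id,
                               well_address = w$well)
    objects[[w$well]] <- detect_well(rnd$fields, min_area = min_area,
                                     min_separation = min_separation,
                                     thr_k = thr_k)
    truths[[w$well]] <- truth
  }

  ctrl_wells <- active$well[active$role == "dmso"]
  ctrl_obj <- do.call(rbind, objects[ctrl_wells])
  thresholds <- calibrate_thresholds(ctrl_obj)

  counts <- do.call(rbind, lapply(objects, function(ob)
    count_well(classify_objects(ob, thresholds))))
  rownames(counts) <- NULL
  scores <- well_scores(counts, plate_map, denominator_mode)
  folds <- fold_changes(scores)
  list(truth = truths, counts = counts, thresholds = thresholds,
       scores = scores, folds = folds)
}

#' Imaging-pipeline enucleation estimates for preset wells
#'
#' Generates `n_wells` wells from a condition preset, renders and quantifies
#' them, calibrates channel cutoffs from matched vehicle wells generated
#' alongside, and returns per-well measured and true enucleation frequencies
#' (among intact cells, the screen's statistic).
#'
#' @param condition `"dmso"` or `"treated"` (see [preset_well_truth()]).
#' @param n_wells Number of preset wells.
#' @param total_cells Cells per well.
#' @param n_fields Fields per well.
#' @param seed Master seed.
#' @param n_calib_wells Vehicle wells used only for threshold calibration.
#' @param image_shape,intensity_model,min_area,min_separation Rendering and
#'   detection parameters.
#' @return Data.frame with one row per well: `well_address`, `true_freq`
#'   (the preset's expected frequency), `measured_freq`.
#' @export
measure_preset_wells <- function(condition, n_wells = 5, total_cells = 5000,
                                 n_fields = 10, seed = 1, n_calib_wells = 3,
                                 image_shape = c(1024, 1024),
                                 intensity_model = default_intensity_model(),
                                 min_area = 20, min_separation = 5) {
  calib_obj <- list()
  for (i in seq_len(n_calib_wells)) {
    wa <- sprintf("C%02d", i)
    truth <- preset_well_truth("dmso", total_cells)
    truth$well_address <- wa
    rnd <- render_field_images(truth, n_fields = n_fields,
                               image_shape = image_shape,
                               intensity_model = intensity_model,
                               seed = derive_seed(seed, "calib", i),
                               well_address = wa)
    calib_obj[[i]] <- detect_well(rnd$fields, min_area = min_area,
                                  min_separation = min_separation)
  }
  thresholds <- calibrate_thresholds(do.call(rbind, calib_obj))

  res <- lapply(seq_len(n_wells), function(i) {
    wa <- sprintf("W%02d", i)
    truth <- preset_well_truth(condition, total_cells)
    truth$well_address <- wa
    fr <- truth$state_fractions
    rnd <- render_field_images(truth, n_fields = n_fields,
                               image_shape = image_shape,
                               intensity_model = intensity_model,
                               seed = derive_seed(seed, "well", i),
                               well_address = wa)
    ob <- detect_well(rnd$fields, min_area = min_area,
                      min_separation = min_separation)
    cnt <- count_well(classify_objects(ob, thresholds))
    data.frame(well_address = wa,
               true_freq = fr[["enucleated"]] /
                 (fr[["viable_nucleated"]] + fr[["enucleated"]]),
               measured_freq = enucleation_frequency(cnt, "methods"))
  })
  do.call(rbind, res)
}

#' Flow-pipeline enucleation estimate for a well composition
#'
#' Simulates flow events from a ground-truth composition, calibrates dye
#' cutoffs from a matched vehicle reference, splits on FSC and gates.
#'
#' @param truth A `"well_truth"`.
#' @param n_events Events to acquire.
#' @param seed Master seed.
#' @param reference_truth Vehicle composition used for cutoff calibration
#'   (defaults to the DMSO preset).
#' @return A `"gate_result"` (see [gate_enucleation()]).
#' @export
flow_enucleation_estimate <- function(truth, n_events = 10000, seed = 1,
                                      reference_truth = preset_well_truth("dmso")) {
  ref <- simulate_flow_events(reference_truth, n_events,
                              seed = derive_seed(seed, "flow-ref"))
  cut <- calibrate_flow_cutoffs(ref)
  ev <- simulate_flow_events(truth, n_events, seed = derive_seed(seed, "flow-test"))
  sp <- split_fsc(ev)
  gate_enucleation(sp, cut[["syto16"]], cut[["aad7"]])
}
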