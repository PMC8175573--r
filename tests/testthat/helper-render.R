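# Shared fixtures built in code.

# Render one synthetic field with disks at given (row, col) centers (1-based
# matrix coordinates), all KuO+SYTO16+ / SYTOXRed-, on the default noisy
# background. Used as a brute-force oracle for detection edge cases.
field_with_disks <- function(centers, r = 4, amp = 10000, shape = c(128, 128),
                             bg_sd = 50, seed = 1) {
  set.seed(seed)
  tmpl <- enucleoscreen:::blurred_disk(r, 1)
  mk_bg <- function() matrix(200 + stats::rnorm(prod(shape), 0, bg_sd),
                             shape[1], shape[2])
  pos <- mk_bg(); neg <- mk_bg()
  for (i in seq_len(nrow(centers))) {
    p <- enucleoscreen:::patch_pixels(shape, tmpl, centers[i, 1], centers[i, 2])
    pos[p$idx] <- pos[p$idx] + amp * p$val
  }
  list(plate_id = "P", well_address = "W", field_index = 0L,
       channels = list(KuO = pos, SYTO16 = pos, SYTOXRed = neg))
}

# Noiseless intensity model: fixed amplitudes, clean background.
noiseless_model <- function() {
  default_intensity_model(sdlog = 0, bg_sd = 0)
}

# A balanced four-state composition handy for mixed-well tests.
mixed_truth <- function(total_cells, well = "M01") {
  well_truth(total_cells,
             c(viable_nucleated = 0.55, enucleated = 0.25,
               dead_cell = 0.1, free_nucleus = 0.1),
             well_address = well)
}

# Channel cutoffs calibrated from one default-noise vehicle control well.
thr_from_default_controls <- function(seed = 1, total_cells = 800, n_fields = 2) {
  ctrl <- preset_well_truth("dmso", total_cells)
  ctrl$well_address <- "CTRL"
  rc <- render_field_images(ctrl, n_fields = n_fields,
                            image_shape = c(768, 768), seed = seed,
                            well_address = "CTRL")
  calibrate_thresholds(detect_well(rc$fields))
}

# Match detections to ground-truth objects within `tol` pixels; returns
# counts used for recall/precision.
match_detections <- function(objects, gt, tol = 3) {
  if (nrow(objects) == 0 || nrow(gt) == 0)
    return(list(tp = 0, fn = nrow(gt), fp = nrow(objects)))
  tp <- 0L
  used <- rep(FALSE, nrow(objects))
  for (i in seq_len(nrow(gt))) {
    d2 <- (objects$row - gt$row[i])^2 + (objects$col - gt$col[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= tol^2) { tp <- tp + 1L; used[j] <- TRUE }
  }
  list(tp = tp, fn = nrow(gt) - tp, fp = sum(!used))
}
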