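# Plain-text interchange: plate maps, object tables, counts and hit tables are
# CSV; ground truth and thresholds are JSON; field images are 16-bit TIFF, one
# file per plate/well/field/channel.

#' @rdname screen_io
#' @param plate_map,path See details.
#' @export
write_plate_map <- function(plate_map, path) {
  utils::write.csv(plate_map, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write screen interchange files
#'
#' Plate maps, object tables, state-count tables and hit tables round-trip
#' through CSV; per-well ground truth and calibrated thresholds through JSON.
#'
#' @name screen_io
#' @param x Object to write.
#' @return Readers return the parsed object; writers return `path` invisibly.
#' @export
read_plate_map <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  m$well <- as.character(m$well)
  m
}

#' @rdname screen_io
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname screen_io
#' @export
write_well_truth <- function(x, path) {
  if (inherits(x, "well_truth")) x <- list(x)
  payload <- lapply(x, function(t) list(
    well_address = t$well_address, total_cells = t$total_cells,
    state_fractions = as.list(t$state_fractions),
    rupture_fraction = t$rupture_fraction))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_well_truth <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(t)
    well_truth(t$total_cells, unlist(t$state_fractions),
               rupture_fraction = t$rupture_fraction,
               well_address = t$well_address %||% NA_character_))
}

#' @rdname screen_io
#' @export
write_thresholds <- function(x, path) {
  jsonlite::write_json(list(cutoff = as.list(x$cutoff), plate_id = x$plate_id,
                            method = x$method),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_thresholds <- function(path) {
  p <- jsonlite::read_json(path)
  structure(list(cutoff = unlist(p$cutoff), plate_id = p$plate_id,
                 method = p$method),
            class = "channel_thresholds")
}

field_image_filename <- function(plate_id, well, field_index, channel) {
  sprintf("%s_%s_f%02d_%s.tif", plate_id, well, field_index, channel)
}

#' Write rendered field images as 16-bit grayscale TIFFs
#'
#' One file per plate/well/field/channel, named
#' `{plate}_{well}_f{field:02d}_{channel}.tif`.
#'
#' @param fields List of field images ([render_field_images()]`$fields`).
#' @param dir Output directory (created if missing).
#' @return The written file paths, invisibly.
#' @export
write_field_images <- function(fields, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (f in fields) {
    for (ch in names(f$channels)) {
      p <- file.path(dir, field_image_filename(f$plate_id, f$well_address,
                                               f$field_index, ch))
      EBImage::writeImage(EBImage::Image(f$channels[[ch]] / 65535), p,
                          type = "tiff", bits.per.sample = 16L)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read field images written by [write_field_images()]
#'
#' @param dir Directory of TIFFs.
#' @param plate_id,well_address Well to read.
#' @return A list of field images (same structure as
#'   [render_field_images()]`$fields`).
#' @export
read_field_images <- function(dir, plate_id, well_address) {
  pat <- sprintf("^%s_%s_f(\\d+)_(%s)\\.tif$", plate_id, well_address,
                 paste(CHANNELS, collapse = "|"))
  files <- list.files(dir, pattern = pat)
  stop_if_not(length(files) > 0, "no matching field images found")
  info <- regmatches(files, regexec(pat, files))
  fi <- as.integer(vapply(info, `[`, character(1), 2))
  ch <- vapply(info, `[`, character(1), 3)
  fields <- lapply(sort(unique(fi)), function(f) {
    chans <- lapply(CHANNELS, function(c0) {
      p <- file.path(dir, files[fi == f & ch == c0])
      stop_if_not(length(p) == 1, "missing channel image")
      round(as.matrix(EBImage::imageData(EBImage::readImage(p))) * 65535)
    })
    names(chans) <- CHANNELS
    list(plate_id = plate_id, well_address = well_address,
         field_index = f, channels = chans)
  })
  fields
}

#' @rdname screen_io
#' @export
write_flow_events <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_flow_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
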