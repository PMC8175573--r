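#' Classify a positivity triple into a cell state
#'
#' The three-signal truth table: the lineage reporter (KuO) marks all viable
#' cells of the line, the cell-permeant dye (SYTO 16) stains every nucleus,
#' and the cell-impermeant dye (SYTOX Red) stains nuclei of
#' membrane-compromised cells and extruded nuclei. The mapping is a total
#' function of the triple:
#'
#' | KuO | SYTO16 | SYTOXRed | state |
#' |-----|--------|----------|-------|
#' | +   | +      | -        | viable_nucleated |
#' | +   | -      | -        | enucleated |
#' | +   | +      | +        | dead_cell |
#' | -   | +      | +        | free_nucleus |
#' | any other triple |  |   | debris |
#'
#' The triple (KuO-, SYTO16+, SYTOXRed-) -- a membrane-intact nucleus-like
#' object without the reporter -- is debris by default; set
#' `orphan_nucleus_as_free = TRUE` to assign it to `free_nucleus`.
#'
#' @param kuo,syto16,sytoxred Logical vectors (recycled to a common length).
#' @param orphan_nucleus_as_free Reassign (KuO-, S16+, SX-) to `free_nucleus`.
#' @return Character vector of states.
#' @export
classify_object <- function(kuo, syto16, sytoxred, orphan_nucleus_as_free = FALSE) {
  n <- max(length(kuo), length(syto16), length(sytoxred))
  kuo <- rep_len(as.logical(kuo), n)
  syto16 <- rep_len(as.logical(syto16), n)
  sytoxred <- rep_len(as.logical(sytoxred), n)
  state <- rep("debris", n)
  state[kuo & syto16 & !sytoxred] <- "viable_nucleated"
  state[kuo & !syto16 & !sytoxred] <- "enucleated"
  state[kuo & syto16 & sytoxred] <- "dead_cell"
  state[!kuo & syto16 & sytoxred] <- "free_nucleus"
  if (orphan_nucleus_as_free) state[!kuo & syto16 & !sytoxred] <- "free_nucleus"
  state
}

#' Call per-channel positivity and classify detected objects
#'
#' @param objects Data.frame from [detect_objects()].
#' @param thresholds A `"channel_thresholds"` object from
#'   [calibrate_thresholds()].
#' @param orphan_nucleus_as_free See [classify_object()].
#' @return `objects` with added logical `pos_<channel>` columns and a `state`
#'   column.
#' @export
classify_objects <- function(objects, thresholds, orphan_nucleus_as_free = FALSE) {
  stop_if_not(inherits(thresholds, "channel_thresholds"),
              "thresholds must come from calibrate_thresholds()")
  for (ch in names(thresholds$cutoff))
    objects[[paste0("pos_", ch)]] <-
      objects[[paste0("mean_", ch)]] > thresholds$cutoff[[ch]]
  objects$state <- classify_object(objects$pos_KuO, objects$pos_SYTO16,
                                   objects$pos_SYTOXRed,
                                   orphan_nucleus_as_free)
  objects
}

#' Aggregate classified objects into per-well state counts
#'
#' @param objects Classified objects for a single well (a `state` column).
#' @param exclude_border Drop objects flagged `touches_border` before counting
#'   (partial objects bias intensity means; fields are a sample, so exclusion
#'   is unbiased).
#' @return A one-row data.frame: `plate_id`, `well_address`, one column per
#'   state (including `debris`), and `n_objects_total`. Counts always sum to
#'   the total.
#' @export
count_well <- function(objects, exclude_border = TRUE) {
  wells <- unique(stats::na.omit(objects$well_address))
  stop_if_not(length(wells) <= 1, "count_well expects objects from one well")
  if (exclude_border && nrow(objects) > 0)
    objects <- objects[!objects$touches_border, , drop = FALSE]
  counts <- vapply(ALL_STATES, function(s) sum(objects$state == s), integer(1))
  out <- data.frame(plate_id = if (nrow(objects)) objects$plate_id[1] else NA_character_,
                    well_address = if (length(wells)) wells else NA_character_,
                    stringsAsFactors = FALSE)
  for (s in ALL_STATES) out[[s]] <- counts[[s]]
  out$n_objects_total <- sum(counts)
  out
}

#' Enucleation frequency of a well
#'
#' Two denominator conventions are retained because the assay description
#' admits both:
#' \describe{
#'   \item{`methods`}{enucleated / (viable nucleated + enucleated): cells
#'     expressing the reporter and negative for the impermeant dye. Default.}
#'   \item{`kuo_total`}{enucleated / (viable nucleated + enucleated +
#'     dead cells): all reporter-positive events. Dead cells classified by the
#'     truth table are KuO-positive by construction.}
#' }
#'
#' @param counts One-row data.frame from [count_well()] (or several rows; the
#'   result is vectorized by row).
#' @param denominator_mode `"methods"` or `"kuo_total"`.
#' @return Numeric vector in `[0, 1]`; `NA` for wells with a zero denominator
#'   (flagged, to be excluded from fold computation).
#' @export
enucleation_frequency <- function(counts, denominator_mode = c("methods", "kuo_total")) {
  denominator_mode <- match.arg(denominator_mode)
  den <- counts$viable_nucleated + counts$enucleated
  if (denominator_mode == "kuo_total") den <- den + counts$dead_cell
  ifelse(den > 0, counts$enucleated / den, NA_real_)
}
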