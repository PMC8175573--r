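#' Score wells: enucleation frequency and reporter-positive cell count
#'
#' @param counts Data.frame of per-well state counts (rows from
#'   [count_well()]), joined with the plate map.
#' @param plate_map Plate map data.frame (see [make_plate_layouts()]).
#' @param denominator_mode Passed to [enucleation_frequency()].
#' @return Data.frame of well scores: plate map columns plus `enuc_freq` and
#'   `kuo_cell_count` (viable nucleated + enucleated + dead, all
#'   reporter-positive under the truth table).
#' @export
well_scores <- function(counts, plate_map, denominator_mode = "methods") {
  m <- merge(plate_map, counts, by.x = c("plate_id", "well"),
             by.y = c("plate_id", "well_address"), sort = FALSE)
  m$enuc_freq <- enucleation_frequency(m, denominator_mode)
  m$kuo_cell_count <- m$viable_nucleated + m$enucleated + m$dead_cell
  m
}

#' Plate-normalized fold changes against in-plate DMSO controls
#'
#' Each well's enucleation frequency and reporter-positive cell count are
#' divided by the mean of the DMSO control wells of the same plate --
#' controls of the matching DMSO volume class when that class has scorable
#' wells, pooled controls otherwise. DMSO wells receive folds relative to
#' their own class mean, so the average control fold is 1 by construction.
#' Wells with an undefined frequency (zero denominator) are dropped with a
#' warning.
#'
#' @param scores Data.frame from [well_scores()] for one or more plates.
#' @return `scores` (minus unscorable wells and empties) with `enuc_fold` and
#'   `cellnum_fold` columns.
#' @export
fold_changes <- function(scores) {
  scores <- scores[scores$role %in% c("test", "dmso"), , drop = FALSE]
  bad <- is.na(scores$enuc_freq)
  if (any(bad)) {
    warning(sprintf("dropping %d unscorable well(s) with zero denominator", sum(bad)))
    scores <- scores[!bad, , drop = FALSE]
  }
  out <- lapply(split(scores, scores$plate_id), function(p) {
    ctrl <- p[p$role == "dmso", , drop = FALSE]
    stop_if_not(nrow(ctrl) >= 2, sprintf("plate %s: need >= 2 scorable DMSO wells",
                                         p$plate_id[1]))
    class_means <- function(cls) {
      cc <- ctrl[ctrl$dmso_volume_class == cls, , drop = FALSE]
      if (nrow(cc) == 0) cc <- ctrl   # pool when the class has no controls
      c(freq = mean(cc$enuc_freq), count = mean(cc$kuo_cell_count))
    }
    mm <- vapply(unique(p$dmso_volume_class), class_means, numeric(2))
    if (any(mm["freq", ] == 0) || any(mm["count", ] == 0))
      stop(sprintf("plate %s: zero control mean; plate unscorable", p$plate_id[1]),
           call. = FALSE)
    ref <- mm[, p$dmso_volume_class, drop = FALSE]
    p$enuc_fold <- p$enuc_freq / ref["freq", ]
    p$cellnum_fold <- p$kuo_cell_count / ref["count", ]
    p
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call hit compounds by the dual enucleation/viability criterion
#'
#' A compound x concentration is a hit when its enucleation fold change
#' exceeds `enuc_threshold` (strictly: "more than") and its cell-number fold
#' is at least `cellnum_threshold` (inclusive: "not less than"). The defaults
#' are the screen's published thresholds (9.0 and 0.25).
#'
#' @param folds Data.frame with columns `name`, `concentration_uM`,
#'   `enuc_fold`, `cellnum_fold` (e.g. the test rows of [fold_changes()]).
#' @param enuc_threshold Strict lower bound on the enucleation fold.
#' @param cellnum_threshold Inclusive lower bound on the cell-number fold.
#' @return `folds` with a logical `is_hit` column.
#' @export
call_hits <- function(folds, enuc_threshold = 9.0, cellnum_threshold = 0.25) {
  stop_if_not(all(is.finite(folds$enuc_fold)) && all(is.finite(folds$cellnum_fold)),
              "folds must be finite")
  folds$is_hit <- folds$enuc_fold > enuc_threshold &
    folds$cellnum_fold >= cellnum_threshold
  folds
}

#' Ranked hit report
#'
#' Rows sorted by enucleation fold descending, ties broken by cell-number fold
#' descending, then name ascending; folds rendered to two decimals, half-up.
#'
#' @param hits Data.frame from [call_hits()].
#' @param hits_only Keep only rows with `is_hit`.
#' @return Ordered data.frame with columns `name`, `concentration_uM`,
#'   `enucleation_fold`, `cellnum_fold`, `is_hit`.
#' @export
rank_report <- function(hits, hits_only = FALSE) {
  if (hits_only && nrow(hits) > 0) hits <- hits[hits$is_hit, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(name = character(), concentration_uM = numeric(),
                      enucleation_fold = numeric(), cellnum_fold = numeric(),
                      is_hit = logical()))
  o <- order(-hits$enuc_fold, -hits$cellnum_fold, hits$name)
  hits <- hits[o, , drop = FALSE]
  out <- data.frame(name = hits$name,
                    concentration_uM = hits$concentration_uM,
                    enucleation_fold = round_half_up(hits$enuc_fold, 2),
                    cellnum_fold = round_half_up(hits$cellnum_fold, 2),
                    is_hit = hits$is_hit,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
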