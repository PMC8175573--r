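#' Split flow events into FSC-low and FSC-high groups
#'
#' Events below the `debris_floor` FSC percentile are discarded as debris.
#' The remainder is partitioned on log FSC either by a deterministic 1-D
#' 2-means (`"kmeans2"`, centers initialized at the sample extremes) or at a
#' fixed cutoff. If 2-means cannot find two separable groups (center
#' separation below 2 pooled within-group SDs, e.g. unimodal or constant
#' FSC), the split falls back to the fixed cutoff with a warning.
#'
#' @param events Data.frame from [simulate_flow_events()] (needs `fsc`).
#' @param debris_floor Percentile (0-100) of FSC below which events are debris.
#' @param split `"kmeans2"` or `"fixed"`.
#' @param fixed_cutoff FSC cutoff used for `split = "fixed"` and as fallback.
#' @param min_events Minimum events required after debris removal.
#' @return List with `low` and `high` event data.frames, the `cutoff` used,
#'   and `n_debris`.
#' @export
split_fsc <- function(events, debris_floor = 2, split = c("kmeans2", "fixed"),
                      fixed_cutoff = 5.5, min_events = 100) {
  split <- match.arg(split)
  floor_val <- stats::quantile(events$fsc, debris_floor / 100)
  keep <- events[events$fsc > floor_val, , drop = FALSE]
  if (nrow(keep) == 0) keep <- events    # degenerate: all identical FSC
  stop_if_not(nrow(keep) >= min_events,
              sprintf("need >= %d events after debris removal", min_events))
  cutoff <- fixed_cutoff
  if (split == "kmeans2") {
    lx <- log(keep$fsc)
    km <- if (diff(range(lx)) > 0) kmeans_1d(lx) else list(separation = 0)
    if (km$separation >= 2) {
      # boundary strictly between the two mode centers
      cutoff <- exp(mean(km$centers))
    } else {
      warning("FSC groups not separable; falling back to fixed cutoff")
    }
  }
  list(low = keep[keep$fsc < cutoff, , drop = FALSE],
       high = keep[keep$fsc >= cutoff, , drop = FALSE],
       cutoff = cutoff, n_debris = nrow(events) - nrow(keep))
}

#' Quadrant gating and flow-based enucleation efficiency
#'
#' Enucleated cells are events negative for both the permeant dye (SYTO 16)
#' and the impermeant dye (7AAD). The enucleation percentage is computed over
#' all gated events, FSC-high and FSC-low together:
#' `100 x (SYTO16- 7AAD- events) / (FSC-high + FSC-low events)`.
#'
#' @param fsc_split Result of [split_fsc()].
#' @param syto16_cutoff,aad7_cutoff Positivity cutoffs, typically calibrated
#'   from a vehicle/unstained reference with [calibrate_thresholds()] (same
#'   histogram-split approach on log signals).
#' @return A list of class `"gate_result"`: `n_events`, per-FSC-group quadrant
#'   count matrices (`quadrants_low`, `quadrants_high`, rows SYTO16-/+ by
#'   columns 7AAD-/+), and `enucleation_pct`.
#' @export
gate_enucleation <- function(fsc_split, syto16_cutoff, aad7_cutoff) {
  quad <- function(ev) {
    s <- factor(ifelse(ev$syto16 > syto16_cutoff, "SYTO16+", "SYTO16-"),
                levels = c("SYTO16-", "SYTO16+"))
    a <- factor(ifelse(ev$aad7 > aad7_cutoff, "7AAD+", "7AAD-"),
                levels = c("7AAD-", "7AAD+"))
    table(s, a)
  }
  ql <- quad(fsc_split$low)
  qh <- quad(fsc_split$high)
  n <- nrow(fsc_split$low) + nrow(fsc_split$high)
  if (n == 0) {
    warning("no gated events; enucleation percentage undefined")
    pct <- NA_real_
  } else {
    pct <- 100 * (ql["SYTO16-", "7AAD-"] + qh["SYTO16-", "7AAD-"]) / n
  }
  structure(list(n_events = n, quadrants_low = ql, quadrants_high = qh,
                 enucleation_pct = as.numeric(pct)),
            class = "gate_result")
}

#' Calibrate flow dye cutoffs from a reference event table
#'
#' Applies the same Otsu histogram split used for imaging channels to the log
#' signals of a reference (vehicle) event table.
#'
#' @param reference_events Data.frame with `syto16` and `aad7` columns.
#' @return Named numeric vector with `syto16` and `aad7` cutoffs.
#' @export
calibrate_flow_cutoffs <- function(reference_events) {
  vapply(c("syto16", "aad7"), function(s) {
    o <- otsu_threshold(log10(pmax(reference_events[[s]], 1e-6)), 256)
    10^o$threshold
  }, numeric(1))
}
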