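#' Detect objects in a multi-channel field image
#'
#' Detection runs on the pixel-wise maximum across channels, so objects bright
#' in any single channel (KuO-only enucleated cells, dye-only free nuclei) are
#' all found. The maximum projection is background-subtracted (per-image median
#' estimate), thresholded at `thr_k` robust standard deviations above
#' background, and touching objects are split by a watershed on the distance
#' map of the foreground mask, with the watershed neighbourhood set from
#' `min_separation`. Per-object mean channel intensities are measured over the
#' object mask after subtracting each channel's own median background.
#'
#' @param image A field image: list with `channels`, a named list of equal-size
#'   numeric matrices (see [render_field_images()]).
#' @param min_area Minimum object area in pixels; smaller detections are
#'   discarded (fragment/debris floor).
#' @param min_separation Minimum distance (pixels) between intensity peaks for
#'   touching objects to be split.
#' @param thr_k Foreground threshold in robust (MAD) standard deviations above
#'   the background median.
#' @return A data.frame with one row per detected object: `plate_id`,
#'   `well_address`, `field_index`, `object`, `row`, `col` (0-based centroid),
#'   `area`, `touches_border`, plus `mean_<channel>` and `total_<channel>`
#'   background-subtracted intensities.
#' @export
detect_objects <- function(image, min_area = 20, min_separation = 5,
                           thr_k = 6) {
  stop_if_not(min_area > 0, "min_area must be positive")
  chans <- image$channels
  dims <- lapply(chans, dim)
  stop_if_not(length(unique(dims)) == 1, "channel images must share one shape")

  mx <- Reduce(pmax, chans)
  bg_med <- stats::median(mx)
  bg_sd <- stats::mad(mx)
  mask <- (mx - bg_med) > (thr_k * max(bg_sd, 1))

  empty <- data.frame(plate_id = character(), well_address = character(),
                      field_index = integer(), object = integer(),
                      row = numeric(), col = numeric(), area = integer(),
                      touches_border = logical())
  for (ch in names(chans)) {
    empty[[paste0("mean_", ch)]] <- numeric()
    empty[[paste0("total_", ch)]] <- numeric()
  }
  if (!any(mask)) return(empty)

  d <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(EBImage::watershed(d, tolerance = 1,
                                               ext = max(1L, as.integer(min_separation))))
  lab_v <- as.integer(lab)
  areas <- tabulate(lab_v)
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return(empty)

  nr <- nrow(lab)
  nc <- ncol(lab)
  px <- which(lab_v > 0L)
  lv <- lab_v[px]
  sel <- lv %in% keep
  px <- px[sel]
  lv <- lv[sel]
  # compact labels
  lid <- match(lv, keep)
  rows0 <- (px - 1L) %% nr          # 0-based row
  cols0 <- (px - 1L) %/% nr         # 0-based col
  n_obj <- length(keep)
  cnt <- tabulate(lid, n_obj)
  cen_r <- tapply_sum(rows0, lid, n_obj) / cnt
  cen_c <- tapply_sum(cols0, lid, n_obj) / cnt
  border <- tapply_sum(as.numeric(rows0 == 0L | rows0 == nr - 1L |
                                    cols0 == 0L | cols0 == nc - 1L),
                       lid, n_obj) > 0

  out <- data.frame(
    plate_id = image$plate_id %||% NA_character_,
    well_address = image$well_address %||% NA_character_,
    field_index = image$field_index %||% NA_integer_,
    object = seq_len(n_obj),
    row = as.numeric(cen_r), col = as.numeric(cen_c),
    area = cnt, touches_border = as.logical(border),
    stringsAsFactors = FALSE
  )
  for (ch in names(chans)) {
    v <- as.numeric(chans[[ch]])[px] - stats::median(chans[[ch]])
    tot <- tapply_sum(v, lid, n_obj)
    out[[paste0("mean_", ch)]] <- tot / cnt
    out[[paste0("total_", ch)]] <- tot
  }
  out
}

# group sums of x by integer group id g, over groups 1..n (absent groups -> 0)
tapply_sum <- function(x, g, n) {
  s <- rowsum(x, g)
  out <- numeric(n)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Otsu threshold of a numeric sample over a binned histogram
#'
#' Maximizes the between-class variance over the boundaries of an `n_bins`
#' equal-width histogram. Returns the threshold on the input scale.
#'
#' @param x Numeric vector.
#' @param n_bins Number of histogram bins.
#' @return List with `threshold` and `eta`, the fraction of total variance
#'   explained by the best split (a separability score in `[0, 1]`).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  stop_if_not(length(x) >= 2, "need at least 2 values")
  rng <- range(x)
  if (diff(rng) == 0) return(list(threshold = rng[1], eta = 0))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins),
                n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- h / sum(h)
  mu <- cumsum(w * mids)
  om <- cumsum(w)
  mu_t <- mu[n_bins]
  # between-class variance at each cut (classes: bins <= k vs > k)
  valid <- om > 0 & om < 1
  sigma_b <- rep(-Inf, n_bins - 1)
  k <- which(valid[-n_bins])
  sigma_b[k] <- (mu_t * om[k] - mu[k])^2 / (om[k] * (1 - om[k]))
  best <- which.max(sigma_b)
  total_var <- sum(w * (mids - mu_t)^2)
  list(threshold = edges[best + 1],
       eta = if (total_var > 0) max(sigma_b) / total_var else 0)
}

#' Calibrate per-channel positivity cutoffs from vehicle-control objects
#'
#' Cutoffs are derived per plate from the DMSO control wells only, mirroring
#' the screen's in-plate normalization philosophy. Calibration works on
#' log10 mean intensities; each channel of a control population contains both
#' negative and positive objects (e.g. the impermeant dye is positive only on
#' the few dead cells and free nuclei), giving a bimodal histogram whose modes
#' the cutoff separates.
#'
#' @param control_objects Data.frame of objects from DMSO wells (output of
#'   [detect_objects()]), with `mean_<channel>` columns.
#' @param method `"otsu"` (between-class variance over a 256-bin histogram of
#'   log-intensities) or `"quantile_midpoint"` (geometric mean of the 10th
#'   percentile of the positive mode and the 90th percentile of the negative
#'   mode, modes seeded by a deterministic 1-D 2-means split).
#' @param channels Channels to calibrate.
#' @param min_objects Minimum number of control objects required.
#' @param min_gap Minimum separation between the split modes: the 5th
#'   percentile of the upper class must exceed the 95th percentile of the
#'   lower class by at least `min_gap` total standard deviations. A channel
#'   below this is considered unimodal and calibration fails with an error
#'   instructing a manual cutoff (a unimodal Gaussian scores about 0.1, well
#'   under the default; cleanly bimodal channels score far above it even when
#'   one mode holds only a few percent of objects).
#' @return A list of class `"channel_thresholds"`: per-channel `cutoff` on the
#'   intensity scale, plus `plate_id` and `method` provenance.
#' @export
calibrate_thresholds <- function(control_objects, method = c("otsu", "quantile_midpoint"),
                                 channels = CHANNELS, min_objects = 50,
                                 min_gap = 0.5) {
  method <- match.arg(method)
  stop_if_not(nrow(control_objects) >= min_objects,
              sprintf("need >= %d control objects for calibration", min_objects))
  cutoffs <- numeric(0)
  for (ch in channels) {
    col <- paste0("mean_", ch)
    stop_if_not(col %in% names(control_objects),
                sprintf("missing column %s", col))
    lx <- log10(pmax(control_objects[[col]], 1))
    if (diff(range(lx)) == 0)
      stop(sprintf("channel %s: constant intensities; set a manual cutoff", ch),
           call. = FALSE)
    if (method == "otsu") {
      o <- otsu_threshold(lx, 256)
      cut <- o$threshold
      lo <- lx[lx <= cut]
      hi <- lx[lx > cut]
      gap <- if (length(lo) == 0 || length(hi) == 0) -Inf else
        (stats::quantile(hi, 0.05) - stats::quantile(lo, 0.95)) / stats::sd(lx)
      if (gap < min_gap)
        stop(sprintf(paste0("channel %s: control intensities look unimodal ",
                            "(mode gap %.2f < %.2f sd); set a manual cutoff"),
                     ch, gap, min_gap), call. = FALSE)
    } else {
      km <- kmeans_1d(lx)
      if (km$separation < 2)
        stop(sprintf("channel %s: modes not separable; set a manual cutoff", ch),
             call. = FALSE)
      neg <- lx[km$cluster == 1]
      pos <- lx[km$cluster == 2]
      cut <- (stats::quantile(pos, 0.10) + stats::quantile(neg, 0.90)) / 2
    }
    cutoffs[ch] <- 10^cut
  }
  structure(list(cutoff = cutoffs,
                 plate_id = unique(control_objects$plate_id)[1],
                 method = method),
            class = "channel_thresholds")
}

# deterministic 1-D 2-means: centers initialized at the sample extremes
kmeans_1d <- function(x, iter = 50) {
  c1 <- min(x); c2 <- max(x)
  for (i in seq_len(iter)) {
    cl <- ifelse(abs(x - c1) <= abs(x - c2), 1L, 2L)
    n1 <- mean(x[cl == 1L]); n2 <- mean(x[cl == 2L])
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) break
    c1 <- n1; c2 <- n2
  }
  v1 <- stats::var(x[cl == 1L]); if (is.na(v1)) v1 <- 0
  v2 <- stats::var(x[cl == 2L]); if (is.na(v2)) v2 <- 0
  s <- sqrt(stats::weighted.mean(c(v1, v2), c(sum(cl == 1L), sum(cl == 2L))))
  list(cluster = cl, centers = c(c1, c2),
       separation = if (is.finite(s) && s > 0) (c2 - c1) / s else Inf)
}
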