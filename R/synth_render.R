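# --- object templates -------------------------------------------------------

# Disk of radius r convolved with a Gaussian PSF, as a small matrix whose sum
# equals the disk area (the PSF redistributes but conserves signal).
blurred_disk <- function(r, psf_sigma) {
  half <- r + max(1L, ceiling(4 * psf_sigma))
  x <- -half:half
  D <- outer(x, x, function(i, j) (i^2 + j^2 <= r^2) * 1)
  if (psf_sigma > 0) {
    g <- stats::dnorm(0:(2 * half), sd = psf_sigma)
    g <- g / (g[1] + 2 * sum(g[-1]))
    # direct "same" separable convolution; patch margin makes truncation negligible
    C <- matrix(g[abs(outer(x, x, "-")) + 1], length(x))
    D <- C %*% D %*% t(C)
  }
  D
}

# cache templates per (radius, sigma) within one render call
template_cache <- function(psf_sigma) {
  cache <- new.env(parent = emptyenv())
  function(r) {
    key <- as.character(r)
    if (is.null(cache[[key]])) cache[[key]] <- blurred_disk(r, psf_sigma)
    cache[[key]]
  }
}

# dart-throwing placement of n centers with a minimum pairwise distance;
# the separation constraint is relaxed stepwise if the field is too crowded
place_centers <- function(n, shape, margin, min_dist) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 300L * max(n, 1L)
  while (placed < n) {
    p <- c(stats::runif(1, margin, shape[1] - 1 - margin),
           stats::runif(1, margin, shape[2] - 1 - margin))
    ok <- placed == 0L ||
      min((pts[seq_len(placed), 1] - p[1])^2 + (pts[seq_len(placed), 2] - p[2])^2) >= min_dist^2
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- p
    }
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      min_dist <- max(min_dist - 2, 2)
      attempts <- 0L
    }
  }
  pts
}

# linear indices and template values of a patch at integer center (r0, c0),
# 0-based, clipped at the image borders
patch_pixels <- function(shape, tmpl, r0, c0) {
  half <- (nrow(tmpl) - 1L) %/% 2L
  rr <- (r0 - half):(r0 + half) + 1L
  cc <- (c0 - half):(c0 + half) + 1L
  keep_r <- rr >= 1L & rr <= shape[1]
  keep_c <- cc >= 1L & cc <= shape[2]
  sub <- tmpl[keep_r, keep_c, drop = FALSE]
  idx <- outer(rr[keep_r], (cc[keep_c] - 1L) * shape[1], "+")
  list(idx = as.integer(idx), val = as.numeric(sub))
}

# --- field rendering --------------------------------------------------------

#' Render a well's cells as multi-channel fluorescence field images
#'
#' Cells are allocated multinomially across fields (the fields are treated as a
#' census of the well, so ground-truth object counts are conserved exactly),
#' placed with a minimum pairwise separation, and rendered in each channel as a
#' PSF-blurred disk whose amplitude is log-normal around the state- and
#' channel-dependent median of `intensity_model`. A `rupture_fraction` of the
#' enucleated cells is rendered as 2-5 small fragments instead of a single
#' disk, emulating damaged enucleated cells whose fragments typically fall
#' below the detection area floor.
#'
#' @param truth A `"well_truth"` object.
#' @param n_fields Number of fields imaged per well.
#' @param image_shape `(rows, cols)` of each field in pixels.
#' @param intensity_model From [default_intensity_model()].
#' @param seed Integer seed; renders are bit-reproducible.
#' @param min_separation Minimum distance between object centers, pixels.
#' @param plate_id,well_address Identifiers stamped on the output.
#' @return A list with `fields` (one element per field: `plate_id`,
#'   `well_address`, `field_index`, `channels` = named list of numeric
#'   matrices on the 16-bit scale) and `objects`, the ground-truth table with
#'   one row per cell: `field_index` (0-based), `object_id`, `row`, `col`
#'   (0-based pixel coordinates), `state`, `ruptured`.
#' @export
render_field_images <- function(truth, n_fields = 50,
                                image_shape = c(1024, 1024),
                                intensity_model = default_intensity_model(),
                                seed = 1, min_separation = 14,
                                plate_id = "P001",
                                well_address = truth$well_address) {
  stop_if_not(n_fields >= 1, "n_fields must be >= 1")
  validate_intensity_model(intensity_model)
  m <- intensity_model
  set.seed(derive_seed(seed, "render", plate_id, well_address))

  n <- truth$total_cells
  states <- if (n > 0)
    sample(STATES, n, replace = TRUE, prob = truth$state_fractions) else character()
  field_of <- if (n > 0) sample.int(n_fields, n, replace = TRUE) else integer()
  ruptured <- states == "enucleated" & stats::runif(n) < truth$rupture_fraction

  tmpl <- template_cache(m$psf_sigma)
  margin <- max(m$radius) + max(1, ceiling(4 * m$psf_sigma))

  gt <- vector("list", n_fields)
  fields <- vector("list", n_fields)
  obj_id <- 0L
  for (f in seq_len(n_fields)) {
    idx <- which(field_of == f)
    nf <- length(idx)
    chans <- lapply(CHANNELS, function(ch) {
      bg <- matrix(m$bg_offset, image_shape[1], image_shape[2])
      if (m$bg_sd > 0)
        bg <- bg + matrix(stats::rnorm(prod(image_shape), 0, m$bg_sd),
                          image_shape[1], image_shape[2])
      bg
    })
    names(chans) <- CHANNELS
    if (nf > 0) {
      pts <- place_centers(nf, image_shape, margin, min_separation)
      # accumulate per-object patches as (index, value) pairs, then add once
      pix <- vector("list", nf)
      amps <- matrix(0, nf, length(CHANNELS))
      for (k in seq_len(nf)) {
        st <- states[idx[k]]
        pos <- m$positivity[st, ]
        if (st == "dead_cell" && m$dead_kuo_pos < 1)
          pos[["KuO"]] <- stats::runif(1) < m$dead_kuo_pos
        med <- ifelse(pos[CHANNELS], m$pos_median, m$neg_median)
        amps[k, ] <- if (m$sdlog > 0)
          stats::rlnorm(length(CHANNELS), log(med), m$sdlog) else med
        r0 <- as.integer(round(pts[k, 1]))
        c0 <- as.integer(round(pts[k, 2]))
        if (ruptured[idx[k]]) {
          # damaged cells scatter into a few dim, pixel-scale fragments
          # (each carrying 2-10% of the parent amplitude) whose masks stay
          # below the detection area floor
          nfrag <- sample(2:5, 1)
          dr <- as.integer(round(stats::runif(nfrag, -8, 8)))
          dc <- as.integer(round(stats::runif(nfrag, -8, 8)))
          dim_frac <- stats::runif(nfrag, 0.02, 0.10)
          pp <- lapply(seq_len(nfrag), function(j) {
            p <- patch_pixels(image_shape, tmpl(1L), r0 + dr[j], c0 + dc[j])
            p$val <- p$val * dim_frac[j]
            p
          })
          pix[[k]] <- list(idx = unlist(lapply(pp, `[[`, "idx")),
                           val = unlist(lapply(pp, `[[`, "val")))
        } else {
          pix[[k]] <- patch_pixels(image_shape, tmpl(m$radius[[st]]), r0, c0)
        }
      }
      all_idx <- unlist(lapply(pix, `[[`, "idx"))
      npx <- lengths(lapply(pix, `[[`, "idx"))
      base_val <- unlist(lapply(pix, `[[`, "val"))
      for (ci in seq_along(CHANNELS)) {
        acc <- rowsum(base_val * rep.int(amps[, ci], npx), all_idx)
        at <- as.integer(rownames(acc))
        chans[[ci]][at] <- chans[[ci]][at] + acc[, 1]
      }
      gt[[f]] <- data.frame(field_index = f - 1L,
                            object_id = obj_id + seq_len(nf),
                            row = pts[, 1], col = pts[, 2],
                            state = states[idx], ruptured = ruptured[idx],
                            stringsAsFactors = FALSE)
      obj_id <- obj_id + nf
    }
    chans <- lapply(chans, function(x) pmin(pmax(round(x), 0), 65535))
    fields[[f]] <- list(plate_id = plate_id, well_address = well_address,
                        field_index = f - 1L, channels = chans)
  }
  objects <- do.call(rbind, gt[!vapply(gt, is.null, logical(1))])
  if (is.null(objects))
    objects <- data.frame(field_index = integer(), object_id = integer(),
                          row = numeric(), col = numeric(),
                          state = character(), ruptured = logical())
  list(fields = fields, objects = objects)
}
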