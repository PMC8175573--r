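test_that("a background-only image yields no detections", {
  ob <- detect_objects(field_with_disks(matrix(numeric(), 0, 2)))
  expect_equal(nrow(ob), 0)
  expect_true(all(c("row", "col", "area", "mean_KuO") %in% names(ob)))
})

test_that("channel shape mismatch and bad parameters are rejected", {
  f <- field_with_disks(rbind(c(60, 60)))
  f$channels$KuO <- f$channels$KuO[1:64, ]
  expect_error(detect_objects(f), "shape")
  expect_error(detect_objects(field_with_disks(rbind(c(60, 60))), min_area = 0),
               "min_area")
})

test_that("rendered disks are each recovered at their ground-truth centroid", {
  cen <- as.matrix(expand.grid(seq(20, 100, by = 20), seq(20, 100, by = 20)))
  f <- field_with_disks(cen, shape = c(128, 128), seed = 4)
  ob <- detect_objects(f)
  expect_equal(nrow(ob), 25)
  for (i in seq_len(nrow(cen))) {
    d <- sqrt((ob$row - cen[i, 1])^2 + (ob$col - cen[i, 2])^2)
    expect_lt(min(d), 1.5)
  }
})

test_that("touching objects split at the separation the oracle predicts", {
  r <- 4
  two <- field_with_disks(rbind(c(60, 60), c(60, 60 + 2 * r + 2)), r = r, seed = 6)
  one <- field_with_disks(rbind(c(60, 60), c(60, 60)), r = r, seed = 6)
  expect_equal(nrow(detect_objects(two)), 2)
  expect_equal(nrow(detect_objects(one)), 1)
})

test_that("detection recall and precision reach 0.99 at screen density", {
  tr <- mixed_truth(300)
  rnd <- render_field_images(tr, n_fields = 3, image_shape = c(768, 768), seed = 11)
  expect_lte(max(table(rnd$objects$field_index)), 130)
  ob <- detect_well(rnd$fields)
  m <- match_detections(ob, rnd$objects)
  recall <- m$tp / (m$tp + m$fn)
  precision <- m$tp / (m$tp + m$fp)
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
})

test_that("mean intensities are invariant to a constant offset", {
  f <- field_with_disks(as.matrix(expand.grid(c(30, 90), c(30, 90))), seed = 8)
  f2 <- f
  f2$channels <- lapply(f$channels, function(x) x + 500)
  a <- detect_objects(f)
  b <- detect_objects(f2)
  expect_equal(nrow(a), nrow(b))
  expect_lt(max(abs(a$mean_KuO - b$mean_KuO)), 1)
  expect_lt(max(abs(a$mean_SYTOXRed - b$mean_SYTOXRed)), 1)
})

test_that("raising a cutoff never increases positive calls", {
  set.seed(42)
  ob <- data.frame(mean_KuO = rlnorm(400, log(1000), 1.5),
                   mean_SYTO16 = rlnorm(400, log(1000), 1.5),
                   mean_SYTOXRed = rlnorm(400, log(1000), 1.5))
  cuts <- sort(rlnorm(20, log(1000), 1))
  pos <- vapply(cuts, function(cu) {
    thr <- structure(list(cutoff = c(KuO = cu, SYTO16 = 500, SYTOXRed = 500),
                          plate_id = "P", method = "otsu"),
                     class = "channel_thresholds")
    sum(classify_objects(ob, thr)$pos_KuO)
  }, numeric(1))
  expect_true(all(diff(pos) <= 0))
})

test_that("otsu threshold matches an exhaustive search oracle", {
  sets <- list(c(1, 1, 2, 2, 3, 8, 9, 9),
               c(0.5, 0.7, 0.9, 1.0, 5.0, 5.2, 5.4, 9.9),
               c(2, 2, 2, 2, 2, 2, 2, 10))
  for (x in sets) {
    n_bins <- 8
    got <- otsu_threshold(x, n_bins)$threshold
    # oracle: naive between-class variance, recomputed from scratch at every
    # bin boundary of the same histogram
    edges <- seq(min(x), max(x), length.out = n_bins + 1)
    bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
    h <- tabulate(bin, n_bins)
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    best <- -Inf; best_cut <- NA
    for (k in 1:(n_bins - 1)) {
      n_lo <- sum(h[1:k]); n_hi <- sum(h[(k + 1):n_bins])
      if (n_lo == 0 || n_hi == 0) next
      mu_lo <- sum(h[1:k] * mids[1:k]) / n_lo
      mu_hi <- sum(h[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n_hi
      sb <- (n_lo * n_hi / sum(h)^2) * (mu_lo - mu_hi)^2
      if (sb > best) { best <- sb; best_cut <- edges[k + 1] }
    }
    expect_equal(got, best_cut)
  }
})

test_that("calibration separates control modes and rejects degenerate channels", {
  mk <- function(v) {
    ob <- data.frame(mean_KuO = v, mean_SYTO16 = v, mean_SYTOXRed = v,
                     plate_id = "P001")
    ob
  }
  v <- c(rep(300, 100), rep(10000, 100)) * exp(rnorm(200, 0, 0.05))
  thr <- calibrate_thresholds(mk(v))
  expect_true(all(thr$cutoff > 300 & thr$cutoff < 10000))
  thr2 <- calibrate_thresholds(mk(v), method = "quantile_midpoint")
  expect_true(all(thr2$cutoff > 300 & thr2$cutoff < 10000))
  expect_error(calibrate_thresholds(mk(rep(500, 100))), "manual cutoff")
  set.seed(1)
  expect_error(calibrate_thresholds(mk(rlnorm(2000, log(800), 0.3))),
               "unimodal")
  expect_error(calibrate_thresholds(mk(v[1:20])), "control objects")
})

test_that("calibration works at realistic control imbalance", {
  # vehicle wells: ~2% of objects negative in the reporter channel
  set.seed(5)
  v <- c(rlnorm(1960, log(5000), 0.4), rlnorm(40, log(80), 0.4))
  ob <- data.frame(mean_KuO = v, mean_SYTO16 = v, mean_SYTOXRed = v,
                   plate_id = "P001")
  thr <- calibrate_thresholds(ob)
  expect_gt(thr$cutoff[["KuO"]], quantile(v, 0.01))
  expect_lt(thr$cutoff[["KuO"]], 5000)
  expect_equal(sum(v > thr$cutoff[["KuO"]]), 1960, tolerance = 5)
})
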