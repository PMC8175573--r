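mk_scores <- function(ctrl_freq, test_freq, ctrl_count = 1000, test_count = 1000,
                      cls = "0.1%") {
  n_c <- length(ctrl_freq); n_t <- length(test_freq)
  data.frame(
    plate_id = "P001",
    well = sprintf("W%02d", seq_len(n_c + n_t)),
    role = c(rep("dmso", n_c), rep("test", n_t)),
    name = c(rep("DMSO", n_c), sprintf("cpd%d", seq_len(n_t))),
    concentration_uM = c(rep(NA, n_c), rep(10, n_t)),
    dmso_volume_class = cls,
    enuc_freq = c(ctrl_freq, test_freq),
    kuo_cell_count = c(rep_len(ctrl_count, n_c), rep_len(test_count, n_t)),
    stringsAsFactors = FALSE)
}

test_that("fold changes normalize to the in-plate DMSO mean", {
  f <- fold_changes(mk_scores(c(0.02, 0.02), 0.02))
  expect_equal(f$enuc_fold[f$role == "test"], 1.0)
  f2 <- fold_changes(mk_scores(c(0.01, 0.03), 0.18))
  expect_equal(f2$enuc_fold[f2$role == "test"], 9.0)
  # cell-number fold uses the control count mean
  f3 <- fold_changes(mk_scores(c(0.02, 0.02), 0.02, ctrl_count = 2000,
                               test_count = 500))
  expect_equal(f3$cellnum_fold[f3$role == "test"], 0.25)
})

test_that("DMSO wells average fold 1 per plate and folds are scale invariant", {
  set.seed(12)
  for (rep in 1:5) {
    sc <- mk_scores(runif(4, 0.01, 0.05), runif(8, 0.01, 0.4),
                    ctrl_count = round(runif(4, 800, 1200)),
                    test_count = round(runif(8, 200, 1500)))
    f <- fold_changes(sc)
    expect_equal(mean(f$enuc_fold[f$role == "dmso"]), 1.0)
    expect_equal(mean(f$cellnum_fold[f$role == "dmso"]), 1.0)
    sc2 <- sc
    sc2$enuc_freq <- sc2$enuc_freq * 3.7
    f2 <- fold_changes(sc2)
    expect_equal(f2$enuc_fold, f$enuc_fold)
  }
})

test_that("normalization is volume-class matched when classes have controls", {
  sc <- rbind(mk_scores(c(0.02, 0.02), 0.06, cls = "0.1%"),
              mk_scores(c(0.04, 0.04), 0.06, cls = "0.005%"))
  sc$well <- sprintf("W%02d", seq_len(nrow(sc)))
  f <- fold_changes(sc)
  tf <- f[f$role == "test", ]
  expect_equal(tf$enuc_fold[tf$dmso_volume_class == "0.1%"], 3.0)
  expect_equal(tf$enuc_fold[tf$dmso_volume_class == "0.005%"], 1.5)
})

test_that("degenerate plates fail loudly and unscorable wells are dropped", {
  expect_error(fold_changes(mk_scores(0.02, 0.02)), "DMSO")
  expect_error(fold_changes(mk_scores(c(0, 0), 0.02)), "zero control mean")
  sc <- mk_scores(c(0.02, 0.02), c(0.02, NA))
  expect_warning(f <- fold_changes(sc), "unscorable")
  expect_equal(sum(f$role == "test"), 1)
})

test_that("the dual hit criterion follows strict/inclusive boundary semantics", {
  folds <- data.frame(
    name = c("a", "b", "c", "d"), concentration_uM = 10,
    enuc_fold = c(11.60, 10.76, 9.0, 9.5),
    cellnum_fold = c(0.46, 0.27, 1.0, 0.24))
  h <- call_hits(folds)
  expect_equal(h$is_hit, c(TRUE, TRUE, FALSE, FALSE))
  # inclusive viability floor: exactly 0.25 passes
  h2 <- call_hits(data.frame(name = "e", concentration_uM = 10,
                             enuc_fold = 9.01, cellnum_fold = 0.25))
  expect_true(h2$is_hit)
  expect_error(call_hits(data.frame(name = "f", concentration_uM = 10,
                                    enuc_fold = NA, cellnum_fold = 1)),
               "finite")
})

test_that("every published hit satisfies the dual criterion", {
  tab <- reference_hit_table()
  expect_equal(nrow(tab), 40)
  h <- call_hits(data.frame(name = tab$name,
                            concentration_uM = tab$concentration_uM,
                            enuc_fold = tab$enucleation_fold,
                            cellnum_fold = tab$cellnum_fold))
  expect_true(all(h$is_hit))
})

test_that("the hit set is monotone under threshold shifts", {
  set.seed(77)
  folds <- data.frame(name = sprintf("c%03d", 1:200), concentration_uM = 10,
                      enuc_fold = rlnorm(200, log(3), 1),
                      cellnum_fold = rlnorm(200, log(0.6), 0.7))
  for (thr in c(5, 9, 12)) {
    at_thr <- call_hits(folds, enuc_threshold = thr)$is_hit
    stricter <- call_hits(folds, enuc_threshold = thr + 1)$is_hit
    looser_cn <- call_hits(folds, enuc_threshold = thr,
                           cellnum_threshold = 0.1)$is_hit
    expect_true(all(stricter <= at_thr))   # raising enuc threshold never adds
    expect_true(all(at_thr <= looser_cn))  # lowering cellnum floor never removes
  }
})

test_that("the ranked report orders by enucleation fold with documented tie-breaks", {
  folds <- data.frame(
    name = c("mid", "top", "low", "tie-b", "tie-a"), concentration_uM = 10,
    enuc_fold = c(10.76, 11.60, 9.07, 10.00, 10.00),
    cellnum_fold = c(0.27, 0.46, 1.87, 0.4, 0.5))
  ranked <- rank_report(call_hits(folds))
  expect_equal(ranked$enucleation_fold, c(11.60, 10.76, 10.00, 10.00, 9.07))
  expect_equal(ranked$name[3:4], c("tie-a", "tie-b"))  # higher cellnum fold first
  # name ascending breaks exact double ties
  folds2 <- data.frame(name = c("zeta", "alpha"), concentration_uM = 10,
                       enuc_fold = 10, cellnum_fold = 0.5)
  expect_equal(rank_report(call_hits(folds2))$name, c("alpha", "zeta"))
  # folds render to 2 decimals, half-up
  folds3 <- data.frame(name = "x", concentration_uM = 10,
                       enuc_fold = 10.125, cellnum_fold = 0.375)
  r3 <- rank_report(call_hits(folds3))
  expect_equal(r3$enucleation_fold, 10.13)
  expect_equal(r3$cellnum_fold, 0.38)
  empty <- rank_report(call_hits(folds)[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("name", "enucleation_fold", "cellnum_fold") %in% names(empty)))
})
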