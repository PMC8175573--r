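test_that("hit-spec compounds carry their exact true folds", {
  lib <- make_library(3, hit_spec = data.frame(
    name = "TSA", true_enuc_fold = 11.60, true_cellnum_fold = 0.46), seed = 1)
  expect_equal(nrow(lib), 3)
  tsa <- lib[lib$name == "TSA", ]
  expect_equal(tsa$true_enuc_fold, 11.60)
  expect_equal(tsa$true_cellnum_fold, 0.46)
  expect_false(anyDuplicated(lib$compound_id) > 0)

  ident <- make_library(1, hit_spec = data.frame(
    name = "null", true_enuc_fold = 1, true_cellnum_fold = 1))
  expect_equal(ident$true_enuc_fold, 1)
  expect_equal(ident$true_cellnum_fold, 1)
})

test_that("null compounds sit near fold 1 with a small toxic tail", {
  lib <- make_library(2000, seed = 3)
  expect_true(all(lib$true_enuc_fold > 0))
  expect_true(all(abs(log(lib$true_enuc_fold)) < 0.5))
  toxic <- lib$true_cellnum_fold < 0.25
  expect_gt(mean(toxic), 0.01)
  expect_lt(mean(toxic), 0.12)
})

test_that("library generation is deterministic and validates folds", {
  expect_identical(make_library(100, seed = 7), make_library(100, seed = 7))
  expect_error(make_library(2, hit_spec = data.frame(
    name = "bad", true_enuc_fold = -1, true_cellnum_fold = 1)), "positive")
  expect_error(make_library(1, hit_spec = data.frame(
    name = c("a", "b"), true_enuc_fold = c(2, 2), true_cellnum_fold = c(1, 1))))
})

test_that("plate layouts test every compound at both concentrations with in-plate controls", {
  lib <- make_library(40, seed = 2)
  lay <- make_plate_layouts(lib, controls_per_plate = 8, seed = 1)
  test <- lay[lay$role == "test", ]
  expect_equal(nrow(test), 80)
  pairs <- unique(paste(test$compound_id, test$concentration_uM))
  expect_equal(length(pairs), 80)
  expect_setequal(unique(test$concentration_uM), c(0.5, 10))
  for (p in unique(lay$plate_id)) {
    ctrl <- lay[lay$plate_id == p & lay$role == "dmso", ]
    expect_equal(nrow(ctrl), 8)
    expect_equal(as.integer(table(ctrl$dmso_volume_class)), c(4L, 4L))
    expect_equal(anyDuplicated(lay$well[lay$plate_id == p]), 0L)
  }
  expect_equal(dmso_class_for(c(0.5, 10)), c("0.005%", "0.1%"))
})

test_that("a single-compound library yields one plate with two test wells", {
  lib <- make_library(1, seed = 1)
  lay <- make_plate_layouts(lib, controls_per_plate = 8, seed = 1)
  expect_equal(length(unique(lay$plate_id)), 1)
  expect_equal(sum(lay$role == "test"), 2)
  expect_identical(lay, make_plate_layouts(lib, controls_per_plate = 8, seed = 1))
  expect_error(make_plate_layouts(lib, controls_per_plate = 3), "2 DMSO")
})

test_that("well populations scale the enucleated fraction and stay normalized", {
  base <- preset_well_truth("dmso", 10000)
  # vehicle wells keep the baseline composition
  w <- sample_well_population("DMSO", base, seed = 1, well_address = "A01")
  expect_equal(sum(w$state_fractions), 1, tolerance = 1e-12)
  expect_equal(w$state_fractions[["enucleated"]], base$state_fractions[["enucleated"]])
  f <- w$state_fractions
  expect_equal(f[["enucleated"]] / (f[["enucleated"]] + f[["viable_nucleated"]]),
               0.04, tolerance = 1e-12)

  cpd <- data.frame(true_enuc_fold = 5, true_cellnum_fold = 0.5)
  w5 <- sample_well_population(cpd, base, seed = 1, well_address = "A02")
  expect_equal(w5$state_fractions[["enucleated"]],
               base$state_fractions[["enucleated"]] * 5)
  expect_equal(sum(w5$state_fractions), 1, tolerance = 1e-12)
  # non-enucleated states rescale proportionally
  r0 <- base$state_fractions[["dead_cell"]] / base$state_fractions[["free_nucleus"]]
  r5 <- w5$state_fractions[["dead_cell"]] / w5$state_fractions[["free_nucleus"]]
  expect_equal(r5, r0, tolerance = 1e-12)

  # enucleated fraction clamps at 0.95
  big <- data.frame(true_enuc_fold = 1000, true_cellnum_fold = 1)
  wb <- sample_well_population(big, base, seed = 1)
  expect_equal(wb$state_fractions[["enucleated"]], 0.95)
})

test_that("degenerate compositions are handled, not errored", {
  allv <- well_truth(100, c(viable_nucleated = 1, enucleated = 0,
                            dead_cell = 0, free_nucleus = 0))
  cpd <- data.frame(true_enuc_fold = 10, true_cellnum_fold = 1)
  w <- sample_well_population(cpd, allv, seed = 1)
  expect_equal(w$state_fractions[["enucleated"]], 0)
  expect_equal(w$state_fractions[["viable_nucleated"]], 1)
})

test_that("realized cell numbers follow Poisson(baseline x fold)", {
  base <- preset_well_truth("dmso", 10000)
  totals <- vapply(1:1000, function(i)
    sample_well_population("DMSO", base, seed = i,
                           well_address = sprintf("W%04d", i))$total_cells,
    integer(1))
  se <- sqrt(10000 / 1000)
  expect_lt(abs(mean(totals) - 10000), 3 * se)
  expect_equal(stats::var(totals) / 10000, 1, tolerance = 0.15)
})
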