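#' Construct a per-well ground-truth record
#'
#' @param total_cells Non-negative integer count of cells in the well.
#' @param state_fractions Named numeric vector over the four cell states,
#'   summing to 1.
#' @param rupture_fraction Fraction of enucleated cells rendered as damaged
#'   (fragmented) objects.
#' @param well_address Optional well address, e.g. `"B07"`.
#' @return A list of class `"well_truth"`.
#' @export
well_truth <- function(total_cells, state_fractions, rupture_fraction = 0,
                       well_address = NA_character_) {
  stop_if_not(total_cells >= 0, "total_cells must be >= 0")
  stop_if_not(setequal(names(state_fractions), STATES),
              "state_fractions must be named over the four cell states")
  state_fractions <- state_fractions[STATES]
  stop_if_not(all(state_fractions >= 0) &&
                abs(sum(state_fractions) - 1) <= 1e-9,
              "state_fractions must be non-negative and sum to 1 (tol 1e-9)")
  stop_if_not(rupture_fraction >= 0 && rupture_fraction <= 1,
              "rupture_fraction must be in [0, 1]")
  structure(list(total_cells = as.integer(round(total_cells)),
                 state_fractions = state_fractions,
                 rupture_fraction = rupture_fraction,
                 well_address = well_address),
            class = "well_truth")
}

#' Baseline well compositions for the vehicle and treated conditions
#'
#' Presets are parameterized on the screen's own statistic -- the enucleation
#' frequency among intact (viable nucleated + enucleated) cells -- which is
#' about 4% for vehicle-treated erythroid progenitor cultures and about 23%
#' after treatment with an enucleation-inducing HDAC inhibitor. Small dead-cell
#' and free-nucleus components are included; free nuclei are kept well below
#' the enucleated fraction because expelled nuclei lyse quickly in culture.
#'
#' @param condition `"dmso"` (vehicle) or `"treated"`.
#' @param total_cells Cells seeded per well (default 10,000).
#' @return A `"well_truth"` object.
#' @export
preset_well_truth <- function(condition = c("dmso", "treated"),
                              total_cells = 10000) {
  condition <- match.arg(condition)
  if (condition == "dmso") {
    dead <- 0.03; free <- 0.02; freq <- 0.04
  } else {
    dead <- 0.03; free <- 0.04; freq <- 0.23
  }
  intact <- 1 - dead - free
  fr <- c(viable_nucleated = intact * (1 - freq),
          enucleated = intact * freq,
          dead_cell = dead, free_nucleus = free)
  well_truth(total_cells, fr)
}

#' Apply a compound's true effects to a baseline well composition
#'
#' Draws the realized cell count as Poisson(baseline total x cell-number fold)
#' and scales the baseline enucleated fraction by the enucleation fold, clamped
#' at 0.95; the other state fractions are rescaled proportionally so the
#' composition stays a probability vector. Vehicle (DMSO) wells use folds of 1.
#'
#' @param compound One row of a [make_library()] data.frame, or `NULL` / the
#'   string `"DMSO"` for a vehicle well.
#' @param baseline A `"well_truth"` template (fractions sum to 1, total > 0).
#' @param seed Integer seed for the Poisson draw.
#' @param well_address Optional well address recorded on the result.
#' @return A `"well_truth"` with the compound's effects applied.
#' @export
sample_well_population <- function(compound, baseline, seed = 1,
                                   well_address = NA_character_) {
  stop_if_not(inherits(baseline, "well_truth"), "baseline must be a well_truth")
  stop_if_not(baseline$total_cells > 0, "baseline total must be > 0")
  if (is.null(compound) || identical(compound, "DMSO")) {
    enuc_fold <- 1; cellnum_fold <- 1
  } else {
    enuc_fold <- compound$true_enuc_fold
    cellnum_fold <- compound$true_cellnum_fold
    stop_if_not(is.finite(enuc_fold) && enuc_fold > 0 &&
                  is.finite(cellnum_fold) && cellnum_fold > 0,
                "compound folds must be positive")
  }
  fr <- baseline$state_fractions
  enuc <- min(max(fr[["enucleated"]] * enuc_fold, 0), 0.95)
  others <- fr[setdiff(STATES, "enucleated")]
  if (sum(others) > 0) {
    others <- others * (1 - enuc) / sum(others)
  } else {
    # baseline enucleated fraction was 1; composition stays all-enucleated
    enuc <- 1
  }
  fr_new <- c(others, enucleated = enuc)[STATES]

  set.seed(derive_seed(seed, "population", well_address))
  total <- stats::rpois(1, baseline$total_cells * cellnum_fold)
  well_truth(total, fr_new, rupture_fraction = baseline$rupture_fraction,
             well_address = well_address)
}
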