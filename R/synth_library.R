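#' Build a synthetic compound library with known true effects
#'
#' Each compound carries a ground-truth fold effect on the baseline enucleation
#' frequency (`true_enuc_fold`) and on the seeded cell number
#' (`true_cellnum_fold`). Compounds named in `hit_spec` get exactly the folds
#' given there; the remainder are null compounds with folds drawn near 1, plus
#' a small toxic tail with strongly reduced cell number, mimicking the mix a
#' real screen encounters.
#'
#' @param n_compounds Number of compounds (>= `nrow of hit_spec`).
#' @param hit_spec A data.frame with columns `name`, `true_enuc_fold`,
#'   `true_cellnum_fold` (may have zero rows), or a list of
#'   `list(name, enuc, cellnum)` triples.
#' @param seed Integer seed; the library is bit-reproducible for a fixed seed.
#' @param toxic_fraction Fraction of null compounds given a cytotoxic
#'   cell-number fold (drawn in `[0.02, 0.2]`).
#' @param library_tag Free-text tag recorded on every entry.
#' @return A data.frame with one row per compound: `compound_id`, `name`,
#'   `true_enuc_fold`, `true_cellnum_fold`, `library_tag`.
#' @export
make_library <- function(n_compounds, hit_spec = NULL, seed = 1,
                         toxic_fraction = 0.05, library_tag = "synthetic") {
  if (is.null(hit_spec)) {
    hit_spec <- data.frame(name = character(), true_enuc_fold = numeric(),
                           true_cellnum_fold = numeric())
  }
  if (is.list(hit_spec) && !is.data.frame(hit_spec)) {
    hit_spec <- do.call(rbind, lapply(hit_spec, function(h)
      data.frame(name = h[[1]], true_enuc_fold = as.numeric(h[[2]]),
                 true_cellnum_fold = as.numeric(h[[3]]))))
    if (is.null(hit_spec))
      hit_spec <- data.frame(name = character(), true_enuc_fold = numeric(),
                             true_cellnum_fold = numeric())
  }
  n_hits <- nrow(hit_spec)
  stop_if_not(n_compounds >= n_hits, "n_compounds must be >= number of hit_spec entries")
  if (n_hits > 0) {
    stop_if_not(all(hit_spec$true_enuc_fold > 0) && all(hit_spec$true_cellnum_fold > 0),
                "hit_spec folds must be positive")
  }

  n_null <- n_compounds - n_hits
  set.seed(derive_seed(seed, "library"))
  enuc <- exp(stats::rnorm(n_null, 0, 0.05))
  cellnum <- exp(stats::rnorm(n_null, 0, 0.05))
  toxic <- stats::runif(n_null) < toxic_fraction
  cellnum[toxic] <- stats::runif(sum(toxic), 0.02, 0.2)

  out <- data.frame(
    compound_id = sprintf("CPD%04d", seq_len(n_compounds)),
    name = c(as.character(hit_spec$name),
             if (n_null > 0) sprintf("null-%04d", seq_len(n_null)) else character()),
    true_enuc_fold = c(hit_spec$true_enuc_fold, enuc),
    true_cellnum_fold = c(hit_spec$true_cellnum_fold, cellnum),
    library_tag = library_tag,
    stringsAsFactors = FALSE
  )
  out
}

# 96-well addresses in row-major order: A1 ... H12
well_addresses <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

# volume class of the DMSO control matching each test concentration
dmso_class_for <- function(conc_uM) {
  ifelse(conc_uM == 0.5, "0.005%", "0.1%")
}

#' Lay out a compound library across 96-well plates
#'
#' Every compound is tested at both concentrations (0.5 and 10 uM by default).
#' Each plate carries its own DMSO control wells, split evenly between the two
#' volume classes matching the two test concentrations, so plate-local
#' normalization is always possible. Remaining wells on the last plate are
#' marked `empty`.
#'
#' @param library Data.frame from [make_library()].
#' @param controls_per_plate Total DMSO wells per plate (even, >= 4 so each
#'   volume class has at least 2 wells).
#' @param concentrations Test concentrations in micromolar.
#' @param seed Integer seed controlling the shuffle of compounds across plates.
#' @return A data.frame with one row per well: `plate_id`, `well`, `role`
#'   (`test`/`dmso`/`empty`), `compound_id`, `name`, `concentration_uM`,
#'   `dmso_volume_class`.
#' @export
make_plate_layouts <- function(library, controls_per_plate = 8,
                               concentrations = c(0.5, 10), seed = 1) {
  stop_if_not(nrow(library) >= 1, "library too small: need at least one compound")
  stop_if_not(controls_per_plate >= 2 * length(concentrations) &&
                controls_per_plate %% length(concentrations) == 0,
              "need at least 2 DMSO wells per volume class, evenly split")
  stop_if_not(!anyDuplicated(library$compound_id),
              "compound_id must be unique within a library")
  n_test_per_plate <- 96 - controls_per_plate
  stop_if_not(n_test_per_plate >= 1, "controls_per_plate leaves no test wells")

  set.seed(derive_seed(seed, "layout"))
  ord <- sample.int(nrow(library))
  pairs <- expand.grid(idx = ord, concentration_uM = concentrations)
  pairs <- pairs[order(match(pairs$idx, ord), pairs$concentration_uM), ]

  addresses <- well_addresses()
  # controls at evenly spaced positions, alternating volume class
  ctrl_pos <- round(seq(1, 96, length.out = controls_per_plate))
  n_plates <- ceiling(nrow(pairs) / n_test_per_plate)

  plates <- lapply(seq_len(n_plates), function(p) {
    take <- pairs[((p - 1) * n_test_per_plate + 1):min(p * n_test_per_plate, nrow(pairs)), ]
    role <- rep("test", 96)
    role[ctrl_pos] <- "dmso"
    test_slots <- which(role == "test")
    if (nrow(take) < length(test_slots))
      role[test_slots[(nrow(take) + 1):length(test_slots)]] <- "empty"
    test_slots <- which(role == "test")
    df <- data.frame(
      plate_id = sprintf("P%03d", p), well = addresses, role = role,
      compound_id = NA_character_, name = NA_character_,
      concentration_uM = NA_real_, dmso_volume_class = NA_character_,
      stringsAsFactors = FALSE
    )
    df$compound_id[test_slots] <- library$compound_id[take$idx]
    df$name[test_slots] <- library$name[take$idx]
    df$concentration_uM[test_slots] <- take$concentration_uM
    df$dmso_volume_class[test_slots] <- dmso_class_for(take$concentration_uM)
    ctrl <- which(role == "dmso")
    df$name[ctrl] <- "DMSO"
    df$dmso_volume_class[ctrl] <- rep(c("0.005%", "0.1%"), length.out = length(ctrl))
    df
  })
  do.call(rbind, plates)
}
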