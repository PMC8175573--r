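#' Default per-state signal model for simulated flow-cytometry events
#'
#' Flow signals follow the flow assay's conventions, which differ from the
#' imaging assay on free nuclei: in flow, membrane-intact extruded nuclei are
#' negative for the impermeant dye (7AAD) and positive for SYTO 16, whereas in
#' imaging extruded nuclei stain with the impermeant dye. Enucleated cells and
#' free nuclei sit low on forward scatter (FSC); viable and dead whole cells
#' sit high.
#'
#' @return A list with per-state log-normal location (`meanlog`) and a common
#'   `sdlog` per signal.
#' @export
default_flow_model <- function() {
  loc <- rbind(  #            fsc  syto16  aad7   kuo
    viable_nucleated = log(c(10.0, 1000,     30, 1000)),
    enucleated       = log(c( 3.0,   30,     30, 1000)),
    dead_cell        = log(c( 8.0, 1000,   1000, 1000)),
    free_nucleus     = log(c( 2.5, 1000,     30,   30))
  )
  colnames(loc) <- c("fsc", "syto16", "aad7", "kuo")
  list(meanlog = loc,
       sdlog = c(fsc = 0.25, syto16 = 0.35, aad7 = 0.35, kuo = 0.35))
}

#' Simulate flow-cytometry events for a well
#'
#' Event states are drawn from the well's ground-truth composition; each
#' event's four signals (FSC, SYTO 16, 7AAD, KuO) are drawn log-normally
#' around the state-specific medians of `signal_model`.
#'
#' @param truth A `"well_truth"` object.
#' @param n_events Number of events to draw (>= 0).
#' @param signal_model From [default_flow_model()].
#' @param seed Integer seed; event tables are bit-reproducible.
#' @return A data.frame with columns `fsc`, `syto16`, `aad7`, `kuo`,
#'   `true_state`.
#' @export
simulate_flow_events <- function(truth, n_events, signal_model = default_flow_model(),
                                 seed = 1) {
  stop_if_not(n_events >= 0, "n_events must be >= 0")
  stop_if_not(all(STATES %in% rownames(signal_model$meanlog)),
              "signal model must cover all four states")
  empty <- data.frame(fsc = numeric(), syto16 = numeric(), aad7 = numeric(),
                      kuo = numeric(), true_state = character())
  if (n_events == 0) return(empty)
  set.seed(derive_seed(seed, "flow", truth$well_address))
  states <- sample(STATES, n_events, replace = TRUE,
                   prob = truth$state_fractions)
  sig <- lapply(colnames(signal_model$meanlog), function(s)
    stats::rlnorm(n_events, signal_model$meanlog[states, s],
                  signal_model$sdlog[[s]]))
  names(sig) <- colnames(signal_model$meanlog)
  out <- as.data.frame(sig)
  out$true_state <- states
  out
}
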