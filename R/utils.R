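#' @keywords internal
"_PACKAGE"

# Canonical channel and state vocabularies used across the pipeline.
CHANNELS <- c("KuO", "SYTO16", "SYTOXRed")
STATES <- c("viable_nucleated", "enucleated", "dead_cell", "free_nucleus")
ALL_STATES <- c(STATES, "debris")

#' Derive a reproducible integer sub-seed from a master seed and labels
#'
#' All stochastic emitters in the package draw from sub-streams derived from a
#' single master seed plus string labels (plate, well, field, stage), so any
#' plate, well or field can be regenerated in isolation, bit-identically,
#' without replaying the whole screen.
#'
#' @param seed Master seed (integer).
#' @param ... Character or numeric labels identifying the sub-stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  h <- 0
  m <- 2147483647
  for (b in utf8ToInt(labels)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# round-half-up to `digits` decimals (base round() is half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
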