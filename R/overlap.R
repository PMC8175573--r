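#' Two-list overlap summary (Venn counts and percentage of union)
#'
#' Either pass two identifier vectors, or the three counts directly. The
#' percentage of the union that is shared is rounded half-up to one decimal,
#' matching the convention of printed Venn-diagram frequencies.
#'
#' @param a,b Character vectors of identifiers (duplicates ignored), or, if
#'   `counts` is given, unused.
#' @param counts Optional numeric vector `c(n_a, n_b, n_common)`.
#' @return A list of class `"overlap_summary"`: `n_a`, `n_b`, `n_common`,
#'   `n_union`, `pct_common_of_union` (one decimal; `NA` with a warning when
#'   the union is empty).
#' @export
overlap_summary <- function(a = NULL, b = NULL, counts = NULL) {
  if (is.null(counts)) {
    a <- unique(a); b <- unique(b)
    counts <- c(length(a), length(b), length(intersect(a, b)))
  }
  stop_if_not(length(counts) == 3 && all(counts >= 0),
              "counts must be three non-negative numbers (n_a, n_b, n_common)")
  n_a <- counts[[1]]; n_b <- counts[[2]]; n_common <- counts[[3]]
  stop_if_not(n_common <= min(n_a, n_b), "n_common cannot exceed min(n_a, n_b)")
  n_union <- n_a + n_b - n_common
  if (n_union == 0) {
    warning("empty union; percentage undefined")
    pct <- NA_real_
  } else {
    pct <- round_half_up(100 * n_common / n_union, 1)
  }
  structure(list(n_a = n_a, n_b = n_b, n_common = n_common, n_union = n_union,
                 pct_common_of_union = pct),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap: %d of union %d (%.1f%%); |A|=%d |B|=%d\n",
              x$n_common, x$n_union, x$pct_common_of_union, x$n_a, x$n_b))
  invisible(x)
}
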