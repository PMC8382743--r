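#' Per-cell channel normalisation
#'
#' Appends the per-cell ratio of two measured channels, e.g. reporter GFP
#' normalised by the nuclear stain.  Cells whose denominator is at or below
#' `epsilon` are excluded (their count is kept in the `n_excluded`
#' attribute); a denominator channel that is zero for every cell is an
#' error.
#'
#' @param table Cell table from [measure_cells()].
#' @param numerator,denominator Channel names (without the `_mean` suffix),
#'   e.g. `"gfp"` and `"nuclear"`.
#' @param epsilon Exclusion threshold for the denominator (default 0:
#'   exclude only non-positive denominators).
#' @return The filtered table with a new `<numerator>_over_<denominator>`
#'   column and attribute `n_excluded`.
#' @export
normalize_channel <- function(table, numerator, denominator, epsilon = 0) {
  num_col <- paste0(numerator, "_mean")
  den_col <- paste0(denominator, "_mean")
  for (col in c(num_col, den_col)) {
    if (!col %in% names(table)) {
      abort(paste0("column not found: ", col,
                   " (was this channel measured?)"))
    }
  }
  den <- table[[den_col]]
  if (nrow(table) > 0 && all(den == 0)) {
    abort(paste0("denominator channel '", denominator,
                 "' is zero for every cell"))
  }
  keep <- den > epsilon
  out <- table[keep, , drop = FALSE]
  ratio_col <- paste0(numerator, "_over_", denominator)
  out[[ratio_col]] <- out[[num_col]] / out[[den_col]]
  for (a in c("pixel_size", "chamber_id", "condition")) {
    attr(out, a) <- attr(table, a, exact = TRUE)
  }
  attr(out, "n_excluded") <- sum(!keep)
  out
}
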