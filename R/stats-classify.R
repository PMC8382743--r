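#' High-expressor classification against a control population
#'
#' Classifies cells as "high" for a marker when their value strictly
#' exceeds `k` times the median of a control population (default `k = 2`,
#' i.e. twice the control median).  A value exactly at the threshold is not
#' high.  The rule is scale-invariant: multiplying all values and controls
#' by any positive constant leaves the classification unchanged.
#'
#' @param values Numeric marker values of the cells to classify.
#' @param control Numeric marker values of the control population
#'   (non-empty).
#' @param k Threshold multiplier (> 0, default 2).
#' @return A list with `high` (logical per cell), `fraction_high`,
#'   `threshold` (`k * median(control)`), `k` and `n`.
#' @export
#' @examples
#' classify_high(c(21, 19, 20), control = c(8, 10, 12))$high
classify_high <- function(values, control, k = 2) {
  if (length(control) == 0L) abort("`control` must be non-empty")
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    abort("`k` must be a single positive number")
  }
  threshold <- k * median(control)
  high <- values > threshold
  structure(
    list(high = high,
         fraction_high = if (length(high)) mean(high) else NA_real_,
         threshold = threshold, k = k,
         n = c(test = length(values), control = length(control))),
    class = "memic_classification"
  )
}

#' @export
print.memic_classification <- function(x, ...) {
  cat(sprintf(paste0("<high-expressor classification> threshold = %.4g ",
                     "(k = %g), %.1f%% high (n = %d vs %d control)\n"),
              x$threshold, x$k, 100 * x$fraction_high, x$n[["test"]],
              x$n[["control"]]))
  invisible(x)
}

#' @rdname classify_high
#' @param x A `memic_classification`.
#' @param ... Unused.
#' @method tidy memic_classification
#' @export
tidy.memic_classification <- function(x, ...) {
  tibble::tibble(fraction_high = x$fraction_high, threshold = x$threshold,
                 k = x$k, n_test = x$n[["test"]],
                 n_control = x$n[["control"]])
}
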